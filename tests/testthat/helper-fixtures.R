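# Shared fixtures: small synthetic sessions (cached per test run) and a
# von Mises sampler for circular-statistics tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a compact two-task session for fast unit tests
small_session <- function() {
  cached("small", make_session(sim_config(
    n_units = 24, tasks = c("A", "B"), trials_per_condition = 12,
    n_bins = 40, seed = 101)))
}

# full default-design session (all five tasks) for cross-task tests
full_session <- function() {
  cached("full", make_session(sim_config(seed = 202)))
}

# random session-like object with arbitrary labels for oracle tests
random_session <- function(seed, m = 30, n = 6, tt = 12) {
  set.seed(seed)
  stim <- sample(c("s1", "s2"), m, replace = TRUE)
  dec <- sample(c("up", "down"), m, replace = TRUE)
  # guarantee all cells occupied
  stim[1:4] <- c("s1", "s1", "s2", "s2")
  dec[1:4] <- c("up", "down", "up", "down")
  go <- rep(1, m)
  rel <- go + runif(m, 0.1, 0.3)
  structure(list(
    spike_counts = array(rpois(m * n * tt, 1.5), c(m, n, tt)),
    trials = data.frame(trial_id = seq_len(m), task = "A", stimulus = stim,
                        decision = dec, outcome = rbinom(m, 1, 0.7)),
    event_times = data.frame(grip_t = rep(-0.5, m), stim_on_t = rep(0, m),
                             go_t = go, release_t = rel,
                             touch_t = rel + runif(m, 0.05, 0.2)),
    bin_ms = 10,
    meta = list(seed = seed, n_units = n, n_bins = tt, tasks = "A",
                format_version = 1L)
  ), class = "session_data")
}

# Best-Fisher (1979) von Mises sampler; mean direction mu in radians
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

# permutation test for equality of two circular means: statistic is the
# absolute angular difference between group mean directions
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

perm_circ_test <- function(a, b, n_perm = 10000) {
  pool_cos <- cos(c(a, b))
  pool_sin <- sin(c(a, b))
  n1 <- length(a)
  n <- length(pool_cos)
  stat <- function(idx1) {
    m1 <- atan2(mean(pool_sin[idx1]), mean(pool_cos[idx1]))
    m2 <- atan2(mean(pool_sin[-idx1]), mean(pool_cos[-idx1]))
    d <- abs(m1 - m2) %% (2 * pi)
    min(d, 2 * pi - d)
  }
  obs <- stat(seq_len(n1))
  perms <- vapply(seq_len(n_perm), function(i) stat(sample.int(n, n1)),
                  numeric(1))
  mean(perms >= obs)
}
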