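# Synthetic multi-task sessions with known latent geometry.
#
# The generator builds a low-dimensional latent space in which
#   * all tasks share a single decision axis (latent coordinate 1),
#   * each task owns a private set of stimulus axes, the first of which is
#     tilted toward the decision axis by exactly `target_angle_deg`,
#   * same-mapping tasks (A, B, C, Revisit-A) share decision dynamics up to
#     a controlled temporal mixture realizing a cross-task trajectory
#     correlation of exactly `reuse_rho`,
#   * the reversed task flips the sign of the decision dynamics relative to
#     the actual decision, emulating activity that follows the original
#     stimulus->decision rule rather than the executed decision.
# Latents map to unit firing rates through an orthogonal-column loading
# matrix and a softplus nonlinearity; spike counts are Poisson per bin.

#' Simulation configuration for a synthetic multi-task session
#'
#' @param n_units number of recorded units (>= latent dimensionality).
#' @param n_stimuli_per_task stimuli per task (2 for the standard pair
#'   design; up to 6 supported).
#' @param tasks character vector of task names. Names containing
#'   `"Reverse"` use the inverted stimulus->decision mapping; names
#'   containing `"Revisit"` reuse task A's stimulus identities. All other
#'   tasks get fresh stimuli. The first task plays the role of task A.
#' @param trials_per_condition trials per (task, stimulus, decision) cell;
#'   the default design is balanced.
#' @param n_bins number of time bins in the analysis epoch (default 100
#'   bins of 10 ms covering the 1 s window before the go cue).
#' @param bin_ms bin width in milliseconds.
#' @param baseline_rate baseline firing rate in spikes/s.
#' @param signal_gain dimensionless multiplier on all task-related latent
#'   amplitudes; 0 yields pure baseline Poisson activity.
#' @param target_angle_deg target smallest principal angle, in degrees
#'   within \[0, 90\], between the stimulus-related and decision latent
#'   subspaces.
#' @param reuse_rho target correlation, in \[-1, 1\], between the decision
#'   trajectories of task A and of every other same-mapping task.
#' @param reverse_flips_decision if TRUE, reversed tasks carry decision
#'   dynamics of opposite sign relative to the executed decision.
#' @param seed integer seed; the session is deterministic given the config.
#' @return an object of class `sim_config`.
#' @seealso [make_session()]
#' @export
sim_config <- function(n_units = 60,
                       n_stimuli_per_task = 2,
                       tasks = c("A", "B", "C", "Revisit-A", "Reverse-A"),
                       trials_per_condition = 50,
                       n_bins = 100,
                       bin_ms = 10,
                       baseline_rate = 10,
                       signal_gain = 1,
                       target_angle_deg = 90,
                       reuse_rho = 1,
                       reverse_flips_decision = TRUE,
                       seed = 1) {
  cfg <- list(
    n_units = assert_count(n_units, "n_units"),
    n_stimuli_per_task = assert_count(n_stimuli_per_task,
                                      "n_stimuli_per_task"),
    tasks = as.character(tasks),
    trials_per_condition = assert_count(trials_per_condition,
                                        "trials_per_condition"),
    n_bins = assert_count(n_bins, "n_bins", min = 4),
    bin_ms = assert_scalar(bin_ms, "bin_ms", lo = 1e-6),
    baseline_rate = assert_scalar(baseline_rate, "baseline_rate", lo = 1e-6),
    signal_gain = assert_scalar(signal_gain, "signal_gain", lo = 0),
    target_angle_deg = assert_scalar(target_angle_deg, "target_angle_deg",
                                     lo = 0, hi = 90),
    reuse_rho = assert_scalar(reuse_rho, "reuse_rho", lo = -1, hi = 1),
    reverse_flips_decision = isTRUE(reverse_flips_decision),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (length(cfg$tasks) < 1 || anyDuplicated(cfg$tasks)) {
    stop("`tasks` must be a non-empty vector of unique task names")
  }
  if (cfg$n_stimuli_per_task > 6) {
    stop("at most 6 stimuli per task are supported")
  }
  latent_dim <- 2 + length(cfg$tasks) * cfg$n_stimuli_per_task
  if (latent_dim > cfg$n_units) {
    stop(sprintf(paste0("latent dimensionality %d (2 + tasks x stimuli) ",
                        "exceeds n_units = %d"),
                 latent_dim, cfg$n_units))
  }
  class(cfg) <- "sim_config"
  cfg
}

task_role <- function(task_names) {
  role <- rep("new", length(task_names))
  role[grepl("Reverse", task_names, ignore.case = TRUE)] <- "reverse"
  role[grepl("Revisit", task_names, ignore.case = TRUE)] <- "revisit"
  role[1] <- "A"
  role
}

# Standardize to zero mean, unit SD over the time grid.
standardize_wave <- function(w) {
  w <- w - mean(w)
  s <- sd(w)
  if (s == 0) stop("degenerate waveform")
  w / s
}

# Half-cosine ramp: smooth pre-movement build-up over the epoch.
ramp_wave <- function(n_bins) {
  x <- seq(0, 1, length.out = n_bins)
  standardize_wave((1 - cos(pi * x)) / 2)
}

# A family of smooth waveforms, each standardized and exactly orthogonal
# (zero Pearson correlation on the grid) to `base` and to one another.
orthogonal_waveforms <- function(n_bins, n, base) {
  x <- seq(0, 1, length.out = n_bins)
  out <- matrix(0, n_bins, n)
  basis <- cbind(1, base)
  k <- 1
  for (i in seq_len(n)) {
    repeat {
      cand <- cos(k * pi * x + 0.3 * k)
      k <- k + 1
      resid <- cand - basis %*% qr.solve(basis, cand)
      if (sd(resid) > 1e-6) break
      if (k > 50 * n) stop("could not construct orthogonal waveforms")
    }
    w <- standardize_wave(resid)
    out[, i] <- w
    basis <- cbind(basis, w)
  }
  out
}

#' Generate a synthetic multi-task session with known ground truth
#'
#' Constructs latent trajectories per (task, stimulus, decision) condition,
#' maps them to unit firing rates through an orthogonal loading matrix and
#' a softplus nonlinearity, and draws Poisson spike counts per bin. The
#' design is balanced: every (task, stimulus, decision) cell receives
#' `trials_per_condition` trials, emulating a subject that samples both
#' decisions for every stimulus while learning.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `session` (class `session_data`: the
#'   trials x units x bins count tensor plus trial labels and event times)
#'   and `ground_truth` (class `ground_truth`: latent axes, loading matrix,
#'   realized angle and reuse, latent time courses).
#' @examples
#' out <- make_session(sim_config(n_units = 20, tasks = c("A", "B"),
#'                                trials_per_condition = 5, seed = 42))
#' dim(out$session$spike_counts)
#' out$ground_truth$realized_angle_deg
#' @export
make_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_tasks <- length(config$tasks)
  n_stim <- config$n_stimuli_per_task
  n_units <- config$n_units
  n_bins <- config$n_bins
  roles <- task_role(config$tasks)
  latent_dim <- 2 + n_tasks * n_stim

  # --- latent time courses ------------------------------------------------
  s_wave <- ramp_wave(n_bins)                       # task A decision dynamics
  extra <- orthogonal_waveforms(n_bins, n_tasks - 1 + n_stim + 1, s_wave)
  h_waves <- extra[, seq_len(max(n_tasks - 1, 1)), drop = FALSE]
  stim_waves <- extra[, (n_tasks - 1) + seq_len(n_stim), drop = FALSE]
  ci_wave <- extra[, ncol(extra)]

  rho <- config$reuse_rho
  dec_tc <- matrix(0, n_bins, n_tasks,
                   dimnames = list(NULL, config$tasks))
  realized_reuse <- numeric(n_tasks)
  names(realized_reuse) <- config$tasks
  for (i in seq_len(n_tasks)) {
    if (roles[i] == "A") {
      u <- s_wave
    } else {
      u <- rho * s_wave + sqrt(max(0, 1 - rho^2)) * h_waves[, i - 1]
    }
    if (roles[i] == "reverse" && config$reverse_flips_decision) u <- -u
    dec_tc[, i] <- u
    realized_reuse[i] <- stats::cor(s_wave, u)
  }

  # --- latent axes --------------------------------------------------------
  theta <- config$target_angle_deg * pi / 180
  dec_axis <- c(1, rep(0, latent_dim - 1))          # e1
  ci_axis <- c(0, 1, rep(0, latent_dim - 2))        # e2
  stim_axes <- array(0, c(latent_dim, n_stim, n_tasks),
                     dimnames = list(NULL, NULL, config$tasks))
  for (i in seq_len(n_tasks)) {
    own <- 2 + (i - 1) * n_stim + seq_len(n_stim)   # private coordinates
    for (k in seq_len(n_stim)) {
      v <- rep(0, latent_dim)
      if (k == 1) {
        v[1] <- cos(theta)
        v[own[1]] <- sin(theta)
      } else {
        v[own[k]] <- 1
      }
      stim_axes[, k, i] <- v
    }
  }
  # realized angle between decision span and task A's stimulus span
  u_s <- qr.Q(qr(stim_axes[, , 1, drop = FALSE][, , 1]))
  sv <- svd(crossprod(matrix(dec_axis, ncol = 1), u_s))$d
  realized_angle <- acos(min(1, max(sv))) * 180 / pi

  # --- trial table --------------------------------------------------------
  decisions <- c("up", "down")
  stim_names_for <- function(i) {
    prefix <- if (roles[i] %in% c("revisit", "reverse")) {
      config$tasks[1]
    } else {
      config$tasks[i]
    }
    paste0(prefix, seq_len(n_stim))
  }
  map_decision <- function(i, k) {
    base <- decisions[(k - 1) %% 2 + 1]             # odd stimuli -> up
    if (roles[i] == "reverse") decisions[decisions != base] else base
  }

  out <- with_seed(config$seed, {
    loading <- qr.Q(qr(matrix(rnorm(n_units * latent_dim), n_units))) *
      sqrt(n_units)
    b0 <- softplus_inv(config$baseline_rate)
    amp_dec <- 4 * config$signal_gain
    amp_stim <- 4 * config$signal_gain
    amp_ci <- 2 * config$signal_gain
    bin_s <- config$bin_ms / 1000
    tpc <- config$trials_per_condition

    trials <- list()
    counts <- list()
    trial_id <- 0L
    for (i in seq_len(n_tasks)) {
      stim_names <- stim_names_for(i)
      block <- list()
      block_counts <- list()
      for (k in seq_len(n_stim)) {
        for (d in seq_along(decisions)) {
          z <- amp_ci * outer(ci_axis, ci_wave) +
            amp_stim * outer(stim_axes[, k, i], stim_waves[, k]) +
            amp_dec * ifelse(decisions[d] == "up", 1, -1) *
              outer(dec_axis, dec_tc[, i])
          rate <- softplus(b0 + loading %*% z)      # units x bins, spikes/s
          lam <- as.vector(rate) * bin_s
          draw <- matrix(rpois(tpc * length(lam), rep(lam, each = tpc)),
                         nrow = tpc)
          block_counts[[length(block_counts) + 1L]] <- draw
          block[[length(block) + 1L]] <- data.frame(
            task = config$tasks[i],
            stimulus = stim_names[k],
            decision = decisions[d],
            outcome = as.integer(decisions[d] == map_decision(i, k)),
            stringsAsFactors = FALSE
          )[rep(1, tpc), , drop = FALSE]
        }
      }
      tab <- do.call(rbind, block)
      cmat <- do.call(rbind, block_counts)
      ord <- sample.int(nrow(tab))                  # shuffle within the block
      trials[[i]] <- tab[ord, , drop = FALSE]
      counts[[i]] <- cmat[ord, , drop = FALSE]
      trial_id <- trial_id + nrow(tab)
    }
    tab <- do.call(rbind, trials)
    cmat <- do.call(rbind, counts)
    m <- nrow(tab)
    tab$trial_id <- seq_len(m)
    rownames(tab) <- NULL

    go_t <- rep(1.0, m)
    release_t <- go_t + runif(m, 0.15, 0.35)
    events <- data.frame(
      grip_t = rep(-0.5, m),
      stim_on_t = rep(0.0, m),
      go_t = go_t,
      release_t = release_t,
      touch_t = release_t + runif(m, 0.1, 0.2)
    )

    spikes <- array(as.integer(cmat), dim = c(m, n_units, n_bins))
    list(loading = loading, tab = tab, events = events, spikes = spikes)
  })

  session <- structure(list(
    spike_counts = out$spikes,
    trials = out$tab[, c("trial_id", "task", "stimulus", "decision",
                         "outcome")],
    event_times = out$events,
    bin_ms = config$bin_ms,
    meta = list(seed = config$seed, n_units = n_units, n_bins = n_bins,
                tasks = config$tasks, format_version = 1L)
  ), class = "session_data")
  validate_session(session)

  gt <- structure(list(
    decision_axes = matrix(dec_axis, latent_dim, n_tasks,
                           dimnames = list(NULL, config$tasks)),
    stimulus_axes = stim_axes,
    loading_matrix = out$loading,
    realized_angle_deg = realized_angle,
    realized_reuse = realized_reuse,
    latent_time_courses = list(decision = dec_tc, stimulus = stim_waves,
                               condition_independent = ci_wave),
    task_roles = roles,
    config = config
  ), class = "ground_truth")

  list(session = session, ground_truth = gt)
}

#' Validate a session object
#'
#' Checks the invariants of the `session_data` container: nonnegative
#' integer counts, label/table lengths matching the trial dimension, and
#' ordered event times.
#'
#' @param session a `session_data` object.
#' @return the session, invisibly; errors describe the violated invariant.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_data"))
  x <- session$spike_counts
  if (length(dim(x)) != 3) stop("spike_counts must be trials x units x bins")
  if (any(x < 0) || any(x != round(x))) {
    stop("spike_counts entries must be nonnegative integers")
  }
  m <- dim(x)[1]
  if (nrow(session$trials) != m) {
    stop(sprintf("trial table has %d rows but tensor has %d trials",
                 nrow(session$trials), m))
  }
  if (nrow(session$event_times) != m) {
    stop("event_times must have one row per trial")
  }
  ev <- session$event_times
  ok <- ev$grip_t < ev$stim_on_t & ev$stim_on_t < ev$go_t &
    ev$go_t <= ev$release_t & ev$release_t < ev$touch_t
  if (!all(ok, na.rm = TRUE)) {
    stop("event times must satisfy grip < stim_on < go <= release < touch")
  }
  invisible(session)
}

#' @export
print.session_data <- function(x, ...) {
  d <- dim(x$spike_counts)
  cat(sprintf("<session_data> %d trials x %d units x %d bins (%g ms)\n",
              d[1], d[2], d[3], x$bin_ms))
  cat("tasks:", paste(unique(x$trials$task), collapse = ", "), "\n")
  invisible(x)
}

#' Behavioral simulation configuration
#'
#' @param n_trials number of trials.
#' @param start_accuracy,asymptote_accuracy initial and asymptotic success
#'   probabilities (asymptote >= start).
#' @param learning_rate per-trial exponential approach rate toward the
#'   asymptote.
#' @param seed integer seed.
#' @return an object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_trials = 100,
                                start_accuracy = 0.5,
                                asymptote_accuracy = 0.95,
                                learning_rate = 0.05,
                                seed = 1) {
  cfg <- list(
    n_trials = assert_count(n_trials, "n_trials"),
    start_accuracy = assert_scalar(start_accuracy, "start_accuracy", 0, 1),
    asymptote_accuracy = assert_scalar(asymptote_accuracy,
                                       "asymptote_accuracy", 0, 1),
    learning_rate = assert_scalar(learning_rate, "learning_rate", lo = 0),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (cfg$asymptote_accuracy < cfg$start_accuracy) {
    stop("asymptote_accuracy must be >= start_accuracy")
  }
  class(cfg) <- "behavior_sim_config"
  cfg
}

#' Simulate a binary outcome sequence under saturating-exponential learning
#'
#' Success probability follows
#' `p_t = asymptote - (asymptote - start) * exp(-learning_rate * (t - 1))`.
#'
#' @param config a [behavior_sim_config()] object.
#' @return integer vector of 0/1 outcomes.
#' @export
make_behavior_sequence <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  t <- seq_len(config$n_trials) - 1
  p <- config$asymptote_accuracy -
    (config$asymptote_accuracy - config$start_accuracy) *
    exp(-config$learning_rate * t)
  with_seed(config$seed, rbinom(config$n_trials, 1, p))
}
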