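# Marginalization decomposition and demixed component fitting.

# nested-loop factorial-mean oracle
brute_marginalize <- function(x) {
  d <- dim(x)
  x_t <- array(0, d); x_ts <- array(0, d); x_td <- array(0, d)
  for (n in seq_len(d[1])) {
    for (t in seq_len(d[4])) {
      mt <- mean(x[n, , , t])
      for (s in seq_len(d[2])) {
        for (dd in seq_len(d[3])) {
          x_t[n, s, dd, t] <- mt
          x_ts[n, s, dd, t] <- mean(x[n, s, , t]) - mt
          x_td[n, s, dd, t] <- mean(x[n, , dd, t]) - mt
        }
      }
    }
  }
  list(x_t = x_t, x_ts = x_ts, x_td = x_td,
       x_tsd = x - x_t - x_ts - x_td)
}

test_that("marginalization handles degenerate single-factor tensors", {
  d <- c(4, 3, 2, 6)
  const <- array(2.5, d)
  m <- marginalize(const)
  expect_equal(m$x_t, const, tolerance = 1e-14)
  expect_equal(max(abs(m$x_ts)), 0, tolerance = 1e-14)
  expect_equal(max(abs(m$x_td)), 0, tolerance = 1e-14)
  expect_equal(max(abs(m$x_tsd)), 0, tolerance = 1e-14)

  # decision-only dependence: all variance in x_td
  dec_only <- array(0, d)
  base <- matrix(rnorm(4 * 6), 4, 6)
  for (dd in 1:2) for (s in 1:3) dec_only[, s, dd, ] <- (-1)^dd * base
  m2 <- marginalize(dec_only)
  expect_equal(max(abs(m2$x_ts)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m2$x_tsd)), 0, tolerance = 1e-12)
  expect_equal(m2$x_t + m2$x_td, dec_only, tolerance = 1e-12)

  expect_error(marginalize(array(1, c(3, 1, 1, 5))), "nothing to demix")
})

test_that("marginalization matches the nested-loop oracle exactly", {
  set.seed(11)
  for (rep in 1:5) {
    d <- c(sample(3:6, 1), sample(2:4, 1), 2, sample(4:8, 1))
    x <- array(rnorm(prod(d)), d)
    m <- marginalize(x)
    o <- brute_marginalize(x)
    expect_lt(max(abs(m$x_t - o$x_t)), 1e-10)
    expect_lt(max(abs(m$x_ts - o$x_ts)), 1e-10)
    expect_lt(max(abs(m$x_td - o$x_td)), 1e-10)
    expect_lt(max(abs(m$x_tsd - o$x_tsd)), 1e-10)
    # exact reconstruction
    expect_lt(max(abs(m$x_t + m$x_ts + m$x_td + m$x_tsd - x)), 1e-10)
    # zero mean over marginalized factors
    expect_lt(max(abs(apply(m$x_ts, c(1, 3, 4), mean))), 1e-12)
    expect_lt(max(abs(apply(m$x_td, c(1, 2, 4), mean))), 1e-12)
    # balanced orthogonality: term variances add to total (after centering)
    xc <- x - mean(x)
    mc <- marginalize(xc)
    expect_lt(abs(sum(vapply(list(mc$x_t, mc$x_ts, mc$x_td, mc$x_tsd),
                             function(a) sum(a^2), numeric(1))) - sum(xc^2)),
              1e-8)
  }
})

# fixture with known orthogonal factor subspaces, one direction per wave:
# full-rank total covariance, marginalization ranks summing to n_units
structured_cond <- function() {
  n <- 5; S <- 2; D <- 2; TT <- 12
  set.seed(21)
  q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  wave <- function(k) {
    w <- sin(k * seq_len(TT) / 2 + k)
    w - mean(w)
  }
  x <- array(0, c(n, S, D, TT))
  for (s in 1:S) {
    for (dd in 1:D) {
      tc <- outer(q[, 1], wave(1)) + outer(q[, 2], wave(2)) +      # time
        (-1)^s * outer(q[, 3], wave(3)) +                           # stimulus
        (-1)^dd * outer(q[, 4], wave(4)) +                          # decision
        (-1)^(s + dd) * outer(q[, 5], wave(5))                      # interaction
      x[, s, dd, ] <- tc
    }
  }
  dimnames(x) <- list(NULL, c("s1", "s2"), c("up", "down"), NULL)
  structure(list(values = x, condition_counts = matrix(1, S, D),
                 tasks = "A", smooth = FALSE, sigma_ms = 50, bin_ms = 10),
            class = "cond_tensor")
}

test_that("complete basis at ridge 0 explains all variance", {
  cond <- structured_cond()
  res <- fit_demix(NULL, cond = cond, p = 5, ridge = 0)
  expect_equal(res$p, 5)
  expect_lt(abs(sum(res$explained_variance_ratio) - 1), 1e-6)
  expect_setequal(res$factor_of_component,
                  c("time", "stimulus", "decision", "interaction"))
  expect_true(all(res$explained_variance_ratio >= 0 &
                    res$explained_variance_ratio <= 1))
})

test_that("rank-deficient data at ridge 0 errors suggesting a ridge", {
  cond <- structured_cond()
  # remove two directions: total covariance rank 3 < 5 units
  x <- cond$values
  d <- dim(x)
  flat <- matrix(x, d[1])
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
  cond$values <- array(q %*% crossprod(q, flat), d, dimnames = dimnames(x))
  expect_error(fit_demix(NULL, cond = cond, p = 3, ridge = 0),
               "ridge > 0")
  expect_silent({
    res <- fit_demix(NULL, cond = cond, p = 3, ridge = 1e-6)
  })
})

test_that("demixing recovers generating axes and factor labels", {
  out <- full_session()
  res <- fit_demix(out$session, tasks = "A")
  gt <- out$ground_truth
  # top decision component aligns with the decision loading direction
  dec_dir <- gt$loading_matrix %*% gt$decision_axes[, "A"]
  dec_dir <- dec_dir / sqrt(sum(dec_dir^2))
  top_dec <- which(res$factor_of_component == "decision")[1]
  expect_gte(abs(sum(res$W[, top_dec] * dec_dir)), 0.95)
  # top stimulus components live in the stimulus loading span
  stim_span <- qr.Q(qr(gt$loading_matrix %*% gt$stimulus_axes[, , 1]))
  top_stim <- which(res$factor_of_component == "stimulus")[1]
  proj <- crossprod(stim_span, res$W[, top_stim])
  expect_gte(sqrt(sum(proj^2)), 0.9)
  # decision components rank above interaction noise
  expect_true(res$explained_variance_ratio[top_dec] >
                max(res$explained_variance_ratio[
                  res$factor_of_component == "interaction"]))
})

test_that("fit_demix is equivariant to unit relabeling", {
  out <- small_session()
  s <- out$session
  res <- fit_demix(s, tasks = "A", p = 6)
  set.seed(9)
  perm <- sample(dim(s$spike_counts)[2])
  s2 <- s
  s2$spike_counts <- s$spike_counts[, perm, , drop = FALSE]
  res2 <- fit_demix(s2, tasks = "A", p = 6)
  expect_equal(res2$explained_variance_ratio, res$explained_variance_ratio,
               tolerance = 1e-8)
  expect_equal(res2$factor_of_component, res$factor_of_component)
  expect_equal(abs(res2$W), abs(res$W[perm, , drop = FALSE]),
               tolerance = 1e-6)
})

test_that("projection is linear, exact for identity bases, and guarded", {
  out <- small_session()
  res <- fit_demix(out$session, tasks = "A", p = 6)
  n <- nrow(res$W)
  x <- matrix(rnorm(n * 10), n)
  y <- matrix(rnorm(n * 10), n)
  pl <- project_demixed(2 * x + 3 * y, res, center = FALSE)
  expect_equal(pl, 2 * project_demixed(x, res, center = FALSE) +
                 3 * project_demixed(y, res, center = FALSE),
               tolerance = 1e-12)
  # identity-like orthonormal columns reproduce coordinates
  res_id <- res
  res_id$W <- diag(n)[, 1:4]
  res_id$factor_of_component <- rep("decision", 4)
  res_id$p <- 4
  res_id$unit_means <- numeric(n)
  expect_equal(project_demixed(x, res_id), x[1:4, ], tolerance = 1e-12)
  # unit mismatch errors
  expect_error(project_demixed(x[1:3, ], res), "unit mismatch")
})

test_that("cross-projection through task A reveals reuse and reversal", {
  out <- full_session()            # reuse_rho = 1, reversed mapping flips
  s <- out$session
  res <- fit_demix(s, tasks = "A")
  traj_a <- decision_trajectories(s, res, "A")
  traj_b <- decision_trajectories(s, res, "B")
  traj_rev <- decision_trajectories(s, res, "Reverse-A")
  expect_gt(manifold_reuse(traj_a, traj_b), 0.9)
  expect_lt(manifold_reuse(traj_a, traj_rev), -0.9)
  # sign convention: "up" trajectory positive on average in the fit task
  expect_gt(mean(traj_a["up", ]), 0)
})
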