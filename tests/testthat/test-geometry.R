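# Manifold reuse, component selection, principal angles and the shuffle
# null.

test_that("manifold reuse handles identity, sign flip and known SNR", {
  set.seed(1)
  s_i <- rbind(up = cumsum(rnorm(200)), down = cumsum(rnorm(200)))
  expect_equal(manifold_reuse(s_i, s_i), 1, tolerance = 1e-12)
  expect_equal(manifold_reuse(s_i, -s_i), -1, tolerance = 1e-12)
  # additive noise at known SNR attenuates the correlation predictably
  set.seed(2)
  tt <- 10000
  sig <- rbind(up = sin(seq_len(tt) / 50), down = cos(seq_len(tt) / 50))
  snr <- 4
  noise <- matrix(rnorm(2 * tt, sd = sd(sig[1, ]) / sqrt(snr)), 2)
  s_j <- sig + noise
  r <- manifold_reuse(sig, s_j)
  expect_equal(r, (1 + 1 / snr)^(-1 / 2), tolerance = 0.02)
  # equals the direct per-class correlation oracle
  expect_equal(r, mean(c(cor(sig[1, ], s_j[1, ]), cor(sig[2, ], s_j[2, ]))),
               tolerance = 1e-12)
  # invariance to common positive affine rescaling
  expect_equal(manifold_reuse(2 * sig + 5, 2 * s_j + 5), r,
               tolerance = 1e-12)
})

test_that("manifold reuse rejects degenerate inputs", {
  flat <- rbind(up = rep(1, 10), down = rep(2, 10))
  ok <- rbind(up = rnorm(10), down = rnorm(10))
  expect_error(manifold_reuse(flat, ok), "zero-variance")
  expect_error(manifold_reuse(ok[, 1:2, drop = FALSE],
                              ok[, 1:2, drop = FALSE]), "3 time points")
  bad <- ok
  rownames(bad) <- c("left", "right")
  expect_error(manifold_reuse(ok, bad), "decision classes")
})

mock_demix <- function(evr, factors, n = 12, seed = 4) {
  set.seed(seed)
  w <- qr.Q(qr(matrix(rnorm(n * length(evr)), n)))
  structure(list(W = w, factor_of_component = factors,
                 explained_variance_ratio = evr, p = length(evr),
                 unit_means = numeric(n)), class = "demix_result")
}

# exhaustive rule-checking oracle for component selection
select_oracle <- function(evr, factor, var_threshold = 0.01,
                          cum_threshold = 0.7) {
  shares <- evr / sum(evr)
  sel <- integer(0)
  for (j in order(evr, decreasing = TRUE)) {
    if (evr[j] <= var_threshold) break
    sel <- c(sel, j)
    if (factor == "stimulus" &&
          sum(shares[sel]) >= cum_threshold) break
  }
  sel
}

test_that("component selection applies the 1% and 70% rules", {
  # stimulus: [0.50 0.30 0.15 0.05] -> 2 components (cumulative 0.80)
  res <- mock_demix(c(0.50, 0.30, 0.15, 0.05), rep("stimulus", 4))
  sel <- select_components(res, "stimulus")
  expect_equal(length(sel$component_index), 2)
  expect_equal(sel$component_index, c(1, 2))
  expect_equal(sel$variance_kept, 0.8, tolerance = 1e-12)
  # decision: [0.60 0.009] -> 1 component (1% rule, no cumulative cutoff)
  res2 <- mock_demix(c(0.60, 0.009), rep("decision", 2))
  sel2 <- select_components(res2, "decision")
  expect_equal(length(sel2$component_index), 1)
  # orthonormality of the returned basis
  expect_lt(max(abs(crossprod(sel$U) - diag(2))), 1e-10)
  expect_error(select_components(
    mock_demix(c(0.005, 0.004), rep("stimulus", 2)), "stimulus"),
    "more than")
})

test_that("component selection matches the exhaustive oracle on random spectra", {
  set.seed(10)
  for (rep in 1:30) {
    k <- sample(2:8, 1)
    evr <- sort(runif(k, 0, 0.3), decreasing = TRUE)
    factor <- sample(c("stimulus", "decision"), 1)
    oracle <- select_oracle(evr, factor)
    res <- mock_demix(evr, rep(factor, k), n = 10, seed = rep)
    if (length(oracle) == 0) {
      expect_error(select_components(res, factor))
    } else {
      expect_equal(select_components(res, factor)$component_index, oracle)
    }
  }
})

test_that("principal angles match constructions and invariances", {
  n <- 10
  e <- diag(n)
  expect_equal(subspace_angle(e[, 1, drop = FALSE],
                              e[, 1, drop = FALSE])$theta_deg, 0,
               tolerance = 1e-10)
  expect_equal(subspace_angle(e[, 1, drop = FALSE],
                              e[, 2, drop = FALSE])$theta_deg, 90,
               tolerance = 1e-10)
  set.seed(3)
  for (phi in c(5, 33.3, 61, 88)) {
    # plane containing a vector at known angle phi from u1
    q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
    u_d <- q[, 1, drop = FALSE]
    v <- cos(phi * pi / 180) * q[, 1] + sin(phi * pi / 180) * q[, 2]
    u_s <- cbind(v, q[, 3])
    ang <- subspace_angle(u_d, u_s)
    expect_equal(ang$theta_deg, phi, tolerance = 1e-8)
    # brute-force SVD of the cross-Gram matrix
    sv <- svd(crossprod(u_d, u_s))$d
    expect_lt(abs(cos(ang$theta_deg * pi / 180) - max(sv)), 1e-10)
    # symmetry and joint rotation invariance
    expect_equal(subspace_angle(u_s, u_d)$theta_deg, ang$theta_deg,
                 tolerance = 1e-8)
    rot <- qr.Q(qr(matrix(rnorm(n * n), n)))
    expect_equal(subspace_angle(rot %*% u_d, rot %*% u_s)$theta_deg,
                 ang$theta_deg, tolerance = 1e-8)
    expect_true(all(ang$spectrum_deg >= 0 & ang$spectrum_deg <= 90))
  }
  # non-orthonormal input triggers re-orthonormalization with a warning
  expect_warning(subspace_angle(2 * e[, 1, drop = FALSE],
                                e[, 2, drop = FALSE]), "orthonormal")
})

test_that("shuffle null is deterministic and sized correctly", {
  out <- small_session()
  n1 <- shuffle_null(out$session, tasks = "A", n_shuffles = 4, seed = 12)
  n2 <- shuffle_null(out$session, tasks = "A", n_shuffles = 4, seed = 12)
  expect_identical(n1$null_deg, n2$null_deg)
  expect_identical(n1$observed_deg, n2$observed_deg)
  expect_length(n1$null_deg, 4)
  expect_true(all(n1$null_deg >= 0 & n1$null_deg <= 90))
  n3 <- shuffle_null(out$session, tasks = "A", n_shuffles = 4, seed = 13)
  expect_false(identical(n1$null_deg, n3$null_deg))
})

test_that("shuffling destroys structure: no-signal sessions sit in the null", {
  out <- make_session(sim_config(n_units = 30, tasks = "A",
                                 trials_per_condition = 20, n_bins = 50,
                                 signal_gain = 0, seed = 61))
  nl <- shuffle_null(out$session, tasks = "A", n_shuffles = 10, seed = 62)
  # with no task signal the observed angle is exchangeable with the null
  # draws; allow the spread of the null around its range
  spread <- max(3 * sd(nl$null_deg), 1)
  expect_gt(nl$observed_deg, min(nl$null_deg) - spread)
  expect_lt(nl$observed_deg, max(nl$null_deg) + spread)
})

test_that("strong orthogonal structure exceeds the shuffle null", {
  out <- make_session(sim_config(seed = 63, target_angle_deg = 90,
                                 tasks = c("A", "B"),
                                 trials_per_condition = 40))
  nl <- shuffle_null(out$session, tasks = "A", n_shuffles = 10, seed = 64)
  expect_gt(nl$observed_deg, mean(nl$null_deg))
})

test_that("reuse statistics order the three mapping regimes correctly", {
  reuse_for <- function(rho, seed) {
    out <- make_session(sim_config(tasks = c("A", "B", "Reverse-A"),
                                   reuse_rho = rho, seed = seed,
                                   trials_per_condition = 30,
                                   n_units = 40))
    res <- fit_demix(out$session, tasks = "A")
    c(same = reuse_between_tasks(out$session, res, "A", "B"),
      rev = reuse_between_tasks(out$session, res, "A", "Reverse-A"))
  }
  high <- reuse_for(1, 71)
  mid <- reuse_for(0.5, 72)
  zero <- reuse_for(0, 73)
  expect_gt(high["same"], mid["same"])
  expect_gt(mid["same"], zero["same"])
  expect_lt(high["rev"], 0)
})
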