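# Demixed decomposition of condition-averaged activity.
#
# The factorial marginalization splits the condition-averaged tensor into
# condition-independent (time), stimulus, decision and interaction parts
# that sum back to the input exactly. Demixed axes are the principal axes
# of each marginalized term's covariance. For balanced designs with
# factors living on distinct population axes this recovers the same
# subspaces as the reduced-rank-regression formulation of demixed PCA,
# while remaining well-defined when two factors share an axis.

broadcast_nt <- function(m_nt, dims) {
  # m_nt: N x T -> N x S x D x T
  aperm(array(m_nt, c(dims[1], dims[4], dims[2], dims[3])), c(1, 3, 4, 2))
}

broadcast_nst <- function(m_nst, dims) {
  # N x S x T -> N x S x D x T
  aperm(array(m_nst, c(dims[1], dims[2], dims[4], dims[3])), c(1, 2, 4, 3))
}

broadcast_ndt <- function(m_ndt, dims) {
  # N x D x T -> N x S x D x T
  aperm(array(m_ndt, c(dims[1], dims[3], dims[4], dims[2])), c(1, 4, 2, 3))
}

#' Factorial marginalization of a condition-averaged tensor
#'
#' Decomposes the N x S x D x T tensor into the classic factorial means:
#' `x_t` (mean over stimuli and decisions), `x_ts` (per-stimulus mean minus
#' `x_t`), `x_td` (per-decision mean minus `x_t`) and the interaction
#' remainder `x_tsd`. The four terms reconstruct the input exactly, and
#' each term averages to zero over the factor(s) it was marginalized
#' against.
#'
#' @param cond a `cond_tensor` from [condition_average()], or a plain
#'   N x S x D x T array.
#' @return an object of class `marginalization` with full-size arrays
#'   `x_t`, `x_ts`, `x_td`, `x_tsd` and a named `term_variance` vector
#'   (sums of squares per term).
#' @export
marginalize <- function(cond) {
  x <- if (inherits(cond, "cond_tensor")) cond$values else cond
  d <- dim(x)
  if (length(d) != 4) stop("input must be a units x S x D x T array")
  if (d[2] == 1 && d[3] == 1) {
    stop("nothing to demix: need at least 2 stimuli or 2 decisions")
  }
  n <- d[1]; S <- d[2]; D <- d[3]; TT <- d[4]

  m_t <- matrix(0, n, TT)                    # mean over (S, D)
  for (t in seq_len(TT)) {
    m_t[, t] <- rowMeans(matrix(x[, , , t], n, S * D))
  }
  m_st <- apply(x, c(1, 2, 4), mean)         # N x S x T, mean over D
  m_dt <- apply(x, c(1, 3, 4), mean)         # N x D x T, mean over S

  x_t <- broadcast_nt(m_t, d)
  x_ts <- broadcast_nst(m_st, d) - x_t
  x_td <- broadcast_ndt(m_dt, d) - x_t
  x_tsd <- x - x_t - x_ts - x_td

  tv <- c(time = sum(x_t^2), stimulus = sum(x_ts^2),
          decision = sum(x_td^2), interaction = sum(x_tsd^2))
  structure(list(x_t = x_t, x_ts = x_ts, x_td = x_td, x_tsd = x_tsd,
                 term_variance = tv, dims = d),
            class = "marginalization")
}

demix_factors <- c("time", "stimulus", "decision", "interaction")

#' Fit demixed components
#'
#' Condition-averages the selected tasks, centers each unit by its grand
#' mean, marginalizes, and extracts demixed axes per marginalization by
#' eigen-decomposition of that marginalized term's covariance `C_m` (the
#' principal axes of the activity aligned to one task factor). Components
#' from all factors are pooled, ranked by the total-variance fraction they
#' capture from their own marginalization, and truncated to `p`.
#' Decision-factor axes are sign-fixed so that the "up" condition projects
#' positively on average; other axes are sign-fixed by their
#' largest-magnitude loading. A variance-ratio (whitened) objective is
#' deliberately not used for the axes: it cannot recover a factor axis
#' that is shared with a stronger factor, which the near-collinear
#' (small-angle) regime requires (see the methods vignette).
#'
#' The regularized total covariance `C_total + lambda I` must be positive
#' definite; with `ridge = 0` and rank-deficient data an error asks for a
#' positive ridge.
#'
#' @param session a `session_data` object (or a precomputed `cond_tensor`
#'   passed via `cond`).
#' @param tasks tasks whose trials enter the fit (default all).
#' @param p total number of demixed components to keep (default 20).
#' @param ridge regularization as a fraction of total variance; the ridge
#'   `lambda = ridge * trace(C_total)` keeps the whitener from amplifying
#'   sampling-noise directions (default 0.01). With `ridge = 0` the total
#'   covariance must be full rank.
#' @param sigma_ms,smooth smoothing options forwarded to
#'   [condition_average()].
#' @param cond optional `cond_tensor` to use directly instead of
#'   recomputing from the session.
#' @return an object of class `demix_result`: projection matrix `W`
#'   (units x p), `factor_of_component`, `explained_variance_ratio`
#'   (fraction of total variance per component), `p`, `lambda`,
#'   `unit_means` used for centering, and bookkeeping fields.
#' @export
fit_demix <- function(session, tasks = NULL, p = 20, ridge = 0.01,
                      sigma_ms = 50, smooth = TRUE, cond = NULL) {
  if (is.null(cond)) {
    cond <- condition_average(session, tasks = tasks, smooth = smooth,
                              sigma_ms = sigma_ms)
  }
  x <- cond$values
  d <- dim(x)
  n <- d[1]
  p <- assert_count(p, "p")
  if (p > n) stop("`p` cannot exceed the number of units")
  if (d[3] < 2) stop("at least 2 decisions are required")

  unit_means <- rowMeans(matrix(x, n))
  xc <- x - broadcast_nt(matrix(unit_means, n, d[4]), d)
  marg <- marginalize(xc)

  n_samples <- prod(d[-1])
  flat <- function(a) matrix(a, n, n_samples)
  terms <- list(time = marg$x_t, stimulus = marg$x_ts,
                decision = marg$x_td, interaction = marg$x_tsd)
  covs <- lapply(terms, function(a) tcrossprod(flat(a)) / n_samples)
  c_total <- Reduce(`+`, covs)
  total_var <- sum(diag(c_total))
  lambda <- ridge * total_var
  # conditioning guard on the regularized total covariance
  tryCatch(chol(c_total + diag(lambda, n)), error = function(e) {
    stop("total covariance is rank-deficient; refit with ridge > 0",
         call. = FALSE)
  })

  comps <- list()
  for (f in demix_factors) {
    c_m <- covs[[f]]
    if (sum(diag(c_m)) <= 1e-12 * max(total_var, 1e-300)) next
    eg <- eigen(c_m, symmetric = TRUE)
    keep <- head(which(eg$values > 1e-12 * max(total_var, 1e-300)), p)
    for (j in keep) {
      comps[[length(comps) + 1L]] <- list(w = eg$vectors[, j], factor = f,
                                          captured = eg$values[j])
    }
  }
  if (length(comps) == 0) stop("no demixable variance found")
  captured <- vapply(comps, `[[`, numeric(1), "captured")
  ord <- order(captured, decreasing = TRUE)
  ord <- head(ord, p)
  w_mat <- vapply(comps[ord], `[[`, numeric(n), "w")
  w_mat <- matrix(w_mat, nrow = n)
  factor_of_component <- vapply(comps[ord], `[[`, character(1), "factor")
  evr <- captured[ord] / total_var

  # sign conventions
  dec_levels <- dimnames(x)[[3]]
  up_idx <- if ("up" %in% dec_levels) which(dec_levels == "up") else 1L
  dec_pattern <- rowMeans(matrix(marg$x_td[, , up_idx, ], n))
  for (j in seq_along(factor_of_component)) {
    flip <- if (factor_of_component[j] == "decision") {
      sum(w_mat[, j] * dec_pattern) < 0
    } else {
      w_mat[which.max(abs(w_mat[, j])), j] < 0
    }
    if (flip) w_mat[, j] <- -w_mat[, j]
  }

  structure(list(
    W = w_mat,
    factor_of_component = factor_of_component,
    explained_variance_ratio = evr,
    p = ncol(w_mat),
    lambda = lambda,
    ridge = ridge,
    total_variance = total_var,
    unit_means = unit_means,
    stim_levels = dimnames(x)[[2]],
    dec_levels = dec_levels,
    tasks = cond$tasks,
    smooth = cond$smooth,
    sigma_ms = cond$sigma_ms,
    bin_ms = cond$bin_ms
  ), class = "demix_result")
}

#' @export
print.demix_result <- function(x, ...) {
  cat(sprintf("<demix_result> %d components over %d units\n",
              x$p, nrow(x$W)))
  print(data.frame(factor = x$factor_of_component,
                   explained_variance = round(x$explained_variance_ratio, 4)))
  invisible(x)
}

#' Project activity through demixed axes
#'
#' Applies the fixed projection matrix of a [fit_demix()] result (or the
#' columns of one factor) to new data: condition-averaged tensors,
#' units x bins matrices, or single-trial trials x units x bins arrays.
#' No refitting takes place, so the same matrix fit on one task can be
#' applied to held-out tasks.
#'
#' @param x a `cond_tensor`, an N x T matrix, or an M x N x T array.
#' @param result a `demix_result`.
#' @param factor one of `"all"`, `"time"`, `"stimulus"`, `"decision"`,
#'   `"interaction"`.
#' @param center subtract the unit means stored in `result` (default TRUE).
#' @return latent trajectories with components as the first dimension:
#'   k x S x D x T for condition tensors, k x T for matrices, and
#'   k x M x T for single-trial arrays.
#' @export
project_demixed <- function(x, result, factor = "all", center = TRUE) {
  stopifnot(inherits(result, "demix_result"))
  cols <- if (identical(factor, "all")) {
    seq_len(result$p)
  } else {
    which(result$factor_of_component == factor)
  }
  if (length(cols) == 0) stop(sprintf("no components for factor '%s'", factor))
  w <- result$W[, cols, drop = FALSE]
  vals <- if (inherits(x, "cond_tensor")) x$values else x
  n <- nrow(w)
  proj_mat <- function(m) {
    if (nrow(m) != n) {
      stop(sprintf("unit mismatch: data has %d units, projection has %d",
                   nrow(m), n))
    }
    if (center) m <- m - result$unit_means
    crossprod(w, m)
  }
  if (is.matrix(vals)) return(proj_mat(vals))
  d <- dim(vals)
  if (length(d) == 4) {                       # N x S x D x T
    flat <- matrix(vals, d[1])
    out <- proj_mat(flat)
    return(array(out, c(length(cols), d[2], d[3], d[4]),
                 dimnames = c(list(NULL), dimnames(vals)[2:4])))
  }
  if (length(d) == 3) {                       # M x N x T -> k x M x T
    m <- d[1]
    flat <- matrix(aperm(vals, c(2, 1, 3)), d[2])
    out <- proj_mat(flat)
    return(array(out, c(length(cols), m, d[3])))
  }
  stop("unsupported input shape for projection")
}

#' Per-decision trajectories on the top decision component
#'
#' Condition-averages one task with the smoothing settings stored in the
#' demixing result, projects it onto the highest-variance decision
#' component of `result` (fit on a possibly different task), and averages
#' over stimuli, yielding one trajectory per decision class. This is the
#' quantity whose across-task correlation measures manifold reuse.
#'
#' @param session a `session_data` object.
#' @param result a `demix_result`, typically fit on the reference task.
#' @param task the task to project.
#' @return a decisions x bins matrix with decision labels as rownames.
#' @seealso [manifold_reuse()]
#' @export
decision_trajectories <- function(session, result, task) {
  cond <- condition_average(session, tasks = task, smooth = result$smooth,
                            sigma_ms = result$sigma_ms,
                            bin_ms = result$bin_ms)
  dec_cols <- which(result$factor_of_component == "decision")
  if (length(dec_cols) == 0) stop("result has no decision components")
  top <- dec_cols[which.max(result$explained_variance_ratio[dec_cols])]
  w <- result$W[, top, drop = FALSE]
  d <- dim(cond$values)
  flat <- matrix(cond$values - result$unit_means, d[1])
  y <- array(crossprod(w, flat), c(d[2], d[3], d[4]))   # S x D x T
  out <- apply(y, c(2, 3), mean)                        # D x T
  rownames(out) <- dimnames(cond$values)[[3]]
  out
}
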