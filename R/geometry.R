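# Subspace selection, principal angles, manifold reuse and the
# label-shuffle null.

#' Cross-task manifold reuse correlation
#'
#' For two tasks' per-decision trajectories on the top decision component
#' (rows = decision classes, columns = time), computes the Pearson
#' correlation over time separately for each decision class and returns
#' the mean over classes. Values near 1 indicate that the decision
#' manifold learned in one task is reused in the other; reversed mappings
#' yield negative values.
#'
#' @param s_i,s_j decisions x bins matrices with matching row names (see
#'   [decision_trajectories()]).
#' @return a single correlation in \[-1, 1\].
#' @export
manifold_reuse <- function(s_i, s_j) {
  stopifnot(is.matrix(s_i), is.matrix(s_j))
  if (!identical(dim(s_i), dim(s_j))) {
    stop("trajectories must have identical dimensions")
  }
  if (!is.null(rownames(s_i)) && !is.null(rownames(s_j))) {
    if (!setequal(rownames(s_i), rownames(s_j))) {
      stop("trajectories must share the same decision classes")
    }
    s_j <- s_j[rownames(s_i), , drop = FALSE]
  }
  if (ncol(s_i) < 3) stop("trajectories need at least 3 time points")
  rho <- vapply(seq_len(nrow(s_i)), function(c) {
    a <- s_i[c, ]; b <- s_j[c, ]
    if (sd(a) == 0 || sd(b) == 0) {
      stop("zero-variance trajectory: correlation undefined")
    }
    cor(a, b)
  }, numeric(1))
  mean(rho)
}

#' Reuse of task i's decision manifold in task j
#'
#' Convenience wrapper: projects both tasks through the top decision
#' component of a demixing result (typically fit on the reference task)
#' and applies [manifold_reuse()].
#'
#' @param session a `session_data` object.
#' @param result a `demix_result` fit on the reference task.
#' @param task_i,task_j task names to compare.
#' @return mean over decision classes of the per-class time correlation.
#' @export
reuse_between_tasks <- function(session, result, task_i, task_j) {
  manifold_reuse(decision_trajectories(session, result, task_i),
                 decision_trajectories(session, result, task_j))
}

#' Select the components defining a factor's subspace
#'
#' Applies the variance-based selection rules: for the stimulus factor,
#' components are taken in descending variance order as long as each
#' explains more than `var_threshold` of the total variance, stopping once
#' the cumulative share within the factor's own subspace reaches
#' `cum_threshold`. For the decision factor (and any other factor), all
#' components above `var_threshold` are kept with no cumulative cutoff.
#' Selected columns are re-orthonormalized.
#'
#' @param result a `demix_result`.
#' @param factor `"stimulus"`, `"decision"`, `"time"` or `"interaction"`.
#' @param var_threshold minimum fraction of total variance per component
#'   (default 0.01).
#' @param cum_threshold cumulative within-subspace variance at which
#'   stimulus selection stops (default 0.7).
#' @return an object of class `subspace_basis`: orthonormal `U`
#'   (units x k), `factor`, `variance_kept` (within-subspace share) and
#'   the selected component indices.
#' @export
select_components <- function(result, factor, var_threshold = 0.01,
                              cum_threshold = 0.7) {
  stopifnot(inherits(result, "demix_result"))
  idx <- which(result$factor_of_component == factor)
  if (length(idx) == 0) {
    stop(sprintf("no components labeled '%s' in this result", factor))
  }
  evr <- result$explained_variance_ratio[idx]
  ord <- idx[order(evr, decreasing = TRUE)]
  evr <- result$explained_variance_ratio[ord]
  shares <- evr / sum(evr)
  sel <- integer(0)
  cum <- 0
  for (j in seq_along(ord)) {
    if (evr[j] <= var_threshold) break
    sel <- c(sel, ord[j])
    cum <- cum + shares[j]
    if (factor == "stimulus" && cum >= cum_threshold) break
  }
  if (length(sel) == 0) {
    stop(sprintf("no '%s' component explains more than %.3g of the variance",
                 factor, var_threshold))
  }
  u <- qr.Q(qr(result$W[, sel, drop = FALSE]))
  structure(list(U = u, factor = factor, variance_kept = cum,
                 component_index = sel),
            class = "subspace_basis")
}

as_basis_matrix <- function(u) {
  if (inherits(u, "subspace_basis")) u$U else as.matrix(u)
}

#' Principal angle between two subspaces
#'
#' Computes the full principal-angle spectrum from the singular values of
#' the cross-Gram matrix of the two orthonormal bases; the reported angle
#' is the smallest one, `acos(sigma_max(U_d' U_s))`, in degrees.
#' Non-orthonormal inputs are re-orthonormalized with a warning.
#'
#' @param u_d,u_s `subspace_basis` objects or plain basis matrices with
#'   units as rows.
#' @return an object of class `subspace_angle`: `theta_deg` (smallest
#'   principal angle), `spectrum_deg` (all principal angles, ascending)
#'   and `sigma_max`.
#' @export
subspace_angle <- function(u_d, u_s) {
  a <- as_basis_matrix(u_d)
  b <- as_basis_matrix(u_s)
  if (nrow(a) != nrow(b)) stop("bases must share the unit dimension")
  fix <- function(m, name) {
    g <- crossprod(m)
    if (max(abs(g - diag(ncol(m)))) > 1e-8) {
      warning(sprintf("%s basis is not orthonormal; re-orthonormalizing",
                      name))
      m <- qr.Q(qr(m))
    }
    m
  }
  a <- fix(a, "first")
  b <- fix(b, "second")
  sv <- svd(crossprod(a, b))$d
  sv <- pmin(pmax(sv, 0), 1)
  structure(list(theta_deg = acos(max(sv)) * 180 / pi,
                 spectrum_deg = sort(acos(sv) * 180 / pi),
                 sigma_max = max(sv)),
            class = "subspace_angle")
}

#' @export
print.subspace_angle <- function(x, ...) {
  cat(sprintf("<subspace_angle> %.2f deg (spectrum: %s)\n", x$theta_deg,
              paste(sprintf("%.1f", x$spectrum_deg), collapse = ", ")))
  invisible(x)
}

#' Full demix -> select -> angle pipeline for one session
#'
#' Fits demixed components on the selected tasks, selects the stimulus and
#' decision subspaces, and returns the principal angle between them.
#'
#' @param session a `session_data` object.
#' @param tasks tasks entering the fit (default all).
#' @param p,ridge,sigma_ms forwarded to [fit_demix()].
#' @param var_threshold,cum_threshold forwarded to [select_components()].
#' @param fallback_top if TRUE and no component of a factor passes the
#'   variance rule (typical for label-shuffled data, where a factor's
#'   marginalization is pure noise), fall back to that factor's single
#'   top-variance component instead of failing. Off by default so that
#'   real analyses surface the selection failure.
#' @return list with `angle` (a `subspace_angle`), `demix`, `U_d`, `U_s`.
#' @export
session_subspace_angle <- function(session, tasks = NULL, p = 20,
                                   ridge = 0.01, sigma_ms = 50,
                                   var_threshold = 0.01,
                                   cum_threshold = 0.7,
                                   fallback_top = FALSE) {
  res <- fit_demix(session, tasks = tasks, p = p, ridge = ridge,
                   sigma_ms = sigma_ms)
  pick <- function(factor) {
    tryCatch(
      select_components(res, factor, var_threshold, cum_threshold),
      error = function(e) {
        if (!fallback_top || !grepl("explains more than",
                                    conditionMessage(e))) {
          stop(e)
        }
        idx <- which(res$factor_of_component == factor)
        if (length(idx) == 0) stop(e)
        top <- idx[which.max(res$explained_variance_ratio[idx])]
        structure(list(U = qr.Q(qr(res$W[, top, drop = FALSE])),
                       factor = factor,
                       variance_kept = 1,
                       component_index = top),
                  class = "subspace_basis")
      })
  }
  u_d <- pick("decision")
  u_s <- pick("stimulus")
  list(angle = subspace_angle(u_d, u_s), demix = res, U_d = u_d, U_s = u_s)
}

#' Label-shuffle null distribution for the subspace angle
#'
#' Independently permutes the stimulus labels and the decision labels
#' across trials (within each task), reruns the full demix -> select ->
#' angle pipeline, and repeats `n_shuffles` times. A permutation that
#' empties a condition cell is resampled (with a message). Because
#' shuffling removes a factor's genuine variance, null runs fall back to
#' the factor's top component when nothing passes the variance-selection
#' rule (see `fallback_top` in [session_subspace_angle()]). The observed
#' angle is computed on the unshuffled labels with the strict rules.
#'
#' @param session a `session_data` object.
#' @param tasks tasks entering the pipeline (default all).
#' @param n_shuffles number of shuffles (default 10).
#' @param seed integer seed making the null deterministic.
#' @param p,ridge,sigma_ms,var_threshold,cum_threshold pipeline settings.
#' @return an object of class `angle_null`: `observed_deg`, `null_deg`
#'   (length `n_shuffles`), `seed`.
#' @export
shuffle_null <- function(session, tasks = NULL, n_shuffles = 10, seed = 1,
                         p = 20, ridge = 0.01, sigma_ms = 50,
                         var_threshold = 0.01, cum_threshold = 0.7) {
  n_shuffles <- assert_count(n_shuffles, "n_shuffles")
  observed <- session_subspace_angle(session, tasks = tasks, p = p,
                                     ridge = ridge, sigma_ms = sigma_ms,
                                     var_threshold = var_threshold,
                                     cum_threshold = cum_threshold)
  keep <- if (is.null(tasks)) {
    rep(TRUE, nrow(session$trials))
  } else {
    session$trials$task %in% tasks
  }
  null_deg <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      for (attempt in seq_len(100)) {
        shuf <- session
        for (tk in unique(session$trials$task[keep])) {
          idx <- which(keep & session$trials$task == tk)
          shuf$trials$stimulus[idx] <-
            session$trials$stimulus[idx][sample.int(length(idx))]
          shuf$trials$decision[idx] <-
            session$trials$decision[idx][sample.int(length(idx))]
        }
        ang <- tryCatch(
          session_subspace_angle(shuf, tasks = tasks, p = p, ridge = ridge,
                                 sigma_ms = sigma_ms,
                                 var_threshold = var_threshold,
                                 cum_threshold = cum_threshold,
                                 fallback_top = TRUE),
          error = function(e) {
            if (grepl("empty condition cell", conditionMessage(e))) {
              message("shuffle produced an empty condition cell; resampling")
              NULL
            } else {
              stop(e)
            }
          })
        if (!is.null(ang)) return(ang$angle$theta_deg)
      }
      stop("could not find a permutation with all condition cells occupied")
    }, numeric(1))
  })
  structure(list(observed_deg = observed$angle$theta_deg,
                 null_deg = null_deg, seed = seed,
                 n_shuffles = n_shuffles),
            class = "angle_null")
}

#' @export
print.angle_null <- function(x, ...) {
  cat(sprintf("<angle_null> observed %.2f deg; null %.2f +/- %.2f deg (n=%d)\n",
              x$observed_deg, mean(x$null_deg), sd(x$null_deg),
              x$n_shuffles))
  invisible(x)
}
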