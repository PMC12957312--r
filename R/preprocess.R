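# Rate smoothing and condition averaging.

# T x T smoothing matrix for a unit-area Gaussian kernel with symmetric
# (reflective) boundary handling; row t holds the weights applied to the
# source series to produce output bin t.
gaussian_smoother_matrix <- function(n_bins, sigma_bins) {
  stopifnot(sigma_bins > 0)
  radius <- ceiling(4 * sigma_bins)
  k <- (-radius):radius
  w <- exp(-0.5 * (k / sigma_bins)^2)
  w <- w / sum(w)
  reflect <- function(i) {
    # symmetric reflection (edge repeated): ... 2 1 | 1 2 ... T | T T-1 ...
    while (any(bad <- i < 1 | i > n_bins)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n_bins] <- 2 * n_bins + 1 - i[i > n_bins]
      if (!any(bad)) break
    }
    i
  }
  s <- matrix(0, n_bins, n_bins)
  for (t in seq_len(n_bins)) {
    src <- reflect(t + k)
    for (j in seq_along(k)) s[t, src[j]] <- s[t, src[j]] + w[j]
  }
  s
}

#' Smooth spike counts with a Gaussian kernel
#'
#' Convolves each unit/trial time series with a unit-area Gaussian of
#' standard deviation `sigma_ms` (in bins: `sigma_ms / bin_ms`), using
#' symmetric (reflective) boundary handling so that constant series stay
#' constant and total mass per series is preserved.
#'
#' @param x spike-count array: trials x units x bins, a units x bins
#'   matrix, or a plain numeric series.
#' @param sigma_ms kernel standard deviation in milliseconds (default 50).
#' @param bin_ms bin width in milliseconds (default 10).
#' @return an object of the same shape as `x` with smoothed values.
#' @export
smooth_rates <- function(x, sigma_ms = 50, bin_ms = 10) {
  if (!is.numeric(sigma_ms) || length(sigma_ms) != 1 || sigma_ms <= 0) {
    stop("`sigma_ms` must be a single positive number")
  }
  if (length(x) == 0) stop("`x` must be a nonempty numeric array")
  sigma_bins <- sigma_ms / bin_ms
  if (is.null(dim(x))) {
    s <- gaussian_smoother_matrix(length(x), sigma_bins)
    return(drop(s %*% x))
  }
  d <- dim(x)
  n_bins <- d[length(d)]
  s <- gaussian_smoother_matrix(n_bins, sigma_bins)
  flat <- matrix(x, nrow = prod(d[-length(d)]), ncol = n_bins)
  out <- flat %*% t(s)
  array(out, dim = d, dimnames = dimnames(x))
}

canonical_decisions <- function(labels) {
  u <- unique(labels)
  if (setequal(u, c("up", "down"))) c("up", "down") else sort(u)
}

#' Condition-averaged activity tensor
#'
#' Averages (optionally smoothed) single-trial activity within each
#' (stimulus, decision) cell of the selected tasks, producing the
#' units x stimuli x decisions x bins tensor that feeds [marginalize()].
#'
#' @param session a `session_data` object.
#' @param tasks tasks to include (default: all tasks in the session).
#' @param smooth if TRUE (default) counts are smoothed with
#'   [smooth_rates()] before averaging.
#' @param sigma_ms,bin_ms smoothing kernel parameters; `bin_ms` defaults
#'   to the session's bin width.
#' @return an object of class `cond_tensor`: list with `values`
#'   (N x S x D x T array with dimnames), `condition_counts` (S x D
#'   matrix) and the averaging parameters.
#' @export
condition_average <- function(session, tasks = NULL, smooth = TRUE,
                              sigma_ms = 50, bin_ms = NULL) {
  stopifnot(inherits(session, "session_data"))
  bin_ms <- bin_ms %||% session$bin_ms
  keep <- if (is.null(tasks)) {
    rep(TRUE, nrow(session$trials))
  } else {
    session$trials$task %in% tasks
  }
  if (!any(keep)) stop("no trials in the requested task subset")
  tr <- session$trials[keep, , drop = FALSE]
  x <- session$spike_counts[keep, , , drop = FALSE]
  if (smooth) x <- smooth_rates(x, sigma_ms = sigma_ms, bin_ms = bin_ms)

  stim_levels <- sort(unique(tr$stimulus))
  dec_levels <- canonical_decisions(tr$decision)
  n_units <- dim(x)[2]
  n_bins <- dim(x)[3]
  values <- array(NA_real_,
                  c(n_units, length(stim_levels), length(dec_levels), n_bins),
                  dimnames = list(NULL, stim_levels, dec_levels, NULL))
  counts <- matrix(0L, length(stim_levels), length(dec_levels),
                   dimnames = list(stim_levels, dec_levels))
  for (si in seq_along(stim_levels)) {
    for (di in seq_along(dec_levels)) {
      idx <- which(tr$stimulus == stim_levels[si] &
                     tr$decision == dec_levels[di])
      if (length(idx) == 0) {
        stop(sprintf(
          "empty condition cell: stimulus '%s' x decision '%s'",
          stim_levels[si], dec_levels[di]))
      }
      counts[si, di] <- length(idx)
      cell <- x[idx, , , drop = FALSE]
      values[, si, di, ] <- matrix(colMeans(matrix(cell, nrow = length(idx))),
                                   n_units, n_bins)
    }
  }
  structure(list(values = values, condition_counts = counts,
                 tasks = unique(tr$task), smooth = smooth,
                 sigma_ms = sigma_ms, bin_ms = bin_ms),
            class = "cond_tensor")
}

#' @export
print.cond_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cond_tensor> %d units x %d stimuli x %d decisions x %d bins\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
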