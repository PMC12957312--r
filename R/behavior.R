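# Behavioral learning metrics and the statistical toolkit: trials to a
# sliding-window accuracy criterion, reaction times, learning-vs-reuse
# regression, standardized effect sizes, and the Watson-Williams test for
# equality of circular means.

#' Trials to a sliding-window accuracy criterion
#'
#' Finds the earliest trial `t >= window` at which the trailing window of
#' outcomes has accuracy at or above `threshold` (with the defaults, at
#' least 14 of 15 correct). If the criterion is never reached the task is
#' treated as not acquired and the normalized measure falls back to 1
#' (i.e. the full session length).
#'
#' @param outcomes binary vector (1 correct / 0 incorrect).
#' @param threshold accuracy criterion (default 0.9).
#' @param window sliding-window length in trials (default 15).
#' @return list of class `learning_result`: `criterion_trial` (index or
#'   NA), `n_session_trials`, `normalized_trials` =
#'   criterion_trial / n_session_trials (1 when not reached).
#' @export
trials_to_criterion <- function(outcomes, threshold = 0.9, window = 15) {
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  window <- assert_count(window, "window")
  n <- length(outcomes)
  if (window > n) stop("window exceeds the number of trials")
  cs <- cumsum(outcomes)
  win_sum <- cs[window:n] - c(0, cs)[seq_len(n - window + 1)]
  hit <- which(win_sum >= threshold * window - 1e-9)
  criterion <- if (length(hit) > 0) hit[1] + window - 1L else NA_integer_
  structure(list(
    criterion_trial = criterion,
    n_session_trials = n,
    normalized_trials = if (is.na(criterion)) 1 else criterion / n
  ), class = "learning_result")
}

#' Reaction times from trial event logs
#'
#' Reaction time is the interval between the go cue and the touch of the
#' selected button. Trials with missing events or with a touch preceding
#' the go cue are excluded with a warning.
#'
#' @param events a `session_data` object or a data frame with columns
#'   `go_t` and `touch_t` (optionally `task`).
#' @param task optional task label per trial, used for the per-task
#'   summary; taken from the session's trial table when available.
#' @return list with `per_trial` (seconds, NA where excluded) and
#'   `summary` (per-task mean, SD and n).
#' @export
reaction_time <- function(events, task = NULL) {
  if (inherits(events, "session_data")) {
    task <- task %||% events$trials$task
    events <- events$event_times
  }
  stopifnot(all(c("go_t", "touch_t") %in% names(events)))
  rt <- events$touch_t - events$go_t
  bad <- is.na(rt) | rt < 0
  if (any(bad)) {
    warning(sprintf("%d trial(s) excluded (missing events or touch before go)",
                    sum(bad)))
    rt[bad] <- NA_real_
  }
  task <- task %||% rep("all", length(rt))
  summ <- do.call(rbind, lapply(split(rt, task), function(v) {
    v <- v[!is.na(v)]
    data.frame(mean_s = mean(v), sd_s = sd(v), n = length(v))
  }))
  summ$task <- rownames(summ)
  rownames(summ) <- NULL
  list(per_trial = rt, summary = summ[, c("task", "mean_s", "sd_s", "n")])
}

#' Linear regression of learning speed on manifold reuse
#'
#' Ordinary least squares of trials-to-criterion (or any learning
#' measure) on the manifold-reuse correlation, with the coefficient of
#' determination against the intercept-only model and a two-sided p-value
#' for the slope.
#'
#' @param reuse numeric predictor (reuse correlations).
#' @param trials numeric response (e.g. normalized trials to criterion).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` and the
#'   underlying `stats::lm` fit.
#' @export
regress_reuse_vs_learning <- function(reuse, trials) {
  if (length(reuse) != length(trials)) stop("lengths differ")
  if (length(reuse) < 3) stop("need at least 3 points")
  if (sd(reuse) == 0) stop("predictor is constant")
  if (sd(trials) == 0) {
    # degenerate flat response: no improvement over the null model
    return(list(slope = 0, intercept = trials[1], r_squared = 0,
                p_value = 1, fit = NULL))
  }
  fit <- lm(trials ~ reuse)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       fit = fit)
}

hedges_g_two_sample <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("zero pooled variance: effect size undefined")
  df <- nx + ny - 2
  j <- 1 - 3 / (4 * df - 1)
  (mean(x) - mean(y)) / sqrt(sp2) * j
}

hedges_g_paired <- function(x, y) {
  d <- x - y
  if (sd(d) == 0) stop("zero variance of differences: effect size undefined")
  df <- length(d) - 1
  j <- 1 - 3 / (4 * df - 1)
  mean(d) / sd(d) * j
}

#' Effect sizes and tests for group comparisons
#'
#' For two samples `x`, `y`: Hedges' g (pooled SD with the small-sample
#' correction `J = 1 - 3/(4 df - 1)`; on the paired differences when
#' `paired = TRUE`) and the matching t-test. For `groups` (a list of
#' numeric vectors or a value/grouping pair): one-way ANOVA with
#' `eta^2 = SS_between / SS_total` and Cohen's
#' `f = sqrt(eta^2 / (1 - eta^2))`.
#'
#' @param x,y numeric samples for a two-group comparison.
#' @param groups alternatively, a named or unnamed list of numeric vectors
#'   for a one-way ANOVA across 2+ groups.
#' @param paired treat `x`, `y` as paired (default FALSE).
#' @return list of class `effect_sizes` with `hedges_g`, `cohens_f`,
#'   `eta_squared`, `r_squared`, `t_statistic`, `t_p_value`,
#'   `f_statistic`, `anova_p_value` (fields not applicable are NA).
#' @export
effect_size_suite <- function(x = NULL, y = NULL, groups = NULL,
                              paired = FALSE) {
  if (is.null(groups)) {
    if (is.null(x) || is.null(y)) stop("supply x and y, or groups")
    groups <- list(x = x, y = y)
  }
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups),
                       vapply(groups, length, integer(1))))
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) stop("zero total variance")
  eta2 <- ss_between / ss_total
  cohens_f <- sqrt(eta2 / max(1 - eta2, .Machine$double.eps))
  a <- anova(aov(values ~ labels))
  g <- t_stat <- t_p <- NA_real_
  if (length(groups) == 2) {
    g <- if (paired) {
      hedges_g_paired(groups[[1]], groups[[2]])
    } else {
      hedges_g_two_sample(groups[[1]], groups[[2]])
    }
    tt <- t.test(groups[[1]], groups[[2]], paired = paired,
                 var.equal = !paired)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  structure(list(hedges_g = g, cohens_f = cohens_f, eta_squared = eta2,
                 r_squared = eta2, t_statistic = t_stat, t_p_value = t_p,
                 f_statistic = a[["F value"]][1],
                 anova_p_value = a[["Pr(>F)"]][1]),
            class = "effect_sizes")
}

# Maximum-likelihood estimate of the von Mises concentration from the
# mean resultant length (standard piecewise approximation).
kappa_from_rbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equality of two circular means
#'
#' The circular analogue of the two-sample test for mean directions, with
#' the standard concentration correction factor `K = 1 + 3/(8 kappa)`.
#' A warning is issued when the pooled mean resultant length is low
#' (< 0.45), where the test's assumptions are doubtful.
#'
#' @param angles_a,angles_b angle samples.
#' @param units `"deg"` (default) or `"rad"`.
#' @return list with `F_statistic`, `p_value`, `kappa`, group resultant
#'   lengths and circular means (degrees).
#' @export
watson_williams <- function(angles_a, angles_b, units = c("deg", "rad")) {
  units <- match.arg(units)
  if (length(angles_a) < 2 || length(angles_b) < 2) {
    stop("need at least 2 angles per group")
  }
  to_rad <- if (units == "deg") pi / 180 else 1
  a <- as.numeric(angles_a) * to_rad
  b <- as.numeric(angles_b) * to_rad
  res <- function(v) {
    c(C = sum(cos(v)), S = sum(sin(v)))
  }
  ra <- res(a); rb <- res(b)
  r1 <- sqrt(sum(ra^2)); r2 <- sqrt(sum(rb^2))
  n <- length(a) + length(b)
  rw <- sqrt(sum((ra + rb)^2))
  rbar <- (r1 + r2) / n
  if (rbar < .Machine$double.eps) stop("undefined concentration (resultant 0)")
  if (rbar < 0.45) {
    warning("low concentration (mean resultant length < 0.45); ",
            "Watson-Williams assumptions are doubtful")
  }
  kappa <- kappa_from_rbar(rbar)
  if (!is.finite(kappa) || kappa <= 0) {
    stop("undefined concentration estimate")
  }
  k_corr <- 1 + 3 / (8 * kappa)
  f_stat <- k_corr * (n - 2) * (r1 + r2 - rw) / (n - (r1 + r2))
  f_stat <- max(f_stat, 0)
  p <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  circ_mean_deg <- function(r) (atan2(r["S"], r["C"]) * 180 / pi) %% 360
  list(F_statistic = f_stat, p_value = p, kappa = kappa,
       resultants = c(r1 = r1, r2 = r2, pooled = rw),
       mean_deg = c(a = unname(circ_mean_deg(ra)),
                    b = unname(circ_mean_deg(rb))))
}
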