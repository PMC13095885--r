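# regressions of per-group fitted parameters on total leaf number

tln_points <- function(points) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("tln", "value")
  points <- points[is.finite(points$tln) & is.finite(points$value), , drop = FALSE]
  points
}

regression_result <- function(rule, coef_se, residual_sd, n_groups,
                              degenerate = FALSE, p_values = NULL) {
  structure(list(rule = rule, coef_se = coef_se, residual_sd = residual_sd,
                 n_groups = n_groups, degenerate = degenerate,
                 p_values = p_values),
            class = "tln_regression")
}

#' @export
print.tln_regression <- function(x, ...) {
  form <- if (inherits(x$rule, "tln_segmented_rule")) "segmented"
          else if (inherits(x$rule, "tln_plateau_rule")) "decline-plateau"
          else "linear"
  cat(sprintf("TLN regression (%s), %d groups, residual sd %.4g%s\n",
              form, x$n_groups, x$residual_sd,
              if (x$degenerate) " [degenerate]" else ""))
  print(unlist(x$rule))
  invisible(x)
}

#' Linear regression of a parameter on total leaf number
#'
#' Ordinary least squares of per-group parameter estimates on TLN; used for
#' the largest-leaf position (xs) in maize and pearl millet.
#'
#' @param points two-column data (tln, parameter value); >= 3 rows.
#' @return A \code{tln_regression} with a [tln_linear_rule()].
#' @export
fit_tln_linear <- function(points) {
  pts <- tln_points(points)
  if (nrow(pts) < 3)
    stop("fit_tln_linear: at least 3 (tln, value) points required", call. = FALSE)
  if (length(unique(pts$tln)) < 2)
    stop("fit_tln_linear: rank-deficient input (all tln values equal)",
         call. = FALSE)
  fit <- stats::lm(value ~ tln, data = pts)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  regression_result(rule = tln_linear_rule(cf[1, 1], cf[2, 1]),
                    coef_se = c(a = cf[1, 2], b = cf[2, 2]),
                    residual_sd = sm$sigma, n_groups = nrow(pts),
                    p_values = c(a = cf[1, 4], b = cf[2, 4]))
}

# profiled RSS of the continuous two-slope fit at a candidate breakpoint;
# linear in (a, b, c) given bp
seg_rss <- function(bp, tln, value) {
  X <- cbind(1, pmin(tln, bp), pmax(tln - bp, 0))
  fit <- stats::lm.fit(X, value)
  sum(fit$residuals^2)
}

plateau_rss <- function(bp, tln, value) {
  X <- cbind(1, pmin(tln, bp))
  fit <- stats::lm.fit(X, value)
  sum(fit$residuals^2)
}

# grid search at 0.1 TLN resolution, then 1-D polish of the profiled RSS
best_breakpoint <- function(tln, value, rss_fn, lo, hi) {
  grid <- seq(lo, hi, by = 0.1)
  rss <- vapply(grid, rss_fn, numeric(1), tln = tln, value = value)
  b0 <- grid[which.min(rss)]
  opt <- stats::optimize(rss_fn, tln = tln, value = value,
                         interval = c(max(lo, b0 - 0.1), min(hi, b0 + 0.1)),
                         tol = 1e-9)
  if (opt$objective <= min(rss)) opt$minimum else b0
}

#' Segmented regression of a parameter on total leaf number
#'
#' Continuous two-slope ("broken stick") least squares fit, used for the
#' largest-leaf position (xs) in sorghum. With a free breakpoint the
#' profiled RSS is scanned on a 0.1-TLN grid and then polished by 1-D
#' optimization; at each candidate breakpoint the remaining coefficients
#' are the exact OLS solution.
#'
#' @param points two-column data (tln, value); >= 5 rows spanning both
#'   sides of the breakpoint.
#' @param breakpoint \code{NULL} to estimate it, or a fixed value.
#' @return A \code{tln_regression} with a [tln_segmented_rule()]. If the
#'   two slopes coincide the breakpoint is unidentifiable and the result is
#'   flagged \code{degenerate}. If all points lie on one side of a fixed
#'   breakpoint, a linear fit is returned with a warning.
#' @export
fit_tln_segmented <- function(points, breakpoint = NULL) {
  pts <- tln_points(points)
  if (nrow(pts) < 5)
    stop("fit_tln_segmented: at least 5 (tln, value) points required",
         call. = FALSE)
  t <- pts$tln; v <- pts$value
  ts <- sort(unique(t))
  if (length(ts) < 3 ||
      (!is.null(breakpoint) && (all(t <= breakpoint) || all(t > breakpoint)))) {
    warning("fit_tln_segmented: points do not span the breakpoint; falling back to a linear fit",
            call. = FALSE)
    return(fit_tln_linear(pts))
  }
  bp <- if (is.null(breakpoint)) {
    # keep >= 2 design points on each side of any candidate
    best_breakpoint(t, v, seg_rss, ts[2], ts[length(ts) - 1])
  } else breakpoint
  X <- cbind(`(Intercept)` = 1, lo = pmin(t, bp), hi = pmax(t - bp, 0))
  fit <- stats::lm(v ~ X - 1)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, 2],
                 error = function(e) rep(NA_real_, 3))
  degenerate <- isTRUE(abs(cf[2] - cf[3]) <=
                         1e-8 * max(abs(cf[2]), abs(cf[3]), 1e-12))
  regression_result(rule = tln_segmented_rule(cf[1], cf[2], cf[3], bp),
                    coef_se = c(a = unname(se[1]), b = unname(se[2]),
                                c = unname(se[3]), bp = NA_real_),
                    residual_sd = suppressWarnings(summary(fit))$sigma, n_groups = nrow(pts),
                    degenerate = degenerate)
}

#' Decline-then-plateau regression of the decay rate on total leaf number
#'
#' Continuous hockey-stick least squares: the decay rate dr falls linearly
#' with TLN up to a breakpoint and is constant beyond it (the plateau value
#' is the line evaluated at the breakpoint). The free breakpoint is found
#' by a 0.1-TLN grid scan of the profiled RSS plus 1-D polish.
#'
#' @param points two-column data (tln, dr); >= 5 rows, at least 2 beyond
#'   any candidate breakpoint.
#' @return A \code{tln_regression} with a [tln_plateau_rule()]. All points
#'   effectively constant => slope unidentifiable, flagged
#'   \code{degenerate}; a decline with no plateau support pins the
#'   breakpoint at the largest TLN with a warning.
#' @export
fit_tln_plateau <- function(points) {
  pts <- tln_points(points)
  if (nrow(pts) < 5)
    stop("fit_tln_plateau: at least 5 (tln, dr) points required", call. = FALSE)
  t <- pts$tln; v <- pts$value
  ts <- sort(unique(t))
  if (length(ts) < 3)
    stop("fit_tln_plateau: need >= 3 distinct tln values", call. = FALSE)
  lo <- ts[2]; hi <- ts[length(ts) - 1]
  bp <- best_breakpoint(t, v, plateau_rss, lo, hi)
  if (bp >= hi - 1e-6 &&
      plateau_rss(ts[length(ts)], t, v) <= plateau_rss(bp, t, v) + 1e-12) {
    warning("fit_tln_plateau: no plateau support in the data; breakpoint pinned at the largest TLN",
            call. = FALSE)
    bp <- ts[length(ts)]
  }
  X <- cbind(`(Intercept)` = 1, lo = pmin(t, bp))
  fit <- stats::lm(v ~ X - 1)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, 2],
                 error = function(e) rep(NA_real_, 2))
  degenerate <- isTRUE(abs(cf[2]) <= 1e-8 * max(abs(cf[1]), 1e-12))
  rule <- tryCatch(tln_plateau_rule(cf[1], cf[2], bp), error = function(e) {
    warning(sprintf("fit_tln_plateau: fitted coefficients violate the rule invariants (%s); returning unvalidated rule",
                    conditionMessage(e)), call. = FALSE)
    structure(list(a = unname(cf[1]), b = unname(cf[2]), bp = bp),
              class = c("tln_plateau_rule", "tln_rule"))
  })
  regression_result(rule = rule,
                    coef_se = c(a = unname(se[1]), b = unname(se[2]),
                                bp = NA_real_),
                    residual_sd = suppressWarnings(summary(fit))$sigma, n_groups = nrow(pts),
                    degenerate = degenerate)
}

#' Robust bivariate outlier screen for decay-rate estimates
#'
#' Per-group decay-rate estimates can be unstable (typically for plants
#' with few leaves). Points are screened on their bivariate (TLN, dr)
#' distribution: robust location and scatter are estimated by a one-step
#' reweighted minimum covariance determinant (raw MCD with 75\% coverage,
#' then classical moments of the points the raw distances accept), and
#' points whose squared Mahalanobis distance exceeds the chi-square(2)
#' quantile are flagged. The 75\% coverage and the reweighting step keep
#' the estimator from collapsing onto the plateau arm of the
#' decline-then-plateau point cloud, which would flag the legitimate
#' low-TLN decline as outlying.
#'
#' @param points two-column data (tln, dr); >= 5 rows for any flagging.
#' @param quantile chi-square probability cutoff (default 0.975);
#'   \code{quantile = 1} flags nothing.
#' @return Logical vector, \code{TRUE} for flagged outliers.
#' @export
flag_dr_outliers <- function(points, quantile = 0.975) {
  pts <- tln_points(points)
  n <- nrow(pts)
  if (n < 5) {
    warning("flag_dr_outliers: fewer than 5 points; nothing flagged",
            call. = FALSE)
    return(rep(FALSE, n))
  }
  if (quantile >= 1) return(rep(FALSE, n))
  X <- cbind(pts$tln, pts$value)
  est <- tryCatch(suppressWarnings(
    MASS::cov.rob(X, method = "mcd", quantile.used = ceiling(0.75 * n))),
    error = function(e) NULL)
  if (is.null(est) || any(!is.finite(est$cov)) || det(est$cov) <= 0)
    est <- tryCatch(list(center = colMeans(X), cov = stats::cov(X)),
                    error = function(e) NULL)
  if (is.null(est) || det(est$cov) <= 0) {
    warning("flag_dr_outliers: scatter estimate is singular; nothing flagged",
            call. = FALSE)
    return(rep(FALSE, n))
  }
  # one-step reweighting: classical moments of the points the raw robust
  # distances accept, then final distances from those
  d2 <- stats::mahalanobis(X, est$center, est$cov)
  keep <- d2 <= stats::qchisq(0.999, df = 2)
  if (sum(keep) >= 3) {
    cov_w <- stats::cov(X[keep, , drop = FALSE])
    if (all(is.finite(cov_w)) && det(cov_w) > 0)
      d2 <- stats::mahalanobis(X, colMeans(X[keep, , drop = FALSE]), cov_w)
  }
  d2 > stats::qchisq(quantile, df = 2)
}
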