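# model function in plain-argument form for the optimizer: no class
# validation, so the LM search may wander without tripping invariants
leaf_dim_fn <- function(x, L1, cm, rm, tb, xs, dr, dsl) {
  rising <- L1 + (cm / rm) * softplus(rm * (x - tb - 1))
  ymax <- L1 + (cm / rm) * softplus(rm * (xs - tb - 1))
  yslevel <- ymax + dsl
  falling <- ymax * yslevel / (ymax + dsl * exp(dr * (x - xs)))
  ifelse(x < xs, rising, falling)
}

PAR_NAMES <- c("L1", "cm", "rm", "tb", "xs", "dr", "dsl")

#' One TLN group of leaf observations
#'
#' A TLN group is the fitting unit of the calibration pipeline: all
#' observations of one trait for plants of one genotype sharing the same
#' total leaf number.
#'
#' @param species species id.
#' @param genotype genotype label.
#' @param trait \code{"blade_length"} or \code{"blade_width"}.
#' @param tln total leaf number of the group.
#' @param position integer leaf positions (1..tln).
#' @param value observed blade sizes, mm.
#' @param min_obs minimum number of observations required (default 8).
#' @return An object of class \code{tln_group}.
#' @export
tln_group <- function(species, genotype, trait, tln, position, value,
                      min_obs = 8) {
  species <- match_species(species)
  trait <- match_trait(trait)
  keep <- is.finite(value)
  position <- position[keep]; value <- value[keep]
  if (length(position) != length(value))
    stop("tln_group: position and value lengths differ", call. = FALSE)
  if (any(position < 1 | position > tln))
    stop("tln_group: positions must lie in 1..tln", call. = FALSE)
  if (length(value) < min_obs)
    stop(sprintf("tln_group: %d observations < required minimum %d",
                 length(value), min_obs), call. = FALSE)
  structure(list(species = species, genotype = as.character(genotype),
                 trait = trait, tln = as.integer(tln),
                 position = as.numeric(position), value = as.numeric(value)),
            class = "tln_group")
}

#' Data-driven starting values for a profile fit
#'
#' Heuristic initialization: \code{L1} at the smallest observed value,
#' \code{xs} at the position of the largest observed value, \code{cm} at
#' the largest successive increase, \code{rm = 1}, \code{tb = 2},
#' \code{dsl} at 5\% of the maximum and \code{dr = 0.5}, all clipped so the
#' result is a valid [profile_params()] object.
#'
#' @param group a [tln_group()].
#' @return A [profile_params()] object.
#' @export
default_init <- function(group) {
  stopifnot(inherits(group, "tln_group"))
  ord <- order(group$position)
  pos <- group$position[ord]; val <- group$value[ord]
  xs0 <- pos[which.max(val)]
  d <- diff(val)
  cm0 <- if (length(d) && max(d) > 0) max(d) else max(val) / length(val)
  profile_params(L1 = max(min(val), 1e-3),
                 cm = max(cm0, 1e-3),
                 rm = 1, tb = 2,
                 xs = max(xs0, 1.1),
                 dr = 0.5,
                 dsl = max(0.05 * max(val), 1e-6))
}

# deterministic alternative starts: the single data-driven init can sit far
# from the optimum when the exponential phase is slow (small rm, large tb)
start_list <- function(init) {
  base <- unlist(init[PAR_NAMES])
  alt <- function(...) {
    s <- base; mods <- list(...)
    s[names(mods)] <- unlist(mods)
    s
  }
  list(base,
       alt(rm = 0.3, tb = max(1, 0.5 * base[["xs"]])),
       alt(rm = 0.2, tb = max(1, base[["xs"]] - 1), dr = 1),
       alt(rm = 2, tb = 1, dr = 0.2),
       alt(rm = 0.6, tb = max(1, 0.3 * base[["xs"]]), dsl = 2 * base[["dsl"]] + 1))
}

#' Fit the expolinear-logistic model to one TLN group
#'
#' Levenberg--Marquardt nonlinear least squares (via
#' \code{minpack.lm::nls.lm}) of the seven-parameter expolinear-logistic
#' profile to the group's (position, value) observations. A small fixed set
#' of starting points (the [default_init()] plus deterministic variants) is
#' tried and the lowest-RSS fit kept; standard errors come from the
#' Jacobian-based covariance at the optimum. The LM damping copes with the
#' rank-deficient Jacobians that arise when a group has few leaves beyond
#' the largest one.
#'
#' @param group a [tln_group()].
#' @param init optional [profile_params()] starting point (replaces the
#'   default initialization; the alternative starts are still tried).
#' @param bounds optional list with numeric vectors \code{lower} and/or
#'   \code{upper} named by parameter.
#' @param control a \code{minpack.lm::nls.lm.control} list.
#' @return An object of class \code{leaf_fit}: a list with \code{params}
#'   (a [profile_params()]), \code{std_errors}, \code{rss}, \code{rmse},
#'   \code{r2}, \code{n}, \code{converged}, \code{fitted},
#'   \code{rss_trace} (objective value per accepted optimizer iteration of
#'   the winning start) and \code{group}. Non-convergence is reported
#'   through \code{converged = FALSE}, never an error.
#' @export
fit_profile <- function(group, init = NULL, bounds = NULL,
                        control = minpack.lm::nls.lm.control(maxiter = 500)) {
  stopifnot(inherits(group, "tln_group"))
  x <- group$position; y <- group$value
  ymax <- max(y)
  lower <- c(L1 = 1e-3, cm = 1e-3, rm = 1e-3, tb = -20, xs = 1.05,
             dr = 0, dsl = 0)
  upper <- c(L1 = 2 * ymax, cm = Inf, rm = 100, tb = max(x) + 20,
             xs = max(x) + 5, dr = 100, dsl = 10 * ymax)
  if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
  if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  if (is.null(init)) init <- default_init(group)
  starts <- start_list(init)
  residual_fn <- function(par) y - leaf_dim_fn(x, par[["L1"]], par[["cm"]],
                                               par[["rm"]], par[["tb"]],
                                               par[["xs"]], par[["dr"]],
                                               par[["dsl"]])

  best <- NULL; best_rss <- Inf
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-8), ifelse(is.finite(upper), upper - 1e-8, s))
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = s, fn = residual_fn,
                         lower = lower, upper = upper, control = control)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(unlist(fit$par)))) next
    rss <- fit$deviance
    if (is.finite(rss) && rss < best_rss) { best <- fit; best_rss <- rss }
    if (best_rss < 1e-18 * sum(y^2)) break
  }

  n <- length(y)
  if (is.null(best)) {
    return(structure(list(params = init,
                          std_errors = stats::setNames(rep(NA_real_, 7), PAR_NAMES),
                          rss = NA_real_, rmse = NA_real_, r2 = NA_real_,
                          n = n, converged = FALSE, fitted = NULL,
                          group = group),
                     class = "leaf_fit"))
  }
  cf <- unlist(best$par)
  se <- tryCatch(suppressWarnings(
    summary(best)$coefficients[PAR_NAMES, "Std. Error"]),
    error = function(e) stats::setNames(rep(NA_real_, 7), PAR_NAMES))
  params <- tryCatch(do.call(profile_params, as.list(cf[PAR_NAMES])),
                     error = function(e) NULL)
  pred <- y - best$fvec
  gof <- evaluate_fit(y, pred)
  structure(list(params = params,
                 std_errors = stats::setNames(as.numeric(se), PAR_NAMES),
                 rss = best_rss, rmse = sqrt(best_rss / n), r2 = gof$r2,
                 n = n,
                 converged = best$info %in% 1:4 && !is.null(params),
                 fitted = as.numeric(pred),
                 rss_trace = as.numeric(best$rsstrace), group = group),
            class = "leaf_fit")
}

#' @export
print.leaf_fit <- function(x, ...) {
  cat(sprintf("Expolinear-logistic fit: %s %s, TLN %d (n = %d)\n",
              x$group$species, x$group$trait, x$group$tln, x$n))
  cat(sprintf("  converged: %s, rmse = %.4g mm, R2 = %.4f\n",
              x$converged, x$rmse, x$r2))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Goodness of fit of predictions against observations
#'
#' Root mean square error and coefficient of determination
#' (\code{1 - SSres/SStot}). With zero variance in the observations R2 is
#' undefined and returned as \code{NA}.
#'
#' @param observed observed values, mm.
#' @param predicted predicted values, mm (same length, >= 2).
#' @return A list with elements \code{rmse} and \code{r2}.
#' @export
#' @examples
#' evaluate_fit(c(1, 2, 3), c(1, 2, 4))  # rmse sqrt(1/3), r2 0.5
evaluate_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("evaluate_fit: observed and predicted must have equal length >= 2",
         call. = FALSE)
  res <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  list(rmse = sqrt(mean(res^2)),
       r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_)
}
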