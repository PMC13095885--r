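#' Calibration configuration
#'
#' @param min_obs minimum observations per TLN group (groups below are
#'   skipped, with the reason logged in the diagnostics).
#' @param min_groups minimum number of distinct TLN values with a
#'   converged fit required per trait.
#' @param xs_form functional form of the xs-vs-TLN rule: \code{"auto"}
#'   (segmented for sorghum, linear otherwise), \code{"linear"} or
#'   \code{"segmented"}.
#' @param xs_breakpoint \code{NULL} to estimate the segmented breakpoint,
#'   or a fixed value (e.g. 20.5 to reproduce the published sorghum rule).
#' @param dr_quantile chi-square probability for [flag_dr_outliers()].
#' @param pool how fixed parameters are pooled across TLN groups:
#'   \code{"mean"} (unweighted, the default) or \code{"invvar"}
#'   (inverse-variance weighted by the squared standard errors).
#' @return A named list of class \code{calib_config}.
#' @export
calib_config <- function(min_obs = 8, min_groups = 4, xs_form = "auto",
                         xs_breakpoint = NULL, dr_quantile = 0.975,
                         pool = c("mean", "invvar")) {
  structure(list(min_obs = min_obs, min_groups = min_groups,
                 xs_form = match.arg(xs_form, c("auto", "linear", "segmented")),
                 xs_breakpoint = xs_breakpoint, dr_quantile = dr_quantile,
                 pool = match.arg(pool)),
            class = "calib_config")
}

pool_estimates <- function(est, se, pool) {
  if (pool == "invvar" && all(is.finite(se)) && all(se > 0)) {
    w <- 1 / se^2
    sum(w * est) / sum(w)
  } else {
    mean(est)
  }
}

#' Calibrate a species parameter set from leaf measurements
#'
#' The full calibration pipeline for one species: observations are grouped
#' by genotype and total leaf number within each trait; the seven-parameter
#' expolinear-logistic model is fitted to every group by nonlinear least
#' squares ([fit_profile()]); the fixed parameters (L1, cm, rm, tb, dsl)
#' are pooled across groups; the largest-leaf position estimates are
#' regressed on TLN ([fit_tln_linear()] or [fit_tln_segmented()]); and the
#' decay-rate estimates, after the robust bivariate outlier screen
#' ([flag_dr_outliers()]), are fitted with the decline-then-plateau rule
#' ([fit_tln_plateau()]).
#'
#' @param records leaf measurement records: a data.frame with columns
#'   \code{plant_id, species, genotype, tln, position, blade_length_mm,
#'   blade_width_mm} (missing sizes as \code{NA}); exactly one species.
#' @param config a [calib_config()].
#' @return A list of class \code{calibration} with elements \code{params}
#'   (the assembled [species_params()]), \code{fits} (per-group
#'   [fit_profile()] results), \code{group_diagnostics} (data.frame, one
#'   row per group), \code{xs_regression} and \code{dr_regression} (per
#'   trait), \code{dr_outliers} (per trait, logical), and \code{log}
#'   (character).
#' @export
calibrate_species <- function(records, config = calib_config()) {
  stopifnot(inherits(config, "calib_config"))
  records <- as.data.frame(records)
  sp <- unique(as.character(records$species))
  if (length(sp) != 1)
    stop(sprintf("calibrate_species: records must contain exactly one species (found: %s)",
                 paste(sp, collapse = ", ")), call. = FALSE)
  sp <- match_species(sp)
  xs_form <- if (config$xs_form == "auto") {
    if (sp == "sorghum") "segmented" else "linear"
  } else config$xs_form

  log <- character(0)
  fits <- list()
  diag_rows <- list()
  traits_out <- list()
  xs_reg <- list(); dr_reg <- list(); dr_out <- list()
  for (trait in TRAITS) {
    col <- if (trait == "blade_length") "blade_length_mm" else "blade_width_mm"
    keys <- unique(records[c("genotype", "tln")])
    keys <- keys[order(keys$genotype, keys$tln), , drop = FALSE]
    trait_fits <- list()
    for (i in seq_len(nrow(keys))) {
      g <- keys$genotype[i]; tl <- keys$tln[i]
      sub <- records[records$genotype == g & records$tln == tl, , drop = FALSE]
      sub <- sub[is.finite(sub[[col]]), , drop = FALSE]
      gid <- sprintf("%s/%s/TLN %d", trait, g, tl)
      if (nrow(sub) < config$min_obs) {
        log <- c(log, sprintf("skipped %s: %d obs < min_obs %d",
                              gid, nrow(sub), config$min_obs))
        next
      }
      grp <- tln_group(sp, g, trait, tl, sub$position, sub[[col]],
                       min_obs = config$min_obs)
      fit <- fit_profile(grp)
      trait_fits[[gid]] <- fit
      est <- if (!is.null(fit$params)) unlist(fit$params[PAR_NAMES])
             else stats::setNames(rep(NA_real_, 7), PAR_NAMES)
      diag_rows[[gid]] <- data.frame(
        trait = trait, genotype = g, tln = tl, n = fit$n,
        rss = fit$rss, rmse = fit$rmse, r2 = fit$r2,
        converged = fit$converged,
        t(est), t(stats::setNames(fit$std_errors, paste0("se_", PAR_NAMES))))
      if (!fit$converged)
        log <- c(log, sprintf("fit for %s did not converge", gid))
    }
    ok <- vapply(trait_fits, function(f) isTRUE(f$converged), logical(1))
    kept <- trait_fits[ok]
    tlns <- vapply(kept, function(f) f$group$tln, numeric(1))
    if (length(unique(tlns)) < config$min_groups)
      stop(sprintf(
        "calibrate_species: %s has %d distinct TLN groups with converged fits; %d required",
        trait, length(unique(tlns)), config$min_groups), call. = FALSE)

    par_mat <- t(vapply(kept, function(f) unlist(f$params[PAR_NAMES]),
                        numeric(7)))
    se_mat <- t(vapply(kept, function(f) f$std_errors, numeric(7)))
    fixed <- vapply(c("L1", "cm", "rm", "tb", "dsl"), function(pn)
      pool_estimates(par_mat[, pn], se_mat[, pn], config$pool), numeric(1))

    xs_pts <- data.frame(tln = tlns, value = par_mat[, "xs"])
    xs_reg[[trait]] <- if (xs_form == "segmented")
      fit_tln_segmented(xs_pts, breakpoint = config$xs_breakpoint)
    else fit_tln_linear(xs_pts)

    dr_pts <- data.frame(tln = tlns, value = par_mat[, "dr"])
    out <- flag_dr_outliers(dr_pts, quantile = config$dr_quantile)
    if (any(out))
      log <- c(log, sprintf("%s: removed %d dr outlier(s) at TLN %s", trait,
                            sum(out), paste(dr_pts$tln[out], collapse = ", ")))
    dr_out[[trait]] <- out
    dr_reg[[trait]] <- fit_tln_plateau(dr_pts[!out, , drop = FALSE])

    traits_out[[trait]] <- list(
      fixed = fixed,
      se = vapply(c("L1", "cm", "rm", "tb", "dsl"), function(pn) {
        e <- par_mat[, pn]
        if (length(e) > 1) stats::sd(e) / sqrt(length(e)) else NA_real_
      }, numeric(1)),
      xs_rule = xs_reg[[trait]]$rule,
      dr_rule = dr_reg[[trait]]$rule)
    fits <- c(fits, trait_fits)
  }

  params <- species_params(sp, traits_out)
  structure(list(params = params, fits = fits,
                 group_diagnostics = do.call(rbind, diag_rows),
                 xs_regression = xs_reg, dr_regression = dr_reg,
                 dr_outliers = dr_out, log = log),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration for %s: %d group fits, %d log messages\n",
              x$params$species, length(x$fits), length(x$log)))
  print(x$params)
  invisible(x)
}
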