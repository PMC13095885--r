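#' Seven-parameter description of one leaf-size trait curve
#'
#' Bundles the parameters of the expolinear-logistic leaf size model for one
#' trait (blade length or blade width) on one axis: the first-leaf size
#' \code{L1} (mm), the maximum linear-phase slope \code{cm} (mm per leaf), the
#' exponential-phase rate \code{rm} (per leaf), the linear-phase offset
#' \code{tb} (leaf positions), the position of the largest leaf \code{xs}
#' (leaf positions, real-valued), the logistic decay rate \code{dr} (per
#' leaf) and the upper-asymptote offset \code{dsl} (mm).
#'
#' @param L1 first-leaf (coleoptile leaf) blade size, mm; must be > 0.
#' @param cm maximum slope of the linear phase, mm per leaf; must be > 0.
#' @param rm rate of the exponential phase, per leaf; must be > 0.
#' @param tb leaf-position offset of the expolinear term.
#' @param xs leaf position of the largest leaf; must be > 1.
#' @param dr decay rate of the logistic phase, per leaf; must be >= 0.
#' @param dsl offset of the upper asymptote above the maximum size, mm;
#'   must be >= 0.
#'
#' @return An object of class \code{profile_params} (a named list).
#' @seealso [leaf_dimension()], [build_params()]
#' @export
#' @examples
#' p <- profile_params(L1 = 51.18, cm = 123.84, rm = 1.17, tb = 2.02,
#'                     xs = 9.09, dr = 0.67, dsl = 12.53)
#' y_max(p)
profile_params <- function(L1, cm, rm, tb, xs, dr, dsl) {
  p <- structure(list(L1 = as.numeric(L1), cm = as.numeric(cm),
                      rm = as.numeric(rm), tb = as.numeric(tb),
                      xs = as.numeric(xs), dr = as.numeric(dr),
                      dsl = as.numeric(dsl)),
                 class = "profile_params")
  validate_profile_params(p)
  p
}

#' @rdname profile_params
#' @param p object to validate.
#' @export
validate_profile_params <- function(p) {
  vals <- unlist(p[c("L1", "cm", "rm", "tb", "xs", "dr", "dsl")])
  if (any(!is.finite(vals)))
    stop("profile_params: all parameters must be finite numbers", call. = FALSE)
  if (p$L1 <= 0) stop("profile_params: invariant violated: L1 > 0", call. = FALSE)
  if (p$cm <= 0) stop("profile_params: invariant violated: cm > 0", call. = FALSE)
  if (p$rm <= 0) stop("profile_params: invariant violated: rm > 0", call. = FALSE)
  if (p$xs <= 1) stop("profile_params: invariant violated: xs > 1", call. = FALSE)
  if (p$dr < 0) stop("profile_params: invariant violated: dr >= 0", call. = FALSE)
  if (p$dsl < 0) stop("profile_params: invariant violated: dsl >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.profile_params <- function(x, ...) {
  cat("Expolinear-logistic profile parameters:\n")
  print(unlist(x[c("L1", "cm", "rm", "tb", "xs", "dr", "dsl")]))
  invisible(x)
}

#' Parameters of the bell-shaped leaf area baseline
#'
#' The single-equation baseline used by earlier crop models expresses
#' mature leaf area directly as a bell-shaped function of leaf position:
#' \code{Y0 * exp(a * (x - x0)^2 + b * (x - x0)^3)}. It is provided here as
#' a comparison baseline for the expolinear-logistic profile.
#'
#' @param Y0 area of the largest leaf, mm^2; must be > 0.
#' @param x0 position of the largest leaf; must be > 0.
#' @param a breadth coefficient (dimensionless, typically negative).
#' @param b skewness coefficient (dimensionless).
#' @return An object of class \code{bell_params}.
#' @seealso [bell_leaf_area()]
#' @export
bell_params <- function(Y0, x0, a, b) {
  if (!is.finite(Y0) || Y0 <= 0) stop("bell_params: Y0 must be > 0", call. = FALSE)
  if (!is.finite(x0) || x0 <= 0) stop("bell_params: x0 must be > 0", call. = FALSE)
  structure(list(Y0 = as.numeric(Y0), x0 = as.numeric(x0),
                 a = as.numeric(a), b = as.numeric(b)),
            class = "bell_params")
}

# ---- TLN rules ------------------------------------------------------------

#' Rules relating a profile parameter to total leaf number
#'
#' Three functional forms relate the TLN-dependent parameters to total leaf
#' number (TLN): a straight line (largest-leaf position `xs` in maize and
#' pearl millet), a continuous segmented line with one breakpoint (`xs` in
#' sorghum), and a continuous decline-then-plateau "hockey stick" (the
#' logistic decay rate `dr` in all species).
#'
#' The segmented rule is parameterized with a single intercept so that it is
#' continuous at the breakpoint by construction:
#' \code{a + b * min(tln, bp) + c * max(tln - bp, 0)}. The plateau rule is
#' the declining line evaluated at \code{min(tln, bp)}, so its constant
#' plateau value equals the line at the breakpoint.
#'
#' @param a intercept.
#' @param b slope (first segment for the segmented/plateau rules).
#' @param c slope of the second segment (segmented rule only).
#' @param bp breakpoint in TLN units; must be > 0.
#' @return An object of class \code{tln_rule} (subclass per form).
#' @seealso [xs_from_tln()], [dr_from_tln()]
#' @export
tln_linear_rule <- function(a, b) {
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = c("tln_linear_rule", "tln_rule"))
}

#' @rdname tln_linear_rule
#' @export
tln_segmented_rule <- function(a, b, c, bp) {
  if (!is.finite(bp) || bp <= 0)
    stop("tln_segmented_rule: breakpoint must be > 0", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 bp = as.numeric(bp)),
            class = c("tln_segmented_rule", "tln_rule"))
}

#' @rdname tln_linear_rule
#' @export
tln_plateau_rule <- function(a, b, bp) {
  if (!is.finite(bp) || bp <= 0)
    stop("tln_plateau_rule: breakpoint must be > 0", call. = FALSE)
  if (b >= 0)
    stop("tln_plateau_rule: slope must be negative (decline then plateau)",
         call. = FALSE)
  if (a + b * bp <= 0)
    stop("tln_plateau_rule: plateau value a + b*bp must be > 0", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), bp = as.numeric(bp)),
            class = c("tln_plateau_rule", "tln_rule"))
}

eval_tln_rule <- function(rule, tln) {
  UseMethod("eval_tln_rule")
}

#' @export
eval_tln_rule.tln_linear_rule <- function(rule, tln) {
  rule$a + rule$b * tln
}

#' @export
eval_tln_rule.tln_segmented_rule <- function(rule, tln) {
  rule$a + rule$b * pmin(tln, rule$bp) + rule$c * pmax(tln - rule$bp, 0)
}

#' @export
eval_tln_rule.tln_plateau_rule <- function(rule, tln) {
  rule$a + rule$b * pmin(tln, rule$bp)
}

#' Largest-leaf position from total leaf number
#'
#' Evaluates the xs-vs-TLN rule (linear or segmented). The position of the
#' largest leaf increases with TLN; for sorghum the slope changes at a TLN
#' of 20.5.
#'
#' @param rule a [tln_linear_rule()] or [tln_segmented_rule()].
#' @param tln total leaf number (>= 2); may be a vector.
#' @return Real-valued leaf position(s) of the largest leaf.
#' @export
#' @examples
#' xs_from_tln(tln_linear_rule(1.10, 0.47), 17)  # maize blade length: 9.09
xs_from_tln <- function(rule, tln) {
  stopifnot(inherits(rule, "tln_rule"))
  if (any(tln < 2)) stop("xs_from_tln: tln must be >= 2", call. = FALSE)
  xs <- eval_tln_rule(rule, tln)
  bad <- xs >= tln | xs <= 1
  if (any(bad))
    warning(sprintf(
      "xs_from_tln: rule gives xs outside (1, tln) for tln = %s; parameter set and tln are inconsistent",
      paste(tln[bad], collapse = ", ")), call. = FALSE)
  xs
}

#' Logistic decay rate from total leaf number
#'
#' Evaluates the decline-then-plateau rule for the decay rate `dr`: the rate
#' falls linearly with TLN up to a species- and trait-specific breakpoint and
#' stays constant beyond it.
#'
#' @param rule a [tln_plateau_rule()].
#' @param tln total leaf number (>= 2); may be a vector.
#' @return Decay rate(s), per leaf.
#' @export
#' @examples
#' dr_from_tln(tln_plateau_rule(2.88, -0.13, 17.63), 17)  # 0.67
dr_from_tln <- function(rule, tln) {
  stopifnot(inherits(rule, "tln_plateau_rule"))
  if (any(tln < 2)) stop("dr_from_tln: tln must be >= 2", call. = FALSE)
  dr <- eval_tln_rule(rule, tln)
  if (any(dr <= 0))
    stop("dr_from_tln: rule gives a non-positive decay rate", call. = FALSE)
  dr
}

# ---- species parameter sets ----------------------------------------------

SPECIES_IDS <- c("maize", "sorghum", "pearl_millet")
TRAITS <- c("blade_length", "blade_width")

match_species <- function(species) {
  match.arg(species, SPECIES_IDS)
}

match_trait <- function(trait) {
  match.arg(trait, TRAITS)
}

#' Assemble a species parameter set
#'
#' A species parameter set holds, for each trait (blade length and blade
#' width), the five fixed parameters \code{L1, cm, rm, tb, dsl} with their
#' standard errors, the xs-vs-TLN rule and the dr-vs-TLN rule, plus the two
#' leaf shape factors (0.71 for ordinary leaves, 0.635 for the flag leaf).
#'
#' @param species one of \code{"maize"}, \code{"sorghum"},
#'   \code{"pearl_millet"}.
#' @param traits named list with elements \code{blade_length} and
#'   \code{blade_width}, each a list with \code{fixed} (named numeric:
#'   L1, cm, rm, tb, dsl), optional \code{se} (same names), \code{xs_rule}
#'   and \code{dr_rule}.
#' @param shape_factors named numeric with \code{standard} and \code{flag}
#'   entries, each in (0, 1].
#' @return An object of class \code{species_params}.
#' @seealso [default_species_params()], [build_params()]
#' @export
species_params <- function(species, traits,
                           shape_factors = c(standard = 0.71, flag = 0.635)) {
  species <- match_species(species)
  if (!all(TRAITS %in% names(traits)))
    stop("species_params: both traits (blade_length, blade_width) are required",
         call. = FALSE)
  sf <- shape_factors
  if (!all(c("standard", "flag") %in% names(sf)) ||
      any(sf[c("standard", "flag")] <= 0) || any(sf[c("standard", "flag")] > 1))
    stop("species_params: shape factors must be named standard/flag, in (0, 1]",
         call. = FALSE)
  fixed_names <- c("L1", "cm", "rm", "tb", "dsl")
  for (tr in TRAITS) {
    t <- traits[[tr]]
    if (!all(fixed_names %in% names(t$fixed)))
      stop(sprintf("species_params: trait %s must provide fixed parameters %s",
                   tr, paste(fixed_names, collapse = ", ")), call. = FALSE)
    if (!inherits(t$xs_rule, "tln_rule") ||
        inherits(t$xs_rule, "tln_plateau_rule"))
      stop("species_params: xs_rule must be a linear or segmented TLN rule",
           call. = FALSE)
    if (!inherits(t$dr_rule, "tln_plateau_rule"))
      stop("species_params: dr_rule must be a plateau TLN rule", call. = FALSE)
  }
  structure(list(species = species, traits = traits,
                 shape_factors = c(standard = unname(sf[["standard"]]),
                                   flag = unname(sf[["flag"]]))),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("Species parameter set: %s\n", x$species))
  for (tr in TRAITS) {
    t <- x$traits[[tr]]
    cat(sprintf("  %s: fixed [%s]\n", tr,
                paste(sprintf("%s=%.4g", names(t$fixed), t$fixed),
                      collapse = ", ")))
    cat(sprintf("    xs rule: %s; dr rule: decline-plateau (bp %.4g)\n",
                if (inherits(t$xs_rule, "tln_segmented_rule"))
                  sprintf("segmented (bp %.4g)", t$xs_rule$bp) else "linear",
                t$dr_rule$bp))
  }
  cat(sprintf("  shape factors: standard %.3f, flag %.3f\n",
              x$shape_factors[["standard"]], x$shape_factors[["flag"]]))
  invisible(x)
}

#' Profile parameters for a given trait and total leaf number
#'
#' Combines a species parameter set with a total leaf number: the fixed
#' parameters are copied, the largest-leaf position is computed from the
#' xs-vs-TLN rule and the decay rate from the dr-vs-TLN rule.
#'
#' @param set a [species_params()] object.
#' @param trait \code{"blade_length"} or \code{"blade_width"}.
#' @param tln total leaf number; must lie within \code{tln_range}.
#' @param tln_range plausibility range for TLN (default 8--45, spanning the
#'   observed extremes across the three species).
#' @return A [profile_params()] object.
#' @export
#' @examples
#' p <- build_params(default_species_params("maize"), "blade_length", 17)
#' p$xs  # 9.09
build_params <- function(set, trait, tln, tln_range = c(8, 45)) {
  stopifnot(inherits(set, "species_params"))
  trait <- match_trait(trait)
  if (length(tln) != 1 || tln < tln_range[1] || tln > tln_range[2])
    stop(sprintf("build_params: tln = %s outside plausibility range [%g, %g]",
                 paste(tln, collapse = ","), tln_range[1], tln_range[2]),
         call. = FALSE)
  t <- set$traits[[trait]]
  xs <- suppressWarnings(xs_from_tln(t$xs_rule, tln))
  dr <- dr_from_tln(t$dr_rule, tln)
  profile_params(L1 = t$fixed[["L1"]], cm = t$fixed[["cm"]],
                 rm = t$fixed[["rm"]], tb = t$fixed[["tb"]],
                 xs = xs, dr = dr, dsl = t$fixed[["dsl"]])
}
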