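# numerically stable log(1 + exp(z)); linear for large z, no overflow
softplus <- function(z) {
  out <- z
  pos <- z > 0
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[!pos] <- log1p(exp(z[!pos]))
  out
}

#' Expolinear phase of the leaf size profile
#'
#' Size of successive leaves during the rising phase of the profile:
#' \deqn{y(x) = L1 + (cm/rm) \, \ln(1 + e^{rm (x - tb - 1)})}
#' an expolinear curve that starts at the lower asymptote \code{L1}, grows
#' exponentially at rate \code{rm} and transitions smoothly into a straight
#' line of slope \code{cm}. Evaluated with a softplus formulation, so it is
#' finite for arbitrarily large \code{rm * (x - tb - 1)}.
#'
#' @param x leaf position(s), real-valued.
#' @param p a [profile_params()] object.
#' @return Blade length or width in mm; strictly increasing in \code{x}.
#' @seealso [logistic_value()], [leaf_dimension()]
#' @export
expolinear_value <- function(x, p) {
  validate_profile_params(p)
  p$L1 + (p$cm / p$rm) * softplus(p$rm * (x - p$tb - 1))
}

#' Maximum blade size of a profile
#'
#' The size of the largest leaf, i.e. the expolinear term evaluated at the
#' largest-leaf position \code{xs} (the two phases of the profile meet
#' there, so this is also the value of the logistic phase at its left end).
#'
#' @inheritParams expolinear_value
#' @return Ymax in mm.
#' @export
y_max <- function(p) {
  expolinear_value(p$xs, p)
}

#' Logistic decay phase of the leaf size profile
#'
#' Size of leaves above the largest leaf:
#' \deqn{y(x) = \frac{Y_{max} \, Y_{slevel}}{Y_{max} + (Y_{slevel} - Y_{max}) e^{dr (x - xs)}}}
#' with \eqn{Y_{slevel} = Y_{max} + dsl}. At \code{x = xs} the value equals
#' \code{Ymax}; for \code{dr > 0} and \code{dsl > 0} it decreases strictly
#' towards 0 as \code{x} grows. With \code{dsl = 0} (or \code{dr = 0}) the
#' phase degenerates to the constant \code{Ymax}.
#'
#' @inheritParams expolinear_value
#' @return Blade length or width in mm, always > 0.
#' @export
logistic_value <- function(x, p) {
  validate_profile_params(p)
  ymax <- y_max(p)
  yslevel <- ymax + p$dsl
  if (p$dsl == 0 || p$dr == 0) return(rep(ymax, length(x)))
  e <- exp(p$dr * (x - p$xs))
  # e may overflow to Inf for very large x; the ratio then correctly -> 0
  ymax * yslevel / (ymax + p$dsl * e)
}

#' Blade length or width at a leaf position
#'
#' The full piecewise profile: expolinear below the largest-leaf position
#' \code{xs}, logistic decay from \code{xs} upwards. The two branches agree
#' at \code{xs} by construction (both equal \code{Ymax}).
#'
#' @param x leaf position(s), >= 1.
#' @param p a [profile_params()] object.
#' @return Blade length or width in mm.
#' @export
#' @examples
#' p <- profile_params(51.18, 123.84, 1.17, 2.02, xs = 9.09, dr = 0.67,
#'                     dsl = 12.53)
#' leaf_dimension(1:17, p)
leaf_dimension <- function(x, p) {
  validate_profile_params(p)
  if (any(x < 1)) stop("leaf_dimension: leaf position x must be >= 1",
                       call. = FALSE)
  out <- numeric(length(x))
  lo <- x < p$xs
  if (any(lo)) out[lo] <- expolinear_value(x[lo], p)
  if (any(!lo)) out[!lo] <- logistic_value(x[!lo], p)
  out
}

#' Bell-shaped leaf area baseline
#'
#' The legacy one-equation leaf-area-by-position model,
#' \code{Y0 * exp(a (x - x0)^2 + b (x - x0)^3)}, retained as a comparison
#' baseline for the expolinear-logistic profile.
#'
#' @param x leaf position(s).
#' @param bp a [bell_params()] object.
#' @return Leaf area in mm^2.
#' @export
bell_leaf_area <- function(x, bp) {
  stopifnot(inherits(bp, "bell_params"))
  d <- x - bp$x0
  bp$Y0 * exp(bp$a * d^2 + bp$b * d^3)
}

#' Leaf area from blade length and width
#'
#' Area is the length-by-width bounding rectangle scaled by a leaf shape
#' factor: 0.71 for ordinary leaves and 0.635 for the flag leaf (the
#' topmost leaf), taken from the parameter set's stored factors.
#'
#' @param length blade length, mm (>= 0).
#' @param width blade width, mm (>= 0).
#' @param is_flag logical; is this the flag leaf (position == TLN)?
#' @param set a [species_params()] object supplying the shape factors.
#' @return Leaf area in mm^2. Arguments recycle as usual.
#' @export
#' @examples
#' set <- default_species_params("maize")
#' leaf_area(100, 50, FALSE, set)  # 3550
#' leaf_area(100, 50, TRUE, set)   # 3175
leaf_area <- function(length, width, is_flag, set) {
  stopifnot(inherits(set, "species_params"))
  if (any(length < 0) || any(width < 0))
    stop("leaf_area: length and width must be >= 0", call. = FALSE)
  factor <- ifelse(is_flag, set$shape_factors[["flag"]],
                   set$shape_factors[["standard"]])
  length * width * factor
}

#' Predict the full leaf size profile for a plant
#'
#' Evaluates blade length and blade width at every main-culm leaf position
#' 1..TLN and composes leaf area with the shape factors (the flag-leaf
#' factor applies only at position TLN).
#'
#' @param set a [species_params()] object.
#' @param tln total leaf number.
#' @param tln_range plausibility range passed to [build_params()].
#' @return A data.frame of class \code{leaf_profile} with columns
#'   \code{tln}, \code{position}, \code{length_mm}, \code{width_mm},
#'   \code{area_mm2}, \code{is_flag}.
#' @export
#' @examples
#' prof <- predict_profile(default_species_params("sorghum"), 18)
#' head(prof)
predict_profile <- function(set, tln, tln_range = c(8, 45)) {
  stopifnot(inherits(set, "species_params"))
  p_len <- build_params(set, "blade_length", tln, tln_range)
  p_wid <- build_params(set, "blade_width", tln, tln_range)
  pos <- seq_len(tln)
  len <- leaf_dimension(pos, p_len)
  wid <- leaf_dimension(pos, p_wid)
  is_flag <- pos == tln
  out <- data.frame(tln = as.integer(tln), position = as.integer(pos),
                    length_mm = len, width_mm = wid,
                    area_mm2 = leaf_area(len, wid, is_flag, set),
                    is_flag = is_flag)
  class(out) <- c("leaf_profile", "data.frame")
  out
}
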