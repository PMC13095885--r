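# parameter-set serialization: YAML keyed species -> trait -> parameters

rule_from_list <- function(lst) {
  type <- lst$type
  if (is.null(type)) {
    # infer: bp + c => segmented, bp without c => plateau, else linear
    type <- if (!is.null(lst$bp) && !is.null(lst$c)) "segmented"
            else if (!is.null(lst$bp)) "plateau" else "linear"
  }
  rule <- switch(type,
    linear = tln_linear_rule(lst$a, lst$b),
    segmented = tln_segmented_rule(lst$a, lst$b, lst$c, lst$bp),
    plateau = tln_plateau_rule(lst$a, lst$b, lst$bp),
    stop(sprintf("unknown TLN rule type: %s", type), call. = FALSE))
  if (!is.null(lst$se)) attr(rule, "se") <- unlist(lst$se)
  rule
}

rule_to_list <- function(rule) {
  out <- unclass(rule)
  out$type <- if (inherits(rule, "tln_segmented_rule")) "segmented"
              else if (inherits(rule, "tln_plateau_rule")) "plateau"
              else "linear"
  se <- attr(rule, "se")
  if (!is.null(se)) out$se <- as.list(se)
  out[c("type", setdiff(names(out), "type"))]
}

#' Read and write species parameter sets
#'
#' Parameter sets are stored as YAML keyed species -> trait ->
#' \{fixed, se, xs_rule, dr_rule\}, with a top-level \code{shape_factors}
#' block. A file may hold one or several species.
#'
#' @param path file path of a parameter-set YAML document.
#' @param species which species to extract.
#' @return \code{read_species_params} returns a [species_params()] object.
#' @export
read_species_params <- function(path, species) {
  species <- match_species(species)
  doc <- yaml::read_yaml(path)
  if (is.null(doc[[species]]))
    stop(sprintf("parameter file %s has no entry for species '%s'",
                 path, species), call. = FALSE)
  sf <- doc$shape_factors
  if (is.null(sf)) sf <- list(standard = 0.71, flag = 0.635)
  traits <- lapply(doc[[species]][TRAITS], function(t) {
    list(fixed = unlist(t$fixed),
         se = if (!is.null(t$se)) unlist(t$se) else NULL,
         xs_rule = rule_from_list(t$xs_rule),
         dr_rule = rule_from_list(t$dr_rule))
  })
  names(traits) <- TRAITS
  species_params(species, traits,
                 shape_factors = c(standard = sf$standard, flag = sf$flag))
}

#' @rdname read_species_params
#' @param set a [species_params()] object to serialize.
#' @return \code{write_species_params} returns \code{path}, invisibly.
#' @export
write_species_params <- function(set, path) {
  stopifnot(inherits(set, "species_params"))
  doc <- list(shape_factors = as.list(set$shape_factors))
  doc[[set$species]] <- lapply(set$traits, function(t) {
    out <- list(fixed = as.list(t$fixed))
    if (!is.null(t$se)) out$se <- as.list(t$se)
    out$xs_rule <- rule_to_list(t$xs_rule)
    out$dr_rule <- rule_to_list(t$dr_rule)
    out
  })
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Packaged species-generic parameter sets
#'
#' Returns the packaged generic parameter set for one of the three species.
#' These are the species-level calibration values (with standard errors)
#' obtained from the multi-experiment training compilation: fixed
#' parameters \code{L1, cm, rm, tb, dsl} per trait, the xs-vs-TLN rule
#' (linear for maize and pearl millet, segmented with breakpoint 20.5 for
#' sorghum) and the decline-then-plateau dr-vs-TLN rule, plus shape factors
#' 0.71 / 0.635.
#'
#' @param species \code{"maize"}, \code{"sorghum"} or \code{"pearl_millet"}.
#' @return A [species_params()] object.
#' @export
#' @examples
#' default_species_params("maize")
default_species_params <- function(species) {
  species <- match_species(species)
  path <- system.file("extdata", "species_params.yaml",
                      package = "leafprofile", mustWork = TRUE)
  read_species_params(path, species)
}
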