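#' Configuration for the synthetic leaf-measurement generator
#'
#' Describes a simulated measurement campaign with the structure of the
#' multi-experiment training compilations: several genotypes per species,
#' a spread of total leaf numbers, several plants per TLN, and per-leaf
#' measurement noise on blade length and width.
#'
#' @param species species id; selects the packaged generating parameter
#'   set unless \code{genotypes} overrides it.
#' @param genotypes character vector of genotype labels, or a named list
#'   label -> [species_params()] override (\code{NULL} entries use the
#'   generic set).
#' @param tln_values integer total leaf numbers to simulate.
#' @param plants_per_tln plants per genotype x TLN combination (>= 1).
#' @param noise list: \code{model} (\code{"additive"} or
#'   \code{"proportional"}), and either \code{sd_mm} (named: blade_length,
#'   blade_width) or \code{cv}. Defaults: additive, sd 20 mm for length
#'   and 3 mm for width.
#' @param missing_rate probability that an individual measurement is
#'   missing (independently per leaf and trait), in [0, 1).
#' @param genotype_cv lognormal coefficient of variation of
#'   genotype-level multiplicative perturbations applied to cm and L1
#'   (default 0: all genotypes share the generic parameters).
#' @param seed integer seed; mandatory, every run is reproducible.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(species,
                       genotypes = c("G1", "G2"),
                       tln_values,
                       plants_per_tln = 5,
                       noise = list(model = "additive",
                                    sd_mm = c(blade_length = 20, blade_width = 3)),
                       missing_rate = 0,
                       genotype_cv = 0,
                       seed) {
  species <- match_species(species)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("sim_config: an explicit integer seed is mandatory", call. = FALSE)
  if (plants_per_tln < 1) stop("sim_config: plants_per_tln must be >= 1",
                               call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("sim_config: missing_rate must be in [0, 1)", call. = FALSE)
  noise$model <- match.arg(noise$model, c("additive", "proportional"))
  if (noise$model == "additive") {
    if (is.null(noise$sd_mm)) noise$sd_mm <- c(blade_length = 20, blade_width = 3)
    if (any(noise$sd_mm < 0)) stop("sim_config: noise sd must be >= 0",
                                   call. = FALSE)
  } else {
    if (is.null(noise$cv)) noise$cv <- 0.05
    if (any(noise$cv < 0)) stop("sim_config: noise cv must be >= 0",
                                call. = FALSE)
  }
  if (is.character(genotypes)) {
    genotypes <- stats::setNames(vector("list", length(genotypes)), genotypes)
  }
  structure(list(species = species, genotypes = genotypes,
                 tln_values = as.integer(tln_values),
                 plants_per_tln = as.integer(plants_per_tln),
                 noise = noise, missing_rate = missing_rate,
                 genotype_cv = genotype_cv, seed = as.integer(seed)),
            class = "sim_config")
}

perturb_set <- function(set, factors) {
  for (tr in TRAITS) {
    set$traits[[tr]]$fixed[["cm"]] <- set$traits[[tr]]$fixed[["cm"]] * factors[["cm"]]
    set$traits[[tr]]$fixed[["L1"]] <- set$traits[[tr]]$fixed[["L1"]] * factors[["L1"]]
  }
  set
}

#' Generate a synthetic leaf-measurement dataset
#'
#' For every genotype x TLN x plant combination, evaluates the
#' expolinear-logistic profile under the generating parameter set, adds
#' independent measurement noise per leaf and trait, truncates at a 1 mm
#' floor, and deletes values at the configured missing rate. The exact
#' generating parameters are returned alongside the records as the truth
#' for parameter-recovery experiments.
#'
#' @param cfg a [sim_config()].
#' @return A list with \code{records} (a data.frame in the leaf-record
#'   CSV layout) and \code{truth} (named list of generating
#'   [species_params()] per genotype).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config("maize", tln_values = 15:18,
#'                                    plants_per_tln = 2, seed = 42))
#' head(sim$records)
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  generic <- default_species_params(cfg$species)
  truth <- list()
  rows <- vector("list", 0)
  plant <- 0L
  for (g in names(cfg$genotypes)) {
    gset <- cfg$genotypes[[g]]
    if (is.null(gset)) gset <- generic
    if (cfg$genotype_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$genotype_cv^2))
      gset <- perturb_set(gset, c(cm = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
                                  L1 = stats::rlnorm(1, -sdlog^2 / 2, sdlog)))
    }
    truth[[g]] <- gset
    for (tl in cfg$tln_values) {
      prof <- predict_profile(gset, tl)
      for (k in seq_len(cfg$plants_per_tln)) {
        plant <- plant + 1L
        len <- add_noise(prof$length_mm, "blade_length", cfg$noise)
        wid <- add_noise(prof$width_mm, "blade_width", cfg$noise)
        if (cfg$missing_rate > 0) {
          len[stats::runif(tl) < cfg$missing_rate] <- NA_real_
          wid[stats::runif(tl) < cfg$missing_rate] <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = sprintf("P%05d", plant), species = cfg$species,
          genotype = g, tln = tl, position = prof$position,
          blade_length_mm = len, blade_width_mm = wid)
      }
    }
  }
  list(records = do.call(rbind, rows), truth = truth)
}

add_noise <- function(values, trait, noise) {
  n <- length(values)
  out <- if (noise$model == "additive") {
    sd <- noise$sd_mm[[trait]]
    values + if (sd > 0) stats::rnorm(n, 0, sd) else 0
  } else {
    values * (1 + if (noise$cv > 0) stats::rnorm(n, 0, noise$cv) else 0)
  }
  pmax(out, 1)  # physical floor, mm
}

TABLE1_TLN_RANGE <- list(maize = c(11L, 25L), sorghum = c(9L, 44L),
                         pearl_millet = c(11L, 27L))

#' Convenience multi-genotype panel with realistic TLN spread
#'
#' Emits a synthetic panel whose total-leaf-number spread matches the
#' observed ranges of the training compilations (maize 11--25, sorghum
#' 9--44, pearl millet 11--27), with three genotypes sharing the generic
#' parameters, five plants per TLN and the default additive noise. For
#' sorghum the TLN range starts at 12 so every group's largest leaf sits
#' below the flag leaf. Intended as a ready-made fixture for tests and
#' examples.
#'
#' @param species species id.
#' @param seed integer seed.
#' @param noise optional noise list (see [sim_config()]).
#' @param plants_per_tln plants per genotype x TLN (default 5).
#' @return A data.frame of leaf records.
#' @export
table1_style_panel <- function(species, seed,
                               noise = list(model = "additive",
                                            sd_mm = c(blade_length = 20,
                                                      blade_width = 3)),
                               plants_per_tln = 5) {
  species <- match_species(species)
  r <- TABLE1_TLN_RANGE[[species]]
  lo <- if (species == "sorghum") 12L else r[1]
  cfg <- sim_config(species, genotypes = c("G1", "G2", "G3"),
                    tln_values = seq(lo, r[2]),
                    plants_per_tln = plants_per_tln,
                    noise = noise, seed = seed)
  generate_dataset(cfg)$records
}
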