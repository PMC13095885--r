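# shared fixtures: random valid parameter draws and noiseless model groups

random_profile_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tb <- stats::runif(1, 0.5, 6)
    profile_params(L1 = stats::runif(1, 2, 60),
                   cm = stats::runif(1, 2, 150),
                   rm = stats::runif(1, 0.2, 3),
                   tb = tb,
                   xs = tb + 1 + stats::runif(1, 0.5, 15),
                   dr = stats::runif(1, 0.05, 3),
                   dsl = stats::runif(1, 0.01, 20))
  })
}

# noiseless observations at integer positions from a packaged species set
model_group <- function(species, trait, tln, genotype = "G1") {
  set <- default_species_params(species)
  prof <- predict_profile(set, tln)
  col <- if (trait == "blade_length") "length_mm" else "width_mm"
  tln_group(species, genotype, trait, tln, prof$position, prof[[col]])
}

# closed-form OLS oracle, independent of stats::lm
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
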