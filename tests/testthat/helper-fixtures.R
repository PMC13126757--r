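# Shared fixtures: published point estimates, the calibrated German-like
# Gompertz hazard, and lazily cached synthetic worlds / fits reused across
# test files (fits are expensive; the cache keeps the suite fast).

published_inc <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") incidence_params(0.076334, 87.5, 25.33680)
  else incidence_params(0.063473, 87.5, 25.18237)
}

published_mrr <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") mrr_params(0.408, -0.0171)
  else mrr_params(0.321, -0.0376)
}

german_gompertz <- function() gompertz_params(-11.1174714, 0.1034062)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

noiseless_world <- function() {
  cached("noiseless_world", generate_truth(synthetic_config(noise = "none")))
}

noisy_world <- function() {
  cached("noisy_world", simulate_prevalence(synthetic_config(seed = 1L)))
}

sex_obs <- function(world, sex) {
  src <- if (!is.null(world$observed)) world$observed else world$prevalence
  aggregated_prevalence(as.data.frame(src[src$sex == sex, ]))
}

world_hazard <- function(world, sex) {
  as_hazard(world$mortality, t = 2013.5, sex = sex)
}

noiseless_fit <- function(sex) {
  cached(paste0("noiseless_fit_", sex), {
    w <- noiseless_world()
    fit_incidence(sex_obs(w, sex), world_hazard(w, sex), seed = 1L)
  })
}

noisy_fit <- function(sex) {
  cached(paste0("noisy_fit_", sex), {
    w <- noisy_world()
    fit_incidence(sex_obs(w, sex), world_hazard(w, sex), seed = 1L)
  })
}
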