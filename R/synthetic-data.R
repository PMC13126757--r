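#' Configuration of the synthetic claims-prevalence generator
#'
#' Describes a synthetic world: true incidence and MRR parameters per sex, a
#' Gompertz all-cause hazard per sex, calendar years, per-group person
#' denominators and the sampling-noise mode.  The defaults emulate the
#' German statutory-health-insurance hypertension setting: the published
#' point estimates as true parameters (peak ages fixed at 87.5 years), a
#' Gompertz hazard calibrated to a German-like life table (life expectancy
#' 80 years at birth, 6 years at age 85), ten annual cross-sections
#' 2009-2018, and claims-scale denominators of 10^5 to 10^7 persons per
#' age-sex group summing to about 70 million insured.
#'
#' @param true_inc Named list (`male`, `female`) of [incidence_params()].
#' @param true_mrr Named list (`male`, `female`) of [mrr_params()].
#' @param gompertz Named list (`male`, `female`) of [gompertz_params()].
#' @param years Calendar years of the annual cross-sections.
#' @param groups Age-group schema (`age_lo`, `age_hi` data frame).
#' @param group_denoms Named list (`male`, `female`) of per-group person
#'   counts (one per row of `groups`).
#' @param noise `"binomial"` or `"none"`.
#' @param top_age Representative age of the open top group.
#' @param seed Integer seed used by [simulate_prevalence()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(true_inc = NULL, true_mrr = NULL,
                             gompertz = NULL, years = 2009:2018,
                             groups = zi_age_groups(),
                             group_denoms = NULL,
                             noise = c("binomial", "none"),
                             top_age = 91, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(true_inc))
    true_inc <- list(male = incidence_params(0.076334, 87.5, 25.33680),
                     female = incidence_params(0.063473, 87.5, 25.18237))
  if (is.null(true_mrr))
    true_mrr <- list(male = mrr_params(0.408, -0.0171),
                     female = mrr_params(0.321, -0.0376))
  if (is.null(gompertz)) {
    g <- gompertz_params(-11.1174714, 0.1034062)
    gompertz <- list(male = g, female = g)
  }
  if (is.null(group_denoms)) {
    # per-sex persons per group, German-age-structure magnitudes (~35M/sex)
    d <- c(8.7e6, 4.5e6, 4.4e6, 5.6e6, 4.6e6, 3.5e6, 2.7e6, 9e5)
    if (nrow(groups) != length(d))
      stop("supply group_denoms for a non-default group schema")
    group_denoms <- list(male = d, female = d)
  }
  stopifnot(length(years) >= 1L,
            all(vapply(group_denoms, function(v) all(v > 0), logical(1))),
            all(vapply(group_denoms, length, integer(1)) == nrow(groups)))
  for (s in c("male", "female")) {
    stopifnot(inherits(true_inc[[s]], "incidence_params"),
              inherits(true_mrr[[s]], "mrr_params"),
              inherits(gompertz[[s]], "gompertz_params"))
  }
  structure(list(true_inc = true_inc, true_mrr = true_mrr,
                 gompertz = gompertz, years = years, groups = groups,
                 group_denoms = group_denoms, noise = noise,
                 top_age = top_age, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic aggregated-prevalence configuration\n")
  cat(sprintf("  years %d-%d, %d age groups, noise: %s, seed: %d\n",
              min(x$years), max(x$years), nrow(x$groups), x$noise, x$seed))
  cat(sprintf("  total denominator: %.1f million persons\n",
              sum(unlist(x$group_denoms)) / 1e6))
  invisible(x)
}

#' Noise-free synthetic prevalence and mortality from known truths
#'
#' Forward model of the whole pipeline: solves the illness-death prevalence
#' ODE at the configured true parameters per sex, aggregates to the
#' age-group level, replicates the (trend-free) cross-section across the
#' configured years, and tabulates the Gompertz hazard as an HMD-style
#' mortality table on integer ages 0-110 (the `total` rates are the
#' unweighted mean of the two sexes).
#'
#' @param config A [synthetic_config()].
#' @param aggregate Group aggregation mode passed to
#'   [model_group_prevalence()].
#' @param age_step Solver grid step.
#' @return List with `prevalence` (noise-free `aggregated_prevalence`),
#'   `mortality` (a `mortality_table`) and `config`.
#' @export
generate_truth <- function(config, aggregate = "midpoint", age_step = 0.05) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- list()
  for (s in c("male", "female")) {
    p_grp <- model_group_prevalence(config$true_inc[[s]], config$true_mrr[[s]],
                                    config$gompertz[[s]], config$groups,
                                    aggregate = aggregate,
                                    top_age = config$top_age,
                                    age_step = age_step)
    for (y in config$years) {
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, year = y,
        age_lo = config$groups$age_lo, age_hi = config$groups$age_hi,
        prev = p_grp, denom = config$group_denoms[[s]],
        stringsAsFactors = FALSE)
    }
  }
  prevalence <- aggregated_prevalence(do.call(rbind, rows))

  ages <- 0:110
  mrows <- list()
  for (y in config$years) {
    fm <- gompertz_mortality(ages, config$gompertz$female)
    ml <- gompertz_mortality(ages, config$gompertz$male)
    mrows[[length(mrows) + 1L]] <- data.frame(
      year = as.integer(y), age = rep(ages, 3L),
      sex = rep(c("female", "male", "total"), each = length(ages)),
      mx = c(fm, ml, (fm + ml) / 2), stringsAsFactors = FALSE)
  }
  mortality <- new_mortality_table(do.call(rbind, mrows),
                                   source = "synthetic Gompertz")
  list(prevalence = prevalence, mortality = mortality, config = config)
}

#' Add binomial sampling noise to noise-free prevalence
#'
#' Each cell's diseased count is drawn `Binomial(denom, prev)` and the
#' observed proportion is count/denom, emulating exhaustive claims counts at
#' the configured denominators.  Uses the current RNG state.
#'
#' @param truth A noise-free `aggregated_prevalence`.
#' @param config A [synthetic_config()] (only `noise` is consulted;
#'   `"none"` returns `truth` unchanged).
#' @return An `aggregated_prevalence` with sampled proportions.
#' @export
add_sampling_noise <- function(truth, config) {
  stopifnot(inherits(truth, "aggregated_prevalence"),
            inherits(config, "synthetic_config"))
  if (config$noise == "none") return(truth)
  counts <- stats::rbinom(nrow(truth), size = round(truth$denom),
                          prob = truth$prev)
  truth$prev <- counts / round(truth$denom)
  truth
}

#' Simulate a full synthetic dataset
#'
#' [generate_truth()] followed by [add_sampling_noise()] under the
#' configured seed.
#'
#' @inheritParams generate_truth
#' @return As [generate_truth()], plus `observed` (the noisy prevalence).
#' @export
simulate_prevalence <- function(config, aggregate = "midpoint",
                                age_step = 0.05) {
  world <- generate_truth(config, aggregate = aggregate, age_step = age_step)
  set.seed(config$seed)
  world$observed <- add_sampling_noise(world$prevalence, config)
  world
}
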