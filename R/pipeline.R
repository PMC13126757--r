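#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end pipeline
#' (simulate -> fit -> bootstrap -> report).  Exactly one input source must
#' be configured: either file paths to observed data (`prevalence`,
#' `mortality`) or a synthetic world (`synthetic = TRUE`, generated from
#' `synthetic_config`).
#'
#' @param prevalence Path to an aggregated prevalence CSV (or `NULL`).
#' @param mortality Path to an HMD-style or long-CSV mortality file (or
#'   `NULL`).
#' @param synthetic If `TRUE`, inputs are generated by the synthetic module.
#' @param synthetic_config A [synthetic_config()] (defaults used if `NULL`
#'   and `synthetic` is `TRUE`).
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param beta2 Fixed age of the incidence maximum (years).
#' @param replicates Bootstrap replicate count.
#' @param seed Root seed; all pipeline randomness flows from it.
#' @param aggregate Group aggregation mode (`"midpoint"`/`"weighted"`).
#' @param objective Objective mode (`"trajectory"`/`"derivative"`).
#' @param t_ref Calendar time of the pooled cross-section.
#' @param top_age Representative age of the open top group.
#' @param out Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(prevalence = NULL, mortality = NULL,
                            synthetic = FALSE, synthetic_config = NULL,
                            sex = "both", beta2 = 87.5, replicates = 1000L,
                            seed = 1L, aggregate = "midpoint",
                            objective = "trajectory", t_ref = 2013.5,
                            top_age = 91, out = ".") {
  have_files <- !is.null(prevalence) || !is.null(mortality)
  if (synthetic && have_files)
    stop("configure either input files or a synthetic world, not both")
  if (!synthetic && (is.null(prevalence) || is.null(mortality)))
    stop("need both 'prevalence' and 'mortality' paths (or synthetic = TRUE)")
  if (synthetic && is.null(synthetic_config))
    synthetic_config <- previnc::synthetic_config(seed = seed)
  stopifnot(replicates >= 1L, sex %in% c("male", "female", "both"))
  structure(list(prevalence = prevalence, mortality = mortality,
                 synthetic = synthetic, synthetic_config = synthetic_config,
                 sex = sex, beta2 = beta2, replicates = as.integer(replicates),
                 seed = as.integer(seed), aggregate = aggregate,
                 objective = objective, t_ref = t_ref, top_age = top_age,
                 out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; the
#' `synthetic_config` block may override true parameters with scalar keys
#' `beta1`, `beta2`, `beta3`, `gamma1`, `gamma2` per sex plus `g0`, `g1`,
#' `years`, `seed` and `noise`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- NULL
  if (!is.null(y$synthetic_config)) {
    s <- y$synthetic_config
    per_sex <- function(block, default) {
      if (is.null(block)) return(default)
      list(male = block$male, female = block$female)
    }
    mk_inc <- function(b) incidence_params(b$beta1, b$beta2 %||% 87.5, b$beta3)
    mk_mrr <- function(b) mrr_params(b$gamma1, b$gamma2)
    mk_gmp <- function(b) gompertz_params(b$g0, b$g1)
    sc <- synthetic_config(
      true_inc = if (!is.null(s$true_inc)) lapply(per_sex(s$true_inc, NULL), mk_inc),
      true_mrr = if (!is.null(s$true_mrr)) lapply(per_sex(s$true_mrr, NULL), mk_mrr),
      gompertz = if (!is.null(s$gompertz)) lapply(per_sex(s$gompertz, NULL), mk_gmp),
      years = s$years %||% 2009:2018,
      noise = s$noise %||% "binomial",
      seed = s$seed %||% (y$seed %||% 1L))
  }
  do.call(pipeline_config,
          c(y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                          "synthetic_config"))],
            list(synthetic_config = sc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(...) message(sprintf(...))

#' Simulate subcommand: write a synthetic dataset to disk
#'
#' Writes `prevalence.csv`, `mortality.csv` and a `truth.json` manifest (the
#' generating parameters, denominators, years, noise mode and seed, for
#' later recovery checks) into the configured output directory.
#'
#' @param config A `pipeline_config` with `synthetic = TRUE`.
#' @return Invisibly, the list of written paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$synthetic) stop("cmd_simulate needs a synthetic configuration")
  sc <- config$synthetic_config
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out)) stop("cannot create output directory ", config$out)
  world <- simulate_prevalence(sc, aggregate = config$aggregate)
  paths <- list(prevalence = file.path(config$out, "prevalence.csv"),
                mortality = file.path(config$out, "mortality.csv"),
                truth = file.path(config$out, "truth.json"))
  write_prevalence(world$observed, paths$prevalence)
  write_mortality(world$mortality, paths$mortality)
  manifest <- list(
    true_params = lapply(c(male = "male", female = "female"), function(s)
      list(beta1 = sc$true_inc[[s]]$beta1, beta2 = sc$true_inc[[s]]$beta2,
           beta3 = sc$true_inc[[s]]$beta3, gamma1 = sc$true_mrr[[s]]$gamma1,
           gamma2 = sc$true_mrr[[s]]$gamma2, g0 = sc$gompertz[[s]]$g0,
           g1 = sc$gompertz[[s]]$g1)),
    years = sc$years, noise = sc$noise, seed = sc$seed,
    top_age = sc$top_age,
    group_denoms = sc$group_denoms,
    groups = sc$groups)
  jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE, digits = NA)
  .log("simulated synthetic dataset: seed=%d noise=%s -> %s",
       sc$seed, sc$noise, config$out)
  invisible(paths)
}

#' Rebuild a synthetic configuration from a truth manifest
#'
#' @param path Path to a `truth.json` written by [cmd_simulate()].
#' @return A [synthetic_config()].
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(s) {
    tp <- m$true_params[[s]]
    list(inc = incidence_params(tp$beta1, tp$beta2, tp$beta3),
         mrr = mrr_params(tp$gamma1, tp$gamma2),
         gmp = gompertz_params(tp$g0, tp$g1))
  }
  male <- mk("male"); female <- mk("female")
  synthetic_config(
    true_inc = list(male = male$inc, female = female$inc),
    true_mrr = list(male = male$mrr, female = female$mrr),
    gompertz = list(male = male$gmp, female = female$gmp),
    years = m$years, groups = as.data.frame(m$groups),
    group_denoms = lapply(m$group_denoms, as.numeric),
    noise = m$noise, top_age = m$top_age, seed = m$seed)
}

.load_inputs <- function(config) {
  if (config$synthetic) {
    world <- simulate_prevalence(config$synthetic_config,
                                 aggregate = config$aggregate)
    list(observed = world$observed, mortality = world$mortality)
  } else {
    if (!file.exists(config$prevalence))
      stop("prevalence file not found: ", config$prevalence)
    if (!file.exists(config$mortality))
      stop("mortality file not found: ", config$mortality)
    list(observed = read_prevalence(config$prevalence),
         mortality = read_mortality(config$mortality))
  }
}

.config_sexes <- function(config)
  if (config$sex == "both") c("male", "female") else config$sex

#' Fit subcommand: least-squares fit per sex
#'
#' Loads (or simulates) the inputs, fits the four free parameters per sex
#' with `beta2` fixed, and writes `fit_<sex>.json` to the output directory.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list of `fit_result` objects.
#' @export
cmd_fit <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .load_inputs(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  for (s in .config_sexes(config)) {
    obs <- inputs$observed[inputs$observed$sex == s, ]
    if (nrow(obs) == 0L) stop("no prevalence rows for sex ", s)
    hz <- as_hazard(inputs$mortality, t = config$t_ref, sex = s)
    .log("fitting sex=%s: beta2=%.1f objective=%s aggregate=%s seed=%d",
         s, config$beta2, config$objective, config$aggregate, config$seed)
    fit <- fit_incidence(aggregated_prevalence(as.data.frame(obs)), hz,
                         fixed_beta2 = config$beta2, seed = config$seed,
                         mode = config$objective,
                         aggregate = config$aggregate,
                         top_age = config$top_age)
    write_fit_result(fit, file.path(config$out, paste0("fit_", s, ".json")))
    fits[[s]] <- fit
  }
  invisible(fits)
}

#' Bootstrap subcommand: perturbation bootstrap per sex
#'
#' Runs [run_bootstrap()] for each configured sex and writes
#' `bootstrap_<sex>.json` and `incidence_<sex>.csv`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list of `bootstrap_summary` objects.
#' @export
cmd_bootstrap <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .load_inputs(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (s in .config_sexes(config)) {
    obs <- aggregated_prevalence(
      as.data.frame(inputs$observed[inputs$observed$sex == s, ]))
    hz <- as_hazard(inputs$mortality, t = config$t_ref, sex = s)
    .log("bootstrap sex=%s: B=%d beta2=%.1f objective=%s seed=%d",
         s, config$replicates, config$beta2, config$objective, config$seed)
    bs <- run_bootstrap(obs, hz, B = config$replicates,
                        fixed_beta2 = config$beta2, seed = config$seed,
                        mode = config$objective, aggregate = config$aggregate,
                        top_age = config$top_age)
    .log("bootstrap sex=%s: %d replicates used, %d dropped",
         s, bs$n_used, bs$n_dropped)
    write_bootstrap_summary(bs,
      csv_path = file.path(config$out, paste0("incidence_", s, ".csv")),
      json_path = file.path(config$out, paste0("bootstrap_", s, ".json")),
      sex = s)
    out[[s]] <- bs
  }
  invisible(out)
}

#' Report subcommand: combined incidence table and optional figure
#'
#' Combines per-sex bootstrap summaries into one reporting table
#' (`incidence_table.csv`: sex, age label, median and 95% CI per 10,000
#' person-years) and optionally draws the two incidence curves to a PDF.
#'
#' @param summaries Named list of `bootstrap_summary` objects (as from
#'   [cmd_bootstrap()]).
#' @param out Output directory.
#' @param plot If `TRUE`, also write `incidence_curves.pdf`.
#' @return Invisibly, the combined data frame.
#' @export
cmd_report <- function(summaries, out = ".", plot = FALSE) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(names(summaries), function(s)
    cbind(sex = s, summaries[[s]]$incidence)))
  utils::write.csv(tab, file.path(out, "incidence_table.csv"),
                   row.names = FALSE, quote = FALSE)
  if (plot) {
    grDevices::pdf(file.path(out, "incidence_curves.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- c(male = "blue", female = "red")
    graphics::plot(NA, xlim = range(tab$age_eval), ylim = c(0, max(tab$hi)),
                   xlab = "Age (years)",
                   ylab = "Incidence per 10,000 person-years",
                   main = "Age-specific incidence (bootstrap median, 95% CI)")
    for (s in names(summaries)) {
      d <- summaries[[s]]$incidence
      graphics::lines(d$age_eval, d$median, col = cols[[s]], lwd = 2)
      graphics::lines(d$age_eval, d$lo, col = cols[[s]], lty = 2)
      graphics::lines(d$age_eval, d$hi, col = cols[[s]], lty = 2)
    }
    graphics::legend("topleft", legend = names(summaries),
                     col = cols[names(summaries)], lwd = 2, bty = "n")
  }
  invisible(tab)
}
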