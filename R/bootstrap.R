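#' Perturb aggregated prevalence proportions
#'
#' The perturbation bootstrap for aggregated data: since individual records
#' are unavailable, classical resampling of persons is impossible.  Instead
#' each cell's prevalence proportion receives an independent Gaussian
#' perturbation on the binomial sampling scale,
#' \eqn{\epsilon \sim N(0,\; p(1-p)/n)} with `n` the cell denominator,
#' truncated back to \[0, 1\].  Cells are treated as independent, justified
#' by the very large per-cell sample sizes of claims data.
#'
#' @param observed An `aggregated_prevalence` object.
#' @param noise_scale Multiplier on the binomial standard deviation
#'   (default 1; 0 returns the data unchanged, the infinite-denominator
#'   limit).
#' @return A perturbed `aggregated_prevalence` of identical shape.  Uses the
#'   current RNG state; seed outside for reproducibility.
#' @export
perturb_prevalence <- function(observed, noise_scale = 1) {
  stopifnot(inherits(observed, "aggregated_prevalence"), noise_scale >= 0)
  if (noise_scale == 0) return(observed)
  sd <- noise_scale * sqrt(observed$prev * (1 - observed$prev) / observed$denom)
  p <- observed$prev + stats::rnorm(nrow(observed), 0, sd)
  observed$prev <- pmin(pmax(p, 0), 1)
  observed
}

#' Incidence table at the reporting ages
#'
#' Evaluates a fitted Gaussian incidence curve at the reporting labels
#' 30, 35, ..., 95 and scales to cases per 10,000 person-years.  Under the
#' default `"midpoint"` convention the row labelled L is evaluated at age
#' L + 2.5, the midpoint of the 5-year interval \[L, L+5): with a peak age of
#' 87.5 this makes the label-85 row attain the curve maximum exactly and
#' renders the table symmetric about label 85, the convention of the
#' published hypertension tables.  `"label"` evaluates at the raw label age.
#'
#' @param params An [incidence_params()] object, or a `fit_result`.
#' @param eval_labels Integer age labels (subset of 30..95; default
#'   `seq(30, 95, by = 5)`).
#' @param convention `"midpoint"` (default) or `"label"`.
#' @return Data frame with columns `label`, `age_eval` and `rate_per_10k`.
#' @examples
#' evaluate_incidence_table(incidence_params(0.076334, 87.5, 25.33680))
#' @export
evaluate_incidence_table <- function(params,
                                     eval_labels = seq(30, 95, by = 5),
                                     convention = c("midpoint", "label")) {
  convention <- match.arg(convention)
  if (inherits(params, "fit_result")) params <- params$params$inc
  stopifnot(inherits(params, "incidence_params"))
  if (!all(eval_labels >= 30 & eval_labels <= 95))
    stop("evaluation labels must lie within 30..95")
  a <- if (convention == "midpoint") eval_labels + 2.5 else eval_labels
  data.frame(label = eval_labels, age_eval = a,
             rate_per_10k = incidence_rate(a, params) * 1e4)
}

# Summarise a replicates x ages incidence matrix and a replicates x 4
# parameter matrix into medians and 2.5%/97.5% quantiles.
summarize_bootstrap <- function(inc_mat, par_mat, eval_labels, age_eval,
                                B, seed, n_dropped) {
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  iq <- apply(inc_mat, 2, qs)
  pq <- apply(par_mat, 2, qs)
  structure(list(
    incidence = data.frame(label = eval_labels, age_eval = age_eval,
                           median = iq[2, ], lo = iq[1, ], hi = iq[3, ]),
    params = data.frame(param = colnames(par_mat),
                        median = pq[2, ], lo = pq[1, ], hi = pq[3, ],
                        row.names = NULL),
    B = B, n_used = nrow(inc_mat), n_dropped = n_dropped, seed = seed
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Perturbation bootstrap summary: B = %d (%d used, %d dropped), seed = %s\n",
              x$B, x$n_used, x$n_dropped, format(x$seed)))
  cat("Parameters (median [2.5%, 97.5%]):\n")
  for (k in seq_len(nrow(x$params)))
    cat(sprintf("  %-6s %.6g [%.6g, %.6g]\n", x$params$param[k],
                x$params$median[k], x$params$lo[k], x$params$hi[k]))
  cat("Incidence per 10,000 person-years:\n")
  print(format(x$incidence, digits = 6), row.names = FALSE)
  invisible(x)
}

#' Perturbation bootstrap of the illness-death prevalence fit
#'
#' For each of `B` replicates: perturb the observed cell prevalences on the
#' binomial scale ([perturb_prevalence()]), refit the four free parameters
#' with `beta2` fixed, and evaluate the fitted incidence curve at the
#' reporting ages.  Age-specific incidence is summarised by the replicate
#' median with 2.5% and 97.5% empirical quantiles as the 95% confidence
#' band; the four parameters are summarised the same way.
#'
#' Each replicate draws its RNG stream from a seed derived once from
#' `(seed, replicate index)`, so results are independent of execution order.
#' Replicate fits are warm-started at the full-data optimum (no random
#' restarts), which is where perturbed optima lie for small perturbations.
#' Non-converged replicates are dropped with a message; more than 20%
#' non-convergence aborts, signalling a data/model mismatch.
#'
#' @param observed Single-sex `aggregated_prevalence`.
#' @param hazard As accepted by [as_hazard()].
#' @param B Number of bootstrap replicates (>= 1; published analyses use
#'   1000).
#' @param fixed_beta2 Fixed peak age (default 87.5).
#' @param seed Integer root seed.
#' @param eval_labels Reporting age labels (default `seq(30, 95, 5)`).
#' @param convention Evaluation-age convention, see
#'   [evaluate_incidence_table()].
#' @param noise_scale Perturbation scale multiplier (see
#'   [perturb_prevalence()]).
#' @param point_fit Optional precomputed full-data `fit_result` to warm-start
#'   from (computed internally if `NULL`).
#' @param ... Passed to [fit_incidence()] / [prevalence_objective()].
#' @return A `bootstrap_summary` (see [summarize_bootstrap] fields).
#' @export
run_bootstrap <- function(observed, hazard, B = 1000L, fixed_beta2 = 87.5,
                          seed = 1L, eval_labels = seq(30, 95, by = 5),
                          convention = c("midpoint", "label"),
                          noise_scale = 1, point_fit = NULL, ...) {
  stopifnot(inherits(observed, "aggregated_prevalence"), B >= 1L)
  convention <- match.arg(convention)
  if (is.null(point_fit))
    point_fit <- fit_incidence(observed, hazard, fixed_beta2 = fixed_beta2,
                               seed = seed, ...)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)

  par_names <- c("beta1", "beta3", "gamma1", "gamma2")
  inc_list <- vector("list", B)
  par_list <- vector("list", B)
  keep <- logical(B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    pert <- perturb_prevalence(observed, noise_scale = noise_scale)
    fit <- fit_incidence(pert, hazard, fixed_beta2 = fixed_beta2,
                         start = point_fit$theta, seed = rep_seeds[b],
                         n_restarts = 0L, reltol = 1e-10, maxit = 500L, ...)
    ok <- is.finite(fit$objective) && fit$restarts$convergence[1] == 0
    keep[b] <- ok
    if (ok) {
      tab <- evaluate_incidence_table(fit, eval_labels, convention)
      inc_list[[b]] <- tab$rate_per_10k
      par_list[[b]] <- fit$theta
    }
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropped %d/%d non-converged bootstrap replicates",
                    n_dropped, B))
  if (n_dropped > 0.2 * B)
    stop("more than 20% of bootstrap replicates failed to converge; ",
         "the model does not match these data")
  inc_mat <- do.call(rbind, inc_list[keep])
  par_mat <- do.call(rbind, par_list[keep])
  colnames(par_mat) <- par_names
  age_eval <- if (convention == "midpoint") eval_labels + 2.5 else eval_labels
  summarize_bootstrap(inc_mat, par_mat, eval_labels, age_eval, B = B,
                      seed = seed, n_dropped = n_dropped)
}

#' Write a bootstrap summary to CSV and JSON
#'
#' @param summary A `bootstrap_summary`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param sex Optional sex label added as a CSV column.
#' @return Invisibly, a list of the written paths.
#' @export
write_bootstrap_summary <- function(summary, csv_path = NULL,
                                    json_path = NULL, sex = NA_character_) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  if (!is.null(csv_path)) {
    df <- cbind(sex = sex, summary$incidence)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(sex = sex, B = summary$B,
                              n_used = summary$n_used,
                              n_dropped = summary$n_dropped,
                              seed = summary$seed,
                              params = summary$params,
                              incidence = summary$incidence),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(csv = csv_path, json = json_path))
}
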