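#' Aggregated age-group prevalence data
#'
#' Container for claims-style aggregated prevalence: one row per (sex, year,
#' age group) with the observed prevalence proportion and the person
#' denominator.  The default schema mirrors the German claims-atlas grouping
#' 0-24, 25-34, 35-44, 45-54, 55-64, 65-74, 75-84 and the open 85-109 group.
#'
#' @param df Data frame with columns `sex` (`male`/`female`), `year`,
#'   `age_lo`, `age_hi` (integer years, inclusive), `prev` (proportion in
#'   \[0,1\]) and `denom` (person count > 0).
#' @return An `aggregated_prevalence` data frame (adds a `group` label
#'   column).
#' @export
aggregated_prevalence <- function(df) {
  need <- c("sex", "year", "age_lo", "age_hi", "prev", "denom")
  if (!all(need %in% names(df)))
    stop("aggregated prevalence needs columns: ", paste(need, collapse = ", "))
  if (!all(df$sex %in% c("male", "female")))
    stop("'sex' must be 'male' or 'female'")
  if (any(df$prev < 0 | df$prev > 1)) stop("'prev' must lie in [0, 1]")
  if (any(df$denom <= 0)) stop("'denom' must be positive")
  if (any(df$age_hi < df$age_lo)) stop("age_hi < age_lo")
  for (s in unique(df$sex)) for (y in unique(df$year[df$sex == s])) {
    g <- df[df$sex == s & df$year == y, ]
    g <- g[order(g$age_lo), ]
    if (any(g$age_lo[-1] <= g$age_hi[-nrow(g)]))
      stop(sprintf("overlapping age groups for sex=%s, year=%s", s, y))
  }
  df$group <- paste0(df$age_lo, "-", df$age_hi)
  df <- df[order(df$sex, df$year, df$age_lo), c(need[1:2], "group", need[3:6])]
  rownames(df) <- NULL
  structure(df, class = c("aggregated_prevalence", "data.frame"))
}

#' @export
print.aggregated_prevalence <- function(x, ...) {
  cat(sprintf("Aggregated prevalence: %d cells, sexes %s, years %s, %d age groups\n",
              nrow(x), paste(sort(unique(x$sex)), collapse = "/"),
              paste(range(x$year), collapse = "-"),
              length(unique(x$group))))
  NextMethod()
}

#' Claims-atlas age grouping
#'
#' @return Data frame of the eight age groups (`age_lo`, `age_hi`) used in
#'   the German hypertension claims atlas: 0-24, 25-34, ..., 75-84, 85-109.
#' @export
zi_age_groups <- function() {
  data.frame(age_lo = c(0L, 25L, 35L, 45L, 55L, 65L, 75L, 85L),
             age_hi = c(24L, 34L, 44L, 54L, 64L, 74L, 84L, 109L))
}

#' Read / write aggregated prevalence CSV
#'
#' Column layout `sex,year,age_lo,age_hi,prev,denom`.
#'
#' @param path File path.
#' @return An `aggregated_prevalence` object (reader); `path` invisibly
#'   (writer).
#' @export
read_prevalence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  aggregated_prevalence(df)
}

#' @rdname read_prevalence
#' @param observed An `aggregated_prevalence` object.
#' @export
write_prevalence <- function(observed, path) {
  stopifnot(inherits(observed, "aggregated_prevalence"))
  df <- as.data.frame(observed)[c("sex", "year", "age_lo", "age_hi", "prev", "denom")]
  df$prev <- vapply(df$prev, function(v) sprintf("%.17g", v), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Representative age of each age group
#'
#' Closed groups are represented by their interval midpoint on integer-year
#' bounds, `(age_lo + age_hi + 1) / 2` (so 25-34 maps to 30).  The open top
#' group is represented by `top_age`, by default 91 years: the lower bound 85
#' plus the rounded pooled remaining life expectancy of about 6 years at age
#' 85 in the German life tables.
#'
#' @param groups Data frame with `age_lo`, `age_hi` (one row per group), or
#'   an `aggregated_prevalence` object (unique groups are taken).
#' @param top_age Representative age of the open top group (default 91).
#' @return Numeric vector of representative ages, one per group, in
#'   increasing group order.
#' @export
representative_ages <- function(groups, top_age = 91) {
  g <- unique(as.data.frame(groups)[c("age_lo", "age_hi")])
  g <- g[order(g$age_lo), ]
  if (any(g$age_lo[-1] <= g$age_hi[-nrow(g)])) stop("overlapping age groups")
  a <- (g$age_lo + g$age_hi + 1) / 2
  a[length(a)] <- top_age   # last (open-ended) group
  a
}

# Aggregate a solved prevalence curve to age groups.
# midpoint: p at the representative age; weighted: stationary-population
# weighted mean of p over [lo, hi+1) with weights S(a) = exp(-int_0^a m).
aggregate_prevalence_curve <- function(curve, groups, hazard = NULL,
                                       aggregate = c("midpoint", "weighted"),
                                       top_age = 91) {
  aggregate <- match.arg(aggregate)
  g <- unique(as.data.frame(groups)[c("age_lo", "age_hi")])
  g <- g[order(g$age_lo), ]
  if (aggregate == "midpoint") {
    a_rep <- representative_ages(g, top_age)
    return(stats::approx(curve$age, curve$p, xout = a_rep)$y)
  }
  haz <- as_hazard(hazard)
  m <- haz(curve$age)
  H <- pracma::cumtrapz(curve$age, m)
  S <- exp(-H)
  vapply(seq_len(nrow(g)), function(j) {
    sel <- curve$age >= g$age_lo[j] & curve$age < g$age_hi[j] + 1
    sum(curve$p[sel] * S[sel]) / sum(S[sel])
  }, numeric(1))
}

#' Model-predicted prevalence per age group
#'
#' Solves the illness-death prevalence ODE at the given parameters and
#' aggregates the solution to the observation level of the age groups,
#' either by evaluating at each group's representative age (default) or by a
#' stationary-population weighted average over the group.
#'
#' @param inc An [incidence_params()] object.
#' @param mrrp An [mrr_params()] object.
#' @param hazard As accepted by [as_hazard()].
#' @param groups Data frame of `age_lo`/`age_hi` rows or an
#'   `aggregated_prevalence` object.
#' @param aggregate `"midpoint"` or `"weighted"`.
#' @param top_age Representative age of the open top group.
#' @param age_step Solver grid step in years (default 0.05).
#' @return Numeric vector of predicted prevalence proportions, one per group
#'   in increasing group order.
#' @export
model_group_prevalence <- function(inc, mrrp, hazard, groups,
                                   aggregate = c("midpoint", "weighted"),
                                   top_age = 91, age_step = 0.05) {
  aggregate <- match.arg(aggregate)
  curve <- solve_prevalence(inc, mrrp, hazard,
                            age_grid = seq(0, 110, by = age_step))
  aggregate_prevalence_curve(curve, groups, hazard = hazard,
                             aggregate = aggregate, top_age = top_age)
}

.theta_bounds <- list(beta1 = c(0, 1), beta3 = c(1, 80),
                      gamma1 = c(-3, 3), gamma2 = c(-3, 3))

.theta_in_bounds <- function(theta) {
  b <- .theta_bounds
  theta[1] > b$beta1[1] && theta[1] < b$beta1[2] &&
    theta[2] > b$beta3[1] && theta[2] < b$beta3[2] &&
    theta[3] > b$gamma1[1] && theta[3] < b$gamma1[2] &&
    theta[4] > b$gamma2[1] && theta[4] < b$gamma2[2]
}

# Pool annual cross-sections to one: mean prevalence per group, summed denom.
pool_years <- function(observed) {
  df <- as.data.frame(observed)
  key <- paste(df$sex, df$age_lo)
  if (!anyDuplicated(key)) {       # already one cross-section per group
    df <- df[order(df$sex, df$age_lo),
             c("sex", "year", "age_lo", "age_hi", "prev", "denom")]
    rownames(df) <- NULL
    return(df)
  }
  key <- interaction(df$sex, df$age_lo, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(sex = g$sex[1], year = mean(g$year), age_lo = g$age_lo[1],
               age_hi = g$age_hi[1], prev = mean(g$prev),
               denom = sum(g$denom), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sex, out$age_lo), ]
  rownames(out) <- NULL
  out
}

#' Least-squares objective for the illness-death prevalence fit
#'
#' Sum of squared differences between observed and model-predicted
#' age-group prevalences for a single sex, as a function of the free
#' parameter vector `theta = (beta1, beta3, gamma1, gamma2)` with the peak
#' age `beta2` held fixed.  Annual cross-sections are pooled by averaging
#' group prevalences across years before comparison.
#'
#' Two objective modes are provided.  `"trajectory"` (default) forward-solves
#' the prevalence ODE and compares predicted with observed group prevalences.
#' `"derivative"` instead differentiates the observed group prevalences
#' across representative ages by central finite differences, plugs them into
#' the incidence inversion of the transport equation, and compares the
#' resulting empirical incidence with the parametric Gaussian curve.  The
#' modes coincide as the number of groups grows and the noise vanishes;
#' with eight coarse groups the derivative mode carries a structural
#' finite-difference bias and is offered for methodological comparison.
#'
#' @param theta Numeric vector `(beta1, beta3, gamma1, gamma2)`.  Outside the
#'   box beta1 in (0,1), beta3 in (1,80), gammas in (-3,3) a large finite
#'   penalty is returned instead of an error, so derivative-free optimisers
#'   can roam safely.
#' @param fixed_beta2 Fixed age of the incidence maximum, years.
#' @param observed An `aggregated_prevalence` object restricted to one sex.
#' @param hazard As accepted by [as_hazard()].
#' @param aggregate Group aggregation mode, `"midpoint"` or `"weighted"`.
#' @param weight `"none"` (default) or `"denom"` for denominator weights.
#' @param mode `"trajectory"` or `"derivative"`.
#' @param top_age Representative age of the open top group.
#' @param age_step Solver grid step.
#' @return Scalar objective value >= 0 (or the penalty).
#' @export
prevalence_objective <- function(theta, fixed_beta2, observed, hazard,
                                 aggregate = c("midpoint", "weighted"),
                                 weight = c("none", "denom"),
                                 mode = c("trajectory", "derivative"),
                                 top_age = 91, age_step = 0.05) {
  aggregate <- match.arg(aggregate)
  weight <- match.arg(weight)
  mode <- match.arg(mode)
  if (!.theta_in_bounds(theta)) {
    viol <- sum(pmax(0, unlist(.theta_bounds)[c(1, 3, 5, 7)] - theta)^2) +
      sum(pmax(0, theta - unlist(.theta_bounds)[c(2, 4, 6, 8)])^2)
    return(1e6 * (1 + viol))
  }
  pooled <- pool_years(observed)
  if (length(unique(pooled$sex)) != 1L)
    stop("objective expects single-sex observations; filter by sex first")
  inc <- incidence_params(theta[1], fixed_beta2, theta[2])
  mrrp <- mrr_params(theta[3], theta[4])
  w <- if (weight == "denom") pooled$denom / sum(pooled$denom) else
    rep(1, nrow(pooled))
  if (mode == "trajectory") {
    pred <- model_group_prevalence(inc, mrrp, hazard, pooled,
                                   aggregate = aggregate, top_age = top_age,
                                   age_step = age_step)
    return(sum(w * (pooled$prev - pred)^2))
  }
  # derivative mode: empirical incidence via the inverted transport equation
  a_rep <- representative_ages(pooled, top_age)
  p_obs <- pooled$prev
  haz <- as_hazard(hazard)
  nG <- length(a_rep)
  idx <- 2:(nG - 1L)
  dp <- (p_obs[idx + 1L] - p_obs[idx - 1L]) / (a_rep[idx + 1L] - a_rep[idx - 1L])
  pj <- pmin(p_obs[idx], 1 - 1e-12)
  i_emp <- invert_incidence(pj, dp, haz(a_rep[idx]), mrr(a_rep[idx], mrrp))
  i_par <- incidence_rate(a_rep[idx], inc)
  sum(w[idx] * (i_emp - i_par)^2)
}

#' Fit the incidence and MRR parameters to aggregated prevalence
#'
#' Estimates `(beta1, beta3, gamma1, gamma2)` for one sex by minimising
#' [prevalence_objective()] with the Nelder-Mead simplex, with the peak age
#' `beta2` held fixed (default 87.5 years).  `beta1` and `beta3` are
#' log-transformed internally to enforce positivity; results are returned on
#' the natural scale.  The optimiser is restarted from `n_restarts` jittered
#' starting points (seeded, so the whole fit is reproducible) and the best
#' local minimum is polished with a final simplex run; ties between restarts
#' are broken by restart order.
#'
#' @param observed An `aggregated_prevalence` object for a single sex (at
#'   least 4 distinct age groups, else the four parameters are
#'   unidentifiable and an error is thrown).
#' @param hazard As accepted by [as_hazard()].
#' @param fixed_beta2 Fixed age of the incidence maximum (default 87.5).
#' @param start Named or positional starting values
#'   `(beta1, beta3, gamma1, gamma2)`; default `c(0.05, 25, 0.4, 0)`,
#'   plausible magnitudes for a late-life chronic disease.
#' @param seed Integer seed driving the restart jitter.
#' @param n_restarts Number of jittered restarts in addition to `start`
#'   itself (default 3).
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @param maxit Iteration cap per simplex run.
#' @param ... Passed to [prevalence_objective()] (`aggregate`, `weight`,
#'   `mode`, `top_age`, `age_step`).
#' @return A `fit_result` list: `params` (list with `inc` and `mrr` model
#'   objects), `theta`, `objective`, `converged`, `boundary`, `n_evals`,
#'   `start`, `fixed_beta2`, `restarts` (per-start diagnostics).
#' @export
fit_incidence <- function(observed, hazard, fixed_beta2 = 87.5,
                          start = c(beta1 = 0.05, beta3 = 25,
                                    gamma1 = 0.4, gamma2 = 0),
                          seed = 1L, n_restarts = 3L,
                          reltol = 1e-12, maxit = 2000L, ...) {
  stopifnot(inherits(observed, "aggregated_prevalence"))
  if (length(unique(observed$sex)) != 1L)
    stop("fit_incidence expects single-sex observations; filter by sex first")
  if (length(unique(observed$group)) < 4L)
    stop("need at least 4 age groups to identify 4 parameters")
  start <- unname(start)
  # pool annual cross-sections once; the objective's internal pooling is then
  # a no-op, keeping per-evaluation cost down
  pooled <- aggregated_prevalence(pool_years(observed))
  obj_nat <- function(theta) prevalence_objective(theta, fixed_beta2,
                                                  pooled, hazard, ...)
  # internal scale: (log beta1, log beta3, gamma1, gamma2)
  to_nat <- function(x) c(exp(x[1]), exp(x[2]), x[3], x[4])
  obj_int <- function(x) obj_nat(to_nat(x))
  x0 <- c(log(start[1]), log(start[2]), start[3], start[4])

  starts <- list(x0)
  if (n_restarts > 0L) {
    set.seed(as.integer(seed))
    for (r in seq_len(n_restarts)) {
      starts[[r + 1L]] <- x0 + c(stats::rnorm(2, 0, 0.2), stats::rnorm(2, 0, 0.1))
    }
  }
  runs <- lapply(starts, function(s)
    stats::optim(s, obj_int, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit)))
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]   # which.min takes the first on ties
  best_code <- best$convergence
  # refinement pass from the best minimum; convergence is judged on the
  # restart that found it, the polish only tightens the solution
  polish <- stats::optim(best$par, obj_int, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = maxit))
  if (polish$value <= best$value) best <- polish

  theta <- to_nat(best$par)
  names(theta) <- c("beta1", "beta3", "gamma1", "gamma2")
  b <- .theta_bounds
  edge <- function(v, lim, frac = 0.01)
    (v - lim[1]) < frac * diff(lim) || (lim[2] - v) < frac * diff(lim)
  boundary <- theta[1] < 1e-6 || edge(theta[2], b$beta3) ||
    edge(theta[3], b$gamma1) || edge(theta[4], b$gamma2)
  converged <- best_code == 0 && is.finite(best$value) && !boundary
  structure(list(
    params = list(inc = incidence_params(theta[1], fixed_beta2, theta[2]),
                  mrr = mrr_params(theta[3], theta[4])),
    theta = theta,
    objective = best$value,
    converged = converged,
    boundary = boundary,
    n_evals = sum(vapply(runs, function(r) r$counts[1], numeric(1))) +
      polish$counts[1],
    start = start,
    fixed_beta2 = fixed_beta2,
    sex = unique(observed$sex),
    restarts = data.frame(value = vals,
                          convergence = vapply(runs, `[[`, numeric(1),
                                               "convergence"))
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Illness-death model fit (%s), beta2 fixed at %.1f\n",
              x$sex, x$fixed_beta2))
  cat(sprintf("  beta1 = %.6f  beta3 = %.5f  gamma1 = %.4f  gamma2 = %.5f\n",
              x$theta[1], x$theta[2], x$theta[3], x$theta[4]))
  cat(sprintf("  objective = %.3e, converged: %s%s, %d evaluations\n",
              x$objective, x$converged,
              if (x$boundary) " (boundary solution)" else "", x$n_evals))
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path (`NULL` returns the JSON string).
#' @return The path (invisibly) or a JSON string.
#' @export
write_fit_result <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(sex = fit$sex, fixed_beta2 = fit$fixed_beta2,
              beta1 = unname(fit$theta[1]), beta3 = unname(fit$theta[2]),
              gamma1 = unname(fit$theta[3]), gamma2 = unname(fit$theta[4]),
              objective = fit$objective, converged = fit$converged,
              boundary = fit$boundary, n_evals = unname(fit$n_evals),
              start = fit$start)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
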