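#' Gompertz hazard parameters
#'
#' The Gompertz law of mortality: the hazard increases exponentially with
#' age, \eqn{m(a) = e^{g_0 + g_1 a}}.  `g0` is the log baseline hazard at age
#' 0 and `g1` the log-linear slope per year of age.
#'
#' @param g0 Log baseline hazard (dimensionless).
#' @param g1 Slope per year of age.
#' @return An object of class `gompertz_params`.
#' @examples
#' gompertz_params(g0 = -11.117, g1 = 0.1034)
#' @export
gompertz_params <- function(g0, g1) {
  stopifnot(is.numeric(g0), length(g0) == 1L, is.finite(g0),
            is.numeric(g1), length(g1) == 1L, is.finite(g1))
  structure(list(g0 = g0, g1 = g1), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz hazard: m(a) = exp(%g + %g * a)\n", x$g0, x$g1))
  invisible(x)
}

#' Gompertz mortality rate
#'
#' @param a Age(s) in years.
#' @param params A [gompertz_params()] object.
#' @return Hazard rate(s) per person-year, `exp(g0 + g1 * a)`.
#' @examples
#' gompertz_mortality(70, gompertz_params(-10, 0.1))   # exp(-3)
#' @export
gompertz_mortality <- function(a, params) {
  stopifnot(inherits(params, "gompertz_params"), is.numeric(a), all(is.finite(a)))
  exp(params$g0 + params$g1 * a)
}

.mt_sexes <- c("female", "male", "total")

new_mortality_table <- function(df, source = "unknown") {
  df <- df[order(df$sex, df$year, df$age), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("mortality_table", "data.frame"), source = source)
}

validate_mortality_table <- function(df) {
  need <- c("year", "age", "sex", "mx")
  if (!all(need %in% names(df)))
    stop("mortality table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$sex %in% .mt_sexes))
    stop("'sex' must be one of: ", paste(.mt_sexes, collapse = ", "))
  if (anyNA(df$mx)) stop("mortality table contains missing rates")
  if (any(df$mx < 0)) stop("negative mortality rate in table")
  if (nrow(df) == 0L) stop("mortality table is empty")
  for (s in unique(df$sex)) for (y in unique(df$year[df$sex == s])) {
    ages <- sort(df$age[df$sex == s & df$year == y])
    if (length(ages) > 1L && any(diff(ages) != 1L))
      stop(sprintf("ages not contiguous for sex=%s, year=%d", s, y))
  }
  invisible(df)
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("All-cause mortality table (source: %s)\n", attr(x, "source")))
  cat(sprintf("  years %d-%d, ages %d-%d, sexes: %s, %d rows\n",
              min(x$year), max(x$year), min(x$age), max(x$age),
              paste(sort(unique(x$sex)), collapse = "/"), nrow(x)))
  NextMethod()
}

# Parse an HMD-style age token: integer years, with "110+" as terminal group.
.parse_age <- function(tok) {
  tok <- sub("\\+$", "", trimws(tok))
  suppressWarnings(as.integer(tok))
}

#' Read an all-cause mortality table
#'
#' Reads central death rates m(a) by single year of age from either the
#' Human Mortality Database Mx 1x1 layout (whitespace- or comma-delimited
#' columns `Year Age Female Male Total`, with possible preamble lines before
#' the header, age `110+` as the terminal group and `.` marking missing
#' cells) or a plain long CSV with columns `year,age,sex,mx`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default; sniffed from the header), `"hmd"` or
#'   `"csv"`.
#' @param strict If `TRUE` (default) a missing (`.` or empty) rate cell is an
#'   error naming the cell; if `FALSE` missing rates are imputed by linear
#'   interpolation of log(mx) across adjacent ages within the same year and
#'   sex (nearest value at the edges).
#' @param source Label stored with the table; defaults to the file name.
#' @return A `mortality_table`: a data frame with columns `year`, `age`
#'   (integer, 110 for the terminal `110+` group), `sex`
#'   (`female`/`male`/`total`) and `mx` (per person-year).
#' @seealso [mortality_at()], [write_mortality()]
#' @export
read_mortality <- function(path, format = c("auto", "hmd", "csv"),
                           strict = TRUE, source = basename(path)) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("mortality file has no data rows: ", path)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*year\\s*,\\s*age\\s*,\\s*sex", lines,
                            ignore.case = TRUE))) "csv" else "hmd"
  }
  if (format == "csv") {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    df$age <- .parse_age(as.character(df$age))
    df$sex <- tolower(df$sex)
    df$mx <- .impute_or_fail(df$mx, df$year, df$age, df$sex, strict, path)
    validate_mortality_table(df)
    return(new_mortality_table(df[c("year", "age", "sex", "mx")], source))
  }
  # HMD dialect: locate the header row, then read Year Age Female Male Total
  hdr <- grep("Year[ ,\t]+Age.*Female", lines)[1]
  if (is.na(hdr)) stop("no 'Year Age Female Male Total' header found in ", path)
  body <- lines[(hdr + 1L):length(lines)]
  toks <- strsplit(trimws(body), "[,[:space:]]+")
  wide <- vector("list", length(toks))
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    if (length(tk) != 5L)
      stop(sprintf("malformed row at line %d of %s: expected 5 fields, got %d",
                   hdr + k, path, length(tk)))
    age <- .parse_age(tk[2])
    if (is.na(age))
      stop(sprintf("malformed age '%s' at line %d of %s", tk[2], hdr + k, path))
    wide[[k]] <- data.frame(year = as.integer(tk[1]), age = age,
                            female = tk[3], male = tk[4], total = tk[5],
                            stringsAsFactors = FALSE)
  }
  wide <- do.call(rbind, wide)
  long <- do.call(rbind, lapply(.mt_sexes, function(s) {
    mx <- suppressWarnings(as.numeric(ifelse(wide[[s]] == ".", NA, wide[[s]])))
    data.frame(year = wide$year, age = wide$age, sex = s, mx = mx,
               stringsAsFactors = FALSE)
  }))
  long$mx <- .impute_or_fail(long$mx, long$year, long$age, long$sex, strict, path)
  validate_mortality_table(long)
  new_mortality_table(long, source)
}

.impute_or_fail <- function(mx, year, age, sex, strict, path) {
  bad <- which(is.na(mx))
  if (!length(bad)) return(mx)
  if (strict)
    stop(sprintf("missing mortality rate for year=%d age=%d sex=%s in %s",
                 year[bad[1]], age[bad[1]], sex[bad[1]], path))
  for (s in unique(sex)) for (y in unique(year[sex == s])) {
    idx <- which(sex == s & year == y)
    idx <- idx[order(age[idx])]
    v <- mx[idx]
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      if (!length(ok)) stop("no observed rates to impute from in ", path)
      if (length(ok) == 1L) {
        v[is.na(v)] <- v[ok]
      } else {
        lv <- stats::approx(age[idx][ok], log(pmax(v[ok], 1e-300)),
                            xout = age[idx], rule = 2)$y
        v[is.na(v)] <- exp(lv[is.na(v)])
      }
      mx[idx] <- v
    }
  }
  mx
}

#' Write a mortality table as long CSV
#'
#' Emits the plain CSV dialect (`year,age,sex,mx`) that [read_mortality()]
#' reads back bit-identically.
#'
#' @param table A `mortality_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality <- function(table, path) {
  stopifnot(inherits(table, "mortality_table"))
  df <- as.data.frame(table)[c("year", "age", "sex", "mx")]
  # format() would round; write full precision so round-trips are exact
  df$mx <- vapply(df$mx, function(v) sprintf("%.17g", v), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' All-cause mortality at a continuous age
#'
#' Continuous-age accessor over the single-year grid of a mortality table.
#' Rates are interpolated piecewise linearly in log(mx) between integer-age
#' nodes (exactly consistent with Gompertz behaviour, where log-hazard is
#' linear in age) and reproduce the node values exactly.  If the requested
#' calendar time is not a tabulated year the nearest available year is used
#' (ties resolved to the earlier year) and a message is emitted.
#'
#' @param a Continuous age(s) in years, within \[0, 110\].
#' @param t Calendar time (e.g. 2013.5).
#' @param sex One of `"female"`, `"male"`, `"total"`.
#' @param table A `mortality_table`.
#' @return Mortality rate(s) per person-year.
#' @export
mortality_at <- function(a, t, sex, table) {
  f <- mortality_interpolator(table, t = t, sex = sex)
  f(a)
}

# Build a fast vectorised hazard function a -> m(a) for one (year, sex) slice.
mortality_interpolator <- function(table, t, sex) {
  stopifnot(inherits(table, "mortality_table"))
  sex <- match.arg(sex, .mt_sexes)
  yrs <- sort(unique(table$year))
  yr <- yrs[which.min(abs(yrs - t))]
  if (abs(yr - t) > 0.5 + 1e-9)
    message(sprintf("calendar time %.1f not tabulated; using nearest year %d", t, yr))
  sl <- table[table$year == yr & table$sex == sex, ]
  if (nrow(sl) == 0L) stop("no mortality rows for sex=", sex, ", year=", yr)
  sl <- sl[order(sl$age), ]
  ages <- sl$age
  logm <- log(pmax(sl$mx, 1e-300))
  function(a) {
    if (any(a < 0 | a > 110)) stop("age outside [0, 110]")
    au <- pmin(pmax(a, min(ages)), max(ages))
    exp(stats::approx(ages, logm, xout = au, rule = 2)$y)
  }
}

#' Coerce to a hazard function of age
#'
#' Returns a vectorised function `a -> m(a)` (per person-year), the common
#' currency of the solver, fitting and bootstrap layers.
#'
#' @param x A `gompertz_params` object, a `mortality_table`, or already a
#'   function of age.
#' @param t Calendar time at which a `mortality_table` is sliced (nearest
#'   tabulated year; default 2013.5, the study-period midpoint convention).
#' @param sex Sex for a `mortality_table` slice.
#' @param ... Unused.
#' @return A function of age.
#' @export
as_hazard <- function(x, ...) UseMethod("as_hazard")

#' @rdname as_hazard
#' @export
as_hazard.function <- function(x, ...) x

#' @rdname as_hazard
#' @export
as_hazard.gompertz_params <- function(x, ...) {
  force(x)
  function(a) gompertz_mortality(a, x)
}

#' @rdname as_hazard
#' @export
as_hazard.mortality_table <- function(x, t = 2013.5, sex = "total", ...) {
  mortality_interpolator(x, t = t, sex = sex)
}

#' Remaining life expectancy under a hazard
#'
#' Computes \eqn{e(a) = \int_0^{110-a} \exp(-\int_0^u m(a+s)\,ds)\,du} by
#' composite trapezoidal quadrature on a fine uniform grid.  Integration is
#' truncated at age 110; survival beyond 110 is ignored (the terminal HMD
#' group closes the table), which understates e(a) by a negligible amount for
#' human-scale hazards.
#'
#' @param a Age in years (scalar, in \[0, 110\)).
#' @param hazard A hazard as accepted by [as_hazard()].
#' @param step Quadrature step in years (default 0.0025; must be <= 0.01).
#' @return Remaining life expectancy in years.
#' @examples
#' remaining_life_expectancy(0, function(a) rep(0.2, length(a)))  # ~ 1/0.2
#' @export
remaining_life_expectancy <- function(a, hazard, step = 0.0025) {
  stopifnot(length(a) == 1L, a >= 0, a < 110, step > 0, step <= 0.01)
  h <- as_hazard(hazard)
  u <- seq(0, 110 - a, by = step)
  if (u[length(u)] < 110 - a) u <- c(u, 110 - a)
  m <- h(a + u)
  if (any(!is.finite(m)) || any(m < 0)) stop("hazard must be finite and non-negative")
  H <- pracma::cumtrapz(u, m)
  pracma::trapz(u, exp(-H))
}
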