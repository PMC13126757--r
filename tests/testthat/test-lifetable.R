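hmd_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("HMD-style Mx files parse, including the 110+ sentinel", {
  path <- hmd_fixture(c(
    "Germany, Death rates (period 1x1)", "",
    "  Year          Age             Female            Male           Total",
    "  2013           0             0.003             0.004          0.0035",
    "  2013           1             0.0002            0.0003         0.00025",
    "  2013           2             0.0001            0.0002         0.00015"))
  tab <- read_mortality(path)
  expect_s3_class(tab, "mortality_table")
  expect_equal(nrow(tab), 9L)                    # 3 ages x 3 sexes
  expect_equal(sort(unique(tab$sex)), c("female", "male", "total"))
  expect_equal(tab$mx[tab$sex == "male" & tab$age == 1], 0.0003)

  path2 <- hmd_fixture(c(
    "Year Age Female Male Total",
    "2013 109 0.6 0.65 0.62",
    "2013 110+ 0.7 0.8 0.75"))
  tab2 <- read_mortality(path2)
  expect_equal(max(tab2$age), 110L)
  expect_equal(tab2$mx[tab2$age == 110 & tab2$sex == "male"], 0.8)
})

test_that("missing and malformed cells are reported with their location", {
  path <- hmd_fixture(c(
    "Year Age Female Male Total",
    "2013 0 0.003 0.004 0.0035",
    "2013 1 . 0.0003 0.00025"))
  expect_error(read_mortality(path), "year=2013 age=1 sex=female")
  # non-strict mode imputes the missing female rate from the neighbours
  tab <- read_mortality(path, strict = FALSE)
  expect_true(all(is.finite(tab$mx)))
  expect_equal(tab$mx[tab$sex == "female" & tab$age == 0], 0.003)

  bad <- hmd_fixture(c("Year Age Female Male Total",
                       "2013 0 0.003 0.004"))
  expect_error(read_mortality(bad), "line 2")
  neg <- hmd_fixture(c("Year Age Female Male Total",
                       "2013 0 0.003 -0.004 0.0035"))
  expect_error(read_mortality(neg), "negative")
})

test_that("CSV dialect round-trips rates bit-identically", {
  ages <- 0:110
  tab <- generate_truth(synthetic_config(years = 2013))$mortality
  path <- withr::local_tempfile(fileext = ".csv")
  write_mortality(tab, path)
  back <- read_mortality(path)
  expect_identical(back$mx, tab$mx)
  expect_identical(back$age, tab$age)
  expect_identical(back$sex, tab$sex)
})

test_that("continuous-age accessor interpolates log-linearly and exactly at nodes", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(year = 2013L, age = rep(60:62, 2),
                   sex = rep(c("male", "female"), each = 3),
                   mx = c(0.01, 0.02, 0.03, 0.008, 0.016, 0.024))
  writeLines(c("year,age,sex,mx",
               apply(df, 1, paste, collapse = ",")), path)
  tab <- read_mortality(path)
  expect_equal(mortality_at(61, 2013, "male", tab), 0.02)
  # midway: geometric mean of the neighbouring rates
  expect_equal(mortality_at(60.5, 2013, "male", tab),
               exp((log(0.01) + log(0.02)) / 2))
  expect_error(mortality_at(111, 2013, "male", tab), "\\[0, 110\\]")
})

test_that("interpolating a Gompertz-tabulated table reproduces the hazard", {
  gz <- german_gompertz()
  tab <- generate_truth(synthetic_config(years = 2013))$mortality
  h <- as_hazard(tab, t = 2013.5, sex = "male")
  a <- seq(30.25, 99.75, by = 0.5)   # strictly off-node ages
  expect_lt(max(abs(h(a) / gompertz_mortality(a, gz) - 1)), 1e-6)
})

test_that("nearest tabulated year is used, ties resolved downwards", {
  df <- rbind(data.frame(year = 2013L, age = 0:2, sex = "total", mx = 0.01),
              data.frame(year = 2014L, age = 0:2, sex = "total", mx = 0.02))
  tab <- previnc:::new_mortality_table(df)
  expect_equal(mortality_at(1, 2013.5, "total", tab), 0.01)
  expect_equal(mortality_at(1, 2013.9, "total", tab), 0.02)
})

test_that("Gompertz hazard has the exponential-growth property", {
  g <- gompertz_params(-10, 0.1)
  expect_equal(gompertz_mortality(70, g), exp(-3))
  expect_equal(gompertz_mortality(0:5, gompertz_params(log(0.01), 0)),
               rep(0.01, 6))
  a <- c(10, 43.7, 80)
  expect_equal(gompertz_mortality(a + 10, g) / gompertz_mortality(a, g),
               rep(exp(10 * 0.1), 3))
})

test_that("remaining life expectancy matches closed forms and an independent oracle", {
  const <- function(m) function(a) rep(m, length(a))
  expect_equal(remaining_life_expectancy(0, const(0.2)), 5, tolerance = 1e-6)
  # halving the hazard doubles e, up to the (known) truncation at age 110
  expect_equal(remaining_life_expectancy(0, const(0.1)),
               (1 - exp(-0.1 * 110)) / 0.1, tolerance = 1e-6)
  # Gompertz case against a brute-force fine-grid quadrature oracle
  gz <- gompertz_params(-9, 0.085)
  oracle <- local({
    u <- seq(0, 25, by = 1e-4)
    m <- exp(-9 + 0.085 * (85 + u))
    H <- c(0, cumsum((m[-1] + m[-length(m)]) / 2 * 1e-4))
    S <- exp(-H)
    sum((S[-1] + S[-length(S)]) / 2 * 1e-4)
  })
  expect_equal(remaining_life_expectancy(85, gz), oracle, tolerance = 1e-4)
})

test_that("life expectancy is positive, bounded, and decreases under hazard inflation", {
  gz <- german_gompertz()
  for (a in c(0, 40, 85, 105)) {
    e <- remaining_life_expectancy(a, gz)
    expect_gt(e, 0)
    expect_lte(e, 110 - a)
  }
  infl <- function(f, k) function(a) k * f(a)
  h <- as_hazard(gz)
  e1 <- remaining_life_expectancy(65, h)
  e2 <- remaining_life_expectancy(65, infl(h, 1.3))
  e3 <- remaining_life_expectancy(65, infl(h, 2))
  expect_true(e1 > e2 && e2 > e3)
  expect_error(remaining_life_expectancy(65, function(a) rep(-0.1, length(a))),
               "non-negative")
})

test_that("the calibrated default hazard reproduces the German-like life table", {
  gz <- german_gompertz()
  expect_equal(remaining_life_expectancy(0, gz), 80, tolerance = 1e-3)
  expect_equal(remaining_life_expectancy(85, gz), 6, tolerance = 1e-3)
})
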