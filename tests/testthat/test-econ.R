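test_that("database-growth regression reproduces the published fits", {
  early <- fit_hits_regression(louisiana_hits_table("early"))
  expect_equal(round_half_up(early$slope, 4), 0.0013)
  expect_equal(round_half_up(early$r2, 2), 0.91)
  full <- fit_hits_regression(louisiana_hits_table("all"))
  expect_equal(round_half_up(full$slope, 4), 0.0002)
  expect_equal(round_half_up(full$r2, 4), 0.9655)
  # two-point sanity fit and degenerate input
  two <- fit_hits_regression(data.frame(db_size = c(0, 1000),
                                        hits = c(0, 1)))
  expect_equal(two$slope, 0.001)
  expect_equal(two$r2, 1)
  expect_error(fit_hits_regression(data.frame(db_size = c(5, 5),
                                              hits = c(1, 2))),
               "degenerate")
})

test_that("regression equals independent oracles", {
  set.seed(12)
  for (i in 1:500) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 1e6)
    y <- runif(n, 0, 500)
    fit <- fit_hits_regression(data.frame(db_size = x, hits = y))
    # independent closed form through cov/var/cor
    expect_equal(fit$slope, stats::cov(x, y) / stats::var(x),
                 tolerance = 1e-12)
    expect_equal(fit$r2, stats::cor(x, y)^2, tolerance = 1e-12)
    # cross-check against the QR-based fitter
    lmfit <- stats::lm(y ~ x)
    expect_equal(fit$slope, unname(stats::coef(lmfit)[2]),
                 tolerance = 1e-9)
    expect_equal(fit$intercept, unname(stats::coef(lmfit)[1]),
                 tolerance = 1e-9)
    expect_equal(fit$r2, summary(lmfit)$r.squared, tolerance = 1e-9)
  }
})

test_that("profiles-per-hit inverts the display-rounded slope", {
  early <- fit_hits_regression(louisiana_hits_table("early"))
  expect_equal(profiles_per_hit(early$slope), 769L)
  expect_equal(profiles_per_hit(0.5), 2L)
  expect_equal(profiles_per_hit(1.0), 1L)
  expect_error(profiles_per_hit(1e-9), "rounds to 0")
  expect_error(profiles_per_hit(0), "slope")
})

test_that("per-hit ratios and hit rates match the published arithmetic", {
  expect_equal(ratio_per_hit(699618, 164), 4266)
  expect_equal(ratio_per_hit(19350445, 587773, decimals = 2), 32.92)
  expect_equal(ratio_per_hit(19350445, 587773), 33)
  expect_equal(ratio_per_hit(100, 100), 1)
  expect_error(ratio_per_hit(10, 0), "hits")
  expect_equal(hit_rate_pct(587773, 1144255), 51.37)
  expect_equal(hit_rate_pct(164, 285), 57.54)
  expect_equal(hit_rate_pct(164, 285, decimals = 0), 58)
  expect_equal(hit_rate_pct(0, 10), 0)
  expect_error(hit_rate_pct(1, 0), "profiles")
})

test_that("expansion cost-benefit reproduces the published table", {
  cb <- expansion_cost_benefit(expansion_inputs())
  expect_equal(cb$display$total_benefit, 1872336534)
  expect_equal(cb$total_cost, 34980900)
  expect_equal(cb$display$benefit_per_dollar, 53.52)
  expect_equal(cb$display$roi_pct, 5352)
  expect_equal(cb$roi_pct, 100 * cb$benefit_per_dollar)
  # trivial arithmetic cases
  zero <- expansion_cost_benefit(list(hits = 0, preventable_per_hit = 1,
                                      cost_per_crime = 1, db_size = 1,
                                      cost_per_sample = 1))
  expect_equal(zero$total_benefit, 0)
  expect_equal(zero$benefit_per_dollar, 0)
  unit <- expansion_cost_benefit(list(hits = 1, preventable_per_hit = 1,
                                      cost_per_crime = 100, db_size = 1,
                                      cost_per_sample = 100))
  expect_equal(unit$benefit_per_dollar, 1)
  expect_equal(unit$roi_pct, 100)
})

test_that("twin extrapolation reproduces the sibship estimate", {
  sib <- twin_extrapolation(twin_inputs())
  expect_equal(sib$sibling_pairs, 134000)
  expect_equal(sib$match_pct, 19.14)
  zero <- twin_extrapolation(list(twin_pairs = 0, db_size = 1000,
                                  births_per_twin_pair = 250,
                                  annual_hits = 0))
  expect_equal(zero$sibling_pairs, 0)
  expect_equal(zero$match_pct, 0)
  half <- twin_extrapolation(list(twin_pairs = 2, db_size = 1000,
                                  births_per_twin_pair = 250,
                                  annual_hits = 0))
  expect_equal(half$sibling_pairs, 500)
  expect_equal(half$match_pct, 50)
  expect_error(twin_extrapolation(list(twin_pairs = 1, db_size = 0,
                                       births_per_twin_pair = 250)),
               "db_size")
})

test_that("the national projection composes on the published inputs", {
  np <- edim_national_projection(twin_inputs())
  expect_equal(np$match_pct, 19.14)
  expect_equal(np$additional_solved, 9563)
  expect_equal(np$prevented, 250741)
  expect_equal(np$savings_billion, 109.18)
  zero <- edim_national_projection(list(twin_pairs = 536, db_size = 700000,
                                        births_per_twin_pair = 250,
                                        annual_hits = 0))
  expect_equal(zero$additional_solved, 0)
  expect_equal(zero$prevented, 0)
  expect_equal(zero$savings_usd, 0)
  simple <- edim_national_projection(
    list(twin_pairs = 40, db_size = 100000, births_per_twin_pair = 250,
         annual_hits = 1000), cost_per_crime = 100,
    preventable_per_hit = 1)
  expect_equal(simple$match_pct, 10)
  expect_equal(simple$additional_solved, 100)
  expect_equal(simple$prevented, 100)
  expect_equal(simple$savings_usd, 10000)
})

test_that("the universal-database case computes from its inputs", {
  uc <- universal_db_case(universal_inputs())
  expect_equal(uc$additional_solved, 58539)
  expect_equal(uc$total_cost, 331.4e6 * 50)
  # independent arithmetic oracle for the benefit chain; the published
  # narrative totals are inconsistent with these inputs and are not
  # reproduced
  expect_equal(uc$total_benefit, 58539 * 26.22 * 435419, tolerance = 1e-12)
  expect_equal(uc$benefit_per_dollar, uc$total_benefit / uc$total_cost)
  zero <- universal_db_case(list(population = 1, cost_per_sample = 50,
                                 annual_crimes = 1000,
                                 unrealized_hit_rate = 0,
                                 cost_per_crime = 1,
                                 preventable_per_hit = 1))
  expect_equal(zero$additional_solved, 0)
})

test_that("monetary pipelines are bit-stable across recomputation", {
  a <- expansion_cost_benefit(expansion_inputs())
  b <- expansion_cost_benefit(expansion_inputs())
  expect_identical(a, b)
  expect_identical(edim_national_projection(twin_inputs()),
                   edim_national_projection(twin_inputs()))
})

test_that("half-up display rounding behaves at ties", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(0.00125, 4), 0.0013)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(53.525, 2), 53.53)
})
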