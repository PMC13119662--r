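# The triangular distribution has closed-form quantile/survival functions,
# so the Monte Carlo engine can be validated against exact oracles: collapsed
# inputs must reproduce the deterministic engine, and exceedance
# probabilities must match the analytic survival function within binomial
# Monte Carlo error.

test_that("the triangular inverse CDF matches its closed form", {
  tri <- triangular_intake()  # Tri(50, 140, 350)
  expect_equal(triangular_inverse_cdf(0, tri), 50)
  expect_equal(triangular_inverse_cdf(1, tri), 350)
  expect_equal(triangular_inverse_cdf(0.3, tri), 140)  # breakpoint = mode
  expect_equal(triangular_inverse_cdf(0.5, tri),
               350 - sqrt(0.5 * 300 * 210))  # ~172.52
  expect_error(triangular_inverse_cdf(1.1, tri), "\\[0, 1\\]")
  expect_error(triangular_inverse_cdf(-0.1, tri), "\\[0, 1\\]")
  # quantile and CDF are mutual inverses across the support
  u <- seq(0.01, 0.99, by = 0.01)
  expect_equal(triangular_cdf(triangular_inverse_cdf(u, tri), tri), u,
               tolerance = 1e-12)
})

test_that("the triangular survival function matches closed-form arithmetic", {
  tri <- triangular_intake()
  expect_equal(triangular_sf(50, tri), 1)
  expect_equal(triangular_sf(350, tri), 0)
  expect_equal(triangular_sf(140, tri), 0.7)
  expect_equal(triangular_sf(98.13, tri), 1 - 48.13^2 / 27000)
  expect_equal(triangular_sf(c(0, 1000), tri), c(1, 0))  # clamped
})

test_that("bootstrap draws preserve the empirical support and frequencies", {
  expect_equal(bootstrap_concentration(0.107, runif(10)), rep(0.107, 10))
  u <- withr::with_seed(5, runif(4000))
  draws <- bootstrap_concentration(c(0.01, 0.03), u)
  p_hat <- mean(draws == 0.01)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 4000))
  sample_vals <- c(0.011, 0.05, 0.2)
  draws2 <- bootstrap_concentration(sample_vals, withr::with_seed(6, runif(500)))
  expect_true(all(draws2 %in% sample_vals))
  expect_error(bootstrap_concentration(numeric(0)), "empty")
})

test_that("collapsing concentration and intake reproduces deterministic THQ", {
  cfg <- mc_config(n_iter = 500, seed = 3,
                   intake = triangular_intake(140, 140, 140))
  out <- run_mc_thq(0.107, list(group = "adults", bw_kg = 70), cfg,
                    return_draws = TRUE)
  det <- compute_thq(0.107, 140, 70)
  expect_true(all(attr(out, "draws") == det))
  expect_equal(out$p50, det)
  expect_equal(out$p95, det)
  expect_equal(round(det, 3), 0.306)
})

test_that("exceedance probability matches the analytic triangular oracle", {
  cfg <- mc_config(n_iter = 30000, seed = 9)
  out <- run_mc_thq(0.107, list(group = "children", bw_kg = 15), cfg)
  # THQ > 1 iff weekly intake exceeds 7000 * BW * RfD / C ~ 98.13 g/week
  ir_crit <- 7000 * 15 * 1e-4 / 0.107
  p_true <- triangular_sf(ir_crit, cfg$intake)
  expect_equal(p_true, 0.914, tolerance = 1e-3)
  expect_lt(abs(out$p_exceed - p_true),
            3 * sqrt(p_true * (1 - p_true) / cfg$n_iter))
  # P50/P95 follow the triangular intake quantiles for degenerate C
  thq_at <- function(q) compute_thq(0.107, triangular_inverse_cdf(q, cfg$intake),
                                    15)
  expect_equal(out$p50, thq_at(0.5), tolerance = 0.01)
  expect_equal(out$p95, thq_at(0.95), tolerance = 0.01)
})

test_that("summaries are ordered, bounded and seed-deterministic", {
  vals <- withr::with_seed(2, exp(rnorm(15, -3, 0.8)))
  cfg <- mc_config(n_iter = 5000, seed = 17)
  a <- run_mc_thq(vals, list(group = "children", bw_kg = 15), cfg)
  b <- run_mc_thq(vals, list(group = "children", bw_kg = 15), cfg)
  expect_identical(a, b)
  expect_lte(a$p50, a$p95)
  expect_gte(a$p_exceed, 0)
  expect_lte(a$p_exceed, 1)
  c2 <- run_mc_thq(vals, list(group = "children", bw_kg = 15),
                   mc_config(n_iter = 5000, seed = 18))
  expect_false(identical(a$p50, c2$p50))
})

test_that("exceedance is monotone in concentration, BW and RfD", {
  vals <- withr::with_seed(4, exp(rnorm(12, -2.5, 0.7)))
  grp <- list(group = "children", bw_kg = 15)
  cfg <- mc_config(n_iter = 4000, seed = 23)
  base <- run_mc_thq(vals, grp, cfg)
  up <- run_mc_thq(vals * 1.5, grp, cfg)
  expect_gte(up$p_exceed, base$p_exceed)
  heavier <- run_mc_thq(vals, list(group = "adults", bw_kg = 70), cfg)
  expect_lte(heavier$p_exceed, base$p_exceed)
  cfg_rfd <- cfg
  cfg_rfd$tox <- tox_reference(rfd_mg_kg_day = 2e-4)
  expect_lte(run_mc_thq(vals, grp, cfg_rfd)$p_exceed, base$p_exceed)
})

test_that("the hazard-index engine reduces to and extends the THQ engine", {
  vals <- withr::with_seed(7, exp(rnorm(10, -3, 1)))
  grp <- list(group = "pregnant", bw_kg = 60)
  cfg <- mc_config(n_iter = 3000, seed = 31)
  one <- run_mc_hi(diet_basket(c(sp = 1), 140), list(sp = vals), grp, cfg,
                   return_draws = TRUE)
  solo <- run_mc_thq(vals, grp, cfg, return_draws = TRUE)
  expect_equal(attr(one, "draws"), attr(solo, "draws"))
  expect_equal(one[c("p50", "p95", "p_exceed")],
               solo[c("p50", "p95", "p_exceed")])

  # two species with identical degenerate C: HI equals THQ at full intake
  two <- run_mc_hi(diet_basket(c(a = 0.4, b = 0.6), 140),
                   list(a = 0.05, b = 0.05), grp, cfg, return_draws = TRUE)
  single <- run_mc_thq(0.05, grp, cfg, return_draws = TRUE)
  expect_equal(attr(two, "draws"), attr(single, "draws"), tolerance = 1e-12)

  # right-skewed inputs give right-skewed HI
  skew <- run_mc_hi(diet_basket(c(a = 0.5, b = 0.5), 140),
                    list(a = withr::with_seed(8, exp(rnorm(20, -3, 1))),
                         b = withr::with_seed(9, exp(rnorm(20, -3.5, 1)))),
                    grp, mc_config(n_iter = 10000, seed = 12),
                    return_draws = TRUE)
  d <- attr(skew, "draws")
  expect_gte(mean(d), median(d))
  expect_error(run_mc_hi(diet_basket(c(a = 1), 140), list(b = vals), grp, cfg),
               "no sample")
})

test_that("the species x group Monte Carlo table is reproducible", {
  s <- generate_survey(calibrate_defaults(), seed = 6)
  cfg <- mc_config(n_iter = 2000, seed = 44)
  t1 <- mc_risk_table(s, cfg)
  t2 <- mc_risk_table(s, cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 7 * 3)
  expect_true(all(t1$p50 <= t1$p95))
  expect_true(all(t1$p_exceed >= 0 & t1$p_exceed <= 1))
  expect_equal(t1$p_exceed_pct, 100 * t1$p_exceed)
})
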