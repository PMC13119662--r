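test_that("the normality gate log-transforms skewed samples only", {
  sym <- withr::with_seed(1, rnorm(50, 10, 1))
  skew <- withr::with_seed(2, exp(rnorm(50, 0, 1.5)))
  g1 <- normality_gate(sym)
  g2 <- normality_gate(skew)
  expect_false(g1$transformed)
  expect_identical(g1$values, sym)
  expect_true(g2$transformed)
  expect_identical(g2$values, log10(skew))
  # the gate's decision agrees with the reference Shapiro-Wilk test
  expect_equal(g1$shapiro_p, shapiro.test(sym)$p.value)
  expect_equal(g2$shapiro_p, shapiro.test(skew)$p.value)
  expect_error(normality_gate(c(1, 2)), "at least 3")
  expect_error(normality_gate(c(exp(rnorm(49, 0, 2)), -1)), "non-positive")
})

test_that("coefficient of variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)  # sd 1, mean 2
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("one-way ANOVA reproduces explicit sum-of-squares arithmetic", {
  # identical group profiles: no between-group variance, F = 0
  r0 <- oneway_anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$result$statistic, 0)

  # SSB = 13.5, SSW = 4, df = (1, 4) => F = 13.5 / 1 = 13.5
  r <- oneway_anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$result$statistic, 13.5)
  expect_equal(r$result$df_between, 1)
  expect_equal(r$result$df_within, 4)

  expect_error(oneway_anova_tukey(c(1, 2, 3), c("a", "a", "b")),
               ">= 2 members")
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(14))
    g <- rep(c("a", "b"), 7)
    r <- oneway_anova_tukey(x, g)
    t2 <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)$statistic^2
    expect_equal(r$result$statistic, unname(t2))
  }
})

test_that("Tukey-adjusted p-values never undercut unadjusted pairwise p", {
  x <- withr::with_seed(10, rnorm(18, rep(c(0, 0.5, 1.5), each = 6)))
  g <- rep(c("a", "b", "c"), each = 6)
  r <- oneway_anova_tukey(x, g)
  raw <- stats::pairwise.t.test(x, g, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  raw_p <- c(raw["b", "a"], raw["c", "a"], raw["c", "b"])
  expect_true(all(r$tukey$p_adj >= raw_p - 1e-12))
})

test_that("species differences in generated muscle THg are detected", {
  s <- generate_survey(calibrate_defaults(), seed = 71)
  mus <- tissue_values(s, "muscle")
  r <- suppressWarnings(
    oneway_anova_tukey(mus$thg_mg_kg_ww, mus$species, gate = TRUE))
  expect_true(r$result$transformed)
  expect_lt(r$result$p_value, 0.05)
})

test_that("correlation cells match exact and rank arithmetic", {
  s <- make_survey(c(0.01, 0.02, 0.03, 0.04), tl = c(10, 20, 30, 40))
  r <- correlation_matrix(s, "tl_cm", "pearson")
  expect_equal(r$estimate, 1)

  # anti-monotone nonlinear pair: rho = -1 while |r| < 1
  s2 <- make_survey(c(8, 4, 2), tl = c(1, 2, 3))
  rho <- correlation_matrix(s2, "tl_cm", "spearman")
  pea <- correlation_matrix(s2, "tl_cm", "pearson")
  expect_equal(rho$estimate, -1)
  expect_lt(abs(pea$estimate), 1)

  # cells under the n >= 3 threshold are flagged absent, not zero
  s3 <- make_survey(c(0.1, 0.2))
  r3 <- correlation_matrix(s3, "tl_cm", "pearson")
  expect_false(r3$estimable)
  expect_true(is.na(r3$estimate))
})

test_that("correlations are invariant to the transforms they should ignore", {
  x <- withr::with_seed(3, rnorm(20, 25, 3))
  y <- withr::with_seed(4, 0.02 + 0.001 * x + rnorm(20, 0, 0.004))
  s_raw <- make_survey(abs(y), tl = x)
  s_aff <- make_survey(abs(y), tl = 3 * x + 7)
  r1 <- correlation_matrix(s_raw, "tl_cm", "pearson")$estimate
  r2 <- correlation_matrix(s_aff, "tl_cm", "pearson")$estimate
  expect_equal(r1, r2)
  s_mono <- make_survey(exp(abs(y)), tl = x)
  rho1 <- correlation_matrix(s_raw, "tl_cm", "spearman")$estimate
  rho2 <- correlation_matrix(s_mono, "tl_cm", "spearman")$estimate
  expect_equal(rho1, rho2)
})

test_that("configured positive size effects surface in generated data", {
  cfg <- calibrate_defaults()
  cfg$counts$n <- cfg$counts$n * 6L
  s <- generate_survey(cfg, seed = 55)
  r <- correlation_matrix(s, "tl_cm", "pearson")
  carp_muscle <- r[r$species == "Carassius gibelio" & r$organ == "muscle", ]
  expect_gt(carp_muscle$estimate, 0)
})

test_that("the OLS size model recovers exact and hand-solved coefficients", {
  # noiseless response in TL only
  tl <- c(10, 15, 20, 25, 30)
  tw <- c(90, 300, 820, 1520, 2700)
  s <- make_survey(0.01 + 0.002 * tl, tl = tl, tw = tw)
  fit <- suppressWarnings(ols_size_model(s, "Perca fluviatilis"))
  expect_equal(fit$coefficients$estimate,
               c(0.01, 0.002, 0), tolerance = 1e-8, ignore_attr = TRUE)

  # 5-point dataset against the normal equations solved directly
  y <- c(0.02, 0.05, 0.03, 0.08, 0.06)
  s2 <- make_survey(y, tl = tl, tw = tw)
  fit2 <- ols_size_model(s2, "Perca fluviatilis")
  X <- cbind(1, tl, tw)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit2$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-8, ignore_attr = TRUE)

  # collinear design: TW dropped, model flagged degenerate
  s3 <- make_survey(y, tl = tl, tw = 10 * tl)
  expect_warning(fit3 <- ols_size_model(s3, "Perca fluviatilis"),
                 "collinear")
  expect_true(fit3$degenerate)
  expect_equal(nrow(fit3$coefficients), 2)

  expect_error(ols_size_model(make_survey(c(0.1, 0.2, 0.3)),
                              "Perca fluviatilis"), "n >= 4")
})

test_that("generated size-effect slopes are recovered by OLS within 10%", {
  cfg <- calibrate_defaults()
  cfg$counts$n <- cfg$counts$n * 20L
  cfg$organ_params$sigma_log <- 0.05
  s <- generate_survey(cfg, seed = 14)
  carp <- tissue_values(s, "muscle", "Carassius gibelio")
  fit <- lm(log(thg_mg_kg_ww) ~ log(tl_cm) + log(tw_g), data = carp)
  expect_lt(abs(coef(fit)[["log(tl_cm)"]] +
                  3 * coef(fit)[["log(tw_g)"]] - 2.0) / 2.0, 0.10)
})

test_that("the Mann-Whitney contrast uses the exact small-sample null", {
  # complete separation: U = 0, exact p = 2/70
  s <- make_survey(c(1, 2, 3, 4, 5, 6, 7, 8),
                   size_class = rep(c("small", "large"), each = 4))
  r <- mann_whitney_size_contrast(s, "Perca fluviatilis")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 70)
  expect_equal(r$n_small, 4)
  expect_equal(r$n_large, 4)

  # maximally interleaved groups: U = n1 * n2 / 2 = 8
  s2 <- make_survey(c(2, 3, 6, 7, 1, 4, 5, 8),
                    size_class = rep(c("small", "large"), each = 4))
  r2 <- mann_whitney_size_contrast(s2, "Perca fluviatilis")
  expect_equal(r2$statistic, 8)

  expect_error(
    mann_whitney_size_contrast(
      make_survey(1:4, size_class = rep("small", 4)), "Perca fluviatilis"),
    "non-empty")
})

test_that("exact Mann-Whitney p equals the full enumeration oracle", {
  sizes <- list(c(2, 3), c(3, 3), c(3, 4), c(4, 4), c(2, 5), c(5, 5))
  for (i in seq_along(sizes)) {
    ns <- sizes[[i]]
    vals <- withr::with_seed(100 + i, sample(seq(1, 60), sum(ns)))
    small <- vals[seq_len(ns[1])]
    large <- vals[-seq_len(ns[1])]
    s <- make_survey(c(small, large),
                     size_class = rep(c("small", "large"), ns))
    r <- mann_whitney_size_contrast(s, "Perca fluviatilis")
    expect_equal(r$p_value, mw_enumeration_p(large, small))
  }
})

test_that("underpowered size contrasts behave like the 4-vs-4 study case", {
  cfg <- calibrate_defaults()
  s <- generate_survey(cfg, seed = 21)
  # restrict to the Ivaylovgrad Prussian carp (8 specimens -> 4 vs 4)
  keep <- s$specimens$species == "Carassius gibelio" &
    s$specimens$reservoir == "Ivaylovgrad"
  sub <- hg_survey(s$specimens[keep, ],
                   s$tissues[s$tissues$specimen_id %in%
                               s$specimens$specimen_id[keep], ])
  sub <- assign_size_classes(sub, "Carassius gibelio")
  expect_equal(sort(as.integer(table(sub$specimens$size_class))), c(4L, 4L))
  r <- mann_whitney_size_contrast(sub, "Carassius gibelio")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_equal(r$n, 8)
})
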