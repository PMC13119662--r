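# Descriptive and comparative statistics for tissue concentrations:
# normality-gated transforms, one-way ANOVA with Tukey HSD, size-concentration
# correlation matrices, OLS size models and the exact Mann-Whitney size-class
# contrast. Significance is read at p < 0.05 throughout; per-cell correlation
# p-values are reported raw (no matrix-wide multiplicity correction), which is
# deliberately liberal.

#' Normality gate
#'
#' Applies the Shapiro-Wilk test to a sample and returns the log10-transformed
#' sample when normality is rejected at p < 0.05, else the raw sample.
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Rejection level for the Shapiro-Wilk test.
#' @return List with `transformed` (logical), `values` (working sample) and
#'   `shapiro_p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("normality gate needs at least 3 observations", call. = FALSE)
  }
  p <- shapiro.test(values)$p.value
  transformed <- p < alpha
  if (transformed && any(values <= 0)) {
    stop("cannot log10-transform a sample with non-positive values",
         call. = FALSE)
  }
  list(transformed = transformed,
       values = if (transformed) log10(values) else values,
       shapiro_p = p)
}

#' Coefficient of variation
#'
#' @param values Numeric sample, n >= 2.
#' @return CV in percent, `100 * sd / mean` (n - 1 denominator).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV needs at least 2 observations", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * sd(values) / m
}

#' One-way ANOVA with Tukey HSD
#'
#' Classical one-way F test with Tukey honest-significant-difference pairwise
#' comparisons. Variance homogeneity is checked with Levene's test (absolute
#' deviations from group medians); failure raises a warning, not an error.
#' Optionally the normality gate is applied to the response first.
#'
#' @param values Numeric response.
#' @param groups Grouping labels (coerced to factor), >= 2 groups with >= 2
#'   members each.
#' @param gate Apply [normality_gate()] to `values` before testing?
#' @return List with `result` (one-row tibble: statistic, df, p_value, n,
#'   transformed), `tukey` (tibble of pairwise contrasts with adjusted
#'   p-values) and `levene_p`.
#' @export
oneway_anova_tukey <- function(values, groups, gate = FALSE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("ANOVA needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  transformed <- FALSE
  if (gate) {
    g <- normality_gate(values)
    values <- g$values
    transformed <- g$transformed
  }
  lev <- car::leveneTest(values ~ groups, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  if (is.finite(levene_p) && levene_p < 0.05) {
    warning("Levene's test indicates heterogeneous variances (p = ",
            signif(levene_p, 3), "); ANOVA F may be unreliable", call. = FALSE)
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  tukey <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  list(
    result = tibble::tibble(
      statistic = tab[["F value"]][1],
      df_between = tab[["Df"]][1],
      df_within = tab[["Df"]][2],
      p_value = tab[["Pr(>F)"]][1],
      n = length(values),
      transformed = transformed
    ),
    tukey = tukey,
    levene_p = levene_p
  )
}

#' Size-concentration correlation matrix
#'
#' Pearson or Spearman correlations between a morphometric predictor (total
#' length or total weight) and tissue THg, either per species x organ cell or
#' pooled across species per organ. Cells with fewer than `min_n` paired
#' observations are reported with `NA` estimates and `estimable = FALSE`
#' rather than zero.
#'
#' @param survey An `hg_survey`.
#' @param predictor `"tl_cm"` or `"tw_g"`.
#' @param method `"pearson"` or `"spearman"`.
#' @param by `"species"` for species x organ cells, `"pooled"` for organ-level
#'   correlations across all specimens.
#' @param organs Organ subset (default: all present).
#' @param min_n Minimum paired sample size per cell.
#' @param log_thg Correlate against log10 THg instead of the raw scale.
#' @return Tibble with one row per cell: estimate, p_value, n, estimable.
#' @export
correlation_matrix <- function(survey, predictor = c("tl_cm", "tw_g"),
                               method = c("pearson", "spearman"),
                               by = c("species", "pooled"),
                               organs = NULL, min_n = 3, log_thg = FALSE) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  by <- match.arg(by)
  flat <- dplyr::inner_join(survey$specimens, survey$tissues,
                            by = "specimen_id")
  if (!is.null(organs)) flat <- flat[flat$organ %in% organs, ]
  if (log_thg) flat$thg_mg_kg_ww <- log10(flat$thg_mg_kg_ww)

  keys <- if (by == "species") c("species", "organ") else "organ"
  cells <- dplyr::distinct(flat[keys])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- dplyr::semi_join(flat, cells[i, ], by = keys)
    x <- sub[[predictor]]
    y <- sub$thg_mg_kg_ww
    ok <- complete.cases(x, y)
    n <- sum(ok)
    row <- cells[i, ]
    if (n < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(row, estimate = NA_real_, p_value = NA_real_,
                            n = n, estimable = FALSE))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = method,
               exact = if (method == "spearman") FALSE else NULL)
    )
    tibble::tibble(row, estimate = unname(ct$estimate),
                   p_value = ct$p.value, n = n, estimable = TRUE)
  })
  out <- dplyr::bind_rows(out)
  out$predictor <- predictor
  out$method <- method
  out
}

#' OLS size model for tissue concentration
#'
#' Ordinary least squares with tissue THg as response and total length and
#' total weight as predictors, fitted per species (optionally log10 response).
#' Reports coefficients with standard errors plus residual diagnostics:
#' Shapiro-Wilk on residuals, maximum leverage, and a score test for
#' non-constant variance. A rank-deficient design (TL and TW collinear to
#' machine precision) is refitted on TL alone and flagged degenerate.
#'
#' @param survey An `hg_survey`.
#' @param species Species token.
#' @param organ Organ token.
#' @param log_response Model log10(THg) instead of THg.
#' @return List with `coefficients` (tibble), `diagnostics` (tibble),
#'   `degenerate` flag and the underlying `lm` fit.
#' @export
ols_size_model <- function(survey, species, organ = "muscle",
                           log_response = FALSE) {
  dat <- tissue_values(survey, organ = organ, species = species)
  if (nrow(dat) < 4) {
    stop("OLS size model needs n >= 4 (two predictors plus intercept)",
         call. = FALSE)
  }
  y <- if (log_response) log10(dat$thg_mg_kg_ww) else dat$thg_mg_kg_ww
  df <- data.frame(y = y, tl_cm = dat$tl_cm, tw_g = dat$tw_g)
  X <- cbind(1, df$tl_cm, df$tw_g)
  degenerate <- qr(X)$rank < 3
  fit <- if (degenerate) lm(y ~ tl_cm, data = df) else lm(y ~ tl_cm + tw_g, data = df)
  if (degenerate) {
    warning("TL and TW are collinear; TW dropped from the model", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  res <- residuals(fit)
  shapiro_p <- if (length(res) >= 3 && sd(res) > 0) {
    shapiro.test(res)$p.value
  } else NA_real_
  ncv_p <- tryCatch(car::ncvTest(fit)$p, error = function(e) NA_real_)
  list(
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      statistic = sm[, 3], p_value = sm[, 4]
    ),
    diagnostics = tibble::tibble(
      n = nrow(df),
      r_squared = summary(fit)$r.squared,
      resid_shapiro_p = shapiro_p,
      max_leverage = max(hatvalues(fit)),
      ncv_p = ncv_p,
      resid_normal = is.na(shapiro_p) | shapiro_p >= 0.05,
      var_homogeneous = is.na(ncv_p) | ncv_p >= 0.05
    ),
    degenerate = degenerate,
    fit = fit
  )
}

#' Mann-Whitney size-class contrast
#'
#' Compares tissue THg between the small and large size classes of one
#' species with the two-sided Mann-Whitney U test, using the exact null
#' distribution when the combined sample size is at most 20 and there are no
#' ties (normal approximation with continuity correction otherwise). The
#' statistic reported follows the smaller-of-the-two-U convention.
#'
#' @param survey An `hg_survey`; size classes are assigned on the fly when
#'   absent (see [assign_size_classes()]).
#' @param species Species token.
#' @param organ Organ token.
#' @return One-row tibble: statistic (U), p_value, n_small, n_large, n,
#'   median_small, median_large, label.
#' @export
mann_whitney_size_contrast <- function(survey, species, organ = "muscle") {
  sp <- survey$specimens
  if (!"size_class" %in% names(sp) ||
      all(is.na(sp$size_class[sp$species == species]))) {
    survey <- assign_size_classes(survey, species)
  }
  dat <- tissue_values(survey, organ = organ, species = species)
  x <- dat$thg_mg_kg_ww[dat$size_class == "large"]
  y <- dat$thg_mg_kg_ww[dat$size_class == "small"]
  if (!length(x) || !length(y)) {
    stop("both size classes must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  u1 <- unname(wt$statistic)
  u2 <- length(x) * length(y) - u1
  tibble::tibble(
    statistic = min(u1, u2),
    p_value = wt$p.value,
    n_small = length(y),
    n_large = length(x),
    n = length(x) + length(y),
    median_small = stats::median(y),
    median_large = stats::median(x),
    label = paste(species, organ, "large vs small")
  )
}

#' Organ-level summary table
#'
#' Pooled per-organ THg summary: n, mean, SD, median, range and coefficient
#' of variation (percent).
#'
#' @param survey An `hg_survey`.
#' @return Tibble with one row per organ present in the survey.
#' @export
organ_summary <- function(survey) {
  dplyr::summarise(
    dplyr::group_by(survey$tissues, organ),
    n = dplyr::n(),
    mean = mean(thg_mg_kg_ww),
    sd = sd(thg_mg_kg_ww),
    median = stats::median(thg_mg_kg_ww),
    min = min(thg_mg_kg_ww),
    max = max(thg_mg_kg_ww),
    cv_percent = 100 * sd(thg_mg_kg_ww) / mean(thg_mg_kg_ww),
    .groups = "drop"
  )
}
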