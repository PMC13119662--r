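# Probabilistic exposure engine: Monte Carlo THQ/HI with triangular weekly
# intake and species-specific empirical bootstrap of muscle concentrations,
# plus closed-form triangular CDF/quantile oracles used both for sampling and
# for validating the simulation.

#' Triangular intake distribution
#'
#' Weekly fish intake Tri(min, mode, max) in g/week; defaults Tri(50, 140,
#' 350). A degenerate point mass (`a == b`) is accepted so deterministic
#' scenarios can be expressed as collapsed distributions.
#'
#' @param a_g_week Minimum.
#' @param c_g_week Mode.
#' @param b_g_week Maximum.
#' @return List of class `hg_tri`.
#' @export
triangular_intake <- function(a_g_week = hg_defaults()$tri_g_week[["min"]],
                              c_g_week = hg_defaults()$tri_g_week[["mode"]],
                              b_g_week = hg_defaults()$tri_g_week[["max"]]) {
  stopifnot(a_g_week <= c_g_week, c_g_week <= b_g_week, a_g_week > 0)
  structure(list(a = a_g_week, c = c_g_week, b = b_g_week), class = "hg_tri")
}

#' Triangular inverse CDF
#'
#' Standard closed form: for `u <= (c-a)/(b-a)`,
#' `a + sqrt(u (b-a)(c-a))`; else `b - sqrt((1-u)(b-a)(b-c))`.
#'
#' @param u Uniform variates in `[0, 1]`.
#' @param tri A [triangular_intake()].
#' @return Quantiles in `[a, b]`. Vectorised over `u`.
#' @export
triangular_inverse_cdf <- function(u, tri = triangular_intake()) {
  if (any(!is.finite(u) | u < 0 | u > 1)) {
    stop("u must lie in [0, 1]", call. = FALSE)
  }
  with(tri, {
    if (b == a) return(rep(a, length(u)))
    fc <- (c - a) / (b - a)
    ifelse(u <= fc,
           a + sqrt(u * (b - a) * (c - a)),
           b - sqrt((1 - u) * (b - a) * (b - c)))
  })
}

#' Triangular CDF and survival function
#'
#' Exact distribution function of the triangular intake model; arguments
#' outside the support are clamped.
#'
#' @param x Intake threshold(s), g/week.
#' @param tri A [triangular_intake()].
#' @return Probabilities. Vectorised over `x`.
#' @export
triangular_cdf <- function(x, tri = triangular_intake()) {
  with(tri, {
    if (b == a) return(as.numeric(x >= a))
    out <- ifelse(
      x <= a, 0,
      ifelse(x >= b, 1,
             ifelse(x <= c,
                    (x - a)^2 / ((b - a) * (c - a)),
                    1 - (b - x)^2 / ((b - a) * (b - c)))))
    # degenerate edges of a non-degenerate triangle (a == c or c == b)
    out[is.nan(out)] <- as.numeric(x[is.nan(out)] > c)
    out
  })
}

#' @rdname triangular_cdf
#' @export
triangular_sf <- function(x, tri = triangular_intake()) {
  1 - triangular_cdf(x, tri)
}

#' One empirical bootstrap draw of concentration
#'
#' Draws values uniformly with replacement from the observed species muscle
#' sample, mapping uniform variates to sample indices so that the
#' concentration stream stays independent of the intake stream. The support
#' of the draws equals the support of the input.
#'
#' @param muscle_values Non-empty sample of muscle THg, mg/kg ww.
#' @param u Uniform variates in `[0, 1)`; defaults to a single `runif()` draw
#'   from the current RNG stream.
#' @return Bootstrap draws, same length as `u`.
#' @export
bootstrap_concentration <- function(muscle_values, u = runif(1)) {
  muscle_values <- muscle_values[!is.na(muscle_values)]
  if (!length(muscle_values)) {
    stop("empty concentration sample", call. = FALSE)
  }
  m <- length(muscle_values)
  idx <- pmin(floor(u * m) + 1L, m)
  muscle_values[idx]
}

#' Monte Carlo configuration
#'
#' @param n_iter Iteration count (default 30,000).
#' @param seed Integer RNG seed.
#' @param intake A [triangular_intake()].
#' @param groups Consumer groups tibble.
#' @param tox A [tox_reference()].
#' @return List of class `hg_mc_config`.
#' @export
mc_config <- function(n_iter = hg_defaults()$mc_iterations, seed = 1L,
                      intake = triangular_intake(),
                      groups = consumer_groups(), tox = tox_reference()) {
  stopifnot(n_iter >= 1, inherits(intake, "hg_tri"), inherits(tox, "hg_tox"))
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 intake = intake, groups = groups, tox = tox),
            class = "hg_mc_config")
}

# shared draw engine: one intake stream (shared across species), then one
# concentration stream per species, in basket order
mc_hi_draws <- function(samples, shares, total_share_ir, bw_kg, config) {
  n <- config$n_iter
  ir <- triangular_inverse_cdf(runif(n), config$intake)
  hi <- numeric(n)
  for (s in names(samples)) {
    cdraw <- bootstrap_concentration(samples[[s]], runif(n))
    hi <- hi + compute_thq(cdraw, shares[[s]] * ir, bw_kg,
                           config$tox$rfd_mg_kg_day,
                           config$tox$mehg_fraction)
  }
  hi
}

mc_summarise <- function(draws, config, species, group) {
  tibble::tibble(
    species = species,
    group = group,
    p50 = unname(quantile(draws, 0.50, type = 7)),
    p95 = unname(quantile(draws, 0.95, type = 7)),
    p_exceed = mean(draws > 1),
    n_iter = config$n_iter,
    seed = config$seed
  )
}

#' Monte Carlo THQ for one species and consumer group
#'
#' Per iteration, the muscle concentration is one bootstrap draw from the
#' species sample and the weekly intake one draw from the triangular model;
#' the two come from independent uniform streams of a single seeded
#' generator, and body weight is fixed per group. THQ is computed per
#' iteration and summarised by the median (P50), 95th percentile (P95,
#' type-7 quantiles) and the exceedance probability `P(THQ > 1)`.
#' Deterministic given the seed.
#'
#' @param muscle_values Non-empty sample of muscle THg, mg/kg ww.
#' @param group One-row tibble (or named list) with `group` and `bw_kg`.
#' @param config An [mc_config()].
#' @param return_draws Attach the raw THQ draws as attribute `draws`?
#' @return One-row summary tibble (`p50`, `p95`, `p_exceed` in `[0, 1]`,
#'   `n_iter`, `seed`).
#' @export
run_mc_thq <- function(muscle_values, group, config = mc_config(),
                       return_draws = FALSE) {
  species <- attr(muscle_values, "species") %||% NA_character_
  withr::with_seed(config$seed, {
    draws <- mc_hi_draws(
      samples = list(x = muscle_values), shares = c(x = 1),
      total_share_ir = NULL, bw_kg = group$bw_kg, config = config)
    out <- mc_summarise(draws, config, species, group$group)
    if (return_draws) attr(out, "draws") <- draws
    out
  })
}

#' Monte Carlo hazard index for a diet basket
#'
#' As [run_mc_thq()], but a single shared intake draw per iteration is split
#' across the basket species by their shares, concentrations are
#' bootstrapped independently per species, and `HI = sum THQ_i` is
#' summarised with `P(HI > 1)`. A single-species basket reproduces
#' [run_mc_thq()] exactly under the same seed.
#'
#' @param basket A [diet_basket()]; its `total_ir_g_week` is ignored in the
#'   probabilistic setting (intake comes from the triangular model).
#' @param samples Named list of per-species muscle samples covering every
#'   basket species with positive share.
#' @inheritParams run_mc_thq
#' @return One-row summary tibble.
#' @export
run_mc_hi <- function(basket, samples, group, config = mc_config(),
                      return_draws = FALSE) {
  stopifnot(inherits(basket, "hg_basket"))
  active <- names(basket$shares)[basket$shares > 0]
  missing <- setdiff(active, names(samples))
  if (length(missing)) {
    stop("no sample for basket species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$seed, {
    draws <- mc_hi_draws(samples[active], basket$shares[active],
                         total_share_ir = NULL, bw_kg = group$bw_kg,
                         config = config)
    out <- mc_summarise(draws, config,
                        paste(active, collapse = "+"), group$group)
    if (return_draws) attr(out, "draws") <- draws
    out
  })
}

#' Monte Carlo risk table
#'
#' Runs [run_mc_thq()] for every species x consumer group in the survey,
#' deriving one sub-seed per cell from the configuration seed so the whole
#' table is reproducible.
#'
#' @param survey An `hg_survey`.
#' @param config An [mc_config()].
#' @return Tibble, one row per species x group, with P50, P95, `p_exceed`
#'   and `p_exceed_pct`.
#' @export
mc_risk_table <- function(survey, config = mc_config()) {
  muscle <- tissue_values(survey, organ = "muscle")
  species <- sort(unique(muscle$species))
  k <- 0L
  rows <- lapply(species, function(s) {
    vals <- muscle$thg_mg_kg_ww[muscle$species == s]
    dplyr::bind_rows(lapply(seq_len(nrow(config$groups)), function(g) {
      k <<- k + 1L
      cell_cfg <- config
      cell_cfg$seed <- as.integer((config$seed + k) %% 2147483647L)
      out <- run_mc_thq(vals, config$groups[g, ], cell_cfg)
      out$species <- s
      out
    }))
  })
  out <- dplyr::bind_rows(rows)
  out$p_exceed_pct <- 100 * out$p_exceed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
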