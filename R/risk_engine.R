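# Deterministic exposure and risk: estimated daily intake (EDI), target
# hazard quotient (THQ), hazard index (HI), safe weekly intake (SWI) and
# traffic-light consumption categories. Concentrations are muscle THg in
# mg/kg wet weight; intakes are g/week and converted to daily intake by
# division by 7 (140 g/week <=> 0.02 kg/day).

#' Consumer groups
#'
#' Default consumer groups and body weights: adults 70 kg, pregnant women
#' 60 kg, children 15 kg.
#'
#' @return Tibble with columns `group`, `bw_kg`.
#' @export
consumer_groups <- function() {
  bw <- hg_defaults()$bw_kg
  tibble::tibble(group = names(bw), bw_kg = unname(bw))
}

#' Toxicological reference values
#'
#' @param rfd_mg_kg_day Oral reference dose, mg/kg bw/day (default 0.0001,
#'   i.e. 0.1 ug/kg/day for methylmercury).
#' @param twi_mg_kg_week Tolerable weekly intake, mg/kg bw/week (default
#'   0.0013, i.e. the EFSA 1.3 ug/kg/week for methylmercury).
#' @param mehg_fraction Fraction of THg assumed to be methylmercury, in
#'   (0, 1]. THg is used as a 1.0 proxy by default; muscle MeHg fractions of
#'   0.8-0.95 can be explored with this knob.
#' @return List of class `hg_tox`.
#' @export
tox_reference <- function(rfd_mg_kg_day = hg_defaults()$rfd_mg_kg_day,
                          twi_mg_kg_week = hg_defaults()$twi_mg_kg_week,
                          mehg_fraction = 1) {
  stopifnot(rfd_mg_kg_day > 0, twi_mg_kg_week > 0,
            mehg_fraction > 0, mehg_fraction <= 1)
  structure(list(rfd_mg_kg_day = rfd_mg_kg_day,
                 twi_mg_kg_week = twi_mg_kg_week,
                 mehg_fraction = mehg_fraction),
            class = "hg_tox")
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]]) | args[[nm]] <= 0)) {
      stop(nm, " must be > 0", call. = FALSE)
    }
  }
}

#' Estimated daily intake
#'
#' `EDI = C * IR_daily / BW` with the weekly intake converted to kg/day
#' (`IR_daily = ir_g_week / 7 / 1000`).
#'
#' @param c_mg_kg Muscle THg concentration, mg/kg ww.
#' @param ir_g_week Fish intake, g/week.
#' @param bw_kg Body weight, kg.
#' @return EDI in mg/kg bw/day. Vectorised with recycling.
#' @export
compute_edi <- function(c_mg_kg, ir_g_week, bw_kg) {
  check_positive(c_mg_kg = c_mg_kg, ir_g_week = ir_g_week, bw_kg = bw_kg)
  c_mg_kg * (ir_g_week / 7 / 1000) / bw_kg
}

#' Target hazard quotient
#'
#' `THQ = EDI / RfD`; values below 1 are read as no significant
#' non-carcinogenic risk.
#'
#' @inheritParams compute_edi
#' @param rfd_mg_kg_day Oral reference dose, mg/kg bw/day.
#' @param mehg_fraction Optional MeHg fraction applied to the concentration.
#' @return THQ, dimensionless. Vectorised with recycling.
#' @export
compute_thq <- function(c_mg_kg, ir_g_week, bw_kg,
                        rfd_mg_kg_day = hg_defaults()$rfd_mg_kg_day,
                        mehg_fraction = 1) {
  check_positive(rfd_mg_kg_day = rfd_mg_kg_day)
  compute_edi(c_mg_kg * mehg_fraction, ir_g_week, bw_kg) / rfd_mg_kg_day
}

#' Diet basket
#'
#' Per-species shares of the total weekly fish intake.
#'
#' @param shares Named non-negative vector summing to 1 (tolerance 1e-9).
#' @param total_ir_g_week Total fish intake, g/week.
#' @return List of class `hg_basket`.
#' @export
diet_basket <- function(shares, total_ir_g_week) {
  stopifnot(!is.null(names(shares)), all(shares >= 0), total_ir_g_week > 0)
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("basket shares must sum to 1", call. = FALSE)
  }
  structure(list(shares = shares, total_ir_g_week = total_ir_g_week),
            class = "hg_basket")
}

#' Hazard index for a diet basket
#'
#' `HI = sum_i THQ(c_i, share_i * total_ir, bw)`: the cumulative
#' non-carcinogenic risk over the species in the basket. A single-species
#' basket reduces to the species THQ.
#'
#' @param basket An [diet_basket()].
#' @param concentrations Named vector of muscle THg (mg/kg ww) covering every
#'   basket species with positive share.
#' @param bw_kg Body weight, kg.
#' @param tox A [tox_reference()].
#' @return HI, dimensionless.
#' @export
compute_hi <- function(basket, concentrations, bw_kg,
                       tox = tox_reference()) {
  stopifnot(inherits(basket, "hg_basket"))
  active <- names(basket$shares)[basket$shares > 0]
  missing <- setdiff(active, names(concentrations))
  if (length(missing)) {
    stop("no concentration for basket species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(vapply(active, function(s) {
    compute_thq(concentrations[[s]],
                basket$shares[[s]] * basket$total_ir_g_week,
                bw_kg, tox$rfd_mg_kg_day, tox$mehg_fraction)
  }, numeric(1)))
}

#' Safe weekly intake
#'
#' `SWI = TWI * BW / C * 1000`, grams of fish per week at which the weekly
#' methylmercury dose equals the tolerable weekly intake. The exact identity
#' `SWI * C = TWI * BW * 1000` holds before rounding; reported tables round
#' to the nearest gram.
#'
#' @param c_mg_kg Muscle THg, mg/kg ww (> 0; an infinite allowance is never
#'   emitted).
#' @param bw_kg Body weight, kg.
#' @param twi_mg_kg_week Tolerable weekly intake, mg/kg bw/week.
#' @return SWI in g/week (unrounded). Vectorised with recycling.
#' @export
compute_swi <- function(c_mg_kg, bw_kg,
                        twi_mg_kg_week = hg_defaults()$twi_mg_kg_week) {
  check_positive(c_mg_kg = c_mg_kg, bw_kg = bw_kg,
                 twi_mg_kg_week = twi_mg_kg_week)
  twi_mg_kg_week * bw_kg / c_mg_kg * 1000
}

#' SWI at the sample median and 95th percentile
#'
#' Evaluates [compute_swi()] at the species-wise median and P95 of the
#' observed muscle concentrations (quantiles by linear interpolation of order
#' statistics, type 7). Since SWI is decreasing in concentration,
#' `swi_p95 <= swi_med` always.
#'
#' @param muscle_values Non-empty sample of muscle THg, mg/kg ww.
#' @inheritParams compute_swi
#' @return Named vector `c(swi_med, swi_p95)`, g/week (unrounded). A warning
#'   is raised for n < 20, where the sample P95 is unstable.
#' @export
swi_at_quantiles <- function(muscle_values, bw_kg,
                             twi_mg_kg_week = hg_defaults()$twi_mg_kg_week) {
  muscle_values <- muscle_values[!is.na(muscle_values)]
  if (!length(muscle_values)) {
    stop("empty concentration sample", call. = FALSE)
  }
  if (length(muscle_values) < 20) {
    warning("P95 from n = ", length(muscle_values),
            " observations is unstable", call. = FALSE)
  }
  c_med <- stats::median(muscle_values)
  c_p95 <- unname(quantile(muscle_values, 0.95, type = 7))
  c(swi_med = compute_swi(c_med, bw_kg, twi_mg_kg_week),
    swi_p95 = compute_swi(c_p95, bw_kg, twi_mg_kg_week))
}

#' Traffic-light consumption category
#'
#' Red: SWI below 140 g/week (less than one national-average weekly meal
#' allowance); yellow: 140-299 g/week; green: 300 g/week and above.
#'
#' @param swi_g_week Non-negative SWI, g/week. Vectorised.
#' @return Character vector in {"red", "yellow", "green"}.
#' @export
classify_traffic_light <- function(swi_g_week) {
  if (any(!is.finite(swi_g_week) | swi_g_week < 0)) {
    stop("swi_g_week must be >= 0", call. = FALSE)
  }
  d <- hg_defaults()
  ifelse(swi_g_week < d$traffic_red_below, "red",
         ifelse(swi_g_week < d$traffic_green_from, "yellow", "green"))
}

#' Deterministic risk table
#'
#' Species x consumer-group deterministic risk summary at a fixed weekly
#' intake: THQ at the species muscle median (3 decimals), SWI at the median
#' and P95 concentrations (nearest gram) and the traffic-light category of
#' the median-based SWI.
#'
#' @param survey An `hg_survey`.
#' @param groups Consumer groups tibble (see [consumer_groups()]).
#' @param tox A [tox_reference()].
#' @param ir_g_week Baseline weekly intake, g/week.
#' @return Tibble, one row per species x group.
#' @export
deterministic_risk <- function(survey, groups = consumer_groups(),
                               tox = tox_reference(),
                               ir_g_week = hg_defaults()$ir_baseline_g_week) {
  muscle <- tissue_values(survey, organ = "muscle")
  species <- sort(unique(muscle$species))
  rows <- lapply(species, function(s) {
    vals <- muscle$thg_mg_kg_ww[muscle$species == s]
    c_med <- stats::median(vals)
    dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(g) {
      bw <- groups$bw_kg[g]
      swi <- suppressWarnings(
        swi_at_quantiles(vals, bw, tox$twi_mg_kg_week))
      tibble::tibble(
        species = s,
        group = groups$group[g],
        n = length(vals),
        c_med_mg_kg = c_med,
        thq = round(compute_thq(c_med, ir_g_week, bw,
                                tox$rfd_mg_kg_day, tox$mehg_fraction), 3),
        swi_med_g_week = round(swi[["swi_med"]]),
        swi_p95_g_week = round(swi[["swi_p95"]]),
        category = classify_traffic_light(round(swi[["swi_med"]]))
      )
    }))
  })
  dplyr::bind_rows(rows)
}
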