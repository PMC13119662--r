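# Single source for study constants: exposure defaults, controlled vocabularies
# and the summary tables the synthetic generator is calibrated against.

#' Controlled vocabularies
#'
#' Canonical tokens for organs, reservoirs and trophic guilds. Nine organs are
#' carried even though dissection protocols often list seven; heart and skin
#' measurements occur in multi-tissue surveys and the data model accepts them.
#'
#' @return Character vector of canonical tokens.
#' @export
hg_organs <- function() {
  c("muscle", "liver", "kidneys", "spleen", "gills",
    "bones", "gonads", "hearts", "skin")
}

#' @rdname hg_organs
#' @export
hg_reservoirs <- function() {
  c("Kardzhali", "StudenKladenets", "Ivaylovgrad")
}

#' @rdname hg_organs
#' @export
hg_guilds <- function() {
  c("predator", "omnivore")
}

#' Exposure and toxicological defaults
#'
#' All constants used by the risk calculations live here so they are defined
#' exactly once: the methylmercury oral reference dose (RfD, mg per kg body
#' weight per day), the EFSA tolerable weekly intake (TWI, mg per kg body
#' weight per week), default consumer-group body weights (kg), the national
#' baseline fish intake (g per week, equivalent to 7.3 kg per year), the
#' triangular intake distribution bounds (g per week), the analytical limit of
#' detection (mg/kg wet weight) and the traffic-light advisory category bounds
#' on safe weekly intake (g per week).
#'
#' @return Named list of constants.
#' @export
hg_defaults <- function() {
  list(
    rfd_mg_kg_day   = 1e-4,
    twi_mg_kg_week  = 0.0013,
    bw_kg           = c(adults = 70, pregnant = 60, children = 15),
    ir_baseline_g_week = 140,
    annual_intake_kg   = 7.3,
    tri_g_week      = c(min = 50, mode = 140, max = 350),
    lod_mg_kg       = 5e-5,
    traffic_red_below    = 140,
    traffic_green_from   = 300,
    mc_iterations   = 30000
  )
}

#' Study species registry
#'
#' The seven species of the reservoir-cascade survey with trophic guild,
#' median morphometrics (total length TL in cm, total weight TW in g) and the
#' species-level muscle THg median (mg/kg ww) used as generator calibration
#' targets.
#'
#' @return A tibble with one row per species.
#' @export
study_species <- function() {
  tibble::tribble(
    ~species,             ~common_name,        ~guild,     ~tl_med_cm, ~tw_med_g, ~muscle_med_mg_kg,
    "Perca fluviatilis",  "European perch",    "predator",       24.2,       235,             0.107,
    "Silurus glanis",     "European catfish",  "predator",       62.0,      1862,             0.044,
    "Vimba melanops",     "Macedonian vimba",  "omnivore",       23.6,       181,             0.042,
    "Carassius gibelio",  "Prussian carp",     "omnivore",       28.4,       451,             0.018,
    "Rutilus rutilus",    "Roach",             "omnivore",       22.7,       196,             0.023,
    "Squalius orpheus",   "Orpheus dace",      "omnivore",       34.6,       609,             0.022,
    "Cyprinus carpio",    "Common carp",       "omnivore",       48.1,      2416,             0.009
  )
}

#' Study sampling design
#'
#' Specimen counts by species and reservoir (49 specimens, 7 species,
#' 3 reservoirs).
#'
#' @return A tibble with columns `species`, `reservoir`, `n`.
#' @export
study_counts <- function() {
  tibble::tribble(
    ~species,            ~reservoir,        ~n,
    "Cyprinus carpio",   "StudenKladenets",  3L,
    "Squalius orpheus",  "Ivaylovgrad",      3L,
    "Vimba melanops",    "Kardzhali",        5L,
    "Silurus glanis",    "StudenKladenets",  3L,
    "Perca fluviatilis", "Kardzhali",        5L,
    "Perca fluviatilis", "Ivaylovgrad",      4L,
    "Carassius gibelio", "Kardzhali",        5L,
    "Carassius gibelio", "StudenKladenets",  4L,
    "Carassius gibelio", "Ivaylovgrad",      8L,
    "Rutilus rutilus",   "Kardzhali",        5L,
    "Rutilus rutilus",   "Ivaylovgrad",      4L
  )
}

#' Organ-level THg reference moments
#'
#' Pooled tissue-specific THg summary (mg/kg ww) across the 49-specimen
#' survey: mean, SD, median and range per organ. These moments are the
#' generator's organ-level calibration targets.
#'
#' @return A tibble with one row per organ.
#' @export
organ_reference <- function() {
  tibble::tribble(
    ~organ,    ~mean,  ~sd,    ~median, ~min,  ~max,
    "bones",   0.023,  0.018,  0.016,   0.002, 0.069,
    "gills",   0.011,  0.011,  0.008,   0.001, 0.042,
    "gonads",  0.006,  0.005,  0.005,   0.001, 0.017,
    "hearts",  0.024,  0.031,  0.011,   0.001, 0.124,
    "kidneys", 0.020,  0.021,  0.011,   0.003, 0.107,
    "liver",   0.032,  0.051,  0.010,   0.002, 0.198,
    "muscle",  0.044,  0.034,  0.032,   0.008, 0.116,
    "skin",    0.016,  0.012,  0.015,   0.001, 0.067,
    "spleen",  0.022,  0.027,  0.007,   0.000, 0.120
  )
}

#' Reservoir-level muscle THg reference means
#'
#' Mean muscle THg (mg/kg ww) per reservoir, reflecting the longitudinal
#' gradient along the cascade (Kardzhali > Ivaylovgrad > Studen Kladenets).
#'
#' @return Named numeric vector.
#' @export
reservoir_reference <- function() {
  c(Kardzhali = 0.058, Ivaylovgrad = 0.039, StudenKladenets = 0.014)
}

# internal: canonicalise a token vector against a set of allowed tokens,
# case-insensitively and ignoring spaces/underscores; NA where no match
canonical_token <- function(x, allowed) {
  squash <- function(v) gsub("[ _]", "", tolower(v))
  allowed[match(squash(x), squash(allowed))]
}
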