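# Fish-survey container, validation and delimited-text I/O.
#
# A survey is a pair of tidy tables: one row per specimen (identity, guild,
# reservoir, morphometrics) and one row per specimen x organ measurement
# (THg, mg/kg wet weight, with a below-detection flag). The on-disk form is a
# single flat CSV, one row per specimen x organ.

SURVEY_COLUMNS <- c("specimen_id", "species", "common_name", "guild",
                    "reservoir", "tl_cm", "tw_g", "organ",
                    "thg_mg_kg_ww", "below_lod")

#' Construct a fish survey
#'
#' @param specimens Tibble with columns `specimen_id`, `species`,
#'   `common_name`, `guild`, `reservoir`, `tl_cm`, `tw_g` and optionally
#'   `size_class`.
#' @param tissues Tibble with columns `specimen_id`, `organ`,
#'   `thg_mg_kg_ww`, `below_lod`.
#' @param lod_mg_kg Analytical limit of detection, mg/kg ww.
#'
#' @return A validated object of class `hg_survey`.
#' @export
hg_survey <- function(specimens, tissues, lod_mg_kg = hg_defaults()$lod_mg_kg) {
  out <- structure(
    list(specimens = tibble::as_tibble(specimens),
         tissues = tibble::as_tibble(tissues),
         lod_mg_kg = lod_mg_kg),
    class = "hg_survey"
  )
  validate_survey(out)
}

#' @export
print.hg_survey <- function(x, ...) {
  cat(sprintf("<hg_survey> %d specimens, %d species, %d tissue records (LOD %g mg/kg)\n",
              nrow(x$specimens), length(unique(x$specimens$species)),
              nrow(x$tissues), x$lod_mg_kg))
  invisible(x)
}

#' Validate a fish survey
#'
#' Checks type, vocabulary and cross-table invariants: positive
#' morphometrics, known organ/reservoir/guild tokens, guild consistency with
#' the study registry for the seven core species, non-negative concentrations,
#' below-LOD records not exceeding the LOD, referential integrity of tissue
#' records, and at most one record per specimen x organ. Violations abort
#' with row-indexed diagnostics.
#'
#' @param survey An `hg_survey`.
#' @return The survey, invisibly valid (returned unchanged).
#' @export
validate_survey <- function(survey) {
  sp <- survey$specimens
  ti <- survey$tissues
  problems <- character()
  note <- function(rows, what, tbl) {
    if (length(rows)) {
      problems <<- c(problems, sprintf(
        "%s (%s row%s %s)", what, tbl, if (length(rows) > 1) "s" else "",
        paste(rows, collapse = ", ")))
    }
  }

  need_sp <- setdiff(c("specimen_id", "species", "common_name", "guild",
                       "reservoir", "tl_cm", "tw_g"), names(sp))
  need_ti <- setdiff(c("specimen_id", "organ", "thg_mg_kg_ww", "below_lod"),
                     names(ti))
  if (length(need_sp) || length(need_ti)) {
    stop("survey schema error: missing column(s) ",
         paste(c(need_sp, need_ti), collapse = ", "), call. = FALSE)
  }

  note(which(duplicated(sp$specimen_id)), "duplicated specimen_id", "specimen")
  note(which(!is.finite(sp$tl_cm) | sp$tl_cm <= 0), "tl_cm must be > 0", "specimen")
  note(which(!is.finite(sp$tw_g) | sp$tw_g <= 0), "tw_g must be > 0", "specimen")
  note(which(is.na(canonical_token(sp$reservoir, hg_reservoirs()))),
       paste0("unknown reservoir token (allowed: ",
              paste(hg_reservoirs(), collapse = ", "), ")"), "specimen")
  note(which(is.na(canonical_token(sp$guild, hg_guilds()))),
       paste0("unknown guild token (allowed: ",
              paste(hg_guilds(), collapse = ", "), ")"), "specimen")
  reg <- study_species()
  idx <- match(sp$species, reg$species)
  bad_guild <- which(!is.na(idx) & sp$guild != reg$guild[idx])
  note(bad_guild, "guild conflicts with the study registry for this species",
       "specimen")
  if ("size_class" %in% names(sp)) {
    note(which(!is.na(sp$size_class) & !sp$size_class %in% c("small", "large")),
         "size_class must be 'small' or 'large'", "specimen")
  }

  note(which(is.na(canonical_token(ti$organ, hg_organs()))),
       paste0("unknown organ token (allowed: ",
              paste(hg_organs(), collapse = ", "), ")"), "tissue")
  note(which(!is.finite(ti$thg_mg_kg_ww) | ti$thg_mg_kg_ww < 0),
       "thg_mg_kg_ww must be >= 0", "tissue")
  note(which(ti$below_lod & ti$thg_mg_kg_ww > survey$lod_mg_kg),
       "below_lod record exceeds the LOD", "tissue")
  note(which(!ti$specimen_id %in% sp$specimen_id),
       "tissue record references unknown specimen", "tissue")
  note(which(duplicated(paste(ti$specimen_id, ti$organ))),
       "duplicate record for a specimen x organ pair", "tissue")

  if (length(problems)) {
    stop("survey validation error:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  survey
}

#' Read a fish survey from CSV
#'
#' Expects a flat table, one row per specimen x organ, with the columns
#' `specimen_id, species, common_name, guild, reservoir, tl_cm, tw_g, organ,
#' thg_mg_kg_ww, below_lod` (an optional `size_class` column is honoured).
#' Organ, reservoir and guild tokens are matched case-insensitively and
#' written back in canonical form. Concentrations are stored internally in
#' mg/kg wet weight; files recorded in ug/kg can be read by setting
#' `conc_unit = "ug_kg"`, which divides by 1000 on read.
#'
#' @param path Path to a CSV file.
#' @param conc_unit Unit of the concentration column in the file.
#' @param lod_mg_kg Limit of detection, mg/kg ww.
#'
#' @return An `hg_survey`.
#' @export
read_survey <- function(path, conc_unit = c("mg_kg", "ug_kg"),
                        lod_mg_kg = hg_defaults()$lod_mg_kg) {
  conc_unit <- match.arg(conc_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("survey schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (conc_unit == "ug_kg") {
    raw$thg_mg_kg_ww <- raw$thg_mg_kg_ww / 1000
  }
  raw$organ <- canonical_token(raw$organ, hg_organs())
  raw$reservoir <- canonical_token(raw$reservoir, hg_reservoirs())
  raw$guild <- canonical_token(raw$guild, hg_guilds())
  raw$below_lod <- as.logical(raw$below_lod)

  spec_cols <- c("specimen_id", "species", "common_name", "guild",
                 "reservoir", "tl_cm", "tw_g",
                 intersect("size_class", names(raw)))
  specimens <- dplyr::distinct(raw[spec_cols])
  if (anyDuplicated(specimens$specimen_id)) {
    dup <- unique(specimens$specimen_id[duplicated(specimens$specimen_id)])
    stop("survey validation error: specimen(s) with inconsistent attributes ",
         "across rows: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tissues <- raw[c("specimen_id", "organ", "thg_mg_kg_ww", "below_lod")]
  hg_survey(specimens, tissues, lod_mg_kg = lod_mg_kg)
}

#' Write a fish survey to CSV
#'
#' Inverse of [read_survey()]: writes the flat one-row-per-specimen-x-organ
#' form with canonical lower-case organ tokens, so that reading the file back
#' reproduces the survey exactly. An empty survey yields a header-only file.
#'
#' @param survey An `hg_survey`.
#' @param path Output path.
#' @return The input survey, invisibly.
#' @export
write_survey <- function(survey, path) {
  validate_survey(survey)
  flat <- dplyr::inner_join(survey$specimens, survey$tissues,
                            by = "specimen_id")
  cols <- SURVEY_COLUMNS
  if ("size_class" %in% names(flat)) cols <- c(cols, "size_class")
  flat <- flat[cols]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(survey)
}

#' Assign size classes within a species
#'
#' Splits the specimens of one species into `small` and `large` classes
#' around the within-species median total weight: strictly above the median
#' is `large`, at or below is `small` (ties conservatively join the small
#' class, which carries the lower concentrations).
#'
#' @param survey An `hg_survey`.
#' @param species Species token present in the survey.
#' @return The survey with `size_class` filled in for that species.
#' @export
assign_size_classes <- function(survey, species) {
  sp <- survey$specimens
  rows <- which(sp$species == species)
  if (!length(rows)) stop("species not present in survey: ", species, call. = FALSE)
  if (length(rows) < 2) {
    stop("need at least 2 specimens of ", species, " to form size classes",
         call. = FALSE)
  }
  med <- stats::median(sp$tw_g[rows])
  if (!"size_class" %in% names(sp)) sp$size_class <- NA_character_
  sp$size_class[rows] <- ifelse(sp$tw_g[rows] > med, "large", "small")
  survey$specimens <- sp
  validate_survey(survey)
}

#' Tissue values for a species and organ
#'
#' Convenience extractor joining specimens and tissue records.
#'
#' @param survey An `hg_survey`.
#' @param organ Organ token (default muscle).
#' @param species Optional species filter.
#' @return Tibble of specimen attributes plus `thg_mg_kg_ww`.
#' @export
tissue_values <- function(survey, organ = "muscle", species = NULL) {
  ti <- survey$tissues[survey$tissues$organ == organ, ]
  out <- dplyr::inner_join(survey$specimens, ti, by = "specimen_id")
  if (!is.null(species)) out <- out[out$species %in% species, ]
  out
}
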