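# Fixture builders and independent oracles used across the suite.

# Build a small single- or multi-species survey from explicit muscle values.
# tl/tw default to plausible morphometrics; size_class may be set directly.
make_survey <- function(muscle, species = "Perca fluviatilis",
                        reservoir = "Kardzhali", tl = NULL, tw = NULL,
                        size_class = NULL, extra_organs = NULL) {
  n <- length(muscle)
  reg <- study_species()
  species <- rep_len(species, n)
  i <- match(species, reg$species)
  specimens <- tibble::tibble(
    specimen_id = sprintf("T%03d", seq_len(n)),
    species = species,
    common_name = ifelse(is.na(i), "Unknown", reg$common_name[i]),
    guild = ifelse(is.na(i), "omnivore", reg$guild[i]),
    reservoir = rep_len(reservoir, n),
    tl_cm = if (is.null(tl)) 20 + seq_len(n) else tl,
    tw_g = if (is.null(tw)) 100 * (20 + seq_len(n))^3 / 8000 else tw
  )
  if (!is.null(size_class)) specimens$size_class <- size_class
  tissues <- tibble::tibble(
    specimen_id = specimens$specimen_id,
    organ = "muscle",
    thg_mg_kg_ww = muscle,
    below_lod = FALSE
  )
  if (!is.null(extra_organs)) {
    for (org in names(extra_organs)) {
      tissues <- dplyr::bind_rows(tissues, tibble::tibble(
        specimen_id = specimens$specimen_id,
        organ = org,
        thg_mg_kg_ww = extra_organs[[org]],
        below_lod = FALSE
      ))
    }
  }
  hg_survey(specimens, tissues)
}

# Full-enumeration two-sided Mann-Whitney p-value (no ties), enumerating all
# choose(n1 + n2, n1) group assignments of the pooled values.
mw_enumeration_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">"))
  combs <- utils::combn(length(vals), n1)
  u_null <- apply(combs, 2, function(ix) u_of(vals[ix], vals[-ix]))
  u_obs <- u_of(x, y)
  p <- if (u_obs > n1 * length(y) / 2) {
    2 * mean(u_null >= u_obs)
  } else {
    2 * mean(u_null <= u_obs)
  }
  min(p, 1)
}

# Write a survey-shaped CSV from a data frame of rows (for I/O error tests).
write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

survey_row <- function(specimen_id = "S1", species = "Perca fluviatilis",
                       common_name = "European perch", guild = "predator",
                       reservoir = "Kardzhali", tl_cm = 24, tw_g = 235,
                       organ = "muscle", thg_mg_kg_ww = 0.1,
                       below_lod = FALSE) {
  tibble::tibble(specimen_id = specimen_id, species = species,
                 common_name = common_name, guild = guild,
                 reservoir = reservoir, tl_cm = tl_cm, tw_g = tw_g,
                 organ = organ, thg_mg_kg_ww = thg_mg_kg_ww,
                 below_lod = below_lod)
}
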