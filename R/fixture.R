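#' The packaged coral exosymbiont survey
#'
#' Loads the colony-level survey shipped with the package: 234 *Pocillopora
#' damicornis* colonies (types alpha and beta, adults and juveniles) from
#' two sites each at Reunion Island (RI) and New Caledonia (NC), with the
#' exosymbiont assemblage recorded for each colony. The five analysis
#' strata contain 61 (RI adults, all beta), 48 (NC alpha adults), 11 (NC
#' beta adults), 56 (RI juveniles) and 40 (NC alpha juveniles) colonies.
#'
#' Assemblages are recorded as presences (each listed taxon with count 1);
#' colony sizes are not part of the packaged data. Transcription
#' conventions, including the two composite assemblage rows with an
#' ambiguous reading, are documented in
#' `system.file("extdata", "fixture_notes.md", package = "coralguild")`.
#'
#' @return A `colony_set` (see [load_colony_tables()]).
#' @examples
#' survey <- coral_survey()
#' survey
#' @export
coral_survey <- function() {
  ext <- function(f) system.file("extdata", f, package = "coralguild",
                                 mustWork = TRUE)
  load_colony_tables(ext("colonies.csv"), ext("occupancy.csv"),
                     taxa = guild_taxa())
}

#' Benchmark observed statistics for the packaged survey
#'
#' Reference values of the observed guild statistics for the packaged
#' survey (richness-profile counts, pairwise co-occurrences and solitary
#' counts per stratum), used by [reproduce_guild_analysis()] to verify that
#' a run reproduces the canonical counts.
#'
#' @return A data frame with columns `stratum`, `family`, `statistic`,
#'   `expected`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv",
                      package = "coralguild", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# the five analysis strata of the packaged survey, in reporting order
survey_strata <- function() {
  list(
    ri_adult    = list(label = "RI adults (beta)",
                       region = "RI", stage = "adult"),
    nc_adult_a  = list(label = "NC adults alpha",
                       region = "NC", stage = "adult", host_type = "alpha"),
    nc_adult_b  = list(label = "NC adults beta",
                       region = "NC", stage = "adult", host_type = "beta"),
    ri_juvenile = list(label = "RI juveniles (beta)",
                       region = "RI", stage = "juvenile"),
    nc_juv_a    = list(label = "NC juveniles alpha",
                       region = "NC", stage = "juvenile",
                       host_type = "alpha")
  )
}
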