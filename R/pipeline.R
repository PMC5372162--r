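#' One-shot guild analysis of the packaged survey
#'
#' Runs [run_guild_analysis()] for all five analysis strata of the packaged
#' survey — richness profiles against M1/M2 and pairwise/solitary
#' statistics against M1/M2/M3 — and writes `richness.tsv`,
#' `cooccurrence.tsv`, a `summary.tsv` comparing the observed statistics
#' against the canonical benchmark counts of the survey
#' ([reference_counts()]), and a machine-readable `config.json` echo.
#' Identical seed and configuration give byte-identical output files.
#'
#' @param out_dir Output directory (created if needed).
#' @param reps Null replicates per model (default 10000).
#' @param ci_level CI level (default 0.95).
#' @param seed Master seed (default 1); each stratum derives its own
#'   sub-seed deterministically.
#' @param survey The `colony_set` to analyse; defaults to [coral_survey()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stratum reports (`reports`), the
#'   benchmark comparison (`summary`) and the paths written.
#' @export
reproduce_guild_analysis <- function(out_dir, reps = 10000L,
                                     ci_level = 0.95, seed = 1L,
                                     survey = coral_survey(),
                                     quiet = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory '", out_dir, "'")
    }
  }
  strata <- survey_strata()
  seeds <- derive_seeds(seed, length(strata))
  reports <- list()
  for (i in seq_along(strata)) {
    st <- strata[[i]]
    if (!quiet) {
      message("stratum ", st$label, " (seed ", seeds[i], ", ", reps,
              " reps per model)")
    }
    rep_i <- run_guild_analysis(
      survey,
      region = st$region, stage = st$stage, host_type = st$host_type,
      models = c("M1", "M2", "M3"),
      reps = reps, ci_level = ci_level, seed = seeds[i])
    rep_i$stratum <- names(strata)[i]
    rep_i$stratum_label <- st$label
    reports[[names(strata)[i]]] <- rep_i
  }
  all <- do.call(rbind, reports)
  rownames(all) <- NULL
  front <- c("stratum", "stratum_label")
  all <- all[, c(front, setdiff(names(all), front))]
  richness <- all[all$family == "richness", , drop = FALSE]
  cooc <- all[all$family %in% c("pairwise", "solitary"), , drop = FALSE]

  ref <- reference_counts()
  obs <- all[!duplicated(all[c("stratum", "statistic_id")]),
             c("stratum", "statistic_id", "observed")]
  summary <- merge(ref, obs,
                   by.x = c("stratum", "statistic"),
                   by.y = c("stratum", "statistic_id"),
                   all.x = TRUE, sort = FALSE)
  summary$match <- !is.na(summary$observed) &
    summary$observed == summary$expected

  paths <- file.path(out_dir,
                     c("richness.tsv", "cooccurrence.tsv", "summary.tsv",
                       "config.json"))
  write_tsv(richness, paths[1])
  write_tsv(cooc, paths[2])
  write_tsv(summary, paths[3])
  echo_config(list(subcommand = "reproduce", reps = reps,
                   ci_level = ci_level, seed = seed,
                   strata = names(strata),
                   fixture_checksum = fixture_checksum()),
              paths[4])
  if (!quiet) {
    message(sum(summary$match), "/", nrow(summary),
            " benchmark statistics reproduced")
  }
  invisible(list(reports = reports, summary = summary, paths = paths))
}

# deterministic sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable configuration echo
#'
#' Every pipeline run records its full configuration (including the seed
#' actually used and the fixture checksum) as JSON next to its outputs, so
#' a run can be repeated exactly from its echo.
#'
#' @param config Named list of configuration values.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
echo_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a configuration echo
#'
#' @param path JSON path written by [echo_config()].
#' @return Named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# md5 of the packaged occupancy table, recorded in run configs
fixture_checksum <- function() {
  path <- system.file("extdata", "occupancy.csv", package = "coralguild",
                      mustWork = TRUE)
  unname(tools::md5sum(path))
}
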