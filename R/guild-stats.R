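#' Key-species richness profile of a stratum
#'
#' Counts the colonies hosting exactly `k` of the key species, for
#' `k = 0 .. S`. Non-key residents never affect `k`: a colony hosting one
#' key species plus any number of non-key taxa counts in `n_1`.
#'
#' @param m Binary incidence matrix restricted to the key-species columns,
#'   with every stratum colony as a row (`drop_empty = FALSE`).
#' @return Named integer vector `n_0 .. n_S` summing to `nrow(m)`.
#' @examples
#' m <- to_incidence(select_stratum(coral_survey(), region = "RI",
#'                                  stage = "adult"), key_taxa())
#' richness_profile(m)  # n_1 = 37
#' @export
richness_profile <- function(m) {
  m <- as_binary_matrix(m)
  s <- ncol(m)
  n_k <- tabulate(rowSums(m) + 1L, nbins = s + 1L)
  names(n_k) <- paste0("n_", 0:s)
  n_k
}

#' Pairwise co-occurrence and solitary-occupancy counts
#'
#' For a key-species incidence matrix, computes the symmetric co-occurrence
#' table `c_ij` (number of colonies where species `i` and `j` are both
#' present; the diagonal holds the prevalences `f_i`) and the solitary
#' counts `s_i` (colonies where `i` is the only key species present).
#'
#' @inheritParams richness_profile
#' @return A list of class `cooccurrence_table` with elements `counts`
#'   (S x S integer matrix), `prevalence` and `solitary` (named integer
#'   vectors).
#' @examples
#' m <- to_incidence(select_stratum(coral_survey(), region = "RI",
#'                                  stage = "adult"), key_taxa())
#' pairwise_cooccurrence(m)$counts["Tgut", "AlotL1"]  # 15
#' @export
pairwise_cooccurrence <- function(m) {
  m <- as_binary_matrix(m)
  cc <- crossprod(m)
  storage.mode(cc) <- "integer"
  r <- rowSums(m)
  sol <- vapply(seq_len(ncol(m)),
                function(s) sum(m[, s] == 1L & r == 1L), integer(1))
  names(sol) <- colnames(m)
  structure(list(counts = cc, prevalence = diag(cc), solitary = sol),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("<cooccurrence_table>\n")
  print(x$counts)
  cat("solitary:\n")
  print(x$solitary)
  invisible(x)
}

#' Solitary-occupancy count for one key species
#'
#' @inheritParams richness_profile
#' @param taxon A key-species column name of `m`.
#' @return Number of colonies where `taxon` is present and no other key
#'   species is.
#' @export
solitary_count <- function(m, taxon) {
  m2 <- as_binary_matrix(m)
  if (!taxon %in% colnames(m2)) {
    stop("'", taxon, "' is not a key-species column of the matrix")
  }
  sum(m2[, taxon] == 1L & rowSums(m2) == 1L)
}

# combined extractor used under the nulls: richness profile, upper-triangle
# pairwise counts and solitary counts in one pass over the matrix
guild_statistics <- function(m) {
  r <- rowSums(m)
  s <- ncol(m)
  n_k <- tabulate(r + 1L, nbins = s + 1L)
  names(n_k) <- paste0("n_", 0:s)
  cc <- crossprod(m)
  ut <- which(upper.tri(cc))
  pair <- cc[ut]
  names(pair) <- outer(colnames(m), colnames(m),
                       function(a, b) paste0("c|", a, "|", b))[ut]
  sol <- vapply(seq_len(s), function(j) sum(m[, j] == 1L & r == 1L),
                numeric(1))
  names(sol) <- paste0("s|", colnames(m))
  c(n_k, pair, sol)
}

#' Guild analysis of one stratum against the community null models
#'
#' The decision procedure for non-random species association: for the
#' stratum's key-species incidence matrix, compares the richness profile
#' (`n_1 .. n_S`, and `n_0` as an informational row) against the M1 and M2
#' nulls, and all pairwise co-occurrence counts and solitary counts against
#' M1, M2 and M3, using percentile confidence intervals from `reps`
#' simulated communities per model. `n_0` is reported but the richness
#' family is judged on `k >= 1`; the richness profile is not compared
#' against M3, under which the whole profile is conserved by construction.
#'
#' @param x A `colony_set`.
#' @param region,site,stage,host_type Stratum selectors (see
#'   [select_stratum()]); the stratum must be non-empty.
#' @param taxa Key-species columns; defaults to `key_taxa(x$taxa)`.
#' @param models Null models to run, a subset of `c("M1","M2","M3")`.
#' @param reps,ci_level,seed,m1_variant Passed to [null_config()]; each
#'   model uses the same master seed so a report is reproducible end to end.
#' @return A data frame of class `guild_report` with columns `family`
#'   (`richness` / `pairwise` / `solitary`), `statistic_id`, `taxon_a`,
#'   `taxon_b`, `model`, `observed`, `null_mean`, `ci_lo`, `ci_hi`, `flag`,
#'   `n_hosts`, `reps`, `seed`; rows ordered by family, taxa, model.
#' @examples
#' \donttest{
#' rep_ri <- run_guild_analysis(coral_survey(), region = "RI",
#'                              stage = "adult", reps = 1000, seed = 42)
#' subset(rep_ri, family == "pairwise" & flag != "inside")
#' }
#' @export
run_guild_analysis <- function(x, region = NULL, site = NULL, stage = NULL,
                               host_type = NULL, taxa = NULL,
                               models = c("M1", "M2", "M3"),
                               reps = 10000L, ci_level = 0.95, seed = NULL,
                               m1_variant = "hypergeometric") {
  stratum <- select_stratum(x, region = region, site = site, stage = stage,
                            host_type = host_type)
  if (nrow(stratum$colonies) == 0) stop("stratum contains no colonies")
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(taxa)) taxa <- key_taxa(x$taxa)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  m <- to_incidence(stratum, taxa = taxa, drop_empty = FALSE)

  rows <- list()
  for (model in models) {
    cfg <- null_config(model, reps = reps, ci_level = ci_level, seed = seed,
                       m1_variant = m1_variant)
    nd <- simulate_null(m, cfg, list(guild = guild_statistics))
    df <- as.data.frame(nd)
    df$statistic_id <- sub("^guild\\.", "", df$statistic_id)
    fam <- ifelse(grepl("^n_", df$statistic_id), "richness",
                  ifelse(grepl("^c\\|", df$statistic_id), "pairwise",
                         "solitary"))
    parts <- strsplit(df$statistic_id, "|", fixed = TRUE)
    df$family <- fam
    df$taxon_a <- vapply(parts, function(p) {
      if (length(p) >= 2) p[2] else NA_character_
    }, character(1))
    df$taxon_b <- vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else NA_character_
    }, character(1))
    # richness vs M1/M2 only
    df <- df[!(fam == "richness" & model == "M3"), , drop = FALSE]
    rows[[model]] <- df
  }
  out <- do.call(rbind, rows)
  out$n_hosts <- nrow(m)
  fam_order <- c(richness = 1L, pairwise = 2L, solitary = 3L)
  out <- out[order(fam_order[out$family],
                   match(out$statistic_id, unique(out$statistic_id)),
                   match(out$model, c("M1", "M2", "M3"))), ]
  rownames(out) <- NULL
  out <- out[, c("family", "statistic_id", "taxon_a", "taxon_b", "model",
                 "observed", "null_mean", "ci_lo", "ci_hi", "flag",
                 "n_hosts", "reps", "seed")]
  class(out) <- c("guild_report", class(out))
  out
}
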