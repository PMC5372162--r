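#' Load colony and occupancy tables into a colony set
#'
#' Reads the two long-format CSV files describing a survey — one row per
#' coral colony (with stratum labels and optional size measurements) and one
#' row per (colony, taxon) occupancy record — and returns a validated
#' `colony_set`. Colonies absent from the occupancy table get empty
#' assemblages; input row order is preserved.
#'
#' @param colony_csv Path to a CSV with header
#'   `colony_id,region,site,stage,host_type,L_cm,l_cm` (sizes may be blank).
#' @param occupancy_csv Path to a CSV with header `colony_id,taxon_id,count`.
#' @param taxa Taxon table resolving `taxon_id`s; defaults to [guild_taxa()].
#' @return An object of class `colony_set`: a list with data frames
#'   `colonies`, `occupancy` and `taxa`.
#' @details Unknown taxon ids, duplicated colony ids, occupancy rows for
#'   unknown colonies and counts below 1 are hard errors naming the
#'   offending row. Size/stage inconsistencies (a juvenile recorded with
#'   diameter above 5 cm, an adult at or below 10 cm) raise warnings only,
#'   since sizes are optional.
#' @seealso [coral_survey()] for the packaged dataset, [select_stratum()],
#'   [to_incidence()].
#' @export
load_colony_tables <- function(colony_csv, occupancy_csv,
                               taxa = guild_taxa()) {
  validate_taxa(taxa)
  colonies <- utils::read.csv(colony_csv, stringsAsFactors = FALSE,
                              colClasses = "character")
  occupancy <- utils::read.csv(occupancy_csv, stringsAsFactors = FALSE)
  need <- c("colony_id", "region", "site", "stage", "host_type",
            "L_cm", "l_cm")
  if (!all(need %in% names(colonies))) {
    stop("colony table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("colony_id", "taxon_id", "count") %in% names(occupancy))) {
    stop("occupancy table must have columns: colony_id, taxon_id, count")
  }
  colonies$L_cm <- suppressWarnings(as.numeric(colonies$L_cm))
  colonies$l_cm <- suppressWarnings(as.numeric(colonies$l_cm))
  if (nrow(occupancy) == 0) {
    occupancy <- data.frame(colony_id = character(), taxon_id = character(),
                            count = integer(), stringsAsFactors = FALSE)
  }
  occupancy$count <- as.integer(occupancy$count)
  new_colony_set(colonies, occupancy, taxa)
}

new_colony_set <- function(colonies, occupancy, taxa) {
  if (anyDuplicated(colonies$colony_id)) {
    stop("duplicate colony_id: ",
         paste(unique(colonies$colony_id[duplicated(colonies$colony_id)]),
               collapse = ", "))
  }
  bad_lvl <- function(col, levels) {
    v <- colonies[[col]]
    if (length(v) && !all(v %in% levels)) {
      stop(col, " must be one of {", paste(levels, collapse = ", "),
           "}; offending colony: ",
           colonies$colony_id[which(!v %in% levels)[1]])
    }
  }
  bad_lvl("region", .regions); bad_lvl("site", .sites)
  bad_lvl("stage", .stages);   bad_lvl("host_type", .host_types)
  if (nrow(occupancy)) {
    unk_t <- which(!occupancy$taxon_id %in% taxa$taxon_id)
    if (length(unk_t)) {
      stop("unknown taxon_id '", occupancy$taxon_id[unk_t[1]],
           "' in occupancy row ", unk_t[1])
    }
    unk_c <- which(!occupancy$colony_id %in% colonies$colony_id)
    if (length(unk_c)) {
      stop("occupancy row ", unk_c[1], " refers to unknown colony_id '",
           occupancy$colony_id[unk_c[1]], "'")
    }
    low <- which(is.na(occupancy$count) | occupancy$count < 1L)
    if (length(low)) {
      stop("count must be >= 1; offending occupancy row ", low[1])
    }
    if (anyDuplicated(occupancy[c("colony_id", "taxon_id")])) {
      stop("duplicated (colony_id, taxon_id) pair in occupancy table")
    }
  }
  # size/stage plausibility: warnings only, sizes are optional
  d <- colonies$L_cm
  juv_big <- !is.na(d) & colonies$stage == "juvenile" & d > 5
  ad_small <- !is.na(d) & colonies$stage == "adult" & d <= 10
  if (any(juv_big)) {
    warning("juvenile colonies with diameter > 5 cm: ",
            paste(colonies$colony_id[juv_big], collapse = ", "))
  }
  if (any(ad_small)) {
    warning("adult colonies with diameter <= 10 cm: ",
            paste(colonies$colony_id[ad_small], collapse = ", "))
  }
  structure(list(colonies = colonies, occupancy = occupancy, taxa = taxa),
            class = "colony_set")
}

#' Write a colony set back to CSV files
#'
#' Inverse of [load_colony_tables()]: writes the colony and occupancy tables
#' in canonical order (colonies in stored order; occupancy ordered by colony
#' then by taxon-set order), so that a load/write round trip is
#' cell-identical.
#'
#' @param x A `colony_set`.
#' @param colony_csv,occupancy_csv Output paths.
#' @return Invisibly, `x`.
#' @export
write_colony_tables <- function(x, colony_csv, occupancy_csv) {
  stopifnot(inherits(x, "colony_set"))
  col <- x$colonies
  col$L_cm <- ifelse(is.na(col$L_cm), "", format(col$L_cm, trim = TRUE))
  col$l_cm <- ifelse(is.na(col$l_cm), "", format(col$l_cm, trim = TRUE))
  occ <- x$occupancy
  occ <- occ[order(match(occ$colony_id, x$colonies$colony_id),
                   match(occ$taxon_id, x$taxa$taxon_id)), ]
  utils::write.csv(col, colony_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(occ, occupancy_csv, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @export
print.colony_set <- function(x, ...) {
  cat("<colony_set> ", nrow(x$colonies), " colonies, ",
      nrow(x$occupancy), " occupancy records, ",
      nrow(x$taxa), " taxa (", sum(x$taxa$is_key), " key)\n", sep = "")
  tab <- table(region = x$colonies$region, stage = x$colonies$stage,
               host_type = x$colonies$host_type)
  print(tab)
  invisible(x)
}

#' Planar area of a coral colony from its diameters
#'
#' Estimates the planar area of a colony as the area of the ellipse with
#' major axis `L` (maximum diameter) and minor axis `l` (maximum
#' perpendicular diameter): `pi * L/2 * l/2`.
#'
#' @param L Maximum diameter, cm.
#' @param l Maximum perpendicular diameter, cm; must not exceed `L`.
#' @return Planar area in cm^2 (vectorised).
#' @examples
#' planar_area(30, 20)   # 471.2389 cm^2
#' @export
planar_area <- function(L, l) {
  if (any(is.na(L) | is.na(l))) stop("L and l must be non-missing")
  if (any(L < 0 | l < 0)) stop("diameters must be non-negative")
  if (any(l > L)) {
    stop("perpendicular diameter l cannot exceed maximum diameter L")
  }
  pi * L * l / 4
}

#' Select a stratum of colonies
#'
#' Filters a colony set by any combination of region, site, stage and host
#' type. Omitted selectors match everything; an empty result is allowed.
#'
#' @param x A `colony_set`.
#' @param region `"RI"` or `"NC"`.
#' @param site `"LI"` or `"HI"`.
#' @param stage `"adult"` or `"juvenile"`.
#' @param host_type `"alpha"` or `"beta"`.
#' @return A `colony_set` restricted to the matching colonies (occupancy
#'   rows of dropped colonies removed).
#' @examples
#' nrow(select_stratum(coral_survey(), region = "RI", stage = "adult")$colonies)
#' @export
select_stratum <- function(x, region = NULL, site = NULL, stage = NULL,
                           host_type = NULL) {
  stopifnot(inherits(x, "colony_set"))
  chk <- function(v, levels, name) {
    if (!is.null(v) && !all(v %in% levels)) {
      stop(name, " must be in {", paste(levels, collapse = ", "), "}")
    }
  }
  chk(region, .regions, "region"); chk(site, .sites, "site")
  chk(stage, .stages, "stage");    chk(host_type, .host_types, "host_type")
  keep <- rep(TRUE, nrow(x$colonies))
  if (!is.null(region))    keep <- keep & x$colonies$region %in% region
  if (!is.null(site))      keep <- keep & x$colonies$site %in% site
  if (!is.null(stage))     keep <- keep & x$colonies$stage %in% stage
  if (!is.null(host_type)) keep <- keep & x$colonies$host_type %in% host_type
  colonies <- x$colonies[keep, , drop = FALSE]
  occupancy <- x$occupancy[x$occupancy$colony_id %in% colonies$colony_id, ,
                           drop = FALSE]
  rownames(colonies) <- NULL; rownames(occupancy) <- NULL
  structure(list(colonies = colonies, occupancy = occupancy, taxa = x$taxa),
            class = "colony_set")
}

#' Build a colonies-by-taxa incidence matrix
#'
#' Converts a colony set into a binary incidence matrix over a chosen taxon
#' subset, with the individual-count abundance matrix attached as an
#' attribute. Row order follows the colony table; column order follows the
#' taxon-set declaration order.
#'
#' @param x A `colony_set`.
#' @param taxa Character vector of `taxon_id`s to use as columns; defaults
#'   to all taxa in the set. Use `key_taxa()` for the five key species.
#' @param drop_empty If `TRUE`, rows that are all-zero over the chosen taxa
#'   are removed (the ordination convention); if `FALSE` (default, the
#'   null-model convention) every colony keeps a row.
#' @return An integer matrix of 0/1 with `dimnames` (colony ids, taxon ids),
#'   of class `incidence_matrix`, with attribute `"abundance"` holding the
#'   count matrix (`incidence == (abundance > 0)`).
#' @export
to_incidence <- function(x, taxa = NULL, drop_empty = FALSE) {
  stopifnot(inherits(x, "colony_set"))
  if (is.null(taxa)) taxa <- x$taxa$taxon_id
  if (length(taxa) == 0) stop("taxa must be non-empty")
  if (!all(taxa %in% x$taxa$taxon_id)) {
    stop("unknown taxon_id: ",
         paste(setdiff(taxa, x$taxa$taxon_id), collapse = ", "))
  }
  taxa <- x$taxa$taxon_id[x$taxa$taxon_id %in% taxa]  # declaration order
  ids <- x$colonies$colony_id
  ab <- matrix(0L, nrow = length(ids), ncol = length(taxa),
               dimnames = list(ids, taxa))
  occ <- x$occupancy[x$occupancy$taxon_id %in% taxa, , drop = FALSE]
  if (nrow(occ)) {
    ab[cbind(match(occ$colony_id, ids), match(occ$taxon_id, taxa))] <-
      as.integer(occ$count)
  }
  if (drop_empty) ab <- ab[rowSums(ab) > 0, , drop = FALSE]
  m <- ab
  m[m > 0L] <- 1L
  structure(m, abundance = ab, class = c("incidence_matrix", class(m)))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", nrow(x), " colonies x ", ncol(x),
      " taxa, ", sum(x), " presences\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Abundance matrix attached to an incidence matrix
#'
#' @param m An `incidence_matrix` from [to_incidence()].
#' @return The integer count matrix with the same dimnames.
#' @export
abundance <- function(m) {
  a <- attr(m, "abundance")
  if (is.null(a)) stop("no abundance attribute on this matrix")
  a
}

# strip class/attributes for internal numeric work
as_binary_matrix <- function(m) {
  m <- unclass(m)
  attr(m, "abundance") <- NULL
  storage.mode(m) <- "integer"
  if (length(m) && !all(m %in% c(0L, 1L))) stop("matrix must be binary 0/1")
  m
}
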