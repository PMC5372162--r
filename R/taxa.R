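#' The default exosymbiont taxon set
#'
#' Returns the reference table of the 13 exosymbiont taxa recognised in the
#' packaged survey: ten *Trapezia* species/lineages, the two cryptic
#' *Alpheus lottini* lineages (L1, L2), and an "unresolved" *A. lottini*
#' placeholder used where shrimp individuals could not be assigned to a
#' lineage. Five taxa are flagged as key species: the taxa that drive guild
#' structure (`AlotL1`, `AlotL2`, `Tgut`, `Tsept`, `Tspe`).
#'
#' @return A data frame with columns `taxon_id`, `genus`, `label`, `is_key`.
#' @examples
#' guild_taxa()
#' @export
guild_taxa <- function() {
  path <- system.file("extdata", "taxa.csv", package = "coralguild",
                      mustWork = TRUE)
  tx <- utils::read.csv(path, stringsAsFactors = FALSE)
  tx$is_key <- as.logical(tx$is_key)
  validate_taxa(tx)
  tx
}

#' Identifiers of the five key exosymbiont species
#'
#' @param taxa A taxon table as returned by [guild_taxa()].
#' @return Character vector of the key `taxon_id`s, in taxon-set order.
#' @examples
#' key_taxa()
#' @export
key_taxa <- function(taxa = guild_taxa()) {
  taxa$taxon_id[taxa$is_key]
}

validate_taxa <- function(taxa) {
  need <- c("taxon_id", "genus", "label", "is_key")
  if (!all(need %in% names(taxa))) {
    stop("taxon table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(taxa$taxon_id)) {
    stop("duplicate taxon_id in taxon table: ",
         paste(unique(taxa$taxon_id[duplicated(taxa$taxon_id)]),
               collapse = ", "))
  }
  invisible(taxa)
}

# enumerations shared by validation and stratum selection
.regions    <- c("RI", "NC")
.sites      <- c("LI", "HI")
.stages     <- c("adult", "juvenile")
.host_types <- c("alpha", "beta")
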