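#' Read an aligned FASTA file
#'
#' Loads an alignment of nucleotide sequences (e.g. a COI or 16S alignment
#' produced by an external aligner) as a set of equal-length upper-case
#' character strings over the alphabet `A C G T - N`.
#'
#' @param path FASTA file of aligned sequences.
#' @return Named character vector of sequences.
#' @export
read_aligned_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(bin), paste, character(1),
                         collapse = ""))
  validate_alignment(seqs)
}

validate_alignment <- function(seqs) {
  seqs <- toupper(seqs)
  if (length(seqs) == 0) stop("empty alignment")
  len <- nchar(seqs)
  if (length(unique(len)) != 1) {
    stop("sequences are not aligned: lengths ",
         paste(unique(len), collapse = ", "))
  }
  ok <- grepl("^[ACGTN-]*$", seqs)
  if (!all(ok)) {
    stop("alignment uses characters outside {A,C,G,T,-,N}: sequence ",
         names(seqs)[!ok][1])
  }
  seqs
}

seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among the comparable sites, with
#' pairwise deletion: any site with a gap (`-`) or `N` in either sequence
#' is excluded from the comparison.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return Fraction of differing comparable sites.
#' @examples
#' p_distance("AAC-G", "AACTG")  # 0: the gapped site is excluded
#' @export
p_distance <- function(a, b) {
  x <- seq_chars(a)
  y <- seq_chars(b)
  if (length(x) != length(y)) stop("sequences must have equal length")
  use <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(use)) stop("no comparable sites (all gapped or ambiguous)")
  mean(x[use] != y[use])
}

jc69 <- function(p) {
  if (any(p >= 0.75)) {
    stop("p-distance >= 0.75: Jukes-Cantor correction undefined")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' All pairwise p-distances of an alignment
#'
#' @param seqs Named character vector of aligned sequences.
#' @param correction `"none"` for raw p-distances (default) or `"jc69"` for
#'   Jukes-Cantor corrected distances.
#' @return A `dist` object.
#' @export
pairwise_p_distance <- function(seqs, correction = c("none", "jc69")) {
  correction <- match.arg(correction)
  seqs <- validate_alignment(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- p_distance(seqs[i], seqs[j])
      }
    }
  }
  if (correction == "jc69") d[] <- ifelse(d == 0, 0, jc69(pmin(d, 0.749999)))
  stats::as.dist(d)
}

mean_pairwise <- function(dm, ids_a, ids_b = NULL) {
  if (is.null(ids_b)) {           # within-group mean
    if (length(ids_a) < 2) return(structure(0, degenerate = TRUE))
    mean(dm[ids_a, ids_a][upper.tri(diag(length(ids_a)))])
  } else {
    mean(dm[ids_a, ids_b, drop = FALSE])
  }
}

#' Net nucleotide divergence between two groups of sequences
#'
#' Nei's net divergence `Da = d_XY - (d_X + d_Y) / 2`, where `d_XY` is the
#' mean pairwise distance between groups and `d_X`, `d_Y` the mean pairwise
#' distances within each group. Distances are uncorrected p-distances with
#' pairwise deletion by default; a Jukes-Cantor corrected variant is
#' available. A group with a single sequence has within-group distance 0 by
#' convention; this is flagged in the result.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param groups Mapping of sequence id to group label: a named character
#'   vector (names = sequence ids) or a data frame with columns `seq_id`
#'   and `group`.
#' @param group_x,group_y The two group labels to compare.
#' @param correction `"none"` or `"jc69"`.
#' @return A list of class `divergence_result`: `da`, `d_between`,
#'   `d_within_x`, `d_within_y`, group sizes, and
#'   `within_degenerate` (TRUE if either group had fewer than 2 sequences).
#' @examples
#' seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "TAAA", b2 = "TAAA")
#' grp <- c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y")
#' net_divergence(seqs, grp, "X", "Y")$da  # 0.25
#' @export
net_divergence <- function(seqs, groups, group_x, group_y,
                           correction = c("none", "jc69")) {
  correction <- match.arg(correction)
  seqs <- validate_alignment(seqs)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$seq_id))
  }
  if (is.null(names(groups))) stop("groups must be named by sequence id")
  for (g in c(group_x, group_y)) {
    if (!g %in% groups) stop("unknown group label '", g, "'")
  }
  ids_x <- names(groups)[groups == group_x]
  ids_y <- names(groups)[groups == group_y]
  missing <- setdiff(c(ids_x, ids_y), names(seqs))
  if (length(missing)) {
    stop("group members absent from alignment: ",
         paste(missing, collapse = ", "))
  }
  dm <- as.matrix(pairwise_p_distance(seqs, correction = correction))
  d_between <- mean_pairwise(dm, ids_x, ids_y)
  d_x <- mean_pairwise(dm, ids_x)
  d_y <- mean_pairwise(dm, ids_y)
  degenerate <- isTRUE(attr(d_x, "degenerate")) ||
    isTRUE(attr(d_y, "degenerate"))
  structure(list(da = d_between - (as.numeric(d_x) + as.numeric(d_y)) / 2,
                 d_between = d_between,
                 d_within_x = as.numeric(d_x), d_within_y = as.numeric(d_y),
                 n_x = length(ids_x), n_y = length(ids_y),
                 group_x = group_x, group_y = group_y,
                 correction = correction,
                 within_degenerate = degenerate),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("<divergence_result> ", x$group_x, " (n=", x$n_x, ") vs ",
      x$group_y, " (n=", x$n_y, "): Da = ",
      sprintf("%.4f", x$da), " (between ", sprintf("%.4f", x$d_between),
      ", within ", sprintf("%.4f", x$d_within_x), "/",
      sprintf("%.4f", x$d_within_y), ", ", x$correction, ")\n", sep = "")
  if (x$within_degenerate) {
    cat("note: a group has < 2 sequences; its within-group distance is 0 ",
        "by convention\n", sep = "")
  }
  invisible(x)
}
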