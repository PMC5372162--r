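#' Correspondence analysis of a community table
#'
#' Classical (chi-square distance) correspondence analysis of a
#' non-negative colony-by-taxon table. The correspondence matrix
#' `P = table / n` is centred by its row and column masses and standardised,
#' `S = Dr^{-1/2} (P - r c') Dc^{-1/2}`; the singular value decomposition of
#' `S` gives the principal axes. Principal inertias are the squared singular
#' values; their sum (the total inertia) equals the Pearson chi-square
#' statistic of the table divided by its grand total.
#'
#' @param tab Non-negative numeric matrix (counts or presences). Colonies
#'   with no observations carry no chi-square information, so empty rows
#'   (and empty columns) are removed when `drop_empty = TRUE` (default).
#' @param drop_empty Drop all-zero rows and columns before the analysis.
#' @return A list of class `ca_result`: `row_coords` and `col_coords`
#'   (principal coordinates), `inertia` (per axis, non-increasing),
#'   `inertia_pct`, `total_inertia`, and the retained `row_names` /
#'   `col_names`.
#' @examples
#' res <- correspondence_analysis(rbind(c(10, 0), c(0, 10)))
#' res$total_inertia   # 1: perfect association
#' res$inertia_pct     # axis 1 carries 100%
#' @export
correspondence_analysis <- function(tab, drop_empty = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("table must be non-negative")
  if (drop_empty) {
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate table: need at least 2 non-empty rows and 2 non-empty ",
         "columns after dropping")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: empty row or column (use drop_empty = TRUE)")
  }
  n <- sum(tab)
  p <- tab / n
  r <- rowSums(p)
  cm <- colSums(p)
  s <- (p - outer(r, cm)) / sqrt(outer(r, cm))
  dec <- svd(s)
  k <- min(nrow(tab), ncol(tab)) - 1L
  d <- dec$d[seq_len(k)]
  inertia <- d^2
  total <- sum(dec$d^2)
  if (total <= .Machine$double.eps) {
    # independence: rank-1 table, zero inertia on every axis
    inertia_pct <- rep(0, k)
  } else {
    inertia_pct <- 100 * inertia / total
  }
  row_coords <- (dec$u[, seq_len(k), drop = FALSE] / sqrt(r)) *
    rep(d, each = nrow(tab))
  col_coords <- (dec$v[, seq_len(k), drop = FALSE] / sqrt(cm)) *
    rep(d, each = ncol(tab))
  dimnames(row_coords) <- list(rownames(tab), paste0("Axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(tab), paste0("Axis", seq_len(k)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = inertia, inertia_pct = inertia_pct,
                 total_inertia = total,
                 row_names = rownames(tab), col_names = colnames(tab)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("<ca_result> ", length(x$row_names), " rows x ", length(x$col_names),
      " columns, total inertia ", format(x$total_inertia, digits = 5),
      "\n", sep = "")
  k <- min(4L, length(x$inertia))
  cat("axis inertia (%):",
      paste(sprintf("%.1f", x$inertia_pct[seq_len(k)]), collapse = " / "),
      "\n")
  invisible(x)
}

#' Pairwise dissimilarities between community rows
#'
#' @param tab Non-negative community table with strictly positive row
#'   totals (drop empty colonies first).
#' @param metric `"bray_curtis"` (counts; computed with
#'   [vegan::vegdist()]) or `"chi_square"` (distance between row profiles
#'   weighted by inverse column mass — the distance underlying
#'   correspondence analysis).
#' @return A `dist` object (zero diagonal, symmetric).
#' @export
community_dissimilarity <- function(tab,
                                    metric = c("bray_curtis", "chi_square")) {
  metric <- match.arg(metric)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("table must be non-negative")
  if (any(rowSums(tab) == 0)) {
    stop("all-zero row in table: drop empty colonies before computing ",
         "dissimilarities")
  }
  if (metric == "bray_curtis") {
    return(vegan::vegdist(tab, method = "bray"))
  }
  n <- sum(tab)
  prof <- tab / rowSums(tab)
  cmass <- colSums(tab) / n
  stats::dist(prof %*% diag(1 / sqrt(cmass), ncol(tab)))
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of compositional difference between
#' predefined groups. With midranks of the pairwise dissimilarities,
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` where
#' `M = n(n-1)/2` is the number of pairs, so `R` lies in `[-1, 1]` and
#' equals 1 under complete separation. The p-value is
#' `(1 + #\{permuted R >= observed R\}) / (1 + n_perm)` under random
#' relabelling of the samples, so it is never 0.
#'
#' @param dissim A `dist` object or square symmetric dissimilarity matrix
#'   with zero diagonal.
#' @param groups Group labels, one per sample; at least 2 groups with at
#'   least 2 members each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list of class `anosim_result`: `R`, `p`, `n_perm`, `seed`,
#'   and `perm_R` (the permuted statistics).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rpois(20, 5), 4), matrix(rpois(20, 20), 4))
#' d <- community_dissimilarity(x)
#' anosim(d, rep(c("a", "b"), each = 4), n_perm = 199, seed = 7)
#' @export
anosim <- function(dissim, groups, n_perm = 999L, seed = NULL) {
  if (inherits(dissim, "dist")) {
    dm <- as.matrix(dissim)
  } else {
    dm <- as.matrix(dissim)
    if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-12)) {
      stop("dissimilarity matrix must be square and symmetric")
    }
    if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  }
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("every group needs at least 2 members; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ij <- which(upper.tri(dm), arr.ind = TRUE)
  rk <- rank(dm[upper.tri(dm)])  # midranks for ties
  m <- length(rk)
  stat <- function(g) {
    within <- g[ij[, 1]] == g[ij[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (m / 2)
  }
  r_obs <- stat(groups)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm_R <- vapply(seq_len(n_perm), function(i) stat(sample(groups)),
                   numeric(1))
  p <- (1 + sum(perm_R >= r_obs)) / (1 + n_perm)
  structure(list(R = r_obs, p = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("<anosim_result> R = ", format(x$R, digits = 4),
      ", p = ", format(x$p, digits = 4),
      " (", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
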