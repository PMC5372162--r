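# Independent oracles used across the suite: exhaustive enumeration of the
# admissible sets of the three null models, naive loop-based guild
# statistics, and exhaustive ANOSIM permutation distributions.

matrix_key <- function(m) paste(as.integer(m), collapse = "")

# all binary N x S matrices with exactly f ones (M1's admissible set)
enum_total <- function(n, s, f) {
  cells <- utils::combn(n * s, f)
  apply(cells, 2, function(idx) {
    m <- matrix(0L, n, s)
    m[idx] <- 1L
    matrix_key(m)
  })
}

# all binary matrices with the given column sums (M2's admissible set)
enum_colsums <- function(n, colsums) {
  per_col <- lapply(colsums, function(f) {
    if (f == 0) return(list(integer(0)))
    asplit(utils::combn(n, f), 2)
  })
  grids <- do.call(expand.grid, lapply(per_col, seq_along))
  apply(grids, 1, function(sel) {
    m <- matrix(0L, n, length(colsums))
    for (s in seq_along(colsums)) m[per_col[[s]][[sel[s]]], s] <- 1L
    matrix_key(m)
  })
}

# all binary matrices with the given row sums (M3's admissible set)
enum_rowsums <- function(s, rowsums) {
  per_row <- lapply(rowsums, function(r) {
    if (r == 0) return(list(integer(0)))
    asplit(utils::combn(s, r), 2)
  })
  grids <- do.call(expand.grid, lapply(per_row, seq_along))
  apply(grids, 1, function(sel) {
    m <- matrix(0L, length(rowsums), s)
    for (i in seq_along(rowsums)) m[i, per_row[[i]][[sel[i]]]] <- 1L
    matrix_key(m)
  })
}

# chi-square goodness of fit of draws from `draw_fn` against the uniform
# distribution over `keys`; returns the p-value
uniformity_p <- function(draw_fn, keys, n_draws, seed = 1) {
  set.seed(seed)
  drawn <- replicate(n_draws, matrix_key(draw_fn()))
  stopifnot(all(drawn %in% keys))  # never leaves the admissible set
  counts <- table(factor(drawn, levels = keys))
  stats::chisq.test(counts, p = rep(1 / length(keys), length(keys)))$p.value
}

# naive per-row / per-pair guild statistics
oracle_richness <- function(m) {
  k <- vapply(seq_len(nrow(m)), function(i) sum(m[i, ]), integer(1))
  vapply(0:ncol(m), function(j) sum(k == j), integer(1))
}
oracle_cooccurrence <- function(m, i, j) {
  sum(vapply(seq_len(nrow(m)), function(r) {
    m[r, i] == 1L && m[r, j] == 1L
  }, logical(1)))
}
oracle_solitary <- function(m, j) {
  sum(vapply(seq_len(nrow(m)), function(r) {
    m[r, j] == 1L && sum(m[r, ]) == 1L
  }, logical(1)))
}

# ANOSIM R by direct definition (midranks, divisor M/2)
oracle_anosim_R <- function(dm, groups) {
  n <- nrow(dm)
  rk <- rank(dm[upper.tri(dm)])
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  within <- groups[idx[, 1]] == groups[idx[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
}

# exhaustive permutation distribution of R for a 2-group labelling
oracle_anosim_exact <- function(dm, groups) {
  n <- nrow(dm)
  g <- unique(groups)
  stopifnot(length(g) == 2)
  nx <- sum(groups == g[1])
  picks <- utils::combn(n, nx)
  apply(picks, 2, function(ix) {
    lab <- rep(g[2], n)
    lab[ix] <- g[1]
    oracle_anosim_R(dm, lab)
  })
}

# naive mean pairwise p-distance oracles
oracle_p_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  nt <- c("A", "C", "G", "T")
  num <- den <- 0
  for (i in seq_along(x)) {
    if (x[i] %in% nt && y[i] %in% nt) {
      den <- den + 1
      if (x[i] != y[i]) num <- num + 1
    }
  }
  num / den
}
oracle_net_divergence <- function(seqs, groups, gx, gy) {
  ids_x <- names(groups)[groups == gx]
  ids_y <- names(groups)[groups == gy]
  pairs_mean <- function(ids_a, ids_b) {
    vals <- c()
    for (a in ids_a) for (b in ids_b) {
      vals <- c(vals, oracle_p_distance(seqs[[a]], seqs[[b]]))
    }
    mean(vals)
  }
  within_mean <- function(ids) {
    if (length(ids) < 2) return(0)
    vals <- c()
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in seq(i + 1, length(ids))) {
        vals <- c(vals, oracle_p_distance(seqs[[ids[i]]], seqs[[ids[j]]]))
      }
    }
    mean(vals)
  }
  pairs_mean(ids_x, ids_y) - (within_mean(ids_x) + within_mean(ids_y)) / 2
}

# random small binary matrix for property tests
random_binary_matrix <- function(n, s, p = 0.4) {
  matrix(rbinom(n * s, 1L, p), n, s,
         dimnames = list(paste0("c", seq_len(n)), paste0("t", seq_len(s))))
}

# tiny two-colony survey written to temp CSVs
write_mini_tables <- function(dir = tempfile("mini")) {
  dir.create(dir, showWarnings = FALSE)
  colony_csv <- file.path(dir, "colonies.csv")
  occupancy_csv <- file.path(dir, "occupancy.csv")
  writeLines(c("colony_id,region,site,stage,host_type,L_cm,l_cm",
               "c1,RI,LI,adult,beta,30,20",
               "c2,RI,LI,adult,beta,,"), colony_csv)
  writeLines(c("colony_id,taxon_id,count",
               "c1,Tgut,2"), occupancy_csv)
  list(colonies = colony_csv, occupancy = occupancy_csv)
}
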