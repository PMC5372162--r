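test_that("degenerate matrices are fixed points of every randomizer", {
  ones <- matrix(1L, 3, 4)
  zeros <- matrix(0L, 3, 4)
  set.seed(1)
  expect_equal(randomize_m1(ones), ones)
  expect_equal(randomize_m1(zeros), zeros)
  expect_equal(randomize_m2(ones), ones)
  expect_equal(randomize_m3(ones), ones)
  # full column unchanged under M2, full row unchanged under M3
  m <- cbind(c(1L, 1L, 1L), c(0L, 1L, 0L))
  expect_equal(randomize_m2(m)[, 1], c(1L, 1L, 1L))
  m2 <- rbind(rep(1L, 4), c(1L, 0L, 0L, 0L))
  expect_equal(randomize_m3(m2)[1, ], rep(1L, 4))
})

test_that("randomizers conserve their defining margins on every draw", {
  m <- to_incidence(select_stratum(coral_survey(), region = "RI",
                                   stage = "adult"), key_taxa())
  f <- sum(m)
  cs <- colSums(m)
  rs <- rowSums(m)
  set.seed(99)
  for (i in seq_len(1000)) {
    expect_identical(sum(randomize_m1(m)), f)
    expect_identical(colSums(randomize_m2(m)), cs)
    expect_identical(rowSums(randomize_m3(m)), rs)
  }
})

test_that("each randomizer is uniform over its admissible set", {
  # M1: 2x2 with one presence — each placement 1/4
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  p <- uniformity_p(function() randomize_m1(m), enum_total(2, 2, 1),
                    4000, seed = 11)
  expect_gt(p, 0.001)
  # M2: identity pattern, column sums (1, 1) — 4 outcomes
  m <- diag(2); storage.mode(m) <- "integer"
  p <- uniformity_p(function() randomize_m2(m), enum_colsums(2, c(1, 1)),
                    4000, seed = 12)
  expect_gt(p, 0.001)
  # M3: single row, 2 of 5 species — C(5,2) = 10 outcomes
  m <- matrix(c(1L, 1L, 0L, 0L, 0L), 1, 5)
  p <- uniformity_p(function() randomize_m3(m), enum_rowsums(5, 2),
                    2000, seed = 13)
  expect_gt(p, 0.001)
})

test_that("the enumeration oracle agrees with an independent randomizer", {
  skip_if_not_installed("picante")
  # picante's frequency model shares M2's admissible set and uniformity
  m <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2)  # column sums 2, 2
  keys <- enum_colsums(3, c(2, 2))
  p <- uniformity_p(function() {
    picante::randomizeMatrix(m, null.model = "frequency")
  }, keys, 1800, seed = 5)
  expect_gt(p, 0.001)
})

test_that("binomial M1 variant conserves margins only in expectation", {
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  set.seed(3)
  totals <- replicate(2000, sum(randomize_m1(m, variant = "binomial")))
  expect_equal(mean(totals), 1, tolerance = 0.1)   # E[F'] = F
  expect_gt(stats::var(totals), 0)                 # not conditioned on F
})

test_that("percentile CI uses attained type-1 quantiles", {
  expect_equal(percentile_ci(1:100, 0.95), c(lo = 3, hi = 98))
  # by-hand inverse-ECDF oracle on random integer samples
  set.seed(42)
  x <- sample.int(50, 301, replace = TRUE)
  for (lvl in c(0.5, 0.9, 0.95, 0.99)) {
    a <- (1 - lvl) / 2
    xs <- sort(x)
    oracle <- c(lo = xs[max(1, ceiling(length(x) * a))],
                hi = xs[max(1, ceiling(length(x) * (1 - a)))])
    expect_equal(percentile_ci(x, lvl), oracle)
  }
  expect_equal(percentile_ci(rep(7, 10), 0.95), c(lo = 7, hi = 7))
  expect_equal(percentile_ci(1:100, 1), c(lo = 1, hi = 100))
  expect_error(percentile_ci(numeric(0)), "non-empty")
})

test_that("simulate_null flags observations against the null CI", {
  m <- to_incidence(select_stratum(coral_survey(), region = "RI",
                                   stage = "adult"), key_taxa())
  stats_fns <- list(
    n_single = function(x) sum(rowSums(x) == 1),
    pair = function(x) c(tg_al = sum(x[, "Tgut"] * x[, "AlotL1"]))
  )
  nd <- simulate_null(m, null_config("M2", reps = 400, seed = 21),
                      stats_fns)
  expect_equal(unname(nd$observed["n_single"]), 37)
  expect_equal(unname(nd$observed["pair.tg_al"]), 15)
  expect_true(all(nd$ci_lo <= nd$ci_hi))
  expect_true(all(nd$flag %in% c("below", "inside", "above")))
  # flag definition: below iff observed < lo, above iff observed > hi
  with_flags <- as.data.frame(nd)
  expect_equal(with_flags$flag,
               ifelse(with_flags$observed < with_flags$ci_lo, "below",
                      ifelse(with_flags$observed > with_flags$ci_hi,
                             "above", "inside")))
  # reps = 1: CI collapses to the single draw
  nd1 <- simulate_null(m, null_config("M2", reps = 1, seed = 5),
                       list(n1 = function(x) sum(rowSums(x) == 1)))
  expect_equal(unname(nd1$ci_lo), unname(nd1$samples[1, 1]))
  expect_equal(unname(nd1$ci_hi), unname(nd1$samples[1, 1]))
})

test_that("identical seed and config give bit-identical null samples", {
  m <- to_incidence(select_stratum(coral_survey(), region = "NC",
                                   stage = "adult", host_type = "alpha"),
                    key_taxa())
  fns <- list(g = function(x) c(n1 = sum(rowSums(x) == 1),
                                f1 = sum(x[, 1])))
  for (model in c("M1", "M2", "M3")) {
    a <- simulate_null(m, null_config(model, reps = 150, seed = 77), fns)
    b <- simulate_null(m, null_config(model, reps = 150, seed = 77), fns)
    expect_identical(a$samples, b$samples)
    c <- simulate_null(m, null_config(model, reps = 150, seed = 78), fns)
    expect_false(identical(a$samples, c$samples))
  }
})

test_that("config validation catches bad inputs", {
  expect_error(null_config("M4"), "arg")
  expect_error(null_config("M1", reps = 0), "reps")
  expect_error(null_config("M1", ci_level = 1), "ci_level")
  expect_error(simulate_null(matrix(0, 2, 2), null_config("M1"),
                             list(function(x) 1)),
               "named list")
})
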