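#' Configuration for a null-model run
#'
#' @param model One of `"M1"` (unconstrained), `"M2"` (species-frequency
#'   constrained) or `"M3"` (per-colony-richness constrained).
#' @param reps Number of random communities to simulate (default 10000).
#' @param ci_level Two-sided confidence level for the percentile interval
#'   (default 0.95).
#' @param seed Integer master seed. If `NULL`, one is drawn from R's
#'   session RNG and recorded in the configuration so the run can be
#'   repeated.
#' @param m1_variant How the unconstrained model places presences:
#'   `"hypergeometric"` (default) scatters the observed grand total of
#'   presences uniformly over the cells without replacement;
#'   `"binomial"` fills each cell independently with probability
#'   `F / (N * S)`.
#' @return A list of class `null_config`.
#' @seealso [simulate_null()]
#' @export
null_config <- function(model = c("M1", "M2", "M3"), reps = 10000L,
                        ci_level = 0.95, seed = NULL,
                        m1_variant = c("hypergeometric", "binomial")) {
  model <- match.arg(model)
  m1_variant <- match.arg(m1_variant)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(model = model, reps = reps, ci_level = ci_level,
                 seed = as.integer(seed), m1_variant = m1_variant),
            class = "null_config")
}

#' Null-model randomizations of a binary occupancy matrix
#'
#' One draw from each of the three community null models used to judge
#' non-random species association:
#' * `randomize_m1()` — unconstrained: the grand total `F` of presences is
#'   placed uniformly at random over the `N x S` cells (without
#'   replacement), so every species can occupy every colony with equal
#'   chance; only `F` is conserved. The `"binomial"` variant instead fills
#'   each cell independently with probability `F/(N*S)`.
#' * `randomize_m2()` — frequency-constrained: each species keeps its total
#'   number of occurrences; its presences are reassigned to a uniform
#'   random subset of colonies. Column sums are conserved exactly, row
#'   sums are free.
#' * `randomize_m3()` — richness-constrained: each colony keeps its number
#'   of species; its presences are reassigned to a uniform random subset
#'   of species. Row sums are conserved exactly, column sums are free.
#'
#' Draws consume R's session RNG; call `set.seed()` (or use
#' [simulate_null()], which manages seeding) for reproducibility.
#'
#' @param m A binary matrix (0/1), e.g. from [to_incidence()].
#' @param variant See `m1_variant` in [null_config()].
#' @return A binary integer matrix of the same dimension and dimnames.
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(15, 1, 0.4), 5, 3)
#' colSums(randomize_m2(m)) == colSums(m)  # always TRUE
#' @export
randomize_m1 <- function(m, variant = c("hypergeometric", "binomial")) {
  variant <- match.arg(variant)
  m <- as_binary_matrix(m)
  out <- m
  out[] <- 0L
  if (variant == "hypergeometric") {
    f <- sum(m)
    if (f > 0L) out[sample.int(length(m), f)] <- 1L
  } else {
    out[] <- as.integer(stats::runif(length(m)) < sum(m) / length(m))
  }
  out
}

#' @rdname randomize_m1
#' @export
randomize_m2 <- function(m) {
  m <- as_binary_matrix(m)
  out <- m
  out[] <- 0L
  n <- nrow(m)
  for (s in seq_len(ncol(m))) {
    f <- sum(m[, s])
    if (f > 0L) out[sample.int(n, f), s] <- 1L
  }
  out
}

#' @rdname randomize_m1
#' @export
randomize_m3 <- function(m) {
  m <- as_binary_matrix(m)
  out <- m
  out[] <- 0L
  s <- ncol(m)
  for (i in seq_len(nrow(m))) {
    r <- sum(m[i, ])
    if (r > 0L) out[i, sample.int(s, r)] <- 1L
  }
  out
}

randomizer_for <- function(config) {
  switch(config$model,
         M1 = function(m) randomize_m1(m, config$m1_variant),
         M2 = randomize_m2,
         M3 = randomize_m3,
         stop("unknown null model '", config$model, "'"))
}

#' Percentile confidence interval of a Monte-Carlo null distribution
#'
#' Two-sided equal-tailed interval using the inverse-empirical-CDF (type-1)
#' quantile, so both endpoints are attained sample values — on integer
#' statistics the bounds are integers.
#'
#' @param samples Non-empty numeric vector of null samples.
#' @param level Confidence level in (0, 1], default 0.95.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' percentile_ci(1:100, 0.95)  # c(3, 98)
#' @export
percentile_ci <- function(samples, level = 0.95) {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!(level > 0 && level <= 1)) stop("level must be in (0, 1]")
  a <- (1 - level) / 2
  q <- unname(stats::quantile(samples, c(a, 1 - a), type = 1, names = FALSE))
  c(lo = q[1], hi = q[2])
}

ci_flag <- function(observed, lo, hi) {
  ifelse(observed < lo, "below", ifelse(observed > hi, "above", "inside"))
}

#' Monte-Carlo null distributions for occupancy statistics
#'
#' Simulates `config$reps` random communities from the configured null
#' model and records, for every statistic, its null samples, percentile
#' confidence interval, the observed value on the input matrix, and a flag
#' `"below"` / `"inside"` / `"above"`. An observed value equal to a CI
#' endpoint is `"inside"`: the random-association hypothesis is rejected
#' only when the observation falls strictly outside the interval.
#'
#' The run is fully reproducible: the master seed in `config` initialises
#' the RNG once and replicates are drawn sequentially, so identical
#' seed + configuration gives bit-identical samples.
#'
#' @param m A binary occupancy matrix ([to_incidence()] with
#'   `drop_empty = FALSE` for the null-model convention).
#' @param config A [null_config()].
#' @param statistics A named list of extractor functions, each mapping a
#'   binary matrix to a named numeric vector (or scalar); a single function
#'   is also accepted. Names of vector elements become statistic ids.
#' @return An object of class `null_distribution_set`: a list with
#'   `samples` (reps x statistics matrix), `observed`, `ci_lo`, `ci_hi`,
#'   `null_mean`, `flag` (all named by statistic id) and `config`. Use
#'   [as.data.frame()] for a tidy summary.
#' @examples
#' m <- to_incidence(select_stratum(coral_survey(), region = "RI",
#'                                  stage = "adult"), key_taxa())
#' nd <- simulate_null(m, null_config("M2", reps = 200, seed = 1),
#'                     list(n_occupied = function(x) sum(rowSums(x) > 0)))
#' as.data.frame(nd)
#' @export
simulate_null <- function(m, config, statistics) {
  stopifnot(inherits(config, "null_config"))
  if (is.function(statistics)) statistics <- list(statistic = statistics)
  if (is.null(names(statistics)) || any(names(statistics) == "")) {
    stop("statistics must be a named list of functions")
  }
  m <- as_binary_matrix(m)
  draw <- randomizer_for(config)
  extract <- function(x) {
    out <- unlist(lapply(names(statistics), function(nm) {
      v <- statistics[[nm]](x)
      if (is.null(names(v))) {
        names(v) <- if (length(v) == 1L) nm else {
          paste0(nm, "_", seq_along(v))
        }
      } else {
        names(v) <- if (length(statistics) == 1L) names(v) else {
          paste0(nm, ".", names(v))
        }
      }
      v
    }))
    out
  }
  observed <- extract(m)
  k <- length(observed)
  samples <- matrix(NA_real_, nrow = config$reps, ncol = k,
                    dimnames = list(NULL, names(observed)))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  for (r in seq_len(config$reps)) {
    samples[r, ] <- extract(draw(m))
  }
  ci <- apply(samples, 2, percentile_ci, level = config$ci_level)
  structure(list(samples = samples,
                 observed = observed,
                 ci_lo = ci["lo", ],
                 ci_hi = ci["hi", ],
                 null_mean = colMeans(samples),
                 flag = ci_flag(observed, ci["lo", ], ci["hi", ]),
                 config = config),
            class = "null_distribution_set")
}

#' @export
as.data.frame.null_distribution_set <- function(x, ...) {
  data.frame(statistic_id = names(x$observed),
             observed = unname(x$observed),
             null_mean = unname(x$null_mean),
             ci_lo = unname(x$ci_lo),
             ci_hi = unname(x$ci_hi),
             flag = unname(x$flag),
             model = x$config$model,
             reps = x$config$reps,
             seed = x$config$seed,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.null_distribution_set <- function(x, ...) {
  cat("<null_distribution_set> model ", x$config$model, ", ",
      x$config$reps, " reps, ", length(x$observed), " statistics\n",
      sep = "")
  print(as.data.frame(x)[, c("statistic_id", "observed", "null_mean",
                             "ci_lo", "ci_hi", "flag")])
  invisible(x)
}
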