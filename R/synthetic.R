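#' Auto-logistic interaction model for synthetic key-species communities
#'
#' Defines a generative model over the presence/absence states of the five
#' key species within one colony: an exponential-family (pairwise
#' auto-logistic, i.e. Ising-type) distribution
#' `P(x) \propto exp(sum_s alpha_s x_s + sum_{s<t} theta_st x_s x_t)` over
#' the `2^S` binary states. With only five species the 32 states are
#' enumerated exactly, so every moment of every downstream statistic has a
#' closed-form oracle.
#'
#' @param alpha Numeric vector of per-species propensities (log-scale);
#'   `-Inf` excludes a species. Names become taxon ids (default the five
#'   key-species ids when `length(alpha) == 5`).
#' @param theta Symmetric matrix of pairwise interaction strengths
#'   (log-odds scale) with zero diagonal; default no interaction.
#' @param n Colonies per generated stratum (default 60).
#' @return A list of class `interaction_model`.
#' @seealso [state_distribution()], [generate_communities()],
#'   [match_prevalence()]
#' @export
interaction_model <- function(alpha, theta = NULL, n = 60L) {
  s <- length(alpha)
  if (s < 1) stop("need at least one species")
  if (is.null(theta)) theta <- matrix(0, s, s)
  theta <- as.matrix(theta)
  if (!all(dim(theta) == s)) stop("theta must be ", s, " x ", s)
  if (any(is.na(theta)) || any(!is.finite(theta))) {
    stop("theta must be finite")
  }
  if (any(abs(theta - t(theta)) > 1e-12)) stop("theta must be symmetric")
  if (any(abs(diag(theta)) > 1e-12)) stop("theta must have zero diagonal")
  if (any(is.na(alpha)) || any(alpha == Inf)) {
    stop("alpha must not contain NA or +Inf")
  }
  ids <- names(alpha)
  if (is.null(ids)) {
    ids <- if (s == 5) {
      c("AlotL1", "AlotL2", "Tgut", "Tsept", "Tspe")
    } else {
      paste0("sp", seq_len(s))
    }
  }
  names(alpha) <- ids
  dimnames(theta) <- list(ids, ids)
  structure(list(alpha = alpha, theta = theta, n = as.integer(n),
                 species = ids),
            class = "interaction_model")
}

#' Exact state distribution of an interaction model
#'
#' Enumerates all `2^S` presence/absence states and their normalised
#' probabilities.
#'
#' @param model An [interaction_model()].
#' @return A list with `states` (2^S x S binary matrix) and `prob`
#'   (probabilities summing to 1).
#' @examples
#' sd0 <- state_distribution(interaction_model(rep(0, 5)))
#' all.equal(sd0$prob, rep(1 / 32, 32))
#' @export
state_distribution <- function(model) {
  stopifnot(inherits(model, "interaction_model"))
  s <- length(model$alpha)
  states <- as.matrix(expand.grid(rep(list(0:1), s)))
  dimnames(states) <- list(NULL, model$species)
  storage.mode(states) <- "integer"
  a <- ifelse(model$alpha == -Inf, -Inf, model$alpha)
  lin <- states %*% ifelse(is.finite(a), a, 0)
  lin[states %*% as.integer(!is.finite(a)) > 0] <- -Inf  # excluded species
  quad <- 0.5 * rowSums((states %*% model$theta) * states)
  loge <- lin + quad
  w <- exp(loge - max(loge[is.finite(loge)]))
  w[!is.finite(loge)] <- 0
  list(states = states, prob = as.numeric(w / sum(w)))
}

#' Expected pairwise co-occurrence probabilities of a model
#'
#' `E[x_s x_t]` for every species pair, from the enumerated state
#' distribution — the moment oracle for co-occurrence counts.
#'
#' @param model An [interaction_model()].
#' @return Symmetric S x S matrix of `P(x_s = 1, x_t = 1)`; the diagonal
#'   holds the marginal prevalences.
#' @export
expected_cooccurrence <- function(model) {
  sd <- state_distribution(model)
  t(sd$states) %*% (sd$states * sd$prob)
}

#' Generate synthetic colony communities
#'
#' Draws `n` i.i.d. colonies from the model's state distribution and wraps
#' them as a `colony_set` with the given stratum labels. Non-key taxa can
#' be added as independent background presences with fixed per-taxon
#' probabilities (they matter only for ordination realism).
#'
#' @param model An [interaction_model()] over the five key species.
#' @param n Number of colonies (default `model$n`).
#' @param region,site,stage,host_type Stratum labels for the generated
#'   colonies.
#' @param seed Integer seed; the same model + seed gives an identical
#'   colony list.
#' @param background Optional named numeric vector of presence
#'   probabilities for additional (non-key) taxa, e.g.
#'   `c(Tser = 0.05, Tbel = 0.03)`.
#' @param taxa Taxon table used to resolve ids; defaults to [guild_taxa()].
#' @return A `colony_set`.
#' @examples
#' mdl <- interaction_model(rep(0, 5))
#' gen <- generate_communities(mdl, n = 10, seed = 1)
#' nrow(gen$colonies)
#' @export
generate_communities <- function(model, n = model$n, region = "RI",
                                 site = "LI", stage = "adult",
                                 host_type = "beta", seed = NULL,
                                 background = NULL, taxa = guild_taxa()) {
  stopifnot(inherits(model, "interaction_model"))
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (!all(model$species %in% taxa$taxon_id)) {
    stop("model species must be taxon ids of the taxon set")
  }
  if (!is.null(background)) {
    if (is.null(names(background)) ||
        !all(names(background) %in% taxa$taxon_id)) {
      stop("background must be named by known taxon ids")
    }
    if (any(background < 0 | background > 1)) {
      stop("background probabilities must be in [0, 1]")
    }
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sd <- state_distribution(model)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sprintf("SYN-%s-%s-%s-%s-%03d", region, site,
                 toupper(substr(stage, 1, 1)), substr(host_type, 1, 1),
                 seq_len(n))
  colonies <- data.frame(colony_id = ids,
                         region = rep(region, n), site = rep(site, n),
                         stage = rep(stage, n),
                         host_type = rep(host_type, n),
                         L_cm = rep(NA_real_, n), l_cm = rep(NA_real_, n),
                         stringsAsFactors = FALSE)
  occ_rows <- list()
  if (n > 0) {
    draw <- sample.int(nrow(sd$states), n, replace = TRUE, prob = sd$prob)
    pres <- sd$states[draw, , drop = FALSE]
    hit <- which(pres == 1L, arr.ind = TRUE)
    if (nrow(hit)) {
      occ_rows$key <- data.frame(colony_id = ids[hit[, 1]],
                                 taxon_id = model$species[hit[, 2]],
                                 count = 1L, stringsAsFactors = FALSE)
    }
    for (bt in names(background)) {
      on_b <- which(stats::runif(n) < background[[bt]])
      if (length(on_b)) {
        occ_rows[[bt]] <- data.frame(colony_id = ids[on_b], taxon_id = bt,
                                     count = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  occupancy <- if (length(occ_rows)) {
    do.call(rbind, occ_rows)
  } else {
    data.frame(colony_id = character(), taxon_id = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  occupancy <- occupancy[order(match(occupancy$colony_id, ids),
                               match(occupancy$taxon_id, taxa$taxon_id)), ]
  rownames(occupancy) <- NULL
  new_colony_set(colonies, occupancy, taxa)
}

#' Solve propensities for target marginal prevalences
#'
#' Finds the `alpha` vector for which the interaction model's marginal
#' prevalences equal the given targets, by damped fixed-point iteration on
#' the exactly enumerated marginals. With `theta = 0` the solution is the
#' logit of the targets; with interactions it adjusts each propensity for
#' the pull of its partners.
#'
#' @param target Numeric vector of target prevalences in (0, 1).
#' @param theta Interaction matrix (default none).
#' @param tol Convergence tolerance on the marginals (default 1e-6).
#' @param max_iter Iteration cap.
#' @return Named `alpha` vector such that
#'   `diag(expected_cooccurrence(interaction_model(alpha, theta)))` matches
#'   `target` within `tol`.
#' @examples
#' a <- match_prevalence(rep(0.4, 5))
#' all.equal(unname(a), rep(qlogis(0.4), 5))
#' @export
match_prevalence <- function(target, theta = NULL, tol = 1e-6,
                             max_iter = 200L) {
  if (any(target <= 0 | target >= 1)) stop("targets must be in (0, 1)")
  s <- length(target)
  alpha <- stats::qlogis(target)
  for (it in seq_len(max_iter)) {
    mdl <- interaction_model(alpha, theta)
    marg <- diag(expected_cooccurrence(mdl))
    if (max(abs(marg - target)) < tol) return(mdl$alpha)
    alpha <- alpha + (stats::qlogis(target) - stats::qlogis(marg))
  }
  stop("marginal matching did not converge within ", max_iter,
       " iterations")
}

#' Type-I error and power of the null-model decision procedure
#'
#' Monte-Carlo experiment over synthetic datasets: for each of
#' `n_datasets` communities generated from a model, runs the pairwise
#' co-occurrence test against the configured null and records the flag per
#' species pair. Generated under a no-interaction model the two-sided flag
#' rate estimates the type-I error of each pair; under an interacting
#' model it estimates power.
#'
#' @param model An [interaction_model()] to generate data from.
#' @param n_datasets Number of synthetic datasets.
#' @param model_id Null model to test against (`"M1"`, `"M2"` or `"M3"`).
#' @param reps Null replicates per dataset (default 1000).
#' @param ci_level CI level of the decision rule (default 0.95).
#' @param seed Master seed; dataset seeds and null seeds derive from it.
#' @return A data frame with one row per species pair: `taxon_a`,
#'   `taxon_b`, `rate_above`, `rate_below`, `rate_flagged` (two-sided),
#'   plus `n_datasets`, `model`, `reps`.
#' @examples
#' \donttest{
#' null5 <- interaction_model(match_prevalence(rep(0.4, 5)))
#' power_experiment(null5, n_datasets = 20, reps = 200, seed = 1)
#' }
#' @export
power_experiment <- function(model, n_datasets, model_id = "M2",
                             reps = 1000L, ci_level = 0.95, seed = 1L) {
  stopifnot(inherits(model, "interaction_model"))
  s <- length(model$species)
  pairs <- which(upper.tri(diag(s)), arr.ind = TRUE)
  above <- below <- matrix(0L, nrow = nrow(pairs), ncol = 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2L * n_datasets)
  pair_stat <- function(m) {
    cc <- crossprod(m)
    cc[upper.tri(cc)]
  }
  for (d in seq_len(n_datasets)) {
    cs <- generate_communities(model, seed = sub_seeds[2L * d - 1L])
    m <- to_incidence(cs, taxa = model$species, drop_empty = FALSE)
    cfg <- null_config(model_id, reps = reps, ci_level = ci_level,
                       seed = sub_seeds[2L * d])
    nd <- simulate_null(m, cfg, list(pair = pair_stat))
    above <- above + (nd$flag == "above")
    below <- below + (nd$flag == "below")
  }
  data.frame(taxon_a = model$species[pairs[, 1]],
             taxon_b = model$species[pairs[, 2]],
             rate_above = as.numeric(above) / n_datasets,
             rate_below = as.numeric(below) / n_datasets,
             rate_flagged = as.numeric(above + below) / n_datasets,
             n_datasets = n_datasets, model = model_id, reps = reps,
             stringsAsFactors = FALSE)
}
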