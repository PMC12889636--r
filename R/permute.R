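# Whole-pedigree sex-permutation null for the carrier scorer, with three
# empirical p-value definitions: the family-wise maximum posterior, the
# maximum z-score within each run, and the rank of a focal individual.
#
# All counting rules are strict ("higher than"), so p = 0 is attainable;
# the more common add-one convention is available via `add_one = TRUE`.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Permute the sexes of a pedigree
#'
#' Returns a permissive-mode pedigree with identical individuals and parent
#' edges, whose multiset of sex labels (including unknowns) is reassigned by
#' a seeded uniform shuffle. The result can place a female label in a father
#' role; that is deliberate, the permutation null keeps the tree topology
#' fixed and randomises everything else.
#'
#' @param ped A [pedigree()].
#' @param seed Integer seed; the same seed reproduces the same permutation.
#' @return A permissive [pedigree()].
#' @export
permute_sexes <- function(ped, seed) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  perm <- with_seed(seed, sample.int(n))
  df <- as.data.frame(ped)
  df$sex <- df$sex[perm]
  validate_pedigree(df, "permissive")
  new_pedigree(df, "permissive",
               paste0(attr(ped, "provenance"), " [sex-permuted]"))
}

new_permutation_result <- function(method, observed_stat, permuted_stats,
                                   p_value, focal_id = NULL, seed = NA_integer_) {
  structure(list(method = method, observed_stat = observed_stat,
                 permuted_stats = permuted_stats,
                 n_permutations = length(permuted_stats),
                 p_value = p_value, focal_id = focal_id, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed=%.4g, p=%.4g (%d permutations)\n",
              x$method, x$observed_stat, x$p_value, x$n_permutations))
  invisible(x)
}

count_pvalue <- function(count, n, add_one) {
  if (add_one) (count + 1) / (n + 1) else count / n
}

#' Family-wise maximum-posterior permutation p-value
#'
#' The observed statistic is the highest carrier posterior in the true run;
#' the p-value is the fraction of permuted runs whose own maximum is
#' strictly greater.
#'
#' @param true_post Carrier posterior of the true pedigree (a
#'   `carrier_posterior` or named numeric vector).
#' @param perm_posts List of carrier posteriors, one per permuted pedigree.
#' @param add_one Use the (count+1)/(n+1) convention instead of strict
#'   count/n (default `FALSE`).
#' @return A `permutation_result`.
#' @export
max_likelihood_pvalue <- function(true_post, perm_posts, add_one = FALSE) {
  tv <- posterior_values(true_post)
  if (!length(tv)) stop("empty posterior map")
  if (!length(perm_posts)) stop("at least one permutation is required")
  obs <- max(tv)
  pm <- vapply(perm_posts, function(p) max(posterior_values(p)), 0)
  new_permutation_result("max_likelihood", obs, pm,
                         count_pvalue(sum(pm > obs), length(pm), add_one))
}

run_max_z <- function(x, label) {
  v <- posterior_values(x)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("zero standard deviation of posteriors in %s", label))
  }
  max((v - mean(v)) / s)
}

#' Maximum-z permutation p-value
#'
#' Posteriors within each run are standardised (subtract the run mean,
#' divide by the run standard deviation); the observed statistic is the
#' maximum z in the true run and the p-value counts permuted runs whose
#' maximum z is strictly greater. Robust to run-to-run shifts in the
#' overall level of posteriors.
#'
#' @inheritParams max_likelihood_pvalue
#' @return A `permutation_result`.
#' @export
z_max_pvalue <- function(true_post, perm_posts, add_one = FALSE) {
  if (!length(perm_posts)) stop("at least one permutation is required")
  obs <- run_max_z(true_post, "the true run")
  pm <- vapply(seq_along(perm_posts), function(k) {
    run_max_z(perm_posts[[k]], sprintf("permutation %d", k))
  }, 0)
  new_permutation_result("z_max", obs, pm,
                         count_pvalue(sum(pm > obs), length(pm), add_one))
}

competition_rank <- function(values, focal_id, label) {
  if (!focal_id %in% names(values)) {
    stop(sprintf("focal individual %s missing from %s", focal_id, label))
  }
  1L + sum(values > values[[focal_id]])
}

#' Focal-rank permutation p-value
#'
#' Ranks the focal individual's posterior within each run (rank 1 is the
#' highest; ties take the minimum, i.e. competition, rank) and counts the
#' permuted runs in which the focal individual ranks strictly better than
#' in the true run. This statistic deliberately ignores multiple testing:
#' it asks whether one named individual outranks its own permuted twins.
#'
#' @param focal_id Id of the focal individual (present in every run).
#' @inheritParams max_likelihood_pvalue
#' @return A `permutation_result` (observed statistic = true rank).
#' @export
focal_rank_pvalue <- function(focal_id, true_post, perm_posts,
                              add_one = FALSE) {
  if (!length(perm_posts)) stop("at least one permutation is required")
  obs <- competition_rank(posterior_values(true_post), focal_id, "the true run")
  pm <- vapply(seq_along(perm_posts), function(k) {
    competition_rank(posterior_values(perm_posts[[k]]), focal_id,
                     sprintf("permutation %d", k))
  }, 0L)
  new_permutation_result("focal_rank", obs, as.numeric(pm),
                         count_pvalue(sum(pm < obs), length(pm), add_one),
                         focal_id = focal_id)
}

#' Putative originator of the top signal
#'
#' The focal individual for the rank test: starting from the individual
#' with the highest posterior, climb to the most ancestral plausible source
#' of the signal. In `male_bias_Y` mode that is the patriline root of the
#' argmax individual (the founder of its Y lineage); in `female_bias_X`
#' mode, the founder reached by repeatedly stepping to the parent with the
#' higher posterior.
#'
#' @param ped A [pedigree()].
#' @param post A carrier posterior for `ped`.
#' @param mode Inheritance mode.
#' @return An individual id.
#' @export
putative_originator <- function(ped, post,
                                mode = c("male_bias_Y", "female_bias_X")) {
  mode <- match.arg(mode)
  v <- posterior_values(post)[ped$id]
  fid <- match(ped$father, ped$id)
  mid <- match(ped$mother, ped$id)
  i <- which.max(v)
  if (mode == "male_bias_Y") {
    while (!is.na(fid[[i]])) i <- fid[[i]]
  } else {
    repeat {
      cand <- c(fid[[i]], mid[[i]])
      cand <- cand[!is.na(cand)]
      if (!length(cand)) break
      i <- cand[[which.max(v[cand])]]
    }
  }
  ped$id[[i]]
}

#' Run the full permutation suite
#'
#' Scores the true pedigree once, then re-scores `n_perm` sex-permuted
#' copies of it with identical parameters and convergence settings (one
#' shared network is reused; only the sex labels change), and computes all
#' three empirical p-values. Permutation seeds are derived deterministically
#' from `seed`. Non-converged permuted runs are kept, with a warning.
#'
#' @param ped A [pedigree()].
#' @param params A [model_params()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Master seed for the permutation stream.
#' @param focal_id Focal individual for the rank test; default is
#'   [putative_originator()] of the true run.
#' @inheritParams run_belief_propagation
#' @inheritParams max_likelihood_pvalue
#' @return A list with elements `max_likelihood`, `z_max`, `focal_rank`
#'   (each a `permutation_result`), plus `true_posterior`, `focal_id`,
#'   `n_non_converged`.
#' @export
run_permutation_suite <- function(ped, params = model_params(),
                                  n_perm = 1000L, seed = 1L,
                                  focal_id = NULL, tol = 1e-9,
                                  max_sweeps = 100L, damping = 1,
                                  add_one = FALSE) {
  stopifnot(inherits(ped, "pedigree"), n_perm >= 1)
  net <- warp_network(ped, params)
  true_post <- run_belief_propagation(net, tol = tol,
                                      max_sweeps = max_sweeps,
                                      damping = damping)
  n <- net$n
  perm_seeds <- with_seed(seed,
                          sample.int(.Machine$integer.max - 1L, n_perm))
  nonconv <- 0L
  perm_posts <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    sx <- with_seed(perm_seeds[[k]], net$sex_code[sample.int(n)])
    r <- run_belief_propagation(net, tol = tol, max_sweeps = max_sweeps,
                                damping = damping, sex_codes = sx)
    if (!r$converged) nonconv <- nonconv + 1L
    perm_posts[[k]] <- r$values
  }
  if (nonconv > 0L) {
    warning(sprintf("%d of %d permuted runs did not converge within %d sweeps",
                    nonconv, n_perm, max_sweeps))
  }
  if (is.null(focal_id)) {
    focal_id <- putative_originator(ped, true_post, params$mode)
  }
  ml <- max_likelihood_pvalue(true_post, perm_posts, add_one = add_one)
  zm <- z_max_pvalue(true_post, perm_posts, add_one = add_one)
  fr <- focal_rank_pvalue(focal_id, true_post, perm_posts, add_one = add_one)
  ml$seed <- zm$seed <- fr$seed <- seed
  list(max_likelihood = ml, z_max = zm, focal_rank = fr,
       true_posterior = true_post, focal_id = focal_id,
       n_non_converged = nonconv)
}
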