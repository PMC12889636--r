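# Carrier-posterior inference: network construction over a pedigree, the
# compiled sum-product engine, the single-sibship closed form and the
# parameter grid sweep.

#' Build the belief network for a pedigree
#'
#' Compiles the pedigree into the factor-graph structure the message-passing
#' engine runs on: one binary carrier variable per individual and one factor
#' per nuclear family. In `male_bias_Y` mode families are keyed by father
#' (the mother's state never matters for a Y-linked distorter), so the
#' factor graph is a forest and inference is exact on any pedigree. In
#' `female_bias_X` mode families are keyed by the (father, mother) pair;
#' inference is exact when that factor graph is a tree and iterative
#' ("loopy", see the `damping` argument of [run_belief_propagation()])
#' otherwise.
#'
#' Priors and conditional probability tables: roots (no recorded father in
#' `male_bias_Y` mode, neither recorded parent in `female_bias_X` mode) get
#' the founder prior `allele_freq` (zero for non-males in `male_bias_Y`
#' mode); [sex_cpt()] links a child's observed sex to the father's carrier
#' state; [inheritance_cpt()] links a child's carrier state to its parents'.
#' Missing recorded parents are treated as non-carriers. Individuals of
#' unknown sex contribute no sex evidence and cannot inherit a Y.
#'
#' The numeric parameters are applied at run time, so one network can be
#' reused across a parameter grid or across sex permutations (the structure
#' depends only on the parent columns and the mode).
#'
#' @param ped A [pedigree()] (permissive pedigrees allowed).
#' @param params A [model_params()].
#' @return A `warp_network` object.
#' @export
warp_network <- function(ped, params = model_params()) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "model_params"))
  n <- nrow(ped)
  fid <- match(ped$father, ped$id)
  mid <- match(ped$mother, ped$id)
  ymode <- params$mode == "male_bias_Y"
  in_family <- if (ymode) !is.na(fid) else (!is.na(fid) | !is.na(mid))
  key <- if (ymode) {
    sprintf("%09d", ifelse(is.na(fid), 0L, fid))
  } else {
    sprintf("%09d.%09d", ifelse(is.na(fid), 0L, fid),
            ifelse(is.na(mid), 0L, mid))
  }
  fams <- if (any(in_family)) {
    unname(split(which(in_family), key[in_family]))
  } else {
    list()
  }
  nf <- length(fams)
  fam_father <- vapply(fams, function(ix) {
    v <- fid[ix[[1L]]]
    if (is.na(v)) -1L else v - 1L
  }, 0L)
  fam_mother <- if (ymode) {
    rep(-1L, nf)
  } else {
    vapply(fams, function(ix) {
      v <- mid[ix[[1L]]]
      if (is.na(v)) -1L else v - 1L
    }, 0L)
  }
  fam_sizes <- lengths(fams)
  fam_cptr <- c(0L, cumsum(fam_sizes))
  fam_cidx <- as.integer(unlist(fams, use.names = FALSE) - 1L)
  gen <- if (n) ped_generations(ped) else integer(0)
  fam_gen <- vapply(fams, function(ix) max(gen[ix]), 0L)
  fam_order <- as.integer(order(fam_gen, method = "radix") - 1L)

  child_fam <- rep(-1L, n)
  child_slot <- rep(-1L, n)
  if (nf) {
    flat <- unlist(fams, use.names = FALSE)
    child_fam[flat] <- rep(seq_len(nf) - 1L, fam_sizes)
    child_slot[flat] <- seq_along(flat) - 1L
  }
  pf <- vector("list", n)
  for (f in seq_len(nf)) {
    fa <- fam_father[[f]]
    if (fa >= 0L) pf[[fa + 1L]] <- c(pf[[fa + 1L]], f - 1L, 0L)
    mo <- fam_mother[[f]]
    if (mo >= 0L) pf[[mo + 1L]] <- c(pf[[mo + 1L]], f - 1L, 1L)
  }
  pf_counts <- vapply(pf, function(x) length(x) %/% 2L, 0L)
  pf_ptr <- c(0L, cumsum(pf_counts))
  pf_flat <- unlist(pf, use.names = FALSE)
  if (is.null(pf_flat)) pf_flat <- integer(0)
  pf_fam <- pf_flat[seq_along(pf_flat) %% 2L == 1L]
  pf_role <- pf_flat[seq_along(pf_flat) %% 2L == 0L]

  is_root <- if (ymode) is.na(fid) else (is.na(fid) & is.na(mid))
  sex_code <- c(male = 1L, female = 2L, unknown = 0L)[ped$sex]

  structure(list(
    ids = ped$id, n = n, sex_code = unname(sex_code),
    fam_father = as.integer(fam_father), fam_mother = as.integer(fam_mother),
    fam_cptr = as.integer(fam_cptr), fam_cidx = fam_cidx,
    fam_order = fam_order,
    child_fam = child_fam, child_slot = child_slot,
    pf_ptr = as.integer(pf_ptr), pf_fam = as.integer(pf_fam),
    pf_role = as.integer(pf_role),
    is_root = as.integer(is_root),
    params = params
  ), class = "warp_network")
}

#' @export
print.warp_network <- function(x, ...) {
  cat(sprintf("<warp_network> %d individuals, %d family factors, mode=%s\n",
              x$n, length(x$fam_father), x$params$mode))
  invisible(x)
}

new_carrier_posterior <- function(values, n_sweeps, converged) {
  structure(list(values = values, n_sweeps = n_sweeps, converged = converged),
            class = "carrier_posterior")
}

#' @export
print.carrier_posterior <- function(x, ...) {
  cat(sprintf("<carrier_posterior> %d individuals, max=%.4g, sweeps=%d, converged=%s\n",
              length(x$values), if (length(x$values)) max(x$values) else NA,
              x$n_sweeps, x$converged))
  invisible(x)
}

# Accept a carrier_posterior or a plain named numeric vector.
posterior_values <- function(x) {
  v <- if (inherits(x, "carrier_posterior")) x$values else x
  if (!is.numeric(v)) stop("expected a carrier posterior or named numeric vector")
  v
}

#' Run sum-product belief propagation
#'
#' Generation-ordered leaves-to-roots then roots-to-leaves message sweeps,
#' repeated until the largest absolute change in any individual's posterior
#' falls below `tol` or `max_sweeps` is reached. On tree-structured factor
#' graphs (always the case in `male_bias_Y` mode) the first sweep is exact
#' and the second confirms convergence.
#'
#' @param net A [warp_network()].
#' @param tol Convergence tolerance on posteriors (default 1e-9).
#' @param max_sweeps Maximum number of up-down sweeps (default 100).
#' @param damping Weight of the fresh message in each update, in (0, 1];
#'   1 (default) is undamped. Values below 1 help loopy (inbred) pedigrees
#'   in `female_bias_X` mode settle.
#' @param params Optional [model_params()] overriding the network's numeric
#'   parameters (the mode must match the network's).
#' @param sex_codes Optional integer vector of per-individual sexes
#'   (1 male, 2 female, 0 unknown) overriding the pedigree's recorded sexes;
#'   used by the permutation machinery to rerun one network under shuffled
#'   labels.
#' @return A `carrier_posterior`: named `values` (P(carrier | all observed
#'   sexes) per individual), `n_sweeps`, and a `converged` flag
#'   (non-convergence is flagged, not an error).
#' @export
run_belief_propagation <- function(net, tol = 1e-9, max_sweeps = 100L,
                                   damping = 1, params = NULL,
                                   sex_codes = NULL) {
  stopifnot(inherits(net, "warp_network"))
  if (is.null(params)) params <- net$params
  stopifnot(inherits(params, "model_params"))
  if (params$mode != net$params$mode) {
    stop("params mode does not match the network mode; rebuild the network")
  }
  if (tol <= 0) stop("tol must be > 0")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  sx <- if (is.null(sex_codes)) net$sex_code else as.integer(sex_codes)
  if (length(sx) != net$n) stop("sex_codes length must match the pedigree")
  res <- bp_run_cpp(net$n, sx,
                    net$fam_father, net$fam_mother,
                    net$fam_cptr, net$fam_cidx, net$fam_order,
                    net$child_fam, net$child_slot,
                    net$pf_ptr, net$pf_fam, net$pf_role,
                    net$is_root,
                    as.integer(params$mode == "male_bias_Y"),
                    params$penetrance, params$allele_freq,
                    params$de_novo_rate,
                    tol, as.integer(max_sweeps), damping)
  new_carrier_posterior(stats::setNames(res$posterior, net$ids),
                        res$n_sweeps, res$converged)
}

#' Score every individual's probability of carrying a distorter
#'
#' Convenience wrapper: builds the belief network for `ped` and runs
#' [run_belief_propagation()].
#'
#' @inheritParams warp_network
#' @inheritParams run_belief_propagation
#' @return A `carrier_posterior`.
#' @examples
#' ped <- pedigree(c("dad", "mom", paste0("son", 1:4)),
#'                 father = c(NA, NA, rep("dad", 4)),
#'                 mother = c(NA, NA, rep("mom", 4)),
#'                 sex = c("M", "F", rep("M", 4)))
#' run_warp(ped)$values[["dad"]]  # ~0.096: four sons raise the prior 0.01
#' @export
run_warp <- function(ped, params = model_params(), tol = 1e-9,
                     max_sweeps = 100L, damping = 1) {
  run_belief_propagation(warp_network(ped, params), tol = tol,
                         max_sweeps = max_sweeps, damping = damping)
}

#' Closed-form carrier posterior for a single sibship
#'
#' One Bayes update for a childless-ancestry father observed to have
#' `n_favored` children of the favored sex and `n_other` of the other:
#' pi p^m (1-p)^f / (pi p^m (1-p)^f + (1-pi) 0.5^(m+f)) with prior
#' pi = `allele_freq` and penetrance p.
#'
#' @param n_favored,n_other Non-negative offspring counts.
#' @param params A [model_params()].
#' @return The posterior carrier probability.
#' @examples
#' single_sibship_posterior(4, 0)  # ~0.0959
#' single_sibship_posterior(2, 2)  # ~0.00131
#' @export
single_sibship_posterior <- function(n_favored, n_other,
                                     params = model_params()) {
  stopifnot(n_favored >= 0, n_other >= 0)
  pi0 <- params$allele_freq
  p <- params$penetrance
  num <- pi0 * p^n_favored * (1 - p)^n_other
  den <- num + (1 - pi0) * 0.5^(n_favored + n_other)
  num / den
}

#' Grid sweep over model parameters
#'
#' Runs the scorer once per parameter combination and reports the maximum
#' posterior and the individual attaining it, so the combination producing
#' the single most confident carrier can be selected.
#'
#' @param ped A [pedigree()].
#' @param penetrances,allele_freqs,de_novo_rates Non-empty numeric grids.
#' @param mode Inheritance mode, as in [model_params()].
#' @inheritParams run_belief_propagation
#' @return A data.frame with one row per combination, in `expand.grid`
#'   order: `penetrance`, `allele_freq`, `de_novo_rate`, `max_posterior`,
#'   `argmax_id`, `converged`.
#' @export
sweep_parameters <- function(ped, penetrances, allele_freqs, de_novo_rates,
                             mode = c("male_bias_Y", "female_bias_X"),
                             tol = 1e-9, max_sweeps = 100L, damping = 1) {
  mode <- match.arg(mode)
  if (!length(penetrances) || !length(allele_freqs) || !length(de_novo_rates)) {
    stop("parameter grids must be non-empty")
  }
  grid <- expand.grid(penetrance = penetrances, allele_freq = allele_freqs,
                      de_novo_rate = de_novo_rates,
                      KEEP.OUT.ATTRS = FALSE)
  net <- warp_network(ped, model_params(penetrance = grid$penetrance[[1L]],
                                        allele_freq = grid$allele_freq[[1L]],
                                        de_novo_rate = grid$de_novo_rate[[1L]],
                                        mode = mode))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- model_params(penetrance = grid$penetrance[[i]],
                      allele_freq = grid$allele_freq[[i]],
                      de_novo_rate = grid$de_novo_rate[[i]], mode = mode)
    post <- run_belief_propagation(net, tol = tol, max_sweeps = max_sweeps,
                                   damping = damping, params = p)
    j <- which.max(post$values)
    data.frame(max_posterior = post$values[[j]],
               argmax_id = names(post$values)[[j]],
               converged = post$converged, stringsAsFactors = FALSE)
  })
  cbind(grid, do.call(rbind, rows))
}
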