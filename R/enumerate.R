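# Exact posterior computation by brute-force enumeration of carrier
# configurations. Exponential in pedigree size; it exists as an independent
# oracle for the message-passing engine and is limited to 20 individuals.

#' Exact carrier posteriors by enumeration
#'
#' Sums the joint probability of the observed sexes over all 2^n carrier
#' assignments, using the same priors and conditional probability tables as
#' the belief-propagation engine but none of its machinery.
#'
#' @inheritParams warp_network
#' @return A `carrier_posterior` with exact marginals.
#' @export
exact_posterior_enumeration <- function(ped, params = model_params()) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "model_params"))
  n <- nrow(ped)
  if (n > 20L) {
    stop("exact enumeration is exponential and limited to pedigrees of at ",
         "most 20 individuals; use run_warp() for larger pedigrees")
  }
  if (n == 0L) {
    return(new_carrier_posterior(stats::setNames(numeric(0), character(0)), 0L, TRUE))
  }
  fid <- match(ped$father, ped$id)
  mid <- match(ped$mother, ped$id)
  ymode <- params$mode == "male_bias_Y"
  favored <- if (ymode) "male" else "female"
  conf <- 0:(2^n - 1L)
  state <- function(i) bitwAnd(bitwShiftR(conf, i - 1L), 1L)
  w <- rep(1, length(conf))
  for (i in seq_len(n)) {
    ci <- state(i)
    is_root <- if (ymode) is.na(fid[[i]]) else (is.na(fid[[i]]) && is.na(mid[[i]]))
    if (is_root) {
      a <- params$allele_freq
      if (ymode && ped$sex[[i]] != "male") a <- 0
      w <- w * ifelse(ci == 1L, a, 1 - a)
    } else {
      cf <- if (!is.na(fid[[i]])) state(fid[[i]]) else 0L
      cm <- if (!is.na(mid[[i]]) && !ymode) state(mid[[i]]) else 0L
      t1 <- carrier_transmission_prob(cf, cm, ped$sex[[i]], params,
                                      father_present = !is.na(fid[[i]]))
      w <- w * ifelse(ci == 1L, t1, 1 - t1)
    }
    if (!is.na(fid[[i]]) && ped$sex[[i]] != "unknown") {
      cf <- state(fid[[i]])
      e1 <- if (ped$sex[[i]] == favored) params$penetrance else 1 - params$penetrance
      w <- w * ifelse(cf == 1L, e1, 0.5)
    }
  }
  z <- sum(w)
  values <- vapply(seq_len(n), function(i) sum(w[state(i) == 1L]) / z, 0)
  new_carrier_posterior(stats::setNames(values, ped$id), 1L, TRUE)
}
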