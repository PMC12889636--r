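# Transmission disequilibrium testing of patrilineal lineages: chi-squared
# against a 50:50 sex expectation, Benjamini-Hochberg FDR across lineages,
# binomial confidence envelopes, and the Monte Carlo family test.

#' Transmission disequilibrium chi-squared test
#'
#' Tests the sexed transmissions of a lineage against the Mendelian 50:50
#' expectation: chi2 = (m - n/2)^2/(n/2) + (f - n/2)^2/(n/2) with
#' n = m + f, 1 degree of freedom, upper tail, no continuity correction.
#'
#' @param n_male,n_female Offspring counts (n_male + n_female >= 1).
#' @return List with `chi2`, `df` (1) and `p_value`.
#' @examples
#' tdt_chi2(60, 29)  # chi2 ~ 10.80, p ~ 0.00102
#' @export
tdt_chi2 <- function(n_male, n_female) {
  stopifnot(n_male >= 0, n_female >= 0)
  n <- n_male + n_female
  if (n < 1) stop("zero transmissions: the TDT needs at least one sexed child")
  e <- n / 2
  chi2 <- (n_male - e)^2 / e + (n_female - e)^2 / e
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate correction, order-preserving with the
#' input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
apply_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Binomial confidence bounds on transmission counts
#'
#' The two binomial quantiles (smallest k with cumulative mass >= q) at the
#' given tail probabilities, used to draw the 99% male-proportion envelope
#' over lineage size.
#'
#' @param n Family size (>= 1).
#' @param prob Null per-transmission success probability (default 0.5).
#' @param q_low,q_high Tail quantiles, 0 < q_low < q_high < 1 (defaults
#'   0.005 and 0.995, a 99% envelope).
#' @return Integer vector `c(count_low, count_high)`.
#' @export
binomial_ci <- function(n, prob = 0.5, q_low = 0.005, q_high = 0.995) {
  stopifnot(n >= 1, prob > 0, prob < 1)
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    stop("invalid quantiles: need 0 < q_low < q_high < 1")
  }
  c(stats::qbinom(q_low, n, prob), stats::qbinom(q_high, n, prob))
}

#' Scan all patrilineal lineages with the TDT
#'
#' Applies [tdt_chi2()] to every lineage with at least one transmission.
#' Lineages with more than `min_offspring` transmissions (strict, the
#' default reproduces the "more than 75 assayable offspring" rule) pass the
#' size filter; Benjamini-Hochberg correction is applied across passing
#' lineages only, and non-passing lineages keep their raw p-value with
#' `p_fdr = NA`.
#'
#' @param ped A [pedigree()].
#' @param min_offspring Size filter: a lineage passes when
#'   `n_transmissions > min_offspring` (default 75).
#' @return A data.frame with one row per lineage (>= 1 transmission):
#'   `lineage_id`, `n_fathers`, `n_transmissions`, `n_male`, `n_female`,
#'   `male_proportion`, `chi2`, `df`, `p_value`, `p_fdr`, `ci_low`,
#'   `ci_high` (99% binomial envelope counts at the lineage's sexed size),
#'   `passed_size_filter`. Lineages whose transmissions are all of unknown
#'   sex get `NA` statistics.
#' @export
scan_lineages <- function(ped, min_offspring = 75) {
  stopifnot(inherits(ped, "pedigree"), min_offspring >= 0)
  lins <- patrilineal_lineages(ped)
  lins <- lins[vapply(lins, `[[`, 0L, "n_transmissions") >= 1L]
  if (!length(lins)) {
    out <- lineage_table(list())
    out$male_proportion <- out$chi2 <- out$p_value <- out$p_fdr <- numeric(0)
    out$df <- out$ci_low <- out$ci_high <- integer(0)
    out$passed_size_filter <- logical(0)
    return(out)
  }
  tab <- lineage_table(lins)
  nsexed <- tab$n_male + tab$n_female
  stats_ <- lapply(seq_len(nrow(tab)), function(i) {
    if (nsexed[[i]] < 1L) {
      return(list(chi2 = NA_real_, p_value = NA_real_,
                  ci_low = NA_integer_, ci_high = NA_integer_,
                  male_proportion = NA_real_))
    }
    t <- tdt_chi2(tab$n_male[[i]], tab$n_female[[i]])
    ci <- binomial_ci(nsexed[[i]])
    list(chi2 = t$chi2, p_value = t$p_value,
         ci_low = ci[[1L]], ci_high = ci[[2L]],
         male_proportion = tab$n_male[[i]] / nsexed[[i]])
  })
  tab$male_proportion <- vapply(stats_, `[[`, 0, "male_proportion")
  tab$chi2 <- vapply(stats_, `[[`, 0, "chi2")
  tab$df <- 1L
  tab$p_value <- vapply(stats_, `[[`, 0, "p_value")
  tab$ci_low <- vapply(stats_, function(s) as.integer(s$ci_low), 0L)
  tab$ci_high <- vapply(stats_, function(s) as.integer(s$ci_high), 0L)
  tab$passed_size_filter <- tab$n_transmissions > min_offspring
  tab$p_fdr <- NA_real_
  sel <- tab$passed_size_filter & !is.na(tab$p_value)
  if (any(sel)) tab$p_fdr[sel] <- apply_fdr(tab$p_value[sel])
  tab
}

#' Monte Carlo test of one family's sex ratio
#'
#' Simulates `n_reps` families of `n` transmissions whose sexes are
#' assigned by independent fair coin flips, and counts the replicates whose
#' favored-sex count is at least as extreme as the observed one. Two-sided
#' extremeness (`|k - n/2| >= |n_favored - n/2|`) approximates the TDT
#' chi-squared; a one-sided option counts only the observed direction.
#'
#' @param n Number of transmissions in the family.
#' @param n_favored Observed count of favored-sex offspring (0..n).
#' @param n_reps Number of simulated families (default 10000).
#' @param seed Integer seed.
#' @param sided `"two"` (default) or `"one"`.
#' @return A `monte_carlo_result`: `n_transmissions`, `n_favored_observed`,
#'   `n_reps`, `n_at_least_as_extreme`, `p_value`, `seed`, `sidedness`.
#' @examples
#' monte_carlo_family(89, 60, seed = 1)$p_value  # ~0.00138
#' @export
monte_carlo_family <- function(n, n_favored, n_reps = 10000L, seed = 1L,
                               sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(n >= 1, n_favored >= 0, n_favored <= n, n_reps >= 1)
  draws <- with_seed(seed, stats::rbinom(n_reps, n, 0.5))
  extreme <- if (sided == "two") {
    abs(draws - n / 2) >= abs(n_favored - n / 2)
  } else if (n_favored >= n / 2) {
    draws >= n_favored
  } else {
    draws <= n_favored
  }
  count <- sum(extreme)
  structure(list(n_transmissions = n, n_favored_observed = n_favored,
                 n_reps = n_reps, n_at_least_as_extreme = count,
                 p_value = count / n_reps, seed = seed, sidedness = sided),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("<monte_carlo_result> %d/%d favored of %d transmissions: p=%.5g (%s-sided, %d reps)\n",
              x$n_favored_observed, x$n_transmissions, x$n_transmissions,
              x$p_value, x$sidedness, x$n_reps))
  invisible(x)
}

#' Scatter-ready lineage summary
#'
#' Per-lineage male proportion against size, with the 99% binomial
#' confidence envelope expressed as proportions; the plain-text analogue of
#' a male-proportion-vs-size scatter.
#'
#' @param scan A data.frame from [scan_lineages()].
#' @return A data.frame with `lineage_id`, `n_transmissions`,
#'   `male_proportion`, `p_value`, `ci_low_prop`, `ci_high_prop`.
#' @export
lineage_scatter <- function(scan) {
  nsexed <- scan$n_male + scan$n_female
  data.frame(lineage_id = scan$lineage_id,
             n_transmissions = scan$n_transmissions,
             male_proportion = scan$male_proportion,
             p_value = scan$p_value,
             ci_low_prop = scan$ci_low / pmax(nsexed, 1L),
             ci_high_prop = scan$ci_high / pmax(nsexed, 1L),
             stringsAsFactors = FALSE)
}
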