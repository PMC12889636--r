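# The genetic model behind the carrier scorer.
#
# A single latent carrier state per individual encodes two competing models:
# C = 0 is the null (Mendelian sex, 50% male, no heritability) and C = 1 the
# distortion model (a carrier father's children are of the favored sex with
# probability `penetrance`, and carrier status is heritable up to a small
# de novo gain/loss rate).

#' Model parameters for the carrier scorer
#'
#' @param penetrance Probability that a carrier father's child is of the
#'   favored sex: male in `male_bias_Y` mode, female in `female_bias_X`
#'   mode. Default 0.90; 0.5 recovers the null model exactly.
#' @param allele_freq Founder prior probability of carrying the distorter
#'   (default 0.01).
#' @param de_novo_rate Per-transmission probability of gaining or losing the
#'   distorter (default 1e-6); keeps the model tolerant of imperfect
#'   inheritance.
#' @param null_sex_prob Probability a non-carrier father's child is of the
#'   favored sex (fixed at 0.5 in the null model).
#' @param mode `"male_bias_Y"`: a Y-linked distorter, carried by males only,
#'   transmitted father to son. `"female_bias_X"`: an X-linked distorter,
#'   distorting only through carrier fathers (who produce mostly daughters),
#'   transmitted father to daughter and mother to either sex with
#'   probability 1/2; the female carrier state is capped at one copy.
#' @return A `model_params` object.
#' @export
model_params <- function(penetrance = 0.90, allele_freq = 0.01,
                         de_novo_rate = 1e-6, null_sex_prob = 0.5,
                         mode = c("male_bias_Y", "female_bias_X")) {
  mode <- match.arg(mode)
  for (nm in c("penetrance", "allele_freq", "de_novo_rate", "null_sex_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("parameter error: %s must be a single probability in [0, 1]", nm))
    }
  }
  if (null_sex_prob != 0.5) {
    stop("parameter error: null_sex_prob is fixed at 0.5")
  }
  if (penetrance < null_sex_prob) {
    stop("parameter error: penetrance must be >= 0.5 (the null sex probability)")
  }
  structure(list(penetrance = penetrance, allele_freq = allele_freq,
                 de_novo_rate = de_novo_rate, null_sex_prob = null_sex_prob,
                 mode = mode),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> mode=%s penetrance=%g allele_freq=%g de_novo_rate=%g\n",
              x$mode, x$penetrance, x$allele_freq, x$de_novo_rate))
  invisible(x)
}

#' Conditional probability tables of the belief network
#'
#' `sex_cpt()` gives P(child sex | father carrier state); `inheritance_cpt()`
#' gives P(child carrier state | father state, mother state) for a child of
#' the given sex. These are the tables the message-passing engine encodes;
#' they are exposed for inspection and testing. Every row sums to 1.
#'
#' @param params A [model_params()].
#' @param child_sex `"male"`, `"female"` or `"unknown"`.
#' @return A matrix with one row per conditioning configuration.
#' @export
sex_cpt <- function(params) {
  favored <- if (params$mode == "male_bias_Y") "male" else "female"
  other <- setdiff(c("male", "female"), favored)
  m <- rbind(`C_father=0` = c(0.5, 0.5),
             `C_father=1` = c(params$penetrance, 1 - params$penetrance))
  colnames(m) <- paste0("S=", c(favored, other))
  m
}

# P(C_child = 1 | C_father = a, C_mother = b, child sex), shared by the
# compiled engine and the enumeration oracle.
carrier_transmission_prob <- function(a, b, child_sex, params,
                                      father_present = TRUE) {
  mu <- params$de_novo_rate
  k <- max(length(a), length(b))
  a <- rep_len(a, k)
  b <- rep_len(b, k)
  if (params$mode == "male_bias_Y") {
    if (child_sex == "male") ifelse(a == 1, 1 - mu, mu) else rep(0, k)
  } else {
    tf <- ifelse(a == 1 & father_present & child_sex == "female", 1 - mu, 0)
    tm <- ifelse(b == 1, 0.5 * (1 - mu), 0)
    1 - (1 - tf) * (1 - tm) * (1 - mu)
  }
}

#' @rdname sex_cpt
#' @export
inheritance_cpt <- function(params, child_sex = c("male", "female", "unknown")) {
  child_sex <- match.arg(child_sex)
  grid <- expand.grid(a = 0:1, b = 0:1)
  p1 <- carrier_transmission_prob(grid$a, grid$b, child_sex, params)
  m <- cbind(`C_child=0` = 1 - p1, `C_child=1` = p1)
  rownames(m) <- sprintf("C_father=%d,C_mother=%d", grid$a, grid$b)
  m
}
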