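# Pedigree builders shared across the test files. Everything is generated
# in code; no fixtures on disk.

# The toy patriline: male root M1 with sons M2, M3 and daughter F1; M2 has
# son M4 and daughter F2. One lineage {M1, M2, M3, M4}; 5 transmissions
# (3 male, 2 female) from fathers {M1, M2}.
toy_lineage_pedigree <- function() {
  pedigree(c("M1", "M2", "M3", "F1", "M4", "F2"),
           father = c(NA, "M1", "M1", "M1", "M2", "M2"),
           sex = c("M", "M", "M", "F", "M", "F"))
}

# Two grandparents, two married sons, one child each: C1 and C2 are first
# cousins (undirected distance 4).
cousin_pedigree <- function() {
  pedigree(c("G1", "G2", "S1", "S2", "W1", "W2", "C1", "C2"),
           father = c(NA, NA, "G1", "G1", NA, NA, "S1", "S2"),
           mother = c(NA, NA, "G2", "G2", NA, NA, "W1", "W2"),
           sex = c("M", "F", "M", "M", "F", "F", "M", "M"))
}

# A founder couple with m sons and f daughters.
sibship_pedigree <- function(m, f) {
  n <- m + f
  pedigree(c("dad", "mom", sprintf("c%02d", seq_len(n))),
           father = c(NA, NA, rep("dad", n)),
           mother = c(NA, NA, rep("mom", n)),
           sex = c("M", "F", rep(c("M", "F"), c(m, f))))
}

# Random pedigree whose nuclear-family factor graph is a tree (no
# inbreeding loops): parents of a child are never already connected, which
# a union-find over pedigree connectivity enforces. Exercises unknown
# sexes, father-only and mother-only children, and (with permuted = TRUE)
# sex-inconsistent parent roles.
random_tree_pedigree <- function(n, seed, permuted = FALSE) {
  set.seed(seed)
  id <- sprintf("p%02d", seq_len(n))
  sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) parent[find(a)] <<- find(b)
  for (i in seq_len(n)) {
    if (i == 1L) next
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (permuted) {
      males <- prev
      females <- prev
    }
    u <- runif(1)
    if (u < 0.7 && length(males)) {
      f <- if (length(males) == 1L) males else sample(males, 1L)
      mcand <- setdiff(females, f)
      mcand <- mcand[vapply(mcand, function(m) find(m) != find(f), TRUE)]
      father[i] <- id[f]
      union_(i, f)
      if (runif(1) < 0.85 && length(mcand)) {
        m <- if (length(mcand) == 1L) mcand else sample(mcand, 1L)
        mother[i] <- id[m]
        union_(i, m)
      }
    } else if (u < 0.85 && length(females)) {
      m <- if (length(females) == 1L) females else sample(females, 1L)
      mother[i] <- id[m]
      union_(i, m)
    }
  }
  pedigree(id, father, mother, sex, mode = "permissive")
}

# Flat synthetic lineage forest for TDT scans: one root father per lineage,
# each with the given numbers of sons and daughters (single generation).
flat_lineage_pedigree <- function(n_male, n_female) {
  stopifnot(length(n_male) == length(n_female))
  rows <- lapply(seq_along(n_male), function(k) {
    kids <- n_male[k] + n_female[k]
    data.frame(
      id = c(sprintf("L%02d", k), sprintf("L%02dw", k),
             sprintf("L%02dc%03d", k, seq_len(kids))),
      father = c(NA, NA, rep(sprintf("L%02d", k), kids)),
      mother = c(NA, NA, rep(sprintf("L%02dw", k), kids)),
      sex = c("male", "female",
              rep(c("male", "female"), c(n_male[k], n_female[k]))),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  pedigree(df$id, df$father, df$mother, df$sex)
}
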