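# The carrier scorer: closed forms, conditional probability tables,
# agreement with the enumeration oracle, and the model's qualitative
# behaviour.

test_that("model parameters are validated", {
  expect_s3_class(model_params(), "model_params")
  expect_error(model_params(penetrance = 1.2), "parameter error")
  expect_error(model_params(allele_freq = -0.1), "parameter error")
  expect_error(model_params(penetrance = 0.3), "parameter error")
  expect_error(model_params(null_sex_prob = 0.6), "parameter error")
})

test_that("every CPT row sums to 1 and penetrance 0.5 recovers the null", {
  for (mode in c("male_bias_Y", "female_bias_X")) {
    p <- model_params(mode = mode)
    expect_equal(unname(rowSums(sex_cpt(p))), c(1, 1))
    for (sx in c("male", "female", "unknown")) {
      expect_equal(unname(rowSums(inheritance_cpt(p, sx))), rep(1, 4))
    }
  }
  nullp <- model_params(penetrance = 0.5)
  cpt <- sex_cpt(nullp)
  expect_equal(cpt["C_father=0", ], cpt["C_father=1", ])
})

test_that("sibship closed form: no evidence returns the prior, known anchors hold", {
  expect_equal(single_sibship_posterior(0, 0), 0.01)
  expect_equal(single_sibship_posterior(4, 0),
               0.01 * 0.9^4 / (0.01 * 0.9^4 + 0.99 * 0.5^4))
  expect_equal(single_sibship_posterior(4, 0), 0.0959, tolerance = 1e-3)
  expect_equal(single_sibship_posterior(2, 2), 0.00131, tolerance = 1e-2)
  # monotone in the favored count at fixed sibship size
  post <- vapply(0:6, function(m) single_sibship_posterior(m, 6 - m), 0)
  expect_true(all(diff(post) > 0))
})

test_that("BP, enumeration and the closed form agree on single sibships", {
  for (counts in list(c(4, 0), c(2, 2), c(0, 4), c(7, 1))) {
    ped <- sibship_pedigree(counts[1], counts[2])
    bp <- run_warp(ped)
    en <- exact_posterior_enumeration(ped)
    cf <- single_sibship_posterior(counts[1], counts[2])
    expect_equal(bp$values[["dad"]], cf, tolerance = 1e-12)
    expect_equal(max(abs(bp$values - en$values)), 0, tolerance = 1e-12)
    expect_true(bp$converged)
  }
  # isolated founder keeps the prior untouched
  solo <- pedigree("only", sex = "M")
  expect_equal(run_warp(solo)$values[["only"]], 0.01)
  expect_equal(exact_posterior_enumeration(solo)$values[["only"]], 0.01)
})

test_that("a father of four sons outranks a father of two sons and two daughters", {
  p40 <- run_warp(sibship_pedigree(4, 0))$values[["dad"]]
  p22 <- run_warp(sibship_pedigree(2, 2))$values[["dad"]]
  expect_gt(p40, p22)
})

test_that("BP matches exact enumeration on random loop-free pedigrees", {
  # deeper dive happens in the acceptance suite; this is the fast everyday
  # version with 60 comparisons
  set.seed(400)
  for (s in 1:30) {
    ped <- random_tree_pedigree(sample(3:12, 1), seed = 4000 + s,
                                permuted = (s %% 5 == 0))
    for (mode in c("male_bias_Y", "female_bias_X")) {
      params <- model_params(mode = mode)
      bp <- run_belief_propagation(warp_network(ped, params))
      en <- exact_posterior_enumeration(ped, params)
      expect_lt(max(abs(bp$values - en$values)), 1e-9)
      expect_true(all(bp$values >= 0 & bp$values <= 1))
    }
  }
})

test_that("enumeration refuses oversized pedigrees", {
  big <- flat_lineage_pedigree(20, 20)
  expect_error(exact_posterior_enumeration(big), "at most 20")
})

test_that("all-female pedigree only disfavors male-line carriers", {
  ped <- pedigree(c("dad", "mom", paste0("d", 1:5)),
                  father = c(NA, NA, rep("dad", 5)),
                  mother = c(NA, NA, rep("mom", 5)),
                  sex = c("M", "F", rep("F", 5)))
  post <- run_warp(ped)
  expect_lte(post$values[["dad"]], 0.01)
  expect_true(all(post$values[paste0("d", 1:5)] == 0))
})

test_that("with penetrance 0.5 sex evidence carries no information", {
  # posteriors must equal the pure prior/inheritance recursion
  ped <- pedigree(c("a", "w1", "b", "w2", "c", "d"),
                  father = c(NA, NA, "a", NA, "b", "b"),
                  mother = c(NA, NA, "w1", NA, "w2", "w2"),
                  sex = c("M", "F", "M", "F", "M", "F"))
  params <- model_params(penetrance = 0.5)
  post <- run_warp(ped, params)
  mu <- params$de_novo_rate
  step <- function(p) p * (1 - mu) + (1 - p) * mu
  expect_equal(post$values[["a"]], 0.01, tolerance = 1e-9)
  expect_equal(post$values[["b"]], step(0.01), tolerance = 1e-9)
  expect_equal(post$values[["c"]], step(step(0.01)), tolerance = 1e-9)
  expect_equal(post$values[["d"]], 0, tolerance = 1e-9)  # no Y in females
})

test_that("a son's posterior is non-decreasing in his father's", {
  # fix the son's own evidence (childless), vary the father's other sons
  son_post <- father_post <- numeric(5)
  for (k in 0:4) {
    ids <- c("dad", "mom", "focal", if (k > 0) paste0("x", seq_len(k)))
    ped <- pedigree(ids, father = c(NA, NA, rep("dad", 1 + k)),
                    mother = c(NA, NA, rep("mom", 1 + k)),
                    sex = c("M", "F", rep("M", 1 + k)))
    post <- run_warp(ped)
    father_post[k + 1] <- post$values[["dad"]]
    son_post[k + 1] <- post$values[["focal"]]
  }
  expect_true(all(diff(father_post) > 0))
  expect_true(all(diff(son_post) >= 0))
})

test_that("posteriors stay in [0, 1] on fuzzed permissive pedigrees", {
  for (s in 1:15) {
    ped <- random_tree_pedigree(30, seed = 8000 + s, permuted = TRUE)
    for (mode in c("male_bias_Y", "female_bias_X")) {
      v <- run_warp(ped, model_params(mode = mode))$values
      expect_true(all(v >= 0 & v <= 1))
      expect_length(v, nrow(ped))
    }
  }
})

test_that("X mode: carrier fathers implicate daughters, not sons", {
  # 8 daughters of 8: closed form gives dad ~0.527, and each daughter
  # inherits his X outright when he carries
  ped <- pedigree(c("dad", "mom", paste0("d", 1:8)),
                  father = c(NA, NA, rep("dad", 8)),
                  mother = c(NA, NA, rep("mom", 8)),
                  sex = c("M", "F", rep("F", 8)))
  px <- model_params(mode = "female_bias_X")
  post <- run_warp(ped, px)
  cf <- single_sibship_posterior(8, 0, px)
  expect_equal(post$values[["dad"]], cf, tolerance = 1e-6)
  expect_gt(min(post$values[paste0("d", 1:8)]), 0.4)  # daughters inherit
  # adding a son: he cannot inherit his father's X
  ped2 <- pedigree(c("dad", "mom", paste0("d", 1:8), "s1"),
                   father = c(NA, NA, rep("dad", 9)),
                   mother = c(NA, NA, rep("mom", 9)),
                   sex = c("M", "F", rep("F", 8), "M"))
  post2 <- run_warp(ped2, px)
  expect_lt(post2$values[["s1"]], 0.01)
  expect_lt(post2$values[["s1"]], post2$values[["dad"]])
})

test_that("belief propagation flags non-convergence instead of erroring", {
  # an inbred loop in X mode: two brothers marry two sisters
  ped <- pedigree(c("f1", "m1", "f2", "m2", "a", "b", "c", "d", "k1", "k2"),
                  father = c(NA, NA, NA, NA, "f1", "f1", "f2", "f2", "a", "b"),
                  mother = c(NA, NA, NA, NA, "m1", "m1", "m2", "m2", "c", "d"),
                  sex = c("M", "F", "M", "F", "M", "M", "F", "F", "F", "F"))
  net <- warp_network(ped, model_params(mode = "female_bias_X"))
  one <- run_belief_propagation(net, max_sweeps = 1)
  expect_false(one$converged)
  expect_equal(one$n_sweeps, 1L)
  full <- run_belief_propagation(net, max_sweeps = 200, damping = 0.7)
  expect_true(all(full$values >= 0 & full$values <= 1))
})

test_that("sweep_parameters is consistent, exhaustive and deterministic", {
  res <- generate_pedigree(sim_config(n_founder_couples = 4,
                                      n_generations = 4, seed = 77))
  ped <- res$pedigree
  # 1x1x1 grid equals a direct run
  one <- sweep_parameters(ped, 0.9, 0.01, 1e-6)
  expect_equal(nrow(one), 1L)
  direct <- run_warp(ped)
  expect_equal(one$max_posterior, max(direct$values), tolerance = 1e-12)
  expect_equal(one$argmax_id, names(direct$values)[which.max(direct$values)])

  # a male-biased pedigree: at any fixed allele frequency the null
  # (penetrance 0.5) row cannot beat the fitted distortion rows
  biased <- sibship_pedigree(8, 1)
  grid <- sweep_parameters(biased, c(0.5, 0.7, 0.9), c(0.01, 0.001), 1e-6)
  expect_equal(nrow(grid), 6L)
  for (af in unique(grid$allele_freq)) {
    rows <- grid[grid$allele_freq == af, ]
    expect_true(rows$max_posterior[rows$penetrance == 0.5] <=
                  min(rows$max_posterior[rows$penetrance != 0.5]) + 1e-12)
  }

  # the published grid completes with unique parameter rows
  pens <- c(0.5, 0.6, 0.62, 0.64, 0.66, 0.68, 0.7, 0.75, 0.8, 0.85, 0.9,
            0.95, 0.97, 0.99)
  afs <- c(0.001, 1e-4, 1e-5, 1e-6)
  dns <- c(0.01, 0.001, 1e-4, 1e-5, 1e-6)
  full <- sweep_parameters(ped, pens, afs, dns)
  expect_equal(nrow(full), 14L * 4L * 5L)
  expect_false(any(duplicated(full[, c("penetrance", "allele_freq",
                                       "de_novo_rate")])))
  expect_error(sweep_parameters(ped, numeric(0), 0.01, 1e-6), "non-empty")
})
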