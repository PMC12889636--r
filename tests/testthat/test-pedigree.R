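# Pedigree construction, I/O, validation, graph queries and lineage
# extraction.

test_that("construction validates ids, parent references and cycles", {
  ped <- pedigree(c("f", "m", "a", "b"), c(NA, NA, "f", "f"),
                  c(NA, NA, "m", "m"), c("M", "F", "M", "F"))
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 4L)
  expect_equal(founders(ped), c("f", "m"))

  expect_error(pedigree(c("a", "a"), sex = "M"), "duplicate individual id: a")
  expect_error(pedigree("a", father = "ghost", sex = "M"),
               "unknown parent reference: ghost")
  # a child listing itself as father is a one-node cycle
  expect_error(pedigree("a", father = "a", sex = "M"), "cyclic ancestry")
  expect_error(pedigree(c("a", "b"), father = c("b", "a"), sex = "M"),
               "cyclic ancestry")
})

test_that("strict mode rejects sex-inconsistent parents; permissive accepts", {
  expect_error(
    pedigree(c("x", "c"), father = c(NA, "x"), sex = c("F", "M")),
    "father x is not recorded male"
  )
  ped <- pedigree(c("x", "c"), father = c(NA, "x"), sex = c("F", "M"),
                  mode = "permissive")
  expect_identical(attr(ped, "ped_mode"), "permissive")
  expect_error(
    pedigree(c("x", "c"), mother = c(NA, "x"), sex = c("M", "M")),
    "mother x is not recorded female"
  )
})

test_that("read_pedigree parses PED dialect: codes, comments, header, errors", {
  txt <- c("# a comment", "id\tfather\tmother\tsex",
           "f1\t0\t0\t1", "m1\t0\t\tF", "c1\tf1\tm1\tmale", "c2\tf1\tm1\t0")
  ped <- read_pedigree(textConnection(txt))
  expect_equal(nrow(ped), 4L)
  expect_equal(ped$sex, c("male", "female", "male", "unknown"))
  expect_true(is.na(ped$mother[ped$id == "m1"]))
  expect_equal(founders(ped), c("f1", "m1"))

  expect_error(read_pedigree(textConnection("a\t0\t0")), "malformed")
  expect_error(read_pedigree(textConnection("c\tc\t0\t1")), "cyclic ancestry")
  # female in a father role: strict errors, permissive loads
  badf <- c("x\t0\t0\t2", "c\tx\t0\t1")
  expect_error(read_pedigree(textConnection(badf)), "not recorded male")
  expect_s3_class(read_pedigree(textConnection(badf), mode = "permissive"),
                  "pedigree")
})

test_that("write_pedigree is canonical and round-trips", {
  ped <- toy_lineage_pedigree()
  f <- withr::local_tempfile()
  write_pedigree(ped, f)
  lines1 <- readLines(f)
  back <- read_pedigree(f)
  expect_setequal(back$id, ped$id)
  expect_equal(back[match(ped$id, back$id), c("father", "mother", "sex")],
               ped[, c("father", "mother", "sex")], ignore_attr = TRUE)
  # byte-stable: writing the re-read pedigree reproduces the file
  write_pedigree(back, f)
  expect_identical(readLines(f), lines1)
  # empty pedigree: header only
  write_pedigree(pedigree(character(0)), f)
  expect_identical(readLines(f), "id\tfather\tmother\tsex")
})

test_that("large simulated pedigree survives a write/read round trip", {
  res <- generate_pedigree(sim_config(n_founder_couples = 30,
                                      n_generations = 4, seed = 11))
  ped <- res$pedigree
  expect_gte(nrow(ped), 100L)
  f <- withr::local_tempfile()
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  ix <- match(ped$id, back$id)
  expect_false(anyNA(ix))
  expect_identical(back$father[ix], ped$father)
  expect_identical(back$mother[ix], ped$mother)
  expect_identical(back$sex[ix], ped$sex)
})

test_that("founders and patriline roots distinguish missing-parent cases", {
  # c has a mother but no father: not a founder, but a patriline root
  ped <- pedigree(c("f", "m", "c", "d"), father = c(NA, NA, NA, "c"),
                  mother = c(NA, NA, "m", NA), sex = c("M", "F", "M", "F"))
  expect_equal(founders(ped), c("f", "m"))
  expect_equal(patriline_roots(ped), c("c", "f"))
  solo <- pedigree("only", sex = "F")
  expect_equal(founders(solo), "only")
  chain <- pedigree(c("a", "b", "c"), father = c(NA, "a", "b"), sex = "M")
  expect_equal(founders(chain), "a")
})

test_that("undirected distance matches hand-enumerated relationships", {
  ped <- cousin_pedigree()
  expect_equal(undirected_distance(ped, "G1", "S1"), 1)  # parent-child
  expect_equal(undirected_distance(ped, "S1", "S2"), 2)  # full siblings
  expect_equal(undirected_distance(ped, "G1", "C1"), 2)  # grandparent
  expect_equal(undirected_distance(ped, "C1", "C2"), 4)  # first cousins
  expect_identical(undirected_distance(ped, "C1", "C2", max_radius = 3), Inf)
  expect_identical(undirected_distance(ped, "W1", "W2"), 6)
  expect_error(undirected_distance(ped, "G1", "nope"), "unknown individual")
  # half siblings share one parent: still distance 2
  half <- pedigree(c("f", "m1", "m2", "a", "b"),
                   father = c(NA, NA, NA, "f", "f"),
                   mother = c(NA, NA, NA, "m1", "m2"),
                   sex = c("M", "F", "F", "M", "M"))
  expect_equal(undirected_distance(half, "a", "b"), 2)
})

test_that("undirected distance is symmetric and satisfies the triangle inequality", {
  ped <- random_tree_pedigree(12, seed = 300)
  set.seed(301)
  for (k in 1:25) {
    trip <- sample(ped$id, 3L)
    dab <- undirected_distance(ped, trip[1], trip[2])
    dba <- undirected_distance(ped, trip[2], trip[1])
    expect_identical(dab, dba)
    dbc <- undirected_distance(ped, trip[2], trip[3])
    dac <- undirected_distance(ped, trip[1], trip[3])
    expect_true(dac <= dab + dbc)
  }
})

test_that("patrilineal lineages partition patriline males", {
  ped <- toy_lineage_pedigree()
  lins <- patrilineal_lineages(ped)
  expect_length(lins, 1L)
  expect_equal(lins[[1]]$member_ids, c("M1", "M2", "M3", "M4"))
  tr <- informative_transmissions(ped, lins[[1]])
  expect_equal(tr$n_transmissions, 5L)
  expect_equal(tr$n_male, 3L)
  expect_equal(tr$n_female, 2L)
  expect_equal(tr$transmitting_father_ids, c("M1", "M2"))

  # two unrelated male founders -> two lineages; all-female -> none
  two <- pedigree(c("a", "b"), sex = "M")
  expect_length(patrilineal_lineages(two), 2L)
  fem <- pedigree(c("a", "b"), sex = "F")
  expect_length(patrilineal_lineages(fem), 0L)

  # members with no children yield zero transmissions
  lone <- patrilineal_lineages(two)
  expect_equal(lone[[1]]$n_transmissions, 0L)
  expect_length(lone[[1]]$transmitting_father_ids, 0L)
})

test_that("lineage extraction is insertion-order invariant and consistent", {
  res <- generate_pedigree(sim_config(n_founder_couples = 8,
                                      n_generations = 4, seed = 21))
  ped <- res$pedigree
  lins <- patrilineal_lineages(ped)
  # shuffle row order: identical lineages
  set.seed(22)
  shuf <- as.data.frame(ped)[sample(nrow(ped)), ]
  ped2 <- pedigree(shuf$id, shuf$father, shuf$mother, shuf$sex)
  expect_identical(lineage_table(patrilineal_lineages(ped2)),
                   lineage_table(lins))
  # lineages are disjoint and cover every male with a recorded father
  members <- unlist(lapply(lins, `[[`, "member_ids"))
  expect_false(any(duplicated(members)))
  males_with_father <- ped$id[ped$sex == "male" & !is.na(ped$father)]
  expect_true(all(males_with_father %in% members))
  # total transmissions = children whose father is some lineage member
  expect_equal(sum(vapply(lins, `[[`, 0L, "n_transmissions")),
               sum(ped$father %in% members, na.rm = TRUE))
  # unknown-sex children count in n_transmissions but neither sex tally
  mix <- pedigree(c("r", "k1", "k2"), father = c(NA, "r", "r"),
                  sex = c("M", "M", "U"))
  l <- patrilineal_lineages(mix)[[1]]
  expect_equal(l$n_transmissions, 2L)
  expect_equal(l$n_male + l$n_female, 1L)
})

test_that("permissive lineages follow the father role despite permuted labels", {
  ped <- pedigree(c("x", "s", "g"), father = c(NA, "x", "s"),
                  sex = c("F", "M", "M"), mode = "permissive")
  lins <- patrilineal_lineages(ped)
  expect_length(lins, 1L)
  expect_equal(lins[[1]]$founder_id, "x")
  expect_true(all(c("s", "g") %in% lins[[1]]$member_ids))
})
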