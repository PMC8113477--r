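test_that("canonical scaffold has the expected residue map and topology", {
  sc <- build_canonical_scaffold()
  expect_length(sc$residues, 14)
  expect_equal(sum(sc$residues == "C"), 4)
  expect_equal(which(sc$residues == "C"), c(2, 3, 7, 13))
  expect_equal(which(sc$residues == "T"), c(4, 10, 14))
  expect_equal(which(sc$residues == "D"), 8)
  expect_equal(sc$disulfide_pairs, list(c(3L, 13L)))
  expect_equal(sc$redox_state, "oxidized")
  expect_setequal(sc$placeholder_positions, c(1, 5, 6, 9, 11, 12))
  expect_true(all(sc$residues[sc$placeholder_positions] == "G"))
})

test_that("scaffold invariants are enforced at construction", {
  expect_error(peptide_scaffold(rep("A", 4), list(c(1, 2))), "Cys")
  expect_error(peptide_scaffold(c("C", "C", "C"), list(c(1, 2), c(2, 3))), "two")
  expect_error(peptide_scaffold(c("C", "C"), list(c(1, 2)), redox_state = "reduced"),
               "reduced")
})

test_that("apply_mutation substitutes residues and handles disulfides", {
  sc <- build_canonical_scaffold()
  m <- apply_mutation(sc, list(c(10, "S")))
  expect_equal(m$residues[10], "S")
  expect_equal(m$disulfide_pairs, list(c(3L, 13L)))
  expect_true(m$cyclic)

  ## knocking out a bridging Cys opens the ring
  m2 <- apply_mutation(sc, list(c(3, "S"), c(13, "S")))
  expect_length(m2$disulfide_pairs, 0)
  expect_false(m2$cyclic)

  ## non-bridging Cys pair keeps the bridge
  m3 <- apply_mutation(sc, list(c(2, "S"), c(7, "S")))
  expect_equal(m3$disulfide_pairs, list(c(3L, 13L)))

  expect_error(apply_mutation(sc, list(c(0, "S"))), "out of range")
  expect_error(apply_mutation(sc, list(c(15, "S"))), "out of range")
  expect_warning(apply_mutation(sc, list(c(5, "A"))), "placeholder")
})

test_that("mutations are idempotent and compose", {
  sc <- build_canonical_scaffold()
  a <- list(c(10, "S"))
  b <- list(c(14, "A"))
  once <- apply_mutation(sc, a)
  twice <- apply_mutation(once, a)
  expect_identical(once, twice)
  seq_then <- apply_mutation(apply_mutation(sc, a), b)
  together <- apply_mutation(sc, c(a, b))
  expect_identical(seq_then, together)
})

test_that("scaffold round-trips through its text record", {
  for (sc in list(build_canonical_scaffold(),
                  apply_mutation(build_canonical_scaffold(),
                                 list(c(3, "S"), c(13, "S"))),
                  peptide_scaffold(c("A", "C", "C"), list(), "reduced"))) {
    expect_identical(scaffold_from_record(scaffold_to_record(sc)), sc)
  }
})

test_that("substitution strings parse and validate against the scaffold", {
  s <- parse_substitutions("T10S;T14S")
  expect_equal(s$position, c(10, 14))
  expect_equal(s$from_aa, c("T", "T"))
  expect_equal(s$to_aa, c("S", "S"))
  expect_equal(nrow(parse_substitutions("")), 0)
  expect_error(parse_substitutions("T10"), "malformed")

  bad <- data.frame(variant_id = "x", substitutions = "T8S",
                    redox_state = "oxidized", concentration = 1, mga_ratio = 0.5)
  expect_error(activity_table(bad), "mismatch")
})

test_that("essentiality query returns Asp8, Thr10 and Thr14 on the packaged table", {
  tab <- packaged_activity_table()
  ess <- essential_residues(tab, 1)
  expect_equal(ess, c(8L, 10L, 14L))
  expect_length(ess, 3)
})

test_that("essentiality rules: single substitutions only, parent required", {
  base <- data.frame(
    variant_id = c("parent", "T4S", "multi"),
    substitutions = c("", "T4S", "T10S;T14S"),
    redox_state = "oxidized",
    concentration = 1,
    mga_ratio = c(0.1, 0.95, 0.95))
  tab <- activity_table(base)
  expect_equal(essential_residues(tab, 1), 4L)   # synthetic: T4S inactive here

  only_parent <- activity_table(base[1, ])
  expect_length(essential_residues(only_parent, 1), 0)

  no_parent <- activity_table(base[-1, ])
  expect_error(essential_residues(no_parent, 1), "parent")

  dead_parent <- base
  dead_parent$mga_ratio[1] <- 0.95
  expect_error(essential_residues(activity_table(dead_parent), 1), "inactive")

  ## output is always a subset of singly substituted positions in the table
  ess <- essential_residues(tab, 1)
  singles <- unlist(lapply(tab$substitutions, function(s) {
    p <- parse_substitutions(s)
    if (nrow(p) == 1) p$position else NULL
  }))
  expect_true(all(ess %in% singles))
})
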