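test_that("registry covers every documented subunit with the right residue", {
  reg <- subunit_registry()
  expect_setequal(reg$name,
                  c("GluN1", "GluN2A", "GluN2B", "GluN2C", "GluN2D",
                    "GluN3A", "GluN3B", "GluA1", "GluA2", "GluA2*",
                    "GluA3", "GluA4"))
  res <- setNames(reg$filter_residue, reg$name)
  expect_true(all(res[c("GluN1", "GluN2A", "GluN2B", "GluN2C",
                        "GluN2D")] == "N"))
  expect_true(all(res[c("GluN3A", "GluN3B")] == "G"))
  expect_true(all(res[c("GluA1", "GluA2", "GluA3", "GluA4")] == "Q"))
  expect_identical(unname(res[["GluA2*"]]), "R")
  # eleven distinct accessions; the edited form shares GluA2's
  expect_length(unique(reg$accession), 11L)
  pos <- setNames(reg$filter_position, reg$name)
  expect_identical(unname(pos[["GluN1"]]), 598L)
  expect_identical(unname(pos[["GluA2"]]), 605L)
})

test_that("residue contributions map onto {-1, 0} and reject junk", {
  expect_identical(residue_contribution(c("N", "Q", "S", "T")),
                   rep(-1L, 4))
  expect_identical(residue_contribution(c("G", "A", "R", "K", "F")),
                   rep(0L, 5))
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_true(all(suppressWarnings(residue_contribution(std)) %in%
                    c(-1L, 0L)))
  expect_error(residue_contribution("X"), "one-letter")
  expect_error(residue_contribution("B"), "one-letter")
  expect_error(residue_contribution("Z"), "one-letter")
  # acidic residues are an extrapolation and say so
  expect_warning(out <- residue_contribution("D"), "extrapolation")
  expect_identical(out, -1L)
})

test_that("ring charges of the canonical compositions are reproduced", {
  expect_identical(ring_charge("GluN1/GluN2A/GluN1/GluN2A"), -4L)
  expect_identical(ring_charge("GluN1/GluN3A/GluN1/GluN3A"), -2L)
  expect_identical(ring_charge("GluN1/GluN2B/GluN3A/GluN2B"), -3L)
  expect_identical(ring_charge("GluA1/GluA2*/GluA1/GluA2*"), -2L)
  expect_identical(ring_charge("GluA2*/GluA2*/GluA2*/GluA2*"), 0L)
  expect_identical(ring_charge("GluA1/GluA1/GluA1/GluA1"), -4L)
})

test_that("composition parsing handles delimiters, case and shorthand", {
  a <- parse_composition("GluN1-2A-1-2A")
  expect_identical(a$ring, -4L)
  expect_identical(vapply(a$subunits, `[[`, "", "name"),
                   c("GluN1", "GluN2A", "GluN1", "GluN2A"))
  expect_identical(ring_charge("glun1/glun2b/glun3a/glun2b"), -3L)
  expect_identical(ring_charge("GluA1/glua2*/GluA1/GluA2*"), -2L)
  expect_error(parse_composition("GluN1/GluN9/GluN1/GluN9"), "GluN9")
  expect_error(parse_composition("GluN1/GluN1/GluN1"), "stoichiometry")
  # hypothetical n-mers are allowed only when asked for
  penta <- parse_composition("GluN1/GluN2A/GluN1/GluN2A/GluN2A",
                             hypothetical = TRUE)
  expect_identical(penta$ring, -5L)
  # order is preserved for display, irrelevant for the ring sum
  expect_identical(ring_charge("GluN2B/GluN1/GluN2B/GluN3A"), -3L)
})

test_that("non-native stoichiometries warn but still evaluate", {
  expect_warning(a <- parse_composition("GluN2A/GluN2A/GluN2A/GluN2A"),
                 "GluN1")
  expect_identical(a$ring, -4L)
  expect_warning(b <- parse_composition("GluN1/GluA2/GluN1/GluA2"),
                 "mixed")
  expect_identical(b$ring, -4L)
})

test_that("every registry tetramer multiset yields r_q in [-4, 0]", {
  reg <- subunit_registry()
  contrib <- residue_contribution(reg$filter_residue)
  n <- nrow(reg)
  rqs <- integer(0)
  for (i in 1:n) for (j in i:n) for (k in j:n) for (l in k:n) {
    rqs <- c(rqs, contrib[i] + contrib[j] + contrib[k] + contrib[l])
  }
  expect_length(rqs, choose(n + 3, 4))
  expect_true(all(rqs %in% -4:0))
  expect_setequal(unique(rqs), -4:0)
})

test_that("swapping one charged-ring subunit for G/R shifts r_q by +1", {
  base <- c("GluN1", "GluN2B", "GluN1", "GluN2B")
  for (replacement in c("GluN3A", "GluN3B", "GluA2*")) {
    swapped <- c("GluN1", "GluN2B", replacement, "GluN2B")
    expect_identical(
      suppressWarnings(ring_charge(swapped)),
      suppressWarnings(ring_charge(base)) + 1L
    )
  }
})

test_that("point mutation of the filter site behaves like the edits", {
  n598q <- mutate_subunit("GluN1", 598, "Q")
  expect_identical(n598q$name, "GluN1-N598Q")
  expect_identical(n598q$filter_residue, "Q")
  expect_identical(residue_contribution(n598q$filter_residue), -1L)
  # original untouched
  expect_identical(get_subunit("GluN1")$filter_residue, "N")
  # mutant-bearing assemblies keep their ring charge (N and Q both polar)
  asm <- receptor_assembly(list(n598q, get_subunit("GluN2A"), n598q,
                                get_subunit("GluN2A")))
  expect_identical(asm$ring, -4L)

  q605r <- mutate_subunit("GluA2", 605, "R")
  expect_identical(q605r$filter_residue, "R")
  expect_identical(residue_contribution(q605r$filter_residue), 0L)

  # reference-residue mismatch and unknown coordinates are guarded
  expect_error(apply_mutation("GluN1", "G598Q"), "expected G.*found N")
  expect_error(mutate_subunit("GluN1", 9999, "Q"), "outside")
  expect_error(mutate_subunit("GluN2B", 598, "Q"), "no known filter")
  # label route works where coordinates resolve
  expect_identical(apply_mutation("GluA2", "Q605R")$filter_residue, "R")
  expect_identical(apply_mutation("GluN2A", "N614Q")$filter_residue, "Q")
})

test_that("assemblies and ring charges export as tables", {
  tab <- assembly_table(parse_composition("GluN1/GluN2A/GluN1/GluN2A"))
  expect_identical(tab$r_q, -4L)
  expect_identical(tab$residue_ring, "NNNN")
  expect_identical(tab$n, 4L)
})
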