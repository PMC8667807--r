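test_that("FASTA reading validates strictly and preserves order", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">q1 first record", "GALTSSAMWFSN", "VLLNSGIGE",
               ">q2", "TIFNSFWFGLGQAMYQGSELS"), fa)
  recs <- read_fasta(fa)
  expect_identical(recs$id, c("q1", "q2"))
  expect_identical(recs$residues[1], "GALTSSAMWFSNVLLNSGIGE")

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">q1", "GALTBSAMW"), bad)
  expect_error(read_fasta(bad), "illegal residue 'B'.*position 5")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">q1", "GAL", ">q1", "TSS"), dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no records|parse")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("global alignment is optimal, with frozen small-case scores", {
  # identical strings score their length
  expect_identical(align_global("GATTACA", "GATTACA")$score, 7L)
  # one substitution costs 2 (match +1 becomes mismatch -1)
  expect_identical(align_global("GATTACA", "GATCACA")$score, 5L)
  # deletion of one residue costs one gap
  expect_identical(align_global("GATACA", "GATTACA")$score, 6L - 2L)
})

test_that("alignment scores equal exhaustive enumeration at length <= 8", {
  withr::with_seed(42, {
    alphabet <- c("A", "C", "G", "N", "Q", "S")
    for (rep in 1:30) {
      la <- sample(1:8, 1); lb <- sample(1:8, 1)
      a <- paste(sample(alphabet, la, replace = TRUE), collapse = "")
      b <- paste(sample(alphabet, lb, replace = TRUE), collapse = "")
      expect_identical(align_global(a, b)$score, oracle_align_score(a, b),
                       info = paste(a, b))
    }
  })
})

test_that("alignment scores agree with an independent aligner", {
  sub_mat <- matrix(-1L, 20, 20,
                    dimnames = list(.ringcharge_aas(), .ringcharge_aas()))
  diag(sub_mat) <- 1L
  withr::with_seed(7, {
    for (rep in 1:10) {
      a <- paste(sample(.ringcharge_aas(), sample(5:25, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(.ringcharge_aas(), sample(5:25, 1),
                        replace = TRUE), collapse = "")
      ref_score <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2,
        type = "global", scoreOnly = TRUE
      )
      expect_identical(align_global(a, b)$score, as.integer(ref_score),
                       info = paste(a, b))
    }
  })
})

test_that("anchoring the reference onto itself returns its own offset", {
  reg <- subunit_registry()
  for (k in which(!is.na(reg$m2_fragment))) {
    a <- anchor_filter_residue(reg$m2_fragment[k], reg$name[k])
    expect_identical(a$aligned_query_position, reg$filter_offset[k])
    expect_identical(a$query_residue, reg$filter_residue[k])
    expect_identical(a$identity_fraction, 1)
    expect_length(a$flags, 0L)
  }
})

test_that("cross-family anchoring maps the filter column onto glycine", {
  glun3a <- get_subunit("GluN3A")$m2_fragment
  a <- anchor_filter_residue(glun3a, "GluN1")
  expect_identical(a$query_residue, "G")
  expect_identical(residue_contribution(a$query_residue), 0L)
})

test_that("filter-site mutations and deletions are reported faithfully", {
  glun1 <- get_subunit("GluN1")
  frag <- glun1$m2_fragment
  off <- glun1$filter_offset
  # N -> Q at the filter offset: same position, contribution unchanged
  mut <- frag
  substr(mut, off, off) <- "Q"
  a <- anchor_filter_residue(mut, "GluN1")
  expect_identical(a$aligned_query_position, off)
  expect_identical(a$query_residue, "Q")
  expect_identical(residue_contribution(a$query_residue), -1L)
  # deleting the filter residue forces a gap at the filter column
  del <- paste0(substr(frag, 1, off - 1),
                substr(frag, off + 1, nchar(frag)))
  d <- anchor_filter_residue(del, "GluN1")
  expect_true("NO_HOMOLOGOUS_RESIDUE" %in% d$flags)
  expect_true(is.na(d$aligned_query_position))
})

test_that("flanking insertions shift the anchor by the left-flank length", {
  glun1 <- get_subunit("GluN1")
  withr::with_seed(11, {
    for (rep in 1:10) {
      left <- paste(sample(.ringcharge_aas(), sample(3:12, 1),
                           replace = TRUE), collapse = "")
      right <- paste(sample(.ringcharge_aas(), sample(3:12, 1),
                            replace = TRUE), collapse = "")
      q <- paste0(left, glun1$m2_fragment, right)
      a <- suppressWarnings(anchor_filter_residue(q, "GluN1"))
      expect_identical(a$aligned_query_position,
                       nchar(left) + glun1$filter_offset)
      expect_identical(a$query_residue, glun1$filter_residue)
    }
  })
})

test_that("low-identity anchors carry the low-confidence warning", {
  cfg <- anchor_config()
  poly <- paste(rep("W", 21), collapse = "")
  expect_warning(a <- anchor_filter_residue(poly, "GluN1"),
                 "below the floor")
  expect_true("LOW_CONFIDENCE" %in% a$flags)
  expect_lt(a$identity_fraction, cfg$identity_floor)
})

test_that("configuration files override scoring and guards", {
  cfgf <- tempfile(fileext = ".cfg")
  writeLines(c("# custom scheme", "match = 2", "gap = -3",
               "identity_floor = 0.9"), cfgf)
  cfg <- anchor_config(cfgf)
  expect_identical(cfg$match, 2L)
  expect_identical(cfg$gap, -3L)
  expect_identical(cfg$identity_floor, 0.9)
  expect_identical(cfg$mismatch, -1L)  # untouched default
  expect_identical(align_global("AAAA", "AAAA", cfg)$score, 8L)
  expect_error(anchor_config({
    f <- tempfile(); writeLines("notakey = 1", f); f
  }), "unknown config key")
  # the length cap guards runaway queries
  small <- anchor_config()
  small$length_cap <- 10L
  expect_error(align_global(paste(rep("A", 11), collapse = ""), "AAA",
                            small), "length cap")
})
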