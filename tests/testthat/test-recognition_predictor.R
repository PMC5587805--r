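test_that("anchor extraction reads the documented residues off the alignment", {
  amII <- extract_anchors(synthetic_taqII_protein())
  expect_equal(amII$residues$p0_a, "S")
  expect_equal(amII$residues$p0_b, "R")
  expect_equal(amII$residues$p3_main, "H")
  expect_equal(amII$residues$p2_main, "K")
  expect_equal(amII$residues$p1_minor, c("H", "K"))
  expect_equal(amII$insertion_len, 2L)

  amIII <- extract_anchors(synthetic_taqIII_protein())
  expect_equal(amIII$residues$p0_a, "P")
  expect_equal(amIII$residues$p0_b, "Y")
  expect_equal(amIII$residues$p3_main, "H")
  expect_equal(amIII$insertion_len, 3L)

  amG <- extract_anchors(synthetic_tspGWI_protein())
  expect_equal(amG$residues$p0_a, "S")
  expect_equal(amG$residues$p0_b, "A")
  expect_equal(amG$residues$p3_main, "D")
  expect_equal(amG$insertion_len, 2L)
})

test_that("the rule table reproduces the three characterized motifs", {
  pII <- predict_motif(extract_anchors(synthetic_taqII_protein()))
  expect_equal(pII$motif7, "GACCGAN")
  expect_equal(pII$trimmed, "GACCGA")
  pIII <- predict_motif(extract_anchors(synthetic_taqIII_protein()))
  expect_equal(pIII$trimmed, "CACCCA")
  pG <- predict_motif(extract_anchors(synthetic_tspGWI_protein()))
  expect_equal(pG$motif7, "NACGGAN")
  expect_equal(pG$trimmed, "ACGGA")
})

test_that("prediction is deterministic and position 5 is always adenine", {
  am <- extract_anchors(synthetic_taqII_protein())
  expect_identical(predict_motif(am)$evidence, predict_motif(am)$evidence)
  overrides <- list(list(), list(p0_b = "R"), list(p3_main = "E"),
                    list(p2_main = "G"), list(p1_minor = c("A", "A")),
                    list(loop = "AAAAA"))
  for (ov in overrides) {
    v <- make_trd_variant(ov)
    pred <- predict_motif(extract_anchors(v$protein))
    expect_equal(substr(pred$motif7, 6, 6), "A")
  }
})

test_that("planted anchor variants are predicted as their expected motifs", {
  cases <- list(
    list(p0_b = "R"),                       # Arg at the 777 column -> G at pos 0
    list(p0_a = "R", p0_b = "L"),           # Arg at the 737 column -> C
    list(p3_main = "D"),                    # acidic -> G at pos 3
    list(p3_main = "E"),
    list(p2_main = "N"),                    # Asn -> T at pos 2
    list(loop = "LTRAS"),                   # R.S register -> C at pos 4
    # all-anchors-small: specificity collapses around the invariant adenine
    list(p0_a = "S", p0_b = "A", p1_minor = c("A", "A"), p2_main = "A",
         p3_main = "A", loop = "LTAAA")
  )
  for (ov in cases) {
    v <- make_trd_variant(ov)
    pred <- predict_motif(extract_anchors(v$protein))
    expect_equal(pred$motif7, v$expected$motif7,
                 info = paste(names(ov), collapse = "+"))
    expect_equal(pred$trimmed, v$expected$trimmed)
  }
  v <- make_trd_variant(list(p0_a = "S", p0_b = "A", p1_minor = c("A", "A"),
                             p2_main = "A", p3_main = "A", loop = "LTAAA"))
  expect_equal(v$expected$trimmed, "A")
})

test_that("mutating one anchor set changes only the corresponding position", {
  base <- predict_motif(extract_anchors(synthetic_taqII_protein()))$motif7
  single <- list(p0_b = 1L, p2_main = 3L, p3_main = 4L)
  muts <- list(p0_b = "L", p2_main = "G", p3_main = "D")
  for (nm in names(single)) {
    ov <- list(); ov[[nm]] <- muts[[nm]]
    v <- make_trd_variant(ov)
    got <- predict_motif(extract_anchors(v$protein))$motif7
    pos <- single[[nm]]
    for (k in 1:7) {
      if (k == pos) expect_false(substr(got, k, k) == substr(base, k, k))
      else expect_equal(substr(got, k, k), substr(base, k, k))
    }
  }
})

test_that("predictions outside the TspGWI branch carry a scope warning", {
  am <- extract_anchors(synthetic_taqII_protein())
  expect_warning(predict_motif(am, enzyme_branch = "TspDTI"), "scope")
})

test_that("anchor placement failure raises a low-confidence error", {
  expect_error(extract_anchors(protein_seq(rand_protein(60))), "low-confidence")
})

test_that("covariation flags the position-0 and position-3 anchor columns", {
  prots <- list(TaqII = synthetic_taqII_protein(),
                TaqIII = synthetic_taqIII_protein(),
                TspGWI = synthetic_tspGWI_protein())
  pos <- taqII_anchor_positions()
  # labelled alignment columns = residues at the reference anchor coordinates
  cols <- c(p0_a = pos$p0_a, p0_b = pos$p0_b, p3_main = pos$p3_main,
            p2_main = pos$p2_main, p6_asn = pos$p6_asn)
  aln <- t(vapply(prots, function(p) {
    am <- extract_anchors(p)
    c(am$residues$p0_a, am$residues$p0_b, am$residues$p3_main,
      am$residues$p2_main, am$residues$p6_asn)
  }, character(5)))
  colnames(aln) <- names(cols)
  motifs <- c("GACCGAN", "CACCCAN", "NACGGAN")
  rep <- covary(aln, motifs)
  perfect0 <- rep[rep$position == 0 & rep$perfect, "column"]
  expect_setequal(perfect0, c(1L, 2L))  # the 737 and 777 columns
  perfect3 <- rep[rep$position == 3 & rep$perfect, "column"]
  expect_true(3L %in% perfect3)
  # invariant columns (K688, N594) are excluded entirely
  expect_false(any(rep$column %in% c(4L, 5L)))
})

test_that("covariation report matches the exhaustive pairwise oracle", {
  set.seed(61)
  n <- 6
  aln <- matrix(sample(c("A", "R", "D"), n * 12, replace = TRUE), nrow = n)
  bases <- c("G", "C", "A", "T")
  motifs <- vapply(1:n, function(i)
    paste0(paste(sample(c(bases, "N"), 5, replace = TRUE), collapse = ""), "A",
           sample(c(bases, "N"), 1)), character(1))
  rep <- covary(aln, motifs)
  for (r in seq_len(nrow(rep))) {
    oracle <- bf_covary_pair(aln[, rep$column[r]],
                             substr(motifs, rep$position[r] + 1, rep$position[r] + 1))
    expect_equal(rep$score[r], oracle$score)
    expect_equal(rep$perfect[r], oracle$perfect)
  }
})

test_that("identical enzymes give no informative columns", {
  aln <- matrix(rep(c("A", "R", "K"), 2), nrow = 2, byrow = TRUE)
  rep <- covary(aln, c("GACCGAN", "GACCGAN"))
  expect_equal(nrow(rep), 0L)
})

test_that("a planted residue-base rule column attains the maximum score", {
  set.seed(67)
  n <- 8
  bases <- sample(c("G", "C", "T"), n, replace = TRUE)
  motifs <- vapply(bases, function(b) paste0(b, "ACCGA", "N"), character(1))
  aln <- matrix(sample(c("A", "L", "V", "I"), n * 20, replace = TRUE), nrow = n)
  code <- c(G = "R", C = "Y", T = "N")
  aln[, 13] <- code[bases]  # planted rule column for position 0
  rep <- covary(aln, motifs)
  r0 <- rep[rep$position == 0, ]
  expect_equal(r0$score[r0$column == 13], 1)
  expect_true(rep$perfect[rep$column == 13 & rep$position == 0])
  expect_true(all(r0$score <= 1))
  expect_equal(max(r0$score), r0$score[r0$column == 13])
})

test_that("motifs without the position-5 adenine frame are rejected", {
  aln <- matrix(c("A", "R"), nrow = 2)
  expect_error(covary(aln, c("GACCGAN", "GACCGT")), "framing")
  expect_error(covary(aln, c("GACCGTN", "GACCGTN")), "framing")
})

test_that("the YAML rule file round-trips the default table", {
  tf <- tempfile(fileext = ".yaml")
  write_rule_table(default_rule_table(), tf)
  back <- read_rule_table(tf)
  expect_equal(back, default_rule_table())
  # and the shipped config mirrors the built-in default
  shipped <- system.file("extdata", "recognition_rules.yaml", package = "thermusRM")
  expect_true(nzchar(shipped))
  expect_equal(read_rule_table(shipped), default_rule_table())
})
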