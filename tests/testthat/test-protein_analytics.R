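test_that("closed-form profile values for degenerate inputs", {
  pg <- protein_profile("G")
  expect_equal(pg$n_aa, 1L)
  expect_equal(pg$mol_weight, 57.0519 + 18.01524)
  expect_equal(protein_profile(strrep("A", 100))$aliphatic_index, 100.0)
  # two glycines: II = (10/2) * DIWV(G,G)
  expect_equal(protein_profile("GG")$instability_index, 5 * 13.34)
})

test_that("profile agrees with independently computed reference values", {
  # reference values computed with Bio.SeqUtils.ProtParam; its IUPAC average
  # masses differ from the ExPASy residue masses used here in the 2nd decimal
  p1 <- protein_profile("MKWVTFISLLFLFSSAYS")
  expect_equal(p1$mol_weight, 2140.5405, tolerance = 5e-5)
  expect_equal(p1$theoretical_pI, 8.3447, tolerance = 0.005)
  expect_equal(p1$instability_index, 17.5667, tolerance = 1e-3)
  expect_equal(p1$stability_call, "stable")
  p2 <- protein_profile("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(p2$mol_weight, 2395.7134, tolerance = 5e-5)
  expect_equal(p2$theoretical_pI, 6.7846, tolerance = 0.005)
  expect_equal(p2$instability_index, 84.74, tolerance = 1e-3)
  expect_equal(p2$stability_call, "unstable")
  expect_equal(p2$n_negative, 2L)
  expect_equal(p2$n_positive, 2L)
  expect_equal(p2$n_cys, 1L)
})

test_that("molecular weight cross-checks against seqinr and is additive", {
  library(seqinr)
  set.seed(71)
  for (i in 1:5) {
    s <- rand_protein(sample(30:300, 1))
    expect_equal(protein_profile(s)$mol_weight, seqinr::pmw(s2c(s)),
                 tolerance = 1e-3)
  }
  a <- rand_protein(50); b <- rand_protein(80)
  expect_equal(protein_profile(paste0(a, b))$mol_weight,
               protein_profile(a)$mol_weight + protein_profile(b)$mol_weight -
                 18.01524, tolerance = 1e-9)
})

test_that("net charge at the returned pI is zero", {
  set.seed(73)
  for (i in 1:10) {
    s <- rand_protein(sample(20:500, 1))
    pI <- theoretical_pI(s)
    ch <- strsplit(s, "")[[1]]
    counts <- table(factor(ch, levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    counts <- stats::setNames(as.numeric(counts), names(counts))
    q <- thermusRM:::.net_charge(counts, ch[1], ch[length(ch)], pI)
    expect_lt(abs(q), 1e-3)
  }
})

test_that("invalid residues are rejected with their positions", {
  expect_error(protein_seq("ACDXFG"), "position")
  expect_error(protein_seq(""), "empty")
})

test_that("global identity handles closed-form cases and is symmetric", {
  r <- global_identity("MKWVTF", "MKWVTF")
  expect_equal(r$percent_identity, 100.0)
  expect_equal(nrow(r$differences), 0L)
  r2 <- global_identity("AAAA", "AATA",
                        domains = domain_map("only", 1, 4))
  expect_equal(r2$percent_identity, 75.0)
  expect_equal(r2$differences$domain, "only")
  expect_equal(r2$differences$a_pos, 3L)
  set.seed(79)
  for (i in 1:5) {
    a <- rand_protein(120); b <- rand_protein(sample(100:140, 1))
    expect_equal(global_identity(a, b)$percent_identity,
                 global_identity(b, a)$percent_identity)
  }
})

test_that("the denominator flag switches between alignment and shorter length", {
  a <- "MKWVTFISLL"; b <- "MKWVTFIS"
  r_aln <- global_identity(a, b, denominator = "alignment")
  r_short <- global_identity(a, b, denominator = "shorter")
  expect_equal(r_aln$percent_identity, 100 * 8 / 10)
  expect_equal(r_short$percent_identity, 100.0)
})

test_that("differences are tallied per domain", {
  a <- paste0(strrep("A", 30), strrep("L", 30))
  bch <- strsplit(a, "")[[1]]
  bch[c(5, 40, 45, 50)] <- c("V", "F", "F", "F")
  b <- paste(bch, collapse = "")
  dm <- domain_map(c("Nterm", "Cterm"), c(1, 31), c(30, 60))
  r <- global_identity(a, b, domains = dm)
  expect_equal(as.integer(r$per_domain["Nterm"]), 1L)
  expect_equal(as.integer(r$per_domain["Cterm"]), 3L)
})

test_that("domain maps reject overlap and inverted bounds", {
  expect_error(domain_map(c("a", "b"), c(1, 5), c(10, 20)), "overlap")
  expect_error(domain_map("a", 10, 5), "end before start")
})

test_that("tryptic digestion cleaves after K/R but not before P", {
  expect_equal(tryptic_peptides("AKR")$peptide, c("AK", "R"))
  expect_equal(tryptic_peptides("AKPR")$peptide, "AKPR")
  set.seed(83)
  for (i in 1:20) {
    s <- rand_protein(sample(10:400, 1))
    pep <- tryptic_peptides(s)
    expect_equal(paste(pep$peptide, collapse = ""), s)  # conservation
    expect_equal(pep$start[1], 1L)
    expect_equal(pep$end[nrow(pep)], nchar(s))
  }
  mc <- tryptic_peptides("AKCKDR", missed_cleavages = 1)
  expect_true("AKCK" %in% mc$peptide)
  expect_true("CKDR" %in% mc$peptide)
  expect_error(tryptic_peptides("AK", missed_cleavages = 3), "0, 1 or 2")
})

test_that("peptide classification separates shared from variant-region peptides", {
  a <- synthetic_taqII_protein()
  same <- classify_peptides(tryptic_peptides(a), tryptic_peptides(a),
                            synthetic_domain_map())
  expect_equal(same$summary$n_unique, 0L)
  b <- synthetic_taqIII_protein()
  cls <- classify_peptides(tryptic_peptides(b), tryptic_peptides(a),
                           synthetic_domain_map())
  expect_gt(cls$summary$n_unique, 0L)
  upd <- cls$summary$unique_per_domain
  # the divergence is concentrated in the TRD band
  expect_equal(names(upd)[which.max(upd)], "TRD")
})

test_that("paralog-analog comparison shows high identity with TRD-clustered differences", {
  r <- global_identity(synthetic_taqII_protein(), synthetic_taqIII_protein(),
                       domains = synthetic_domain_map())
  expect_gt(r$percent_identity, 90)
  expect_lt(r$percent_identity, 97)
  expect_equal(names(which.max(r$per_domain)), "TRD")
})
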