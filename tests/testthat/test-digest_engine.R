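taqIII <- enzyme_registry()$TaqIII
taqII <- enzyme_registry()$TaqII

test_that("cut bonds sit 11/9 downstream of the site, leaving a 2-nt 3' end", {
  ev <- cut_positions(list(start = 2L, strand = "+"), taqIII, seq_len = 30L)
  expect_equal(ev$top_cut, 19L)
  expect_equal(ev$bottom_cut, 17L)
  expect_equal(ev$overhang, 2L)
  # downstream bonds do not fit on a 17-mer: site present, not cleavable
  expect_null(cut_positions(list(start = 2L, strand = "+"), taqIII, seq_len = 17L))
})

test_that("minus-strand cuts mirror the plus-strand rule through the midpoint", {
  set.seed(31)
  for (i in 1:25) {
    L <- sample(40:200, 1)
    s <- sample(15:(L - 6), 1)
    ev <- cut_positions(list(start = s, strand = "-"), taqIII, seq_len = L)
    # oracle: apply the + strand rule on the reverse complement and map back
    s_rc <- L - s - 6L
    ev_rc <- cut_positions(list(start = s_rc, strand = "+"), taqIII, seq_len = L)
    if (is.null(ev_rc)) {
      expect_null(ev)
    } else {
      expect_equal(ev$top_cut, L - ev_rc$bottom_cut)
      expect_equal(ev$bottom_cut, L - ev_rc$top_cut)
    }
  }
})

test_that("cut_positions validates its site", {
  expect_error(cut_positions(list(start = 40L, strand = "+"), taqIII, 30L),
               "consistency")
  expect_error(cut_positions(list(start = 2L, strand = "x"), taqIII, 30L),
               "consistency")
})

test_that("a substrate without sites is returned intact", {
  d <- digest(nuc_seq(strrep("A", 100)), taqIII)
  expect_equal(nrow(d$fragments), 1L)
  expect_equal(d$fragments$start, 0L)
  expect_equal(d$fragments$end, 100L)
  expect_equal(fragment_sizes(d), 100L)
})

test_that("a single plus-strand site yields the two arithmetic fragments", {
  s <- paste0(strrep("T", 10), "CACCCA", strrep("G", 30))
  d <- digest(nuc_seq(s), taqIII)
  ev <- cut_positions(list(start = 10L, strand = "+"), taqIII, nchar(s))
  expect_equal(sort(d$fragments$top_len),
               sort(c(ev$top_cut, nchar(s) - ev$top_cut)))
  expect_equal(d$junctions$overhang, 2L)
  expect_equal(d$junctions$polarity, "3'")
})

test_that("complete digests conserve substrate length and 3' end chemistry", {
  set.seed(41)
  for (i in 1:40) {
    L <- sample(100:800, 1)
    s <- rand_dna(L, gc = 0.5)
    d <- digest(nuc_seq(s), list(taqII, taqIII))
    expect_equal(sum(d$fragments$top_len), L)
    expect_equal(sum(d$fragments$bottom_len), L)
    if (nrow(d$junctions)) {
      expect_true(all(d$junctions$overhang == 2L))
      expect_true(all(d$junctions$polarity == "3'"))
    }
  }
})

test_that("fragment sizes equal differences of sorted cut bonds plus flanks", {
  set.seed(43)
  for (i in 1:20) {
    L <- sample(200:800, 1)
    s <- rand_dna(L, gc = 0.55)
    d <- digest(nuc_seq(s), list(taqII, taqIII))
    # independent arithmetic: recompute bonds from the site table
    sites <- d$sites[d$sites$cleavable, , drop = FALSE]
    bonds <- integer(0)
    for (j in seq_len(nrow(sites))) {
      sys <- if (sites$enzyme[j] == "TaqII") taqII else taqIII
      b <- if (sites$strand[j] == "+") sites$start[j] + 6L + 11L
           else sites$start[j] - 9L
      bonds <- c(bonds, b)
    }
    expected <- diff(sort(unique(c(0L, bonds, L))))
    expect_equal(fragment_sizes(d), sort(expected[expected > 0], decreasing = TRUE))
  }
})

test_that("digesting the reverse complement mirrors the fragment multiset", {
  # flipping the duplex swaps the strands, so the mirrored digest's top-strand
  # lengths are the original digest's bottom-strand lengths (and vice versa)
  set.seed(47)
  for (i in 1:15) {
    L <- sample(200:600, 1)
    ch <- strsplit(rand_dna(L, gc = 0.5), "")[[1]]
    at <- sample(20:(L - 30), 1)  # guarantee at least one cleavable site
    ch[(at + 1):(at + 6)] <- strsplit("CACCCA", "")[[1]]
    s <- paste(ch, collapse = "")
    d1 <- digest(nuc_seq(s), taqIII)
    d2 <- digest(nuc_seq(revcomp(s)), taqIII)
    expect_equal(sort(d2$fragments$top_len), sort(d1$fragments$bottom_len))
    expect_equal(sort(d2$fragments$bottom_len), sort(d1$fragments$top_len))
  }
})

test_that("convergent two-enzyme substrate gives three distinct lanes, both = union", {
  sub <- make_substrate(390, data.frame(motif = c("GACCGA", "CACCCA"),
                                        start = c(100L, 300L),
                                        strand = c("+", "-")), seed = 7)
  lane_II <- fragment_sizes(digest(sub$seq, taqII))
  lane_III <- fragment_sizes(digest(sub$seq, taqIII))
  lane_both <- fragment_sizes(digest(sub$seq, list(taqII, taqIII)))
  expect_false(identical(lane_II, lane_III))
  expect_false(identical(lane_II, lane_both))
  expect_false(identical(lane_III, lane_both))
  # union of cuts: bonds 100+6+11 and 300-9
  expect_equal(lane_both, sort(diff(sort(c(0, 117, 291, 390))), decreasing = TRUE))
})

test_that("partial digestion cuts exactly the requested subset", {
  sub <- make_substrate(390, data.frame(motif = c("GACCGA", "CACCCA"),
                                        start = c(100L, 300L),
                                        strand = c("+", "-")), seed = 7)
  all_digests <- enumerate_partial_digests(sub$seq, list(taqII, taqIII))
  expect_length(all_digests, 4L)  # 2^2 subsets
  sizes <- lapply(all_digests, fragment_sizes)
  expect_true(any(vapply(sizes, function(x) identical(x, 390L), logical(1))))
  d_one <- digest(sub$seq, list(taqII, taqIII), mode = "partial", site_subset = 1L)
  expect_equal(nrow(d_one$fragments), 2L)
  expect_error(digest(sub$seq, list(taqII, taqIII), mode = "partial",
                      site_subset = 9L), "unknown site")
})

test_that("a circular substrate with one cut linearizes to full length", {
  s <- paste0(strrep("T", 40), "CACCCA", strrep("G", 40))
  d <- digest(nuc_seq(s, topology = "circular"), taqIII)
  expect_equal(nrow(d$fragments), 1L)
  expect_equal(d$fragments$top_len, nchar(s))
  # and an uncut circle stays circular
  d0 <- digest(nuc_seq(strrep("A", 50), topology = "circular"), taqIII)
  expect_equal(d0$fragments$left_end, "circular")
})

test_that("near-end sites wrap on circles but are skipped on linear substrates", {
  s <- paste0(strrep("T", 10), "CACCCA", "GG")  # cuts run off the linear end
  d_lin <- digest(nuc_seq(s), taqIII)
  expect_equal(nrow(d_lin$fragments), 1L)
  expect_false(d_lin$sites$cleavable[1])
  d_circ <- digest(nuc_seq(s, topology = "circular"), taqIII)
  expect_equal(d_circ$fragments$top_len, nchar(s))
})

test_that("methylated sites are protected when modelling self-protection", {
  s <- paste0(strrep("T", 10), "CACCCA", strrep("G", 30))
  d <- digest(nuc_seq(s), taqIII, methylated = 1L, respect_methylation = TRUE)
  expect_equal(fragment_sizes(d), nchar(s))
  d2 <- digest(nuc_seq(s), taqIII, methylated = 1L, respect_methylation = FALSE)
  expect_length(fragment_sizes(d2), 2L)
})
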