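#!/usr/bin/env Rscript
# In-silico digestion of PCR-substrate analogs.
#
# Builds 390-bp linear substrates carrying GACCGA and/or CACCCA sites in the
# orientations used to assay the two enzymes — a single-site (CACCCA)(<-)
# substrate, the convergent (GACCGA/CACCCA)(-><-) substrate, and a
# (CACCCA/CACCCA)(-><-) substrate — digests each with TaqII only, TaqIII
# only, and both, and writes the resulting gel-lane fragment sizes.
# The two enzymes cut 11/9 nt downstream of their sites, so every junction
# carries a 2-nt 3'-protruding end.

suppressMessages(library(thermusRM))
dir.create("results", showWarnings = FALSE)

reg <- enzyme_registry()

specs <- list(
  `CACCCA_rev` = data.frame(motif = "CACCCA", start = 300L, strand = "-"),
  `GACCGA_CACCCA_conv` = data.frame(motif = c("GACCGA", "CACCCA"),
                                    start = c(100L, 300L),
                                    strand = c("+", "-")),
  `CACCCA_CACCCA_conv` = data.frame(motif = c("CACCCA", "CACCCA"),
                                    start = c(100L, 300L),
                                    strand = c("+", "-"))
)

lanes <- list()
frag_rows <- list()
for (nm in names(specs)) {
  sub <- make_substrate(390, specs[[nm]], gc = 0.66, seed = 390L,
                        id = paste0("PCR_", nm))
  for (enz in list("TaqII", "TaqIII", c("TaqII", "TaqIII"))) {
    d <- digest(sub$seq, reg[enz])
    lane <- fragment_sizes(d)
    lanes[[length(lanes) + 1L]] <- data.frame(
      substrate = nm, enzymes = paste(enz, collapse = "+"),
      n_fragments = length(lane),
      fragment_sizes = paste(lane, collapse = ","))
    f <- d$fragments
    if (nrow(f)) frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      substrate = nm, enzymes = paste(enz, collapse = "+"), f)
  }
  # sanity: generator truth equals engine output for the complete digest
  stopifnot(identical(fragment_sizes(digest(sub$seq, reg[c("TaqII", "TaqIII")])),
                      sub$truth$fragment_sizes))
}

lane_tbl <- do.call(rbind, lanes)
write.table(lane_tbl, "results/digestion_lanes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, frag_rows), "results/digestion_fragments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Gel-lane emulation (fragment sizes, bp, descending):\n")
print(lane_tbl, row.names = FALSE)
cat("\nOn the single-site substrate TaqII leaves the 390-bp band intact while",
    "TaqIII cuts it; on the convergent substrate the two single-enzyme lanes",
    "differ and the two-enzyme lane is the union of their cuts.\n")
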