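#!/usr/bin/env Rscript
# Cleavage-site mapping by simulated run-off sequencing.
#
# A 497-bp analog of the sequencing substrate carries one CACCCA site. After
# cleavage, a read synthesizing the bottom strand terminates at the
# top-strand scissile bond and a read synthesizing the top strand terminates
# at the bottom-strand bond; the sequencing polymerase appends one
# template-independent base to each. Inverting the two termini recovers the
# cleavage geometry: 11 nt (top) / 9 nt (bottom) downstream of the site,
# i.e. a 2-nt 3'-protruding end.

suppressMessages(library(thermusRM))
dir.create("results", showWarnings = FALSE)

taqIII <- enzyme_registry()$TaqIII
sub <- make_substrate(497, data.frame(motif = "CACCCA", start = 240L,
                                      strand = "+"),
                      gc = 0.66, seed = 497L, id = "runoff_substrate")
site <- scan_sites(sub$seq, taqIII$motif)

rows <- list()
for (art in c(TRUE, FALSE)) {
  ot <- simulate_runoff(sub$seq, taqIII, site[1, ], "synthesizes-top", art)
  ob <- simulate_runoff(sub$seq, taqIII, site[1, ], "synthesizes-bottom", art)
  call <- infer_cleavage(ot, ob)
  rows[[length(rows) + 1L]] <- data.frame(
    plus_one_artifact = art,
    term_top_read = ot$termination_coord,
    term_bottom_read = ob$termination_coord,
    top_offset = call$top_offset, bottom_offset = call$bottom_offset,
    overhang = call$overhang_len, polarity = call$overhang_polarity)
}
tbl <- do.call(rbind, rows)
write.table(tbl, "results/runoff_inference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Run-off read termini and inferred cleavage geometry (site at",
    site$start[1], "+):\n")
print(tbl, row.names = FALSE)
cat("\nWith or without the +1 correction the inferred call is 11/9 with a",
    "2-nt 3'-protruding end; the artifact flag only shifts the raw termini.\n")

# single-read partial call: one offset, overhang undetermined
partial <- infer_cleavage(obs_top = simulate_runoff(sub$seq, taqIII, site[1, ],
                                                    "synthesizes-top"))
cat(sprintf("Single-read partial call: bottom offset %d, overhang undetermined.\n",
            partial$bottom_offset))
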