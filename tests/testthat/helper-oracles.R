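# Independent oracles, deliberately naive: every expectation they feed is
# checked against the package's optimized code paths.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force window scan on both strands; N in the substrate matches nothing
bf_scan <- function(seq_str, pattern, topology = "linear") {
  L <- nchar(seq_str)
  m <- nchar(pattern)
  ext <- if (topology == "circular" && m > 1L)
    paste0(seq_str, substr(seq_str, 1, m - 1)) else seq_str
  match_at <- function(pat) {
    pch <- strsplit(pat, "")[[1]]
    hits <- integer(0)
    if (nchar(ext) >= m) for (s in 0:(nchar(ext) - m)) {
      win <- strsplit(substr(ext, s + 1, s + m), "")[[1]]
      ok <- all(vapply(seq_len(m), function(i)
        win[i] != "N" && win[i] %in% IUPAC_SETS[[pch[i]]], logical(1)))
      if (ok) hits <- c(hits, s)
    }
    hits[hits < L]
  }
  plus <- match_at(pattern)
  minus <- match_at(rc_chr(pattern))
  df <- data.frame(start = c(plus, minus),
                   strand = c(rep("+", length(plus)), rep("-", length(minus))))
  df[order(df$start, df$strand), , drop = FALSE]
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# brute-force covariation verdict for one column/position pair
bf_covary_pair <- function(residues, bases) {
  keep <- which(bases != "N")
  if (length(keep) < 2) return(NULL)
  pr <- utils::combn(keep, 2)
  conc <- mapply(function(i, j)
    (residues[i] == residues[j]) == (bases[i] == bases[j]), pr[1, ], pr[2, ])
  varies <- length(unique(residues[keep])) > 1 || length(unique(bases[keep])) > 1
  list(score = mean(conc), perfect = all(conc) && varies)
}

# tiny GenBank flat-file fixture built in code
write_genbank_fixture <- function(path, seq, cds_lines) {
  body <- vapply(seq(1, nchar(seq), by = 60), function(i) {
    chunk <- substr(seq, i, min(i + 59, nchar(seq)))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    sprintf("%9d %s", i, tolower(trimws(grp)))
  }, character(1))
  writeLines(c(
    sprintf("LOCUS       TESTSEQ %d bp    DNA     linear   SYN 01-JAN-2020", nchar(seq)),
    "DEFINITION  synthetic fixture.",
    "FEATURES             Location/Qualifiers",
    cds_lines,
    "ORIGIN",
    body,
    "//"), path)
}
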