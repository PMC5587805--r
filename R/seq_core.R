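# Sequence data model, degenerate-motif scanning and small gene-level analytics.
# Coordinates are 0-based, half-open throughout; motif hits are reported by their
# top-strand start regardless of strand.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' DNA sequence object
#'
#' A minimal container for a DNA sequence with an identifier and topology.
#' The alphabet is restricted to A, C, G, T and N; anything else is rejected.
#'
#' @param seq Character scalar, the sequence (case-insensitive).
#' @param id Character scalar label.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `nuc_seq` with fields `id`, `seq`, `topology`.
#' @examples
#' s <- nuc_seq("TTCACCCATT")
#' nchar(s$seq)
#' @export
nuc_seq <- function(seq, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string")
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L)
    stop("invalid alphabet: sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(list(id = as.character(id), seq = seq, topology = topology),
            class = "nuc_seq")
}

as_nuc_seq <- function(x, topology = "linear") {
  if (inherits(x, "nuc_seq")) return(x)
  nuc_seq(x, topology = topology)
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s: %d bp (%s)\n", x$id, nchar(x$seq), x$topology))
  invisible(x)
}

#' IUPAC degenerate motif
#'
#' @param pattern Character scalar over the 15 IUPAC nucleotide codes.
#' @return Object of class `iupac_motif` with fields `pattern` and `length`.
#' @examples
#' iupac_motif("CACCCA")
#' @export
iupac_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("`pattern` must be a single character string")
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L) stop("motif length must be >= 1")
  letters_ <- strsplit(pattern, "")[[1]]
  if (!all(letters_ %in% names(IUPAC_CODES)))
    stop("invalid IUPAC code(s): ",
         paste(unique(letters_[!letters_ %in% names(IUPAC_CODES)]), collapse = ", "))
  structure(list(pattern = pattern, length = nchar(pattern)),
            class = "iupac_motif")
}

as_iupac_motif <- function(x) {
  if (inherits(x, "iupac_motif")) return(x)
  iupac_motif(x)
}

#' Reverse complement of a DNA string
#'
#' Accepts the full IUPAC alphabet (so motifs can be complemented too).
#'
#' @param x Character scalar or `nuc_seq`.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  if (inherits(x, "nuc_seq")) x <- x$seq
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Finds all occurrences of `motif` on the top strand (`+`) and of its reverse
#' complement (`-` strand occurrences, i.e. the motif read 5'->3' on the bottom
#' strand). Circular sequences are scanned across the origin; such hits are
#' reported with a start in `[0, len)`. An `N` in the substrate never matches
#' any motif letter.
#'
#' @param seq A `nuc_seq` (or plain string, taken as linear).
#' @param motif An `iupac_motif` (or plain pattern string).
#' @return A data frame with columns `start` (0-based top-strand start),
#'   `strand` (`"+"`/`"-"`) and `motif`, sorted by `start` then strand
#'   (`+` before `-`).
#' @examples
#' scan_sites(nuc_seq("TTCACCCATT"), "CACCCA")
#' @export
scan_sites <- function(seq, motif) {
  seq <- as_nuc_seq(seq)
  motif <- as_iupac_motif(motif)
  L <- nchar(seq$seq)
  if (L == 0L) stop("empty sequence")
  m <- motif$length
  subject_str <- seq$seq
  if (seq$topology == "circular" && L > 1L && m > 1L) {
    # duplicate the first (m - 1) bases past the end so origin-spanning
    # occurrences fall inside one linear scan
    subject_str <- paste0(subject_str, substr(subject_str, 1L, min(m - 1L, L)))
  }
  hits <- .scan_one_strand(subject_str, motif$pattern)
  hits_m <- .scan_one_strand(subject_str, revcomp(motif$pattern))
  starts <- c(hits, hits_m)
  strands <- c(rep("+", length(hits)), rep("-", length(hits_m)))
  keep <- starts < L  # starts >= L are origin duplicates
  starts <- starts[keep]; strands <- strands[keep]
  ord <- order(starts, strands)  # "+" < "-" in C locale
  out <- data.frame(start = starts[ord], strand = strands[ord],
                    motif = rep(motif$pattern, sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "motif_length") <- m
  attr(out, "seq_len") <- L
  attr(out, "topology") <- seq$topology
  out
}

# 0-based starts of `pattern` (IUPAC) on the given strand of `subject_str`.
# Biostrings does the degenerate matching; windows containing N are dropped
# afterwards (conservative matching: substrate N matches nothing).
.scan_one_strand <- function(subject_str, pattern) {
  m <- nchar(pattern)
  if (m > nchar(subject_str)) return(integer(0))
  mp <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject_str),
                                 fixed = c(pattern = FALSE, subject = TRUE))
  starts <- BiocGenerics::start(mp) - 1L
  if (length(starts)) {
    win <- substring(subject_str, starts + 1L, starts + m)
    starts <- starts[!grepl("N", win, fixed = TRUE)]
  }
  starts
}

#' G+C content of a sequence
#'
#' `N` bases are excluded from both numerator and denominator (with a warning
#' when present).
#'
#' @param seq A `nuc_seq` or string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("GCGC")
#' @export
gc_content <- function(seq) {
  seq <- as_nuc_seq(seq)
  if (nchar(seq$seq) == 0L) stop("empty sequence")
  ch <- strsplit(seq$seq, "")[[1]]
  n_n <- sum(ch == "N")
  if (n_n > 0L) {
    warning(sprintf("%d N base(s) excluded from G+C computation", n_n))
    ch <- ch[ch != "N"]
    if (length(ch) == 0L) stop("sequence contains only N")
  }
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Protein length implied by an ORF
#'
#' An ORF of `n` nucleotides (start codon through stop codon) encodes
#' `n / 3 - 1` amino acids, the stop codon contributing none.
#'
#' @param orf_nt_length Positive integer, divisible by 3, at least 6.
#' @return Integer amino-acid count.
#' @examples
#' orf_protein_length(3306)  # 1101
#' @export
orf_protein_length <- function(orf_nt_length) {
  n <- as.integer(orf_nt_length)
  if (is.na(n) || n < 6L) stop("ORF length must be an integer >= 6 (start + stop codon)")
  if (n %% 3L != 0L) stop("frame error: ORF length ", n, " is not divisible by 3")
  n %/% 3L - 1L
}

#' Count recognition sites of one or more motifs within a gene
#'
#' Total occurrence count over both strands across all motifs; used e.g. to
#' verify that a restriction-modification gene is devoid of its own (and its
#' paralog's) recognition sites.
#'
#' @param gene A `nuc_seq` or string.
#' @param motifs List (or character vector) of motifs.
#' @return Integer count.
#' @examples
#' count_self_sites("AAAA", c("GACCGA", "CACCCA"))  # 0
#' @export
count_self_sites <- function(gene, motifs) {
  gene <- as_nuc_seq(gene)
  if (is.character(motifs)) motifs <- as.list(motifs)
  sum(vapply(motifs, function(m) nrow(scan_sites(gene, m)), integer(1)))
}

## ---- File I/O -------------------------------------------------------------

#' Read DNA sequences from a FASTA file
#'
#' @param path File path.
#' @param topology Topology to assign to all records.
#' @return List of `nuc_seq`.
#' @export
read_fasta_dna <- function(path, topology = "linear") {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i)
    nuc_seq(as.character(ss[[i]]), id = names(ss)[i], topology = topology))
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_dna <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(ss) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a GenBank flat file (sequence and CDS features only)
#'
#' A deliberately minimal reader: it extracts the LOCUS name, the ORIGIN
#' sequence, and the location of every CDS feature (simple `a..b` and
#' `complement(a..b)` locations). All other features are ignored.
#'
#' @param path File path.
#' @param topology Override topology; default taken from the LOCUS line.
#' @return A list with `seq` (a `nuc_seq`) and `cds`, a data frame with
#'   columns `start`, `end` (0-based half-open) and `strand`.
#' @export
read_genbank <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "genbank"
  if (is.null(topology)) {
    topology <- if (length(locus) && grepl("circular", locus[1], ignore.case = TRUE))
      "circular" else "linear"
  }
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("no ORIGIN record in ", path)
  end_rec <- grep("^//", lines)
  end_rec <- end_rec[end_rec > ori[1]]
  seq_lines <- lines[(ori[1] + 1L):(if (length(end_rec)) end_rec[1] - 1L else length(lines))]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat <- grep("^FEATURES", lines)
  cds <- data.frame(start = integer(0), end = integer(0), strand = character(0),
                    stringsAsFactors = FALSE)
  if (length(feat)) {
    fl <- lines[(feat[1] + 1L):(ori[1] - 1L)]
    cds_lines <- grep("^\\s{5}CDS\\s", fl, value = TRUE)
    for (cl in cds_lines) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", cl))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) >= 2L) {
        a <- as.integer(nums[1]); b <- as.integer(nums[2])
        cds <- rbind(cds, data.frame(start = a - 1L, end = b, strand = strand,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  list(seq = nuc_seq(seq, id = id, topology = topology), cds = cds)
}

#' Write motif hits as a BED file
#'
#' BED is 0-based half-open, matching the package's internal convention.
#'
#' @param hits Data frame from [scan_sites()].
#' @param seq_id Chromosome/sequence name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(hits, seq_id, path) {
  m <- attr(hits, "motif_length")
  if (is.null(m)) m <- nchar(hits$motif)
  bed <- data.frame(chrom = seq_id,
                    chromStart = hits$start,
                    chromEnd = hits$start + m,
                    name = hits$motif,
                    score = 0L,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
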