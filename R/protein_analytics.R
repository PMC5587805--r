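# ProtParam-style physicochemical profiling, global pairwise comparison with
# domain-level difference mapping, and theoretical tryptic digestion.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein sequence object
#'
#' @param seq Amino-acid string over the 20 standard residues.
#' @param id Label.
#' @return Object of class `protein_seq`.
#' @export
protein_seq <- function(seq, id = "protein") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string")
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty protein sequence")
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% AA_STANDARD)
  if (length(bad))
    stop("non-standard amino acid letter(s) at position(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "")
  structure(list(id = as.character(id), seq = seq), class = "protein_seq")
}

as_protein_seq <- function(x, id = "protein") {
  if (inherits(x, "protein_seq")) return(x)
  protein_seq(x, id = id)
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s: %d aa\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path File path.
#' @return List of `protein_seq`.
#' @export
read_fasta_protein <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  lapply(seq_along(ss), function(i)
    protein_seq(as.character(ss[[i]]), id = names(ss)[i]))
}

# net charge at a given pH, Henderson-Hasselbalch with the Bjellqvist pK set
.net_charge <- function(counts, nterm_res, cterm_res, pH) {
  pos_pk <- c(Nterm = unname(
    if (nterm_res %in% names(PK_NTERM_BY_RESIDUE)) PK_NTERM_BY_RESIDUE[nterm_res]
    else PK_POSITIVE["Nterm"]),
    PK_POSITIVE[c("K", "R", "H")])
  neg_pk <- c(Cterm = unname(
    if (cterm_res %in% names(PK_CTERM_BY_RESIDUE)) PK_CTERM_BY_RESIDUE[cterm_res]
    else PK_NEGATIVE["Cterm"]),
    PK_NEGATIVE[c("D", "E", "C", "Y")])
  pos_n <- c(Nterm = 1, counts[c("K", "R", "H")])
  neg_n <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  sum(pos_n / (1 + 10^(pH - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - pH)))
}

#' Theoretical isoelectric point
#'
#' Bisection to net charge zero using the Bjellqvist/ExPASy pK set with
#' Henderson-Hasselbalch charge terms for D, E, C, Y, H, K, R and the
#' (residue-specific) termini. Bisection tolerance 1e-4 pH units.
#'
#' @param p A `protein_seq` or string.
#' @return pI estimate.
#' @export
theoretical_pI <- function(p) {
  p <- as_protein_seq(p)
  ch <- strsplit(p$seq, "")[[1]]
  counts <- table(factor(ch, levels = AA_STANDARD))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, ch[1], ch[length(ch)], mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' ProtParam-style physicochemical profile
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the instability index is `(10/L) * sum(DIWV(x_i, x_i+1))` over the
#' Guruprasad dipeptide weights, with the classical instability call at
#' index > 40; the aliphatic index is
#' `mole% Ala + 2.9 * mole% Val + 3.9 * (mole% Ile + mole% Leu)`.
#'
#' @param p A `protein_seq` or string.
#' @return Object of class `protein_profile` with fields `id`, `n_aa`,
#'   `mol_weight` (Da), `theoretical_pI`, `n_negative` (Asp+Glu),
#'   `n_positive` (Arg+Lys), `n_cys`, `instability_index`,
#'   `stability_call`, `aliphatic_index`.
#' @examples
#' protein_profile("ACDEFGHIKLMNPQRSTVWY")
#' @export
protein_profile <- function(p) {
  p <- as_protein_seq(p)
  ch <- strsplit(p$seq, "")[[1]]
  L <- length(ch)
  counts <- table(factor(ch, levels = AA_STANDARD))
  mw <- sum(AA_AVG_MASS[ch]) + WATER_AVG_MASS
  ii <- if (L >= 2L) {
    10 / L * sum(DIWV_TABLE[cbind(ch[-L], ch[-1])])
  } else 0
  ai <- 100 * (counts["A"] + 2.9 * counts["V"] + 3.9 * (counts["I"] + counts["L"])) / L
  structure(list(
    id = p$id,
    n_aa = L,
    mol_weight = unname(mw),
    theoretical_pI = theoretical_pI(p),
    n_negative = unname(counts["D"] + counts["E"]),
    n_positive = unname(counts["R"] + counts["K"]),
    n_cys = unname(counts["C"]),
    instability_index = unname(ii),
    stability_call = if (ii > 40) "unstable" else "stable",
    aliphatic_index = unname(ai)
  ), class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s\n", x$id))
  cat(sprintf("  No. of aa:           %d\n", x$n_aa))
  cat(sprintf("  Molecular weight:    %.3f kDa\n", x$mol_weight / 1000))
  cat(sprintf("  Theoretical pI:      %.2f\n", x$theoretical_pI))
  cat(sprintf("  Asp + Glu:           %d\n", x$n_negative))
  cat(sprintf("  Arg + Lys:           %d\n", x$n_positive))
  cat(sprintf("  Cysteines:           %d\n", x$n_cys))
  cat(sprintf("  Instability index:   %.2f (%s)\n", x$instability_index, x$stability_call))
  cat(sprintf("  Aliphatic index:     %.2f\n", x$aliphatic_index))
  invisible(x)
}

#' Domain map over a protein
#'
#' Ordered, non-overlapping domains in 1-based inclusive protein coordinates.
#'
#' @param name Character vector of domain names (typically from
#'   REase / helical / MTase / TRD).
#' @param start,end Integer vectors, 1-based inclusive.
#' @return Object of class `domain_map` (a data frame).
#' @export
domain_map <- function(name, start, end) {
  d <- data.frame(name = as.character(name), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  d <- d[order(d$start), , drop = FALSE]
  if (any(d$end < d$start)) stop("domain end before start")
  if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
    stop("domains overlap")
  rownames(d) <- NULL
  class(d) <- c("domain_map", "data.frame")
  d
}

.domain_of <- function(domains, pos) {
  if (is.null(domains)) return(rep(NA_character_, length(pos)))
  vapply(pos, function(p) {
    i <- which(domains$start <= p & domains$end >= p)
    if (length(i)) domains$name[i[1]] else "outside"
  }, character(1))
}

#' Global alignment report for two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via Biostrings.
#' By default percent identity uses the full alignment length as denominator
#' (gapped columns count as differences); `denominator = "shorter"` divides
#' by the shorter sequence length instead. Every difference (substitution or
#' indel column) is assigned to the domain containing its coordinate on
#' sequence `a`.
#'
#' @param a,b `protein_seq` objects or strings.
#' @param domains Optional `domain_map` defined on `a`.
#' @param denominator `"alignment"` or `"shorter"`.
#' @return Object of class `alignment_report`: `n_identical`,
#'   `alignment_length`, `percent_identity`, `differences` data frame
#'   (`a_pos`, `type`, `a_res`, `b_res`, `domain`), `per_domain` counts,
#'   `n_substitutions`, `n_indel_columns`.
#' @export
global_identity <- function(a, b, domains = NULL,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- as_protein_seq(a, "a"); b <- as_protein_seq(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$seq), Biostrings::AAString(b$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  aal <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  bal <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  alen <- length(aal)
  apos <- cumsum(aal != "-")  # a-coordinate of each column (last a residue seen)
  ident <- aal == bal & aal != "-"
  diffs <- which(!ident)
  type <- ifelse(aal[diffs] == "-", "insertion_in_b",
                 ifelse(bal[diffs] == "-", "deletion_in_b", "substitution"))
  dd <- data.frame(a_pos = pmax(apos[diffs], 1L), type = type,
                   a_res = aal[diffs], b_res = bal[diffs],
                   stringsAsFactors = FALSE)
  dd$domain <- .domain_of(domains, dd$a_pos)
  denom <- if (denominator == "alignment") alen else min(nchar(a$seq), nchar(b$seq))
  per_domain <- if (nrow(dd)) table(dd$domain) else table(character(0))
  structure(list(
    a = a$id, b = b$id,
    n_identical = sum(ident),
    alignment_length = alen,
    percent_identity = 100 * sum(ident) / denom,
    differences = dd,
    per_domain = per_domain,
    n_substitutions = sum(dd$type == "substitution"),
    n_indel_columns = sum(dd$type != "substitution")
  ), class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> %s vs %s: %.1f%% identity (%d/%d columns)\n",
              x$a, x$b, x$percent_identity, x$n_identical, x$alignment_length))
  cat(sprintf("  %d substitutions, %d indel columns\n",
              x$n_substitutions, x$n_indel_columns))
  if (length(x$per_domain)) {
    cat("  differences per domain:\n")
    print(x$per_domain)
  }
  invisible(x)
}

#' Theoretical tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. With
#' `missed_cleavages > 0`, peptides spanning up to that many internal
#' cleavage points are also reported.
#'
#' @param p A `protein_seq` or string.
#' @param missed_cleavages Integer 0-2.
#' @return Data frame with `peptide`, `start`, `end` (1-based inclusive) and
#'   `n_missed`.
#' @examples
#' tryptic_peptides("AKPR")$peptide  # "AKPR"
#' @export
tryptic_peptides <- function(p, missed_cleavages = 0L) {
  p <- as_protein_seq(p)
  missed_cleavages <- as.integer(missed_cleavages)
  if (missed_cleavages < 0L || missed_cleavages > 2L)
    stop("missed_cleavages must be 0, 1 or 2")
  ch <- strsplit(p$seq, "")[[1]]
  L <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & ch[cut_after + 1L] != "P" | cut_after == L]
  bounds <- c(0L, cut_after[cut_after < L], L)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  out <- data.frame(peptide = substring(p$seq, starts, ends),
                    start = starts, end = ends, n_missed = 0L,
                    stringsAsFactors = FALSE)
  if (missed_cleavages > 0L) {
    n <- length(starts)
    for (k in seq_len(missed_cleavages)) {
      i <- seq_len(max(0L, n - k))
      if (length(i))
        out <- rbind(out, data.frame(
          peptide = substring(p$seq, starts[i], ends[i + k]),
          start = starts[i], end = ends[i + k], n_missed = k,
          stringsAsFactors = FALSE))
    }
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Classify one protein's tryptic peptides against another's
#'
#' Marks each peptide of `pA` as shared (its exact sequence occurs among
#' `pB`'s peptides) or unique, and annotates the domain containing its start
#' coordinate.
#'
#' @param pA,pB Peptide tables from [tryptic_peptides()].
#' @param domains Optional `domain_map` on the protein behind `pA`.
#' @return List with `peptides` (pA's table plus `shared` and `domain`
#'   columns) and `summary` (counts of shared/unique, and unique-per-domain).
#' @export
classify_peptides <- function(pA, pB, domains = NULL) {
  stopifnot(is.data.frame(pA), is.data.frame(pB))
  pA$shared <- pA$peptide %in% pB$peptide
  pA$domain <- .domain_of(domains, pA$start)
  uniq <- pA[!pA$shared, , drop = FALSE]
  list(peptides = pA,
       summary = list(n_shared = sum(pA$shared),
                      n_unique = nrow(uniq),
                      unique_per_domain = if (nrow(uniq)) table(uniq$domain)
                                          else table(character(0))))
}
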