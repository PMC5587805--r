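# Recognition-element model for the TspGWI branch of the Thermus enzyme
# family: anchor residues at TaqII-numbered target-recognition-domain (TRD)
# positions are read off a pairwise global alignment and mapped to bases of
# the 7-position recognition frame (positions 0-6, position 5 being the
# methylated adenine) through a declarative residue -> base rule table.

#' TaqII-numbered anchor positions
#'
#' Coordinates (1-based protein positions in TaqII numbering) of the residues
#' that align with the base-contacting positions of the Type ISP enzymes
#' LlaGI/LlaBIII. `p3_aux` are the two glycines just downstream of the
#' position-3/4 loop; `p1_minor` are the MTase-domain minor-groove contacts.
#'
#' @return Named list of integer positions.
#' @export
taqII_anchor_positions <- function() {
  list(p6_small = 586L, p6_asn = 594L,
       p2_aux = 683L, p2_main = 688L,
       p0_a = 737L, p0_b = 777L,
       p3_main = 817L, p3_aux = c(823L, 824L),
       p1_minor = c(1056L, 1058L))
}

#' Reference for anchor extraction
#'
#' Couples a reference protein sequence with the anchor coordinate table.
#' The default reference is the package's synthetic TaqII-like scaffold (see
#' [synthetic_taqII_protein()]), which carries the documented anchor residues
#' at the documented TaqII coordinates over a synthetic background.
#'
#' @param seq A `protein_seq` (defaults to the synthetic TaqII scaffold).
#' @param anchors Anchor position list (defaults to [taqII_anchor_positions()]).
#' @return List with `seq` and `anchors`.
#' @export
taqII_reference <- function(seq = synthetic_taqII_protein(),
                            anchors = taqII_anchor_positions()) {
  list(seq = seq, anchors = anchors)
}

# flat vector of all anchor coordinates (one element per residue slot)
.anchor_slots <- function(anchors) {
  unlist(anchors, use.names = TRUE)
}

#' Extract anchor residues from a Thermus-family protein
#'
#' Globally aligns `protein` to the TaqII reference (BLOSUM62, affine gaps)
#' and reads off the residues at the alignment columns of each TaqII-numbered
#' anchor. The residues lying strictly between the position-3 contact anchors
#' (TaqII 817 and 823) form the position-4 loop; its length in excess of the
#' three-residue Type ISP spacing is the `insertion_len` (2 for TaqII and
#' TspGWI, 3 for TaqIII, 0 for an enzyme with no insertion).
#'
#' @param protein A `protein_seq` or plain amino-acid string.
#' @param reference A [taqII_reference()] list.
#' @return Object of class `anchor_map`: `residues` (named list, gap = `"-"`),
#'   `loop` (inter-anchor residue string), `insertion_len`, and
#'   `query_positions` (1-based positions in `protein` for each anchor slot).
#' @examples
#' am <- extract_anchors(synthetic_taqIII_protein())
#' am$residues$p0_a  # "P"
#' @export
extract_anchors <- function(protein, reference = taqII_reference()) {
  protein <- as_protein_seq(protein)
  refseq <- as_protein_seq(reference$seq)
  anchors <- reference$anchors

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein$seq), Biostrings::AAString(refseq$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  qal <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ral <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  nref <- nchar(refseq$seq)
  res_at <- character(nref)   # query residue aligned to each ref position
  qpos_at <- integer(nref)    # query coordinate (0 = gap)
  col_of <- integer(nref)     # alignment column of each ref position
  qp <- 0L; rp <- 0L
  for (i in seq_along(ral)) {
    if (qal[i] != "-") qp <- qp + 1L
    if (ral[i] != "-") {
      rp <- rp + 1L
      res_at[rp] <- if (qal[i] == "-") "-" else qal[i]
      qpos_at[rp] <- if (qal[i] == "-") 0L else qp
      col_of[rp] <- i
    }
  }

  slots <- .anchor_slots(anchors)
  residues <- lapply(anchors, function(pos) res_at[pos])
  qpositions <- lapply(anchors, function(pos) {
    q <- qpos_at[pos]; q[q == 0L] <- NA_integer_; q
  })
  placed <- sum(unlist(residues) != "-" & !is.na(unlist(residues)))
  if (placed < ceiling(0.8 * length(slots)))
    stop("low-confidence anchor placement: only ", placed, "/", length(slots),
         " anchors aligned to a residue")

  # residues strictly between the columns of ref 817 and ref 823
  c1 <- col_of[anchors$p3_main]
  c2 <- col_of[anchors$p3_aux[1]]
  loop_chars <- qal[(c1 + 1L):(c2 - 1L)]
  loop <- paste(loop_chars[loop_chars != "-"], collapse = "")
  insertion_len <- nchar(loop) - 3L
  if (!insertion_len %in% c(0L, 2L, 3L))
    warning("position-3/4 inter-anchor insertion length ", insertion_len,
            " is outside the characterized set {0, 2, 3}")

  structure(list(residues = residues, loop = loop,
                 insertion_len = insertion_len,
                 query_positions = qpositions,
                 protein_id = protein$id),
            class = "anchor_map")
}

#' @export
print.anchor_map <- function(x, ...) {
  cat(sprintf("<anchor_map> %s: insertion_len=%d, loop=%s\n",
              x$protein_id, x$insertion_len, x$loop))
  for (nm in names(x$residues))
    cat(sprintf("  %-9s %s\n", nm, paste(x$residues[[nm]], collapse = " ")))
  invisible(x)
}

## ---- Rule table -----------------------------------------------------------

.rule <- function(id, base, confidence, conditions = list(), special = NULL) {
  list(id = id, base = base, confidence = confidence,
       conditions = conditions, special = special)
}

#' Default amino-acid to base rule table for the TspGWI branch
#'
#' One ordered rule list per recognition position 0-6; evaluation is
#' first-match-wins and every position ends in a fallback, so degenerate
#' inputs degrade to `N` rather than erroring. Conditions name anchors (with
#' a 1-based index for multi-residue anchors, e.g. `"p1_minor[1]"`) and the
#' residue sets that satisfy them; position 4 uses the special loop patterns
#' `S.R` (recognize G) and `R.S` (recognize C), and position 5 is
#' unconditionally the methylatable adenine.
#'
#' @return Object of class `rule_table`: a list with one component per
#'   position `pos0` .. `pos6`.
#' @export
default_rule_table <- function() {
  rt <- list(
    pos0 = list(
      .rule("p0.argB_G", "G", "common", list(`p0_b` = "R")),
      .rule("p0.argA_C", "C", "common", list(`p0_a` = "R")),
      .rule("p0.proTyr_C", "C", "uncommon", list(`p0_a` = "P", `p0_b` = "Y")),
      .rule("p0.small_N", "N", "common",
            list(`p0_a` = c("S", "A", "G"), `p0_b` = c("S", "A", "G"))),
      .rule("p0.fallback", "N", "default")
    ),
    pos1 = list(
      .rule("p1.minor_large_A", "A", "common",
            list(`p1_minor[1]` = c("H", "K", "R"), `p1_minor[2]` = c("H", "K", "R"))),
      .rule("p1.fallback", "N", "default")
    ),
    pos2 = list(
      .rule("p2.lys_C", "C", "common", list(`p2_main` = "K")),
      .rule("p2.asn_T", "T", "common", list(`p2_main` = "N")),
      .rule("p2.fallback", "N", "default")
    ),
    pos3 = list(
      .rule("p3.his_C", "C", "common", list(`p3_main` = "H")),
      .rule("p3.acidic_G", "G", "common", list(`p3_main` = c("D", "E"))),
      .rule("p3.fallback", "N", "default")
    ),
    pos4 = list(
      .rule("p4.SxR_G", "G", "common", special = "loop_SxR"),
      .rule("p4.RxS_C", "C", "common", special = "loop_RxS"),
      .rule("p4.fallback", "N", "default")
    ),
    pos5 = list(
      .rule("p5.mtase_A", "A", "common", special = "always")
    ),
    pos6 = list(
      .rule("p6.nonspecific", "N", "common",
            list(`p6_small` = c("G", "A", "S"), `p6_asn` = "N")),
      .rule("p6.fallback", "N", "low-confidence")
    )
  )
  class(rt) <- "rule_table"
  rt
}

#' Read / write a rule table as YAML
#'
#' The rule table is a declarative config so uncharacterized homologs can be
#' screened with edited rules and no code changes.
#'
#' @param path YAML file path.
#' @return A `rule_table` (for the reader); `path` invisibly (writer).
#' @export
read_rule_table <- function(path) {
  raw <- yaml::read_yaml(path)
  rt <- lapply(raw, function(rules) lapply(rules, function(r) {
    .rule(r$id, r$base, r$confidence,
          conditions = if (is.null(r$conditions)) list() else
            lapply(r$conditions, function(x) as.character(unlist(x))),
          special = r$special)
  }))
  class(rt) <- "rule_table"
  rt
}

#' @rdname read_rule_table
#' @param rules A `rule_table`.
#' @export
write_rule_table <- function(rules, path) {
  raw <- lapply(unclass(rules), function(rl) lapply(rl, function(r) {
    out <- list(id = r$id, base = r$base, confidence = r$confidence)
    if (length(r$conditions)) out$conditions <- r$conditions
    if (!is.null(r$special)) out$special <- r$special
    out
  }))
  yaml::write_yaml(raw, path)
  invisible(path)
}

# residue for a condition key like "p0_a" or "p1_minor[2]"
.anchor_residue <- function(am, key) {
  ix <- 1L
  if (grepl("\\[", key)) {
    ix <- as.integer(sub(".*\\[(\\d+)\\].*", "\\1", key))
    key <- sub("\\[.*", "", key)
  }
  r <- am$residues[[key]]
  if (is.null(r)) NA_character_ else r[ix]
}

# loop windows matching S.R / R.S; returns 1-based window start offsets
.loop_matches <- function(loop, pattern) {
  n <- nchar(loop)
  if (n < 3L) return(integer(0))
  first <- substr(pattern, 1, 1); last <- substr(pattern, 3, 3)
  ch <- strsplit(loop, "")[[1]]
  which(ch[seq_len(n - 2L)] == first & ch[3:n] == last)
}

#' Predict a recognition motif from an anchor map
#'
#' Applies the rule table position by position (fixed order,
#' first-match-wins). Position 5 is always `A` (the MTase pocket flips and
#' methylates that adenine regardless of the TRD). The position-4 loop is
#' scanned in every register; if both the `S.R` and `R.S` patterns occur in
#' different registers the first match wins and the conflict is recorded in
#' the evidence.
#'
#' @param anchors An `anchor_map` from [extract_anchors()].
#' @param rules A `rule_table` (default [default_rule_table()]).
#' @param enzyme_branch Branch annotation; anything other than `"TspGWI"`
#'   triggers a scope warning (the rules are calibrated on the TspGWI branch
#'   and are not guaranteed for TspDTI-subfamily or Type ISP enzymes).
#' @return Object of class `motif_prediction`: `motif7` (7-character IUPAC
#'   string for positions 0-6), `trimmed` (flanking `N` removed), and
#'   `evidence` (one row per position: rule fired, base, confidence, anchors
#'   used, notes).
#' @examples
#' predict_motif(extract_anchors(synthetic_taqII_protein()))$trimmed  # "GACCGA"
#' @export
predict_motif <- function(anchors, rules = default_rule_table(),
                          enzyme_branch = "TspGWI") {
  stopifnot(inherits(anchors, "anchor_map"))
  if (!identical(enzyme_branch, "TspGWI"))
    warning("recognition rules are calibrated for the TspGWI branch of the ",
            "Thermus family; predictions for '", enzyme_branch,
            "' enzymes are out of the rules' validated scope")
  bases <- character(7)
  ev <- vector("list", 7)
  for (p in 0:6) {
    rl <- rules[[paste0("pos", p)]]
    fired <- NULL
    note <- ""
    for (r in rl) {
      ok <- if (!is.null(r$special)) {
        switch(r$special,
               always = TRUE,
               loop_SxR = length(.loop_matches(anchors$loop, "S.R")) > 0,
               loop_RxS = length(.loop_matches(anchors$loop, "R.S")) > 0,
               stop("unknown special predicate: ", r$special))
      } else if (length(r$conditions) == 0L) TRUE else {
        all(vapply(names(r$conditions), function(k) {
          res <- .anchor_residue(anchors, k)
          !is.na(res) && res %in% r$conditions[[k]]
        }, logical(1)))
      }
      if (ok) { fired <- r; break }
    }
    if (p == 4L) {
      sxr <- .loop_matches(anchors$loop, "S.R")
      rxs <- .loop_matches(anchors$loop, "R.S")
      if (length(sxr) && length(rxs))
        note <- sprintf("both S.R (at %s) and R.S (at %s) present; first rule wins",
                        paste(sxr, collapse = ","), paste(rxs, collapse = ","))
    }
    bases[p + 1L] <- fired$base
    ev[[p + 1L]] <- data.frame(
      position = p, base = fired$base, rule = fired$id,
      confidence = fired$confidence,
      anchors = paste(names(fired$conditions), collapse = ","),
      note = note, stringsAsFactors = FALSE)
  }
  motif7 <- paste(bases, collapse = "")
  trimmed <- sub("N+$", "", sub("^N+", "", motif7))
  structure(list(motif7 = motif7, trimmed = trimmed,
                 evidence = do.call(rbind, ev),
                 protein_id = anchors$protein_id),
            class = "motif_prediction")
}

#' @export
print.motif_prediction <- function(x, ...) {
  cat(sprintf("<motif_prediction> %s: 5'-%s-3' (frame %s)\n",
              x$protein_id, x$trimmed, x$motif7))
  invisible(x)
}

## ---- Covariation scan -----------------------------------------------------

#' Covariation scan of labelled TRD alignment columns against known motifs
#'
#' For every non-invariant alignment column and every motif position, tests
#' whether residue identity partitions the enzymes exactly as base identity
#' does. Enzymes with no specificity (`N`) at a motif position carry no base
#' observation and are excluded from that position's comparison. The score is
#' the fraction of enzyme pairs classified concordantly (same residue iff
#' same base), in `[0, 1]`; the `perfect` flag additionally requires that the
#' compared subset actually varies.
#'
#' @param alignment Character matrix of aligned residues, one row per enzyme
#'   (rownames = enzyme names), one column per alignment column.
#' @param motifs Character vector of 7-character framed motifs (position 5,
#'   i.e. string index 6, must be `A` in all of them), one per enzyme.
#' @return Data frame with `column`, `position` (0-based), `n_informative`,
#'   `score`, `perfect`.
#' @export
covary <- function(alignment, motifs) {
  if (!is.matrix(alignment)) alignment <- as.matrix(alignment)
  n <- nrow(alignment)
  if (n < 2L) stop("at least 2 enzymes with known motifs are required")
  if (length(motifs) != n) stop("one motif per alignment row is required")
  if (any(nchar(motifs) != 7L) || any(substr(motifs, 6, 6) != "A"))
    stop("framing error: motifs must be 7-position frames with A at position 5")

  pairs <- utils::combn(n, 2)
  out <- list()
  for (j in seq_len(ncol(alignment))) {
    colres <- alignment[, j]
    if (length(unique(colres)) < 2L) next  # invariant column
    for (p in 0:6) {
      basep <- substr(motifs, p + 1L, p + 1L)
      keep <- which(basep != "N")
      if (length(keep) < 2L) next
      kp <- pairs[, pairs[1, ] %in% keep & pairs[2, ] %in% keep, drop = FALSE]
      if (!ncol(kp)) next
      same_res <- colres[kp[1, ]] == colres[kp[2, ]]
      same_base <- basep[kp[1, ]] == basep[kp[2, ]]
      score <- mean(same_res == same_base)
      varies <- length(unique(colres[keep])) > 1L || length(unique(basep[keep])) > 1L
      out[[length(out) + 1L]] <- data.frame(
        column = j, position = p, n_informative = length(keep),
        score = score, perfect = (score == 1) && varies)
    }
  }
  if (!length(out))
    return(data.frame(column = integer(0), position = integer(0),
                      n_informative = integer(0), score = numeric(0),
                      perfect = logical(0)))
  do.call(rbind, out)
}
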