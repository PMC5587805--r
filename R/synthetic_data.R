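# Seed-deterministic generators for every input the pipeline needs at desk
# scale: PCR-like DNA substrates with planted recognition sites, run-off
# observation pairs, and TRD protein variants with controlled anchor
# residues. Ground-truth records are computed by arithmetic deliberately
# duplicated here, independent of the digest / run-off / predictor modules.

# evaluate `code` under `seed` without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.random_dna <- function(n, gc) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# independent occurrence counter: IUPAC pattern -> regex, both strands
.regex_for_motif <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  paste(vapply(ch, function(x) {
    set <- IUPAC_CODES[[x]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

.count_occurrences <- function(seq, pattern) {
  n_on <- function(s, pat) {
    m <- gregexpr(sprintf("(?=%s)", pat), s, perl = TRUE)[[1]]
    sum(m > 0)
  }
  pat <- .regex_for_motif(pattern)
  rcpat <- .regex_for_motif(revcomp(pattern))
  n_on(seq, pat) + n_on(seq, rcpat)
}

#' Generate a PCR-substrate analog with planted recognition sites
#'
#' Background bases are drawn at the requested G+C fraction (default 66%,
#' the composition of the source organism's restriction-modification genes);
#' the requested motifs are planted exactly (reverse-complemented for `-`
#' strand placements) and the background is re-rolled until it contains no
#' spurious occurrence of any planted motif on either strand (rejection
#' sampling, so background composition stays honest).
#'
#' The attached truth record (site list, expected scissile bonds, expected
#' complete-digest fragment sizes) is computed by arithmetic independent of
#' the digest engine.
#'
#' @param length Substrate length (bp).
#' @param placements Data frame with columns `motif`, `start` (0-based),
#'   `strand`; placements must not overlap.
#' @param topology `"linear"` or `"circular"`.
#' @param gc Background G+C fraction.
#' @param seed Integer seed; identical specs and seeds give byte-identical
#'   substrates.
#' @param systems Enzyme systems for the truth record; defaults to the
#'   registry entries whose motifs occur among the placements.
#' @param max_tries Rejection-sampling budget.
#' @param id Sequence id.
#' @return List with `seq` (a `nuc_seq`) and `truth` (list: `sites`,
#'   `cut_bonds`, `fragment_sizes`).
#' @examples
#' sub <- make_substrate(390, data.frame(motif = "CACCCA", start = 100,
#'                                       strand = "+"), seed = 1)
#' sub$truth$fragment_sizes
#' @export
make_substrate <- function(length, placements, topology = c("linear", "circular"),
                           gc = 0.66, seed = 1L, systems = NULL,
                           max_tries = 50L, id = "synthetic_substrate") {
  topology <- match.arg(topology)
  L <- as.integer(length)
  stopifnot(is.data.frame(placements),
            all(c("motif", "start", "strand") %in% names(placements)))
  placements$motif <- toupper(as.character(placements$motif))
  placements$start <- as.integer(placements$start)
  placements$strand <- as.character(placements$strand)
  mlen <- nchar(placements$motif)
  if (any(placements$start < 0L) ||
      (topology == "linear" && any(placements$start + mlen > L)))
    stop("placement spec error: motif outside substrate bounds")
  if (nrow(placements) > 1L) {
    iv <- placements[order(placements$start), ]
    ivl <- nchar(iv$motif)
    if (any(iv$start[-1] < iv$start[-nrow(iv)] + ivl[-nrow(iv)]))
      stop("placement spec error: placements overlap")
  }

  planted_per_motif <- table(placements$motif)
  seq <- NULL
  for (try in seq_len(max_tries)) {
    cand <- .with_seed(seed + (try - 1L) * 10007L, .random_dna(L, gc))
    for (i in seq_len(nrow(placements))) {
      ins <- if (placements$strand[i] == "+") placements$motif[i]
             else revcomp(placements$motif[i])
      substr(cand, placements$start[i] + 1L,
             placements$start[i] + nchar(ins)) <- ins
    }
    counts <- vapply(names(planted_per_motif), function(m)
      .count_occurrences(cand, m), numeric(1))
    if (all(counts == as.numeric(planted_per_motif))) { seq <- cand; break }
  }
  if (is.null(seq))
    stop("generation error: retry budget exhausted without a spurious-site-free background")

  # truth record: independently re-derived cut arithmetic
  if (is.null(systems)) {
    reg <- enzyme_registry()
    systems <- Filter(function(s) s$motif$pattern %in% placements$motif, reg)
  }
  if (inherits(systems, "enzyme_system")) systems <- list(systems)
  cb <- do.call(rbind, lapply(systems, function(sys) {
    pl <- placements[placements$motif == sys$motif$pattern, , drop = FALSE]
    if (!nrow(pl)) return(NULL)
    m <- nchar(sys$motif$pattern)
    top <- ifelse(pl$strand == "+",
                  pl$start + m + sys$top_offset,
                  pl$start - sys$bottom_offset)
    bottom <- ifelse(pl$strand == "+",
                     pl$start + m + sys$bottom_offset,
                     pl$start - sys$top_offset)
    data.frame(enzyme = sys$name, start = pl$start, strand = pl$strand,
               top_cut = top, bottom_cut = bottom, stringsAsFactors = FALSE)
  }))
  if (is.null(cb)) cb <- data.frame(enzyme = character(0), start = integer(0),
                                    strand = character(0), top_cut = integer(0),
                                    bottom_cut = integer(0))
  if (topology == "linear") {
    cleav <- cb$top_cut >= 0 & cb$top_cut <= L & cb$bottom_cut >= 0 & cb$bottom_cut <= L
  } else {
    cb$top_cut <- ((cb$top_cut %% L) + L) %% L
    cb$bottom_cut <- ((cb$bottom_cut %% L) + L) %% L
    cleav <- rep(TRUE, nrow(cb))
  }
  cb$cleavable <- cleav
  bonds <- sort(unique(cb$top_cut[cleav]))
  frag_sizes <- if (topology == "linear") {
    sort(diff(c(0L, bonds, L)), decreasing = TRUE)
  } else if (length(bonds) <= 1L) {
    L
  } else {
    sort(diff(c(bonds, bonds[1] + L)), decreasing = TRUE)
  }
  frag_sizes <- frag_sizes[frag_sizes > 0]

  list(seq = nuc_seq(seq, id = id, topology = topology),
       truth = list(sites = placements, cut_bonds = cb,
                    fragment_sizes = frag_sizes))
}

#' Generate a matched pair of run-off observations with known truth
#'
#' Builds the two strand-specific run-off reads across one cleaved site,
#' using termination arithmetic restated here independently of
#' [simulate_runoff()], and attaches the generating cleavage geometry as
#' ground truth.
#'
#' @param substrate A `nuc_seq` (or the list returned by [make_substrate()]).
#' @param system An `enzyme_system`.
#' @param site Optional site selector (one-row data frame / list with
#'   `start`, `strand`); required when the substrate has several cleavable
#'   sites.
#' @param plus_one_artifact Include the polymerase +1 artifact.
#' @return List with `obs_top`, `obs_bottom` (class `runoff_observation`) and
#'   `truth` (`top_offset`, `bottom_offset`, `overhang_len`,
#'   `overhang_polarity`).
#' @export
make_runoff_pair <- function(substrate, system, site = NULL,
                             plus_one_artifact = TRUE) {
  if (is.list(substrate) && !inherits(substrate, "nuc_seq") &&
      !is.null(substrate$seq)) substrate <- substrate$seq
  substrate <- as_nuc_seq(substrate)
  L <- nchar(substrate$seq)
  m <- system$motif$length
  if (is.null(site)) {
    hits <- scan_sites(substrate, system$motif)
    # independent cleavability screen
    ok <- vapply(seq_len(nrow(hits)), function(i) {
      s <- hits$start[i]
      tc <- if (hits$strand[i] == "+") s + m + system$top_offset else s - system$bottom_offset
      bc <- if (hits$strand[i] == "+") s + m + system$bottom_offset else s - system$top_offset
      substrate$topology == "circular" || (tc >= 0 && tc <= L && bc >= 0 && bc <= L)
    }, logical(1))
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits) == 0L) stop("no cleavable site on the substrate")
    if (nrow(hits) > 1L)
      stop("ambiguity error: multiple cleavable sites; supply `site`")
    site <- hits[1, ]
  }
  s <- as.integer(site$start); strand <- as.character(site$strand)
  art <- as.integer(isTRUE(plus_one_artifact))
  if (strand == "+") {
    top_cut <- s + m + system$top_offset
    bottom_cut <- s + m + system$bottom_offset
  } else {
    top_cut <- s - system$bottom_offset
    bottom_cut <- s - system$top_offset
  }
  obs_bottom <- structure(list(
    site = list(start = s, strand = strand, motif_length = m),
    read_direction = "synthesizes-bottom",
    termination_coord = top_cut - art,
    plus_one_artifact = art == 1L), class = "runoff_observation")
  obs_top <- structure(list(
    site = list(start = s, strand = strand, motif_length = m),
    read_direction = "synthesizes-top",
    termination_coord = bottom_cut - 1L + art,
    plus_one_artifact = art == 1L), class = "runoff_observation")
  ov <- system$top_offset - system$bottom_offset
  list(obs_top = obs_top, obs_bottom = obs_bottom,
       truth = list(top_offset = system$top_offset,
                    bottom_offset = system$bottom_offset,
                    overhang_len = abs(ov),
                    overhang_polarity = if (ov > 0) "3'" else if (ov < 0) "5'" else "blunt"))
}

## ---- Synthetic TRD protein scaffolds --------------------------------------

.scaffold_cache <- new.env(parent = emptyenv())

# Fixed synthetic background (1105 aa) carrying the documented TaqII anchor
# residues at the documented TaqII coordinates. The inter-anchor background
# is random protein sequence: these scaffolds are synthetic stand-ins, not
# the deposited TaqII/TaqIII/TspGWI sequences.
.base_scaffold_chars <- function() {
  if (!is.null(.scaffold_cache$base)) return(.scaffold_cache$base)
  ch <- .with_seed(620017L, sample(AA_STANDARD, 1105L, replace = TRUE))
  plant <- c(`586` = "G", `594` = "N", `683` = "S", `688` = "K",
             `737` = "S", `777` = "R",
             `817` = "H", `818` = "L", `819` = "T", `820` = "S", `821` = "A",
             `822` = "R", `823` = "G", `824` = "G",
             `1056` = "H", `1057` = "L", `1058` = "K")
  ch[as.integer(names(plant))] <- plant
  .scaffold_cache$base <- ch
  ch
}

.next_residue <- function(x, shift = 1L) {
  i <- match(x, AA_STANDARD)
  AA_STANDARD[((i - 1L + shift) %% 20L) + 1L]
}

#' Synthetic TaqII-like scaffold protein
#'
#' A 1105-aa synthetic protein carrying the documented TaqII anchor residues
#' (G586, N594, S683, K688, S737, R777, H817, the S820-x-R822 loop with the
#' characteristic 2-aa insertion, G823/G824, H1056, K1058) on a random
#' background. It is the default reference for [extract_anchors()] and the
#' base scaffold for [make_trd_variant()]. It is a synthetic stand-in: only
#' the anchor residues and their coordinates are the characterized ones.
#'
#' @return A `protein_seq`.
#' @export
synthetic_taqII_protein <- function() {
  protein_seq(paste(.base_scaffold_chars(), collapse = ""),
              id = "TaqII_synthetic_scaffold")
}

#' Synthetic TaqIII-like scaffold protein
#'
#' Derived from the TaqII scaffold by the documented anchor changes
#' (P737, Y777, the R820-x-S822 loop register with a 3-aa insertion) plus a
#' block of background substitutions and a short deletion confined to the
#' C-terminal TRD band, emulating the paralog pair's high global identity
#' with TRD-concentrated divergence. Final length 1101 aa.
#'
#' @return A `protein_seq`.
#' @export
synthetic_taqIII_protein <- function() {
  if (!is.null(.scaffold_cache$taqIII)) return(.scaffold_cache$taqIII)
  ch <- .base_scaffold_chars()
  ch[737] <- "P"; ch[777] <- "Y"
  # TRD-band substitutions (TaqII coords 956..1105), sparing the p1_minor
  # anchors and the deletion zone
  allowed <- setdiff(956:1105, c(1053:1061, 1088:1096))
  subs <- .with_seed(730301L, sort(sample(allowed, 61L)))
  ch[subs] <- .next_residue(ch[subs], 7L)
  # 3-aa insertion register: loop becomes L T R A S T between H817 and G823
  ch2 <- c(ch[1:817], c("L", "T", "R", "A", "S", "T"), ch[823:1089], ch[1095:1105])
  p <- protein_seq(paste(ch2, collapse = ""), id = "TaqIII_synthetic_scaffold")
  .scaffold_cache$taqIII <- p
  p
}

#' Synthetic TspGWI-like scaffold protein
#'
#' Derived from the TaqII scaffold by the documented anchor changes (A at the
#' 777 column, D at the 817 column; small residues leave position 0
#' unspecific), an insertion and a deletion away from the anchors, and
#' scattered background substitutions, emulating a more distant family
#' member. Final length 1097 aa.
#'
#' @return A `protein_seq`.
#' @export
synthetic_tspGWI_protein <- function() {
  if (!is.null(.scaffold_cache$tspGWI)) return(.scaffold_cache$tspGWI)
  ch <- .base_scaffold_chars()
  ch[777] <- "A"; ch[817] <- "D"
  protected <- c(295:305, 580:600, 678:695, 730:745, 770:785, 810:830,
                 895:922, 1050:1065)
  allowed <- setdiff(seq_along(ch), protected)
  subs <- .with_seed(911003L, sort(sample(allowed, 140L)))
  ch[subs] <- .next_residue(ch[subs], 5L)
  ch2 <- c(ch[1:300], strsplit("GASLDEKTNV", "")[[1]], ch[301:899], ch[918:1105])
  p <- protein_seq(paste(ch2, collapse = ""), id = "TspGWI_synthetic_scaffold")
  .scaffold_cache$tspGWI <- p
  p
}

#' Synthetic TaqII/TaqIII analog domain map
#'
#' Approximate domain bands for the 1105-aa scaffold, mirroring the
#' REase / helical / MTase / C-terminal TRD architecture of the family.
#'
#' @return A `domain_map`.
#' @export
synthetic_domain_map <- function() {
  domain_map(name = c("REase", "helical", "MTase", "TRD"),
             start = c(1L, 291L, 556L, 956L),
             end = c(290L, 555L, 955L, 1105L))
}

#' Plant anchor residues on the TaqII scaffold and state the expected motif
#'
#' Builds a TRD variant by overriding anchor residues (and/or the
#' position-3/4 loop) on the synthetic TaqII scaffold, and computes the
#' recognition motif such a variant should be assigned, using a restatement
#' of the residue -> base rules kept independent of the predictor module.
#'
#' @param overrides Named list; names among `p0_a`, `p0_b`, `p1_minor`
#'   (length-2), `p2_main`, `p2_aux`, `p3_main`, `p6_small`, `p6_asn`
#'   (single residues) and `loop` (replacement string for the residues
#'   between TaqII 817 and 823).
#' @param seed Unused placeholder for API symmetry; the construction is
#'   deterministic.
#' @return List with `protein` (a `protein_seq`) and `expected` (list
#'   `motif7`, `trimmed`).
#' @examples
#' v <- make_trd_variant(list(p3_main = "D"))
#' v$expected$motif7
#' @export
make_trd_variant <- function(overrides = list(), seed = 1L) {
  pos <- taqII_anchor_positions()
  valid <- c("p0_a", "p0_b", "p1_minor", "p2_main", "p2_aux", "p3_main",
             "p6_small", "p6_asn", "loop")
  bad <- setdiff(names(overrides), valid)
  if (length(bad))
    stop("override spec error: not a defined anchor: ", paste(bad, collapse = ", "))
  ch <- .base_scaffold_chars()
  anchors <- list(p0_a = ch[pos$p0_a], p0_b = ch[pos$p0_b],
                  p1_minor = ch[pos$p1_minor], p2_main = ch[pos$p2_main],
                  p2_aux = ch[pos$p2_aux], p3_main = ch[pos$p3_main],
                  p6_small = ch[pos$p6_small], p6_asn = ch[pos$p6_asn])
  loop <- paste(ch[818:822], collapse = "")
  for (nm in names(overrides)) {
    val <- toupper(as.character(overrides[[nm]]))
    if (nm == "loop") {
      loop <- paste(val, collapse = "")
    } else if (nm == "p1_minor") {
      if (length(val) != 2L) stop("p1_minor override must supply 2 residues")
      anchors$p1_minor <- val
    } else {
      if (length(val) != 1L || nchar(val) != 1L)
        stop("override for ", nm, " must be a single residue")
      anchors[[nm]] <- val
    }
  }
  if (!all(strsplit(loop, "")[[1]] %in% AA_STANDARD))
    stop("loop override contains non-standard residues")
  ch[pos$p0_a] <- anchors$p0_a; ch[pos$p0_b] <- anchors$p0_b
  ch[pos$p1_minor] <- anchors$p1_minor
  ch[pos$p2_main] <- anchors$p2_main; ch[pos$p2_aux] <- anchors$p2_aux
  ch[pos$p3_main] <- anchors$p3_main
  ch[pos$p6_small] <- anchors$p6_small; ch[pos$p6_asn] <- anchors$p6_asn
  ch2 <- c(ch[1:817], strsplit(loop, "")[[1]], ch[823:1105])
  protein <- protein_seq(paste(ch2, collapse = ""), id = "TRD_variant")
  expected <- .expected_motif_restatement(anchors, loop)
  list(protein = protein, expected = expected)
}

# Independent restatement of the recognition rules (plain conditionals; kept
# deliberately separate from the predictor's rule-table machinery).
.expected_motif_restatement <- function(a, loop) {
  lch <- strsplit(loop, "")[[1]]
  has_pat <- function(f, l) {
    n <- length(lch)
    n >= 3L && any(lch[seq_len(n - 2L)] == f & lch[3:n] == l)
  }
  b0 <- if (a$p0_b == "R") "G"
        else if (a$p0_a == "R") "C"
        else if (a$p0_a == "P" && a$p0_b == "Y") "C"
        else "N"
  b1 <- if (all(a$p1_minor %in% c("H", "K", "R"))) "A" else "N"
  b2 <- if (a$p2_main == "K") "C" else if (a$p2_main == "N") "T" else "N"
  b3 <- if (a$p3_main == "H") "C" else if (a$p3_main %in% c("D", "E")) "G" else "N"
  b4 <- if (has_pat("S", "R")) "G" else if (has_pat("R", "S")) "C" else "N"
  motif7 <- paste0(b0, b1, b2, b3, b4, "A", "N")
  list(motif7 = motif7,
       trimmed = sub("N+$", "", sub("^N+", "", motif7)))
}
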