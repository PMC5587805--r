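# Cleavage simulation for Type IIC/IIL enzymes that cut at fixed offsets
# downstream of an asymmetric recognition motif (11/9 for the Thermus family),
# producing fragment maps and end chemistry.
#
# Scissile bonds are encoded as the index of the base to their right
# (half-open convention), so fragment lengths are plain subtractions.

#' Enzyme definition: asymmetric motif plus downstream cut offsets
#'
#' The motif is written 5'->3' on the strand that carries the methylated
#' adenine. `top_offset`/`bottom_offset` are the distances, in nucleotides,
#' from the bond just 3' of the motif's terminal base to the scissile bond on
#' the motif strand and on the opposite strand respectively (11/9 for the
#' Thermus family, leaving 2-nt 3'-protruding ends).
#'
#' @param name Enzyme name.
#' @param motif Recognition motif (IUPAC string or `iupac_motif`).
#' @param top_offset,bottom_offset Non-negative integers,
#'   `top_offset >= bottom_offset`.
#' @param methyl_index 0-based index of the methylated adenine within the
#'   motif; the motif must have an A there.
#' @return Object of class `enzyme_system`.
#' @examples
#' enzyme_system("TaqIII", "CACCCA", 11, 9, methyl_index = 5)
#' @export
enzyme_system <- function(name, motif, top_offset = 11L, bottom_offset = 9L,
                          methyl_index = NULL) {
  motif <- as_iupac_motif(motif)
  top_offset <- as.integer(top_offset); bottom_offset <- as.integer(bottom_offset)
  if (bottom_offset < 0L || top_offset < bottom_offset)
    stop("offsets must satisfy top_offset >= bottom_offset >= 0")
  if (is.null(methyl_index)) {
    # default: last A of the motif
    a_pos <- which(strsplit(motif$pattern, "")[[1]] == "A")
    if (!length(a_pos)) stop("motif has no A; supply `methyl_index` explicitly")
    methyl_index <- a_pos[length(a_pos)] - 1L
  }
  methyl_index <- as.integer(methyl_index)
  if (methyl_index < 0L || methyl_index >= motif$length ||
      substr(motif$pattern, methyl_index + 1L, methyl_index + 1L) != "A")
    stop("motif position `methyl_index` must hold an A")
  structure(list(name = name, motif = motif, top_offset = top_offset,
                 bottom_offset = bottom_offset, methyl_index = methyl_index),
            class = "enzyme_system")
}

#' @export
print.enzyme_system <- function(x, ...) {
  cat(sprintf("<enzyme_system> %s: %s (%d/%d), m6A at motif index %d\n",
              x$name, x$motif$pattern, x$top_offset, x$bottom_offset,
              x$methyl_index))
  invisible(x)
}

#' Built-in Thermus-family enzyme registry
#'
#' TaqII = GACCGA(11/9), TaqIII = CACCCA(11/9), TspGWI = ACGGA(11/9).
#'
#' @return Named list of `enzyme_system`.
#' @export
enzyme_registry <- function() {
  list(
    TaqII  = enzyme_system("TaqII",  "GACCGA", 11L, 9L, methyl_index = 5L),
    TaqIII = enzyme_system("TaqIII", "CACCCA", 11L, 9L, methyl_index = 5L),
    TspGWI = enzyme_system("TspGWI", "ACGGA",  11L, 9L, methyl_index = 4L)
  )
}

#' Scissile-bond coordinates for one motif occurrence
#'
#' For a `+` strand site whose last motif base sits at top-strand index
#' `e = start + motif_length - 1`, the cuts are `top_cut = e + 1 + top_offset`
#' and `bottom_cut = e + 1 + bottom_offset`, both expressed as bond indices in
#' top-strand coordinates. `-` strand sites are the mirror image: the cut on
#' the top strand is `start - bottom_offset` and on the bottom strand
#' `start - top_offset`.
#'
#' On a linear substrate a site whose cut bonds fall outside `[0, seq_len]`
#' is present but not cleavable and `NULL` is returned (the enzyme cannot cut
#' past the end of the molecule); circular substrates wrap.
#'
#' @param site One hit: a one-row data frame or list with `start` and
#'   `strand`.
#' @param system An `enzyme_system`.
#' @param seq_len Substrate length.
#' @param topology `"linear"` or `"circular"`.
#' @return A list of class `cut_event` with `site`, `top_cut`, `bottom_cut`,
#'   `overhang`, or `NULL` when the site is not cleavable.
#' @examples
#' s <- list(start = 2L, strand = "+")
#' cut_positions(s, enzyme_registry()$TaqIII, seq_len = 30L)
#' @export
cut_positions <- function(site, system, seq_len, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!inherits(system, "enzyme_system")) stop("`system` must be an enzyme_system")
  start <- as.integer(site$start); strand <- as.character(site$strand)
  m <- system$motif$length
  if (is.na(start) || start < 0L ||
      (topology == "linear" && start > seq_len - m))
    stop("consistency error: site start ", start,
         " incompatible with motif length ", m, " and sequence length ", seq_len)
  if (!strand %in% c("+", "-")) stop("consistency error: strand must be '+' or '-'")
  if (strand == "+") {
    e <- start + m - 1L
    top_cut <- e + 1L + system$top_offset
    bottom_cut <- e + 1L + system$bottom_offset
  } else {
    top_cut <- start - system$bottom_offset
    bottom_cut <- start - system$top_offset
  }
  if (topology == "linear") {
    if (top_cut < 0L || top_cut > seq_len || bottom_cut < 0L || bottom_cut > seq_len)
      return(NULL)  # site present, not cleavable
  } else {
    top_cut <- ((top_cut %% seq_len) + seq_len) %% seq_len
    bottom_cut <- ((bottom_cut %% seq_len) + seq_len) %% seq_len
  }
  structure(list(site = list(start = start, strand = strand),
                 top_cut = top_cut, bottom_cut = bottom_cut,
                 overhang = system$top_offset - system$bottom_offset),
            class = "cut_event")
}

#' Digest a substrate with one or more enzymes
#'
#' In `complete` mode every cleavable site of every system is cut. In
#' `partial` mode exactly the sites named in `site_subset` (row indices into
#' the combined site table, see the `sites` component of the result) are cut,
#' modelling the characteristically incomplete digestion of the Thermus
#' family. Sites flagged as methylated are never cut when
#' `respect_methylation` is on (restriction-modification self-protection).
#'
#' @param seq A `nuc_seq` or string.
#' @param systems An `enzyme_system` or list of them.
#' @param mode `"complete"` or `"partial"`.
#' @param site_subset Integer indices of sites to cut (partial mode).
#' @param methylated Optional integer indices of methylated sites.
#' @param respect_methylation If `TRUE`, methylated sites are not cut.
#' @return Object of class `digest_result`: `fragments` data frame (`start`,
#'   `end`, `top_len`, `bottom_len`, `left_end`, `right_end`), `junctions`
#'   data frame (`top_cut`, `bottom_cut`, `overhang`, `polarity`), the site
#'   table (`sites`, with `cleavable` flags), and `complete`.
#' @examples
#' d <- digest(nuc_seq(strrep("A", 40)), enzyme_registry()$TaqIII)
#' fragment_sizes(d)
#' @export
digest <- function(seq, systems, mode = c("complete", "partial"),
                   site_subset = NULL, methylated = integer(0),
                   respect_methylation = FALSE) {
  mode <- match.arg(mode)
  seq <- as_nuc_seq(seq)
  if (inherits(systems, "enzyme_system")) systems <- list(systems)
  L <- nchar(seq$seq)

  sites <- do.call(rbind, lapply(systems, function(sys) {
    h <- scan_sites(seq, sys$motif)
    if (nrow(h)) h$enzyme <- sys$name else h$enzyme <- character(0)
    h
  }))
  if (is.null(sites)) sites <- data.frame(start = integer(0), strand = character(0),
                                          motif = character(0), enzyme = character(0))
  rownames(sites) <- NULL
  sysbyname <- stats::setNames(systems, vapply(systems, `[[`, "", "name"))

  events <- vector("list", nrow(sites))
  cleavable <- logical(nrow(sites))
  if (nrow(sites)) for (i in seq_len(nrow(sites))) {
    ev <- cut_positions(sites[i, ], sysbyname[[sites$enzyme[i]]], L, seq$topology)
    events[[i]] <- ev
    cleavable[i] <- !is.null(ev)
  }
  sites$cleavable <- cleavable
  if (respect_methylation && length(methylated)) {
    cleavable[intersect(seq_len(nrow(sites)), methylated)] <- FALSE
    sites$methylated <- seq_len(nrow(sites)) %in% methylated
  }

  selected <- if (mode == "complete") which(cleavable) else {
    if (is.null(site_subset)) integer(0) else {
      site_subset <- as.integer(site_subset)
      if (any(site_subset < 1L | site_subset > nrow(sites)))
        stop("site_subset references unknown site(s)")
      site_subset[cleavable[site_subset]]
    }
  }

  evs <- events[selected]
  # coinciding scissile bonds count once
  if (length(evs)) {
    tc <- vapply(evs, `[[`, integer(1), "top_cut")
    evs <- evs[!duplicated(tc)]
    evs <- evs[order(vapply(evs, `[[`, integer(1), "top_cut"))]
  }

  res <- .assemble_fragments(L, seq$topology, evs)
  res$sites <- sites
  res$complete <- (mode == "complete")
  res$substrate <- seq$id
  res$topology <- seq$topology
  class(res) <- "digest_result"
  res
}

.assemble_fragments <- function(L, topology, evs) {
  n <- length(evs)
  tcut <- vapply(evs, `[[`, integer(1), "top_cut")
  bcut <- vapply(evs, `[[`, integer(1), "bottom_cut")
  ov <- vapply(evs, `[[`, integer(1), "overhang")
  junctions <- data.frame(top_cut = tcut, bottom_cut = bcut, overhang = ov,
                          polarity = ifelse(ov > 0, "3'", ifelse(ov < 0, "5'", "blunt")))
  if (topology == "linear") {
    tb <- c(0L, tcut, L); bb <- c(0L, bcut, L)
    frag <- data.frame(start = tb[-length(tb)], end = tb[-1])
    frag$top_len <- frag$end - frag$start
    frag$bottom_len <- bb[-1] - bb[-length(bb)]
    ends <- c("blunt", junctions$polarity)
    frag$left_end <- ends
    frag$right_end <- c(junctions$polarity, "blunt")
    frag <- frag[frag$top_len > 0L | frag$bottom_len > 0L, , drop = FALSE]
    rownames(frag) <- NULL
  } else if (n == 0L) {
    frag <- data.frame(start = 0L, end = L, top_len = L, bottom_len = L,
                       left_end = "circular", right_end = "circular")
  } else if (n == 1L) {
    # one cut linearizes the circle into a single full-length fragment
    frag <- data.frame(start = tcut, end = tcut + L, top_len = L, bottom_len = L,
                       left_end = junctions$polarity, right_end = junctions$polarity)
  } else {
    tb <- tcut; nxt <- c(tb[-1], tb[1] + L)
    bb <- bcut; bnxt <- c(bb[-1], bb[1] + L)
    frag <- data.frame(start = tb, end = nxt)
    frag$top_len <- frag$end - frag$start
    frag$bottom_len <- bnxt - bb
    frag$left_end <- junctions$polarity
    frag$right_end <- c(junctions$polarity[-1], junctions$polarity[1])
  }
  list(fragments = frag, junctions = junctions)
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s (%s): %d site(s), %d fragment(s)%s\n",
              x$substrate, x$topology, nrow(x$sites), nrow(x$fragments),
              if (x$complete) ", complete digest" else ", partial digest"))
  print(x$fragments)
  invisible(x)
}

#' Gel-lane fragment sizes
#'
#' @param result A `digest_result`.
#' @return Top-strand fragment lengths in descending order, as a gel lane
#'   would order them.
#' @export
fragment_sizes <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  sort(result$fragments$top_len, decreasing = TRUE)
}

#' Enumerate all partial digests of a substrate
#'
#' Produces the digest for every subset of cleavable sites (all `2^k`
#' subsets). Capped at `k <= max_k` sites.
#'
#' @param seq Substrate.
#' @param systems Enzyme system(s).
#' @param max_k Cap on the number of cleavable sites (default 12).
#' @return List of `digest_result`, one per subset; each carries a `subset`
#'   attribute with the site indices cut.
#' @export
enumerate_partial_digests <- function(seq, systems, max_k = 12L) {
  full <- digest(seq, systems, mode = "complete")
  k_idx <- which(full$sites$cleavable)
  k <- length(k_idx)
  if (k > max_k)
    stop("partial-digest enumeration capped at 2^", max_k, " subsets (", k,
         " cleavable sites found)")
  subsets <- lapply(0:(2^k - 1L), function(mask) k_idx[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0])
  lapply(subsets, function(ss) {
    r <- digest(seq, systems, mode = "partial", site_subset = ss)
    attr(r, "subset") <- ss
    r
  })
}

#' Write digest fragments as TSV
#'
#' Columns: start, end, length, left_end, right_end (0-based half-open).
#'
#' @param result A `digest_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(result, path) {
  f <- result$fragments
  out <- data.frame(start = f$start, end = f$end, length = f$top_len,
                    left_end = f$left_end, right_end = f$right_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
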