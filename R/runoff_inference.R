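# Run-off Sanger logic: a polymerase copying one strand of a cleaved substrate
# stops where its template ends, so read termini reveal scissile bonds. Most
# sequencing polymerases then append a single template-independent base
# (the "+1 artifact"), which shifts the apparent terminus by one position in
# the direction of travel.
#
# Conventions (top-strand coordinates, bonds encoded as the index of the base
# to their right):
#   * a read that synthesizes the bottom strand travels towards decreasing
#     coordinates and runs off at the top-strand cut bond `t`; its last
#     templated base is index `t`, and the +1 artifact lands at `t - 1`.
#   * a read that synthesizes the top strand travels towards increasing
#     coordinates and runs off at the bottom-strand cut bond `b`; its last
#     templated base is index `b - 1`, and the artifact lands at `b`.

#' Simulate a run-off sequencing observation across a cleaved terminus
#'
#' @param substrate A `nuc_seq` or string.
#' @param system An `enzyme_system`.
#' @param site One site (list/one-row data frame with `start`, `strand`),
#'   as returned by [scan_sites()].
#' @param read_direction `"synthesizes-bottom"` (reverse-primer read, as used
#'   to map the top-strand cut) or `"synthesizes-top"`.
#' @param plus_one_artifact Model the single template-independent base added
#'   by the polymerase (default `TRUE`).
#' @return Object of class `runoff_observation` with fields `site`,
#'   `read_direction`, `termination_coord` (0-based coordinate of the last
#'   base implied by the read, artifact included) and `plus_one_artifact`.
#' @examples
#' s <- nuc_seq(paste0("TT", "CACCCA", strrep("G", 22)))
#' site <- scan_sites(s, "CACCCA")[1, ]
#' simulate_runoff(s, enzyme_registry()$TaqIII, site, "synthesizes-bottom")
#' @export
simulate_runoff <- function(substrate, system, site,
                            read_direction = c("synthesizes-bottom", "synthesizes-top"),
                            plus_one_artifact = TRUE) {
  read_direction <- match.arg(read_direction)
  substrate <- as_nuc_seq(substrate)
  L <- nchar(substrate$seq)
  ev <- cut_positions(site, system, L, substrate$topology)
  if (is.null(ev)) stop("site is not cleavable on this substrate")
  term <- if (read_direction == "synthesizes-bottom") {
    ev$top_cut - as.integer(plus_one_artifact)
  } else {
    ev$bottom_cut - 1L + as.integer(plus_one_artifact)
  }
  if (term < 0L || term >= L)
    stop("termination coordinate ", term, " outside substrate bounds")
  structure(list(site = list(start = as.integer(site$start),
                             strand = as.character(site$strand),
                             motif_length = system$motif$length),
                 read_direction = read_direction,
                 termination_coord = term,
                 plus_one_artifact = isTRUE(plus_one_artifact)),
            class = "runoff_observation")
}

#' Infer cleavage geometry from a pair of run-off observations
#'
#' Inverts [simulate_runoff()]: subtracts the +1 artifact where flagged,
#' converts termination coordinates back to scissile-bond coordinates, and
#' expresses each bond as nucleotides downstream of the recognition motif's
#' terminal (methylated-A) base. Supplying only one observation yields a
#' partial call: one offset, overhang undetermined.
#'
#' @param obs_top Observation from a top-synthesizing read (reveals the
#'   bottom-strand cut), or `NULL`.
#' @param obs_bottom Observation from a bottom-synthesizing read (reveals the
#'   top-strand cut), or `NULL`.
#' @return Object of class `cleavage_call`: `top_offset`, `bottom_offset`,
#'   `overhang_len`, `overhang_polarity` (`"3'"`, `"5'"` or `"blunt"`; `NA`
#'   for partial calls).
#' @export
infer_cleavage <- function(obs_top = NULL, obs_bottom = NULL) {
  if (is.null(obs_top) && is.null(obs_bottom))
    stop("at least one observation is required")
  for (o in list(obs_top, obs_bottom))
    if (!is.null(o) && !inherits(o, "runoff_observation"))
      stop("observations must be runoff_observation objects")
  if (!is.null(obs_top) && obs_top$read_direction != "synthesizes-top")
    stop("consistency error: `obs_top` must come from a top-synthesizing read")
  if (!is.null(obs_bottom) && obs_bottom$read_direction != "synthesizes-bottom")
    stop("consistency error: `obs_bottom` must come from a bottom-synthesizing read")
  if (!is.null(obs_top) && !is.null(obs_bottom)) {
    if (!identical(obs_top$site[c("start", "strand")],
                   obs_bottom$site[c("start", "strand")]))
      stop("consistency error: observations refer to different sites")
  }
  site <- if (!is.null(obs_top)) obs_top$site else obs_bottom$site
  s <- site$start; m <- site$motif_length

  top_cut <- if (!is.null(obs_bottom))
    obs_bottom$termination_coord + as.integer(obs_bottom$plus_one_artifact) else NA_integer_
  bottom_cut <- if (!is.null(obs_top))
    obs_top$termination_coord + 1L - as.integer(obs_top$plus_one_artifact) else NA_integer_

  if (site$strand == "+") {
    ref <- s + m  # bond just 3' of the methylated A
    top_offset <- top_cut - ref
    bottom_offset <- bottom_cut - ref
  } else {
    top_offset <- s - bottom_cut
    bottom_offset <- s - top_cut
  }
  for (v in c(top_offset, bottom_offset))
    if (!is.na(v) && v < 0L)
      stop("geometry error: inferred negative cleavage offset (", v, ")")

  if (is.na(top_offset) || is.na(bottom_offset)) {
    call <- list(top_offset = top_offset, bottom_offset = bottom_offset,
                 overhang_len = NA_integer_, overhang_polarity = NA_character_,
                 partial = TRUE)
  } else {
    ov <- top_offset - bottom_offset
    call <- list(top_offset = top_offset, bottom_offset = bottom_offset,
                 overhang_len = abs(ov),
                 overhang_polarity = if (ov > 0) "3'" else if (ov < 0) "5'" else "blunt",
                 partial = FALSE)
  }
  structure(call, class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  if (isTRUE(x$partial)) {
    cat(sprintf("<cleavage_call> partial: top_offset=%s, bottom_offset=%s, overhang undetermined\n",
                x$top_offset, x$bottom_offset))
  } else {
    cat(sprintf("<cleavage_call> %d/%d, %d nt %s\n", x$top_offset, x$bottom_offset,
                x$overhang_len,
                if (x$overhang_len == 0) "blunt" else paste0(x$overhang_polarity, "-protruding")))
  }
  invisible(x)
}
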