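# Golden-Gate oligo construction, Type IIS digestion simulation, and
# multiplex mini-CRISPR array assembly.
#
# Oligo layout (top strand, 5'->3'):
#   prime5 . SITE . x . OH5 . spacer . OH3 . y . rc(SITE) . prime3
# where SITE is the enzyme recognition sequence (BsaI GGTCTC / Esp3I CGTCTC),
# x/y are 1-nt offset bases (both enzymes cut 1 nt downstream of their site on
# the top strand and 5 nt on the bottom, leaving 4-nt 5' overhangs), and
# OH5/OH3 are the programmable overhangs that direct ligation into the
# receiving repeat-spacer cassette.

ENZYME_SITES <- c(BsaI = "GGTCTC", Esp3I = "CGTCTC")

#' Golden-Gate flank configuration
#'
#' Priming and overhang sequences are experiment-specific (they live in the
#' cloning design, not in this package); the shipped example configuration is
#' a synthetic stand-in. Priming sequences must be free of the chosen enzyme's
#' recognition site in both orientations.
#'
#' @param prime5,prime3 PCR priming sequences added 5' and 3'.
#' @param enzyme `"BsaI"` or `"Esp3I"`.
#' @param overhang5,overhang3 4-nt Golden-Gate overhangs.
#' @param spacer_site_offset nt between recognition site and cut (1 for both).
#' @return Object of class `flank_config`.
#' @export
flank_config <- function(prime5, prime3, enzyme = c("BsaI", "Esp3I"),
                         overhang5, overhang3, spacer_site_offset = 1L) {
  enzyme <- match.arg(enzyme)
  prime5 <- toupper(prime5); prime3 <- toupper(prime3)
  overhang5 <- toupper(overhang5); overhang3 <- toupper(overhang3)
  site <- ENZYME_SITES[[enzyme]]
  if (nchar(overhang5) != 4L || nchar(overhang3) != 4L)
    stop("overhangs must be 4 nt", call. = FALSE)
  for (p in c(prime5, prime3))
    if (grepl(site, p, fixed = TRUE) || grepl(revcomp(site), p, fixed = TRUE))
      stop("priming sequence contains the ", enzyme, " recognition site",
           call. = FALSE)
  if (overhang5 == overhang3 || overhang5 == revcomp(overhang5) ||
      overhang3 == revcomp(overhang3) || overhang5 == revcomp(overhang3))
    warning("overhang collision: identical or palindromic overhangs can ",
            "ligate in the wrong orientation", call. = FALSE)
  structure(list(prime5 = prime5, prime3 = prime3, enzyme = enzyme,
                 site = site, overhang5 = overhang5, overhang3 = overhang3,
                 spacer_site_offset = as.integer(spacer_site_offset)),
            class = "flank_config")
}

#' Build a Golden-Gate oligo for one guide
#'
#' Refuses (with the offending position) spacers containing the enzyme's
#' recognition site in either orientation; no silent fixes.
#'
#' @param guide A manifest row (needs `guide_id`, `spacer`) or a spacer string.
#' @param flanks A [flank_config()].
#' @return Object of class `oligo_construct`: list(guide_id, spacer, oligo,
#'   length).
#' @export
make_oligo <- function(guide, flanks) {
  stopifnot(inherits(flanks, "flank_config"))
  if (is.character(guide)) guide <- list(guide_id = guide, spacer = guide)
  spacer <- toupper(guide$spacer)
  for (motif in c(flanks$site, revcomp(flanks$site))) {
    pos <- regexpr(motif, spacer, fixed = TRUE)
    if (pos > 0)
      stop("spacer for ", guide$guide_id %||% "guide", " contains ",
           flanks$enzyme, " site (", motif, ") at position ", pos,
           call. = FALSE)
  }
  pad <- strrep("A", flanks$spacer_site_offset)
  oligo <- paste0(flanks$prime5, flanks$site, pad, flanks$overhang5, spacer,
                  flanks$overhang3, revcomp(pad), revcomp(flanks$site),
                  flanks$prime3)
  structure(list(guide_id = guide$guide_id %||% spacer, spacer = spacer,
                 oligo = oligo, length = nchar(oligo)),
            class = "oligo_construct")
}

#' Simulate Type IIS digestion of a linear oligo
#'
#' Both enzymes cut outside their recognition site (top strand
#' `spacer_site_offset` nt downstream, bottom strand 4 nt further), leaving
#' 4-nt 5' overhangs. Each duplex fragment is reported with its full extent
#' (it keeps the staggered overhangs generated on its side away from the
#' recognition site), so the insert released from a [make_oligo()] construct
#' is exactly `overhang5 + spacer + overhang3`. Fragment extents partition
#' the input.
#'
#' @param oligo An `oligo_construct` or a sequence string.
#' @param enzyme `"BsaI"` or `"Esp3I"`.
#' @param spacer_site_offset nt between site and cut (default 1).
#' @return data.frame: fragment sequence, start, end (0-based half-open on
#'   the top strand), overhang_left, overhang_right (the 4-nt overhang
#'   sequences in top-strand letters; NA at molecule ends and blunt cuts).
#' @export
simulate_digest <- function(oligo, enzyme = c("BsaI", "Esp3I"),
                            spacer_site_offset = 1L) {
  enzyme <- match.arg(enzyme)
  seq <- if (inherits(oligo, "oligo_construct")) oligo$oligo else toupper(oligo)
  site <- ENZYME_SITES[[enzyme]]
  k <- nchar(site)
  fwd <- .motif_starts(seq, site)
  rev_ <- .motif_starts(seq, revcomp(site))
  # One boundary per cut pair, placed at the cut away from the recognition
  # site so that the overhang travels with the released fragment. "side"
  # records where the 4-nt overhang sits relative to the boundary.
  b_fwd <- fwd + k + spacer_site_offset       # overhang on the right
  b_rev <- rev_ - spacer_site_offset          # overhang on the left
  cuts <- data.frame(pos = c(b_fwd, b_rev),
                     side = rep(c("right", "left"),
                                c(length(b_fwd), length(b_rev))))
  cuts <- cuts[cuts$pos > 0 & cuts$pos < nchar(seq), , drop = FALSE]
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  bounds <- c(0L, cuts$pos, nchar(seq))
  nfrag <- length(bounds) - 1L
  oh_at <- function(i) {  # overhang at internal boundary i (between frag i, i+1)
    if (cuts$side[i] == "right") substr(seq, cuts$pos[i] + 1L, cuts$pos[i] + 4L)
    else substr(seq, cuts$pos[i] - 3L, cuts$pos[i])
  }
  ohs <- if (nrow(cuts)) vapply(seq_len(nrow(cuts)), oh_at, "") else character(0)
  data.frame(
    fragment = substring(seq, head(bounds, -1) + 1L, bounds[-1]),
    start = head(bounds, -1), end = bounds[-1],
    overhang_left = c(NA_character_, ohs),
    overhang_right = c(ohs, NA_character_),
    stringsAsFactors = FALSE)
}

#' Assemble a multiplex mini-CRISPR array
#'
#' Repeat-led alternation `R S1 R S2 ... Sn R`: `n` spacers imply `n + 1`
#' repeats. Mixing repression- and cleavage-length spacers is refused unless
#' `allow_mixed_modes = TRUE`; multiplexed arrays in practice carry
#' mode-homogeneous tgRNAs.
#'
#' @param spacers Character vector of spacers (1..max_spacers).
#' @param repeat_seq Repeat sequence (configuration value, not a constant).
#' @param promoter_label Optional label (e.g. `"P_xylA"`, `"P_RplsWT"`).
#' @param max_spacers Maximum multiplexing degree (default 10).
#' @param mode_boundary Switch point used for the mode-homogeneity check.
#' @param allow_mixed_modes Permit mixing repression and cleavage spacers.
#' @return Object of class `crispr_array`: list(repeat_seq, spacers,
#'   assembled, promoter_label).
#' @export
build_array <- function(spacers, repeat_seq, promoter_label = NULL,
                        max_spacers = 10L, mode_boundary = 26L,
                        allow_mixed_modes = FALSE) {
  spacers <- toupper(spacers)
  repeat_seq <- toupper(repeat_seq)
  if (!nzchar(repeat_seq)) stop("repeat must be non-empty", call. = FALSE)
  n <- length(spacers)
  if (n < 1L || n > max_spacers)
    stop("need between 1 and ", max_spacers, " spacers", call. = FALSE)
  if (any(!nzchar(spacers))) stop("empty spacer", call. = FALSE)
  if (anyDuplicated(spacers))
    warning("duplicate spacers in array", call. = FALSE)
  modes <- classify_mode(nchar(spacers), mode_boundary)
  if (length(unique(modes)) > 1L && !allow_mixed_modes)
    stop("array mixes repression and cleavage spacers; set ",
         "allow_mixed_modes = TRUE to permit", call. = FALSE)
  assembled <- paste0(repeat_seq,
                      paste0(spacers, repeat_seq, collapse = ""))
  structure(list(repeat_seq = repeat_seq, spacers = spacers,
                 assembled = assembled,
                 promoter_label = promoter_label),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %d spacer(s), %d repeats, %d bp%s\n",
              length(x$spacers), length(x$spacers) + 1L,
              nchar(x$assembled),
              if (is.null(x$promoter_label)) "" else
                paste0(", promoter ", x$promoter_label)))
  invisible(x)
}

#' Write oligos as FASTA and vendor-style CSV
#'
#' @param oligos List of `oligo_construct`s.
#' @param fasta,csv Output paths (either may be NULL).
#' @export
write_oligos <- function(oligos, fasta = NULL, csv = NULL) {
  ids <- vapply(oligos, `[[`, "", "guide_id")
  seqs <- vapply(oligos, `[[`, "", "oligo")
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(setNames(seqs, ids))
    Biostrings::writeXStringSet(ss, filepath = fasta, width = 80L)
  }
  if (!is.null(csv))
    write.table(data.frame(id = ids, sequence = seqs, length = nchar(seqs)),
                csv, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
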