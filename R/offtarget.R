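# Genome-wide specificity search under the permissive PAM set.
#
# The intended site is identified by coordinates (contig, strand, leftmost
# window offset), never by sequence, so a perfect duplicate of the spacer at
# another locus is correctly counted as an off-target. Truncated guides are
# screened at their truncated length. Mismatch counting is positionally
# uniform (no seed weighting): the system's only mismatch evidence is
# categorical.

#' Off-target rejection policy
#'
#' A candidate guide is disqualified when a secondary site within
#' `max_mm_reject` mismatches lies next to a PAM in scope. The default scope
#' is the permissive set (TTA plus the four weakly active variants), because
#' even weak PAMs retain measurable interference activity.
#'
#' @param max_mm_reject Mismatch count at or below which a secondary site
#'   disqualifies a guide (default 1, matching the observed interference by a
#'   1-mispair protospacer).
#' @param pam_scope `"permissive_set"` or `"core_only"`.
#' @return Object of class `offtarget_policy`.
#' @export
offtarget_policy <- function(max_mm_reject = 1L,
                             pam_scope = c("permissive_set", "core_only")) {
  pam_scope <- match.arg(pam_scope)
  if (max_mm_reject < 0L) stop("max_mm_reject must be >= 0", call. = FALSE)
  structure(list(max_mm_reject = as.integer(max_mm_reject),
                 pam_scope = pam_scope),
            class = "offtarget_policy")
}

.pam_in_scope <- function(pam_class, policy) {
  if (policy$pam_scope == "core_only") pam_class == "core"
  else pam_class %in% c("core", "permissive")
}

#' Exhaustive off-target search for one guide
#'
#' Scans both strands of every contig for windows within `max_mm` mismatches
#' of the spacer, excludes the intended site by coordinates, and classifies
#' each hit's 5'-flank core as `core`, `permissive`, or `none`.
#'
#' @param guide A manifest row (list/data.frame row with `spacer`,
#'   `contig_id`, `strand`, and either `offset` or `protospacer_start`), or a
#'   bare spacer string (no intended site excluded).
#' @param genome An `ib_genome`.
#' @param max_mm Scan depth (default 3).
#' @param policy An [offtarget_policy()].
#' @param model A [pam_model()].
#' @return Object of class `offtarget_report`: list(guide_id, hits,
#'   counts_by_mm, pass).
#' @export
find_offtargets <- function(guide, genome, max_mm = 3L,
                            policy = offtarget_policy(),
                            model = pam_model()) {
  stopifnot(inherits(genome, "ib_genome"))
  if (is.character(guide)) guide <- list(spacer = guide)
  spacer <- toupper(guide$spacer)
  k <- nchar(spacer)
  hits <- match_spacer(spacer, genome, max_mm = max_mm, model = model)
  if (!is.null(guide[["contig_id"]]) && !is.null(guide[["strand"]])) {
    # [[ with exact matching: a manifest row also carries offset_in_gene,
    # which $ would partial-match.
    left <- if (!is.null(guide[["offset"]])) guide[["offset"]]
            else .proto_left(guide[["protospacer_start"]],
                             guide[["strand"]], k)
    intended <- hits$target_id == guide[["contig_id"]] &
      hits$strand == guide[["strand"]] & hits$offset == left
    hits <- hits[!intended, , drop = FALSE]
  }
  counts <- vapply(0:max_mm, function(m) sum(hits$mismatches == m), integer(1))
  names(counts) <- as.character(0:max_mm)
  bad <- hits$mismatches <= policy$max_mm_reject &
    .pam_in_scope(hits$pam_class, policy)
  structure(list(guide_id = guide$guide_id %||% spacer, hits = hits,
                 counts_by_mm = counts, pass = !any(bad)),
            class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat(sprintf("<offtarget_report> %s: %d hit(s) [%s], pass = %s\n",
              x$guide_id, nrow(x$hits),
              paste(names(x$counts_by_mm), x$counts_by_mm, sep = ":",
                    collapse = " "), x$pass))
  invisible(x)
}

#' Batch specificity screening
#'
#' One [find_offtargets()] report per manifest row; results are identical to
#' per-guide calls. The aggregate pass rate is attached as an attribute.
#'
#' @param guides Manifest data.frame (needs `guide_id`, `spacer`, `contig_id`,
#'   `strand`, `protospacer_start`).
#' @param genome An `ib_genome`.
#' @param policy An [offtarget_policy()].
#' @param max_mm Scan depth.
#' @param model A [pam_model()].
#' @return List of `offtarget_report`s with attribute `pass_rate`.
#' @export
batch_specificity <- function(guides, genome, policy = offtarget_policy(),
                              max_mm = 3L, model = pam_model()) {
  if (nrow(guides) == 0) return(structure(list(), pass_rate = NA_real_))
  reports <- lapply(seq_len(nrow(guides)), function(i)
    find_offtargets(as.list(guides[i, , drop = FALSE]), genome,
                    max_mm = max_mm, policy = policy, model = model))
  names(reports) <- guides$guide_id
  attr(reports, "pass_rate") <-
    mean(vapply(reports, `[[`, logical(1), "pass"))
  reports
}

#' Write off-target reports as TSV
#' @param reports Result of [batch_specificity()].
#' @param path Output path.
#' @export
write_offtarget_tsv <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    if (nrow(r$hits) == 0)
      return(data.frame(guide_id = r$guide_id, target_id = NA, offset = NA,
                        strand = NA, mismatches = NA, flank5 = NA,
                        pam_class = NA, pass = r$pass))
    cbind(guide_id = r$guide_id,
          r$hits[, c("target_id", "offset", "strand", "mismatches",
                     "flank5", "pam_class")],
          pass = r$pass)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
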