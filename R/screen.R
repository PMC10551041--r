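# Pooled-screen analysis: tgRNA counting from amplicon FASTQ reads and
# enrichment ranking of guides between a baseline (pre-selection) and a
# selected (post-selection) pool.
#
# Read architecture: a fixed 5' anchor immediately precedes the spacer; the
# spacer window has the library's (single) spacer length. The anchor is
# located anywhere in the read, exact-first with a <= 1 mismatch fallback.
# Anchors are configuration, not constants.

#' Read a FASTQ file
#' @param path FASTQ path (plain or gzipped).
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path, call. = FALSE)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  setNames(toupper(lines[seq(2, length(lines), 4)]), ids)
}

#' Write reads as FASTQ
#' @param seqs Character vector of read sequences (names used as read ids).
#' @param path Output path.
#' @param qual Quality character replicated per base (default `"I"`, Q40).
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      strrep(qual, nchar(seqs))), con)
  invisible(path)
}

# All sequences at Hamming distance exactly 1 from `s`.
.hamming1_neighbors <- function(s) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Detect library ambiguity at the chosen tolerance; returns collision pairs.
.library_collisions <- function(spacers, max_mm) {
  dup <- spacers[duplicated(spacers)]
  if (length(dup)) return(unique(dup))
  if (max_mm == 0L) return(character(0))
  env <- new.env(hash = TRUE, parent = emptyenv())
  collisions <- character(0)
  for (s in spacers) assign(s, s, envir = env)
  for (s in spacers) {
    for (nb in .hamming1_neighbors(s)) {
      owner <- env[[nb]]
      if (!is.null(owner)) collisions <- c(collisions, paste(s, owner))
      else assign(nb, s, envir = env)
    }
  }
  unique(collisions)
}

#' Count guide abundances from screen reads
#'
#' Assigns each read to at most one guide by locating the 5' anchor and
#' matching the following fixed-length window against the library spacers.
#' Counting conserves reads: assigned + unassigned = reads processed, with
#' unassigned reasons tallied.
#'
#' @param reads FASTQ path or a character vector of read sequences.
#' @param manifest Library manifest (needs `guide_id`, `spacer`; spacers must
#'   be unique at the chosen mismatch tolerance, checked up front).
#' @param anchor5 Constant sequence immediately 5' of the spacer.
#' @param max_mm_spacer Spacer mismatch tolerance, 0 or 1.
#' @param orient `"forward"` (anchors on the read as given) or `"both"` (also
#'   try the reverse complement of each read).
#' @return Object of class `count_table`: list(counts — named integer vector
#'   over all guides, total, assigned, unassigned, reasons).
#' @export
count_guides <- function(reads, manifest, anchor5, max_mm_spacer = 0L,
                         orient = c("forward", "both")) {
  orient <- match.arg(orient)
  if (!max_mm_spacer %in% c(0L, 1L))
    stop("max_mm_spacer must be 0 or 1", call. = FALSE)
  stopifnot(all(c("guide_id", "spacer") %in% names(manifest)))
  spacers <- toupper(manifest$spacer)
  slen <- unique(nchar(spacers))
  if (length(slen) != 1L)
    stop("library spacers must share one length", call. = FALSE)
  coll <- .library_collisions(spacers, max_mm_spacer)
  if (length(coll))
    stop("ambiguous library at max_mm_spacer = ", max_mm_spacer, ": ",
         paste(head(coll, 5), collapse = "; "), call. = FALSE)
  anchor5 <- toupper(anchor5)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- toupper(reads)
  n <- length(reads)
  counts <- setNames(integer(nrow(manifest)), manifest$guide_id)
  reasons <- c(no_anchor = 0L, short_read = 0L, no_spacer_match = 0L)
  if (n == 0L)
    return(structure(list(counts = counts, total = 0L, assigned = 0L,
                          unassigned = 0L, reasons = reasons),
                     class = "count_table"))
  locate <- function(rds) {
    # 0-based spacer start per read; NA when the anchor is absent.
    pos <- regexpr(anchor5, rds, fixed = TRUE)       # exact, first occurrence
    miss <- which(pos < 0)
    if (length(miss)) {                              # <= 1-mm fallback
      for (i in miss) {
        prof <- hamming_profile(rds[i], anchor5)
        hit <- which(prof <= 1L)
        pos[i] <- if (length(hit)) hit[1] else -1L
      }
    }
    ifelse(pos < 0, NA_integer_, as.integer(pos) - 1L + nchar(anchor5))
  }
  start0 <- locate(reads)
  if (orient == "both") {
    flip <- which(is.na(start0))
    if (length(flip)) {
      rc <- revcomp(reads[flip])
      st2 <- locate(rc)
      reads[flip] <- rc
      start0[flip] <- st2
    }
  }
  no_anchor <- is.na(start0)
  reasons["no_anchor"] <- sum(no_anchor)
  window <- rep(NA_character_, n)
  ok <- !no_anchor
  too_short <- ok & (start0 + slen > nchar(reads))
  reasons["short_read"] <- sum(too_short)
  ok <- ok & !too_short
  window[ok] <- substr(reads[ok], start0[ok] + 1L, start0[ok] + slen)
  idx <- match(window, spacers)
  if (max_mm_spacer == 1L) {
    # Resolve near-misses through a 1-neighbor lookup built over the library.
    unres <- which(ok & is.na(idx))
    if (length(unres)) {
      nb_env <- new.env(hash = TRUE, parent = emptyenv())
      for (j in seq_along(spacers))
        for (nb in .hamming1_neighbors(spacers[j]))
          assign(nb, j, envir = nb_env)
      for (i in unres) {
        j <- nb_env[[window[i]]]
        if (!is.null(j)) idx[i] <- j
      }
    }
  }
  assigned <- ok & !is.na(idx)
  reasons["no_spacer_match"] <- sum(ok & is.na(idx))
  tab <- table(factor(idx[assigned], levels = seq_len(nrow(manifest))))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, total = n, assigned = sum(assigned),
                 unassigned = n - sum(assigned), reasons = reasons),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d guides; %d reads (%d assigned, %d unassigned)\n",
              length(x$counts), x$total, x$assigned, x$unassigned))
  invisible(x)
}

#' Write a count table as TSV
#' @param counts A `count_table`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  write.table(data.frame(guide_id = names(counts$counts),
                         count = as.integer(counts$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts()]
#' @param path TSV path.
#' @return A `count_table` (reasons unavailable; totals recomputed).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(counts = setNames(as.integer(df$count), df$guide_id),
                 total = sum(df$count), assigned = sum(df$count),
                 unassigned = 0L,
                 reasons = c(no_anchor = NA, short_read = NA,
                             no_spacer_match = NA)),
            class = "count_table")
}

.as_counts <- function(x) {
  if (inherits(x, "count_table")) return(x$counts)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a count_table or a named count vector", call. = FALSE)
}

#' Per-guide enrichment between baseline and selected pools
#'
#' For each guide, tests the selected count against the guide's baseline
#' proportion with a two-sided binomial test (doubled smaller tail, capped at
#' 1; the baseline proportion uses a Jeffreys-style `(b + c)/(B + 2c)`
#' shrinkage so zero-baseline guides are testable), then applies
#' Benjamini-Hochberg FDR correction. Log2 fold changes are computed on
#' pseudocounted counts-per-million. Ordering: significant guides
#' (`q <= alpha`) first by decreasing log2fc, then the rest by decreasing
#' log2fc; ties break on `guide_id`.
#'
#' An exact permutation alternative is available behind `method =
#' "permutation"`: permuting pool labels over reads while conditioning on
#' each guide's total yields the hypergeometric null, so the permutation
#' p-value is computed exactly from hypergeometric tails (again doubled
#' smaller tail).
#'
#' @param baseline,selected `count_table`s (or named count vectors) over the
#'   same guide universe.
#' @param pseudocount Pseudocount `c` for CPM and shrinkage (default 0.5).
#' @param alpha FDR threshold for the significance tier (default 0.05).
#' @param method `"binomial"` (default) or `"permutation"`.
#' @return data.frame: guide_id, baseline_count, selected_count,
#'   baseline_cpm, selected_cpm, log2fc, p_value, q_value, rank.
#' @export
enrich <- function(baseline, selected, pseudocount = 0.5, alpha = 0.05,
                   method = c("binomial", "permutation")) {
  method <- match.arg(method)
  b <- .as_counts(baseline)
  s <- .as_counts(selected)
  if (!setequal(names(b), names(s)))
    stop("baseline and selected must cover the same guides", call. = FALSE)
  s <- s[names(b)]
  B <- sum(b); S <- sum(s)
  if (B == 0 || S == 0) stop("zero-total sample", call. = FALSE)
  c0 <- pseudocount
  b_cpm <- (b + c0) / (B + c0 * length(b)) * 1e6
  s_cpm <- (s + c0) / (S + c0 * length(s)) * 1e6
  log2fc <- log2(s_cpm / b_cpm)
  if (method == "binomial") {
    p0 <- (b + c0) / (B + 2 * c0)
    lower <- pbinom(s, S, p0)
    upper <- pbinom(s - 1, S, p0, lower.tail = FALSE)
  } else {
    # Read-label permutation, conditioned on each guide's pooled total:
    # selected count ~ Hypergeometric(S, B, b + s) under the null.
    t <- b + s
    lower <- stats::phyper(s, S, B, t)
    upper <- stats::phyper(s - 1, S, B, t, lower.tail = FALSE)
  }
  p <- pmin(1, 2 * pmin(lower, upper))
  q <- p.adjust(p, method = "BH")
  res <- data.frame(guide_id = names(b),
                    baseline_count = as.integer(b),
                    selected_count = as.integer(s),
                    baseline_cpm = b_cpm, selected_cpm = s_cpm,
                    log2fc = log2fc, p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  sig <- res$q_value <= alpha
  ord <- order(!sig, -res$log2fc, res$guide_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Top-ranked enriched guides (or genes)
#'
#' The first `k` rows of the [enrich()] ordering. With `by = "gene"`, guides
#' are aggregated to genes by each gene's best guide (screen validation is
#' per-tgRNA, so the gene score is the max, not a mean).
#'
#' @param results [enrich()] output.
#' @param k Number of hits (default 6, the validation set size used for the
#'   transformation screen).
#' @param by `"guide"` or `"gene"`.
#' @param manifest Manifest with `guide_id`, `gene_id` (required for genes).
#' @return Character vector of guide or gene identifiers.
#' @export
top_hits <- function(results, k = 6L, by = c("guide", "gene"),
                     manifest = NULL) {
  by <- match.arg(by)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (by == "gene") {
    if (is.null(manifest)) stop("gene aggregation needs a manifest",
                                call. = FALSE)
    results <- merge(results, manifest[, c("guide_id", "gene_id")],
                     by = "guide_id", sort = FALSE)
    results <- results[order(results$rank), , drop = FALSE]
    ids <- results$gene_id[!duplicated(results$gene_id)]
  } else {
    ids <- results$guide_id
  }
  if (k > length(ids)) {
    warning("k exceeds the number of available ", by, "s; truncated",
            call. = FALSE)
    k <- length(ids)
  }
  ids[seq_len(k)]
}
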