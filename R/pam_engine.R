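# PAM model, PAM scanning, variant enumeration, position frequency matrices,
# and mismatch-tolerant spacer matching.
#
# Orientation convention: the 3-nt PAM core sits immediately 5' of the
# protospacer on the protospacer-carrying strand. Two further-upstream
# positions (-5,-4) are recorded in 5' flanks but never constrained: they were
# shown to be functionally independent by saturation mutagenesis, so only
# -3..-1 are part of the recognition motif. All coordinates reported on the
# forward axis, 0-based; for a minus-strand site `pam_start` is the forward
# coordinate of the base that is the first base of the core when read 5'->3'
# on the minus strand.

#' PAM recognition model
#'
#' The type I-B system here recognizes the 3-nt core `TTA` as its effective
#' PAM; `CTA`, `TCA`, `TTG` and `TTT` retain (much weaker) interference
#' activity and form the permissive set used for off-target screening. The two
#' positions 5' of the core (-5,-4) are unconstrained.
#'
#' @param core 3-nt core motif (default `"TTA"`).
#' @param permissive_set Motifs retaining activity; must contain `core`.
#' @param upstream_free Number of unconstrained upstream positions (default 2).
#' @return Object of class `pam_model`.
#' @export
pam_model <- function(core = "TTA",
                      permissive_set = c("TTA", "CTA", "TCA", "TTG", "TTT"),
                      upstream_free = 2L) {
  core <- toupper(core)
  permissive_set <- toupper(permissive_set)
  if (!all(nchar(c(core, permissive_set)) == 3L) ||
      any(grepl("[^ACGT]", c(core, permissive_set))))
    stop("PAM motifs must be 3 nt over {A,C,G,T}", call. = FALSE)
  if (!core %in% permissive_set)
    stop("core must be a member of the permissive set", call. = FALSE)
  structure(list(core = core, permissive_set = unique(permissive_set),
                 upstream_free = as.integer(upstream_free)),
            class = "pam_model")
}

# 0-based start positions of all (possibly overlapping) occurrences of
# `motif` in `seq`; on circular sequences occurrences may span the origin.
.motif_starts <- function(seq, motif, circular = FALSE) {
  k <- nchar(motif)
  subject <- if (circular && nchar(seq) > k)
    paste0(seq, substr(seq, 1L, k - 1L)) else seq
  hits <- gregexpr(paste0("(?=", motif, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  starts <- as.integer(hits) - 1L
  starts[starts < nchar(seq)]
}

#' Scan a genome for PAM sites
#'
#' Finds every occurrence of the PAM core on the requested strand(s) and
#' reports it with the position of the adjacent protospacer window (the
#' sequence immediately 3' of the core on the same strand) and the number of
#' protospacer bases available before the contig end (unlimited on circular
#' contigs).
#'
#' @param record A [genome_record()] (or an `ib_genome` with one contig).
#' @param model A [pam_model()].
#' @param region Optional 0-based half-open interval `c(start, end)`; only
#'   cores fully inside it are reported.
#' @param strands `"+"`, `"-"`, or `"both"`.
#' @return data.frame: contig_id, strand, pam_start, protospacer_start,
#'   max_protospacer_len — sorted by (strand, pam_start). Coordinates 0-based
#'   forward-axis.
#' @export
scan_pams <- function(record, model = pam_model(), region = NULL,
                      strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (inherits(record, "ib_genome")) {
    if (length(record$records) != 1L)
      stop("scan_pams on an ib_genome requires exactly one contig; ",
           "call per record", call. = FALSE)
    record <- record$records[[1]]
  }
  stopifnot(inherits(record, "genome_record"), inherits(model, "pam_model"))
  L <- nchar(record$sequence)
  circ <- record$topology == "circular"
  core <- model$core
  out <- list()
  if (strands %in% c("both", "+")) {
    st <- .motif_starts(record$sequence, core, circ)
    if (length(st)) {
      proto <- st + 3L
      if (circ) proto <- proto %% L
      maxlen <- if (circ) rep(Inf, length(st)) else pmax(L - proto, 0L)
      out[["+"]] <- data.frame(contig_id = record$contig_id, strand = "+",
                               pam_start = st, protospacer_start = proto,
                               max_protospacer_len = maxlen,
                               stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "-")) {
    st <- .motif_starts(record$sequence, revcomp(core), circ)
    if (length(st)) {
      pam <- st + 2L            # first core base read on the minus strand
      proto <- st - 1L          # immediately 3' of the core on minus strand
      if (circ) {
        pam <- pam %% L
        proto <- proto %% L
      }
      maxlen <- if (circ) rep(Inf, length(st)) else pmax(proto + 1L, 0L)
      out[["-"]] <- data.frame(contig_id = record$contig_id, strand = "-",
                               pam_start = pam, protospacer_start = proto,
                               max_protospacer_len = maxlen,
                               stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(), strand = character(),
               pam_start = integer(), protospacer_start = integer(),
               max_protospacer_len = numeric(), stringsAsFactors = FALSE)
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 0, region[2] <= L)
    left <- ifelse(res$strand == "+", res$pam_start, res$pam_start - 2L)
    res <- res[left >= region[1] & left + 3L <= region[2], , drop = FALSE]
  }
  res <- res[order(res$strand, res$pam_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate PAM variants from a wildcard template
#'
#' Completes every `N` position of a motif template with all four bases, in
#' lexicographic order. Mirrors the saturation designs used to map the PAM:
#' `"NNN"` gives the 64 trinucleotides tested at -3..-1, `"NNTTA"` the 16
#' variants tested at -5,-4 over a fixed TTA core.
#'
#' @param template Motif over `{A,C,G,T,N}`.
#' @return Character vector of `4^(#N)` motifs, lexicographic, no duplicates.
#' @export
enumerate_pam_variants <- function(template) {
  template <- toupper(template)
  if (grepl("[^ACGTN]", template))
    stop("template must be over {A,C,G,T,N}", call. = FALSE)
  chars <- strsplit(template, "")[[1]]
  pools <- lapply(chars, function(ch)
    if (ch == "N") c("A", "C", "G", "T") else ch)
  grid <- do.call(expand.grid,
                  c(rev(pools), list(stringsAsFactors = FALSE)))
  motifs <- do.call(paste0, rev(grid))
  sort(unique(motifs))
}

# ---- Position frequency matrices ----------------------------------------

#' Build a position frequency matrix
#'
#' Tallies base counts per column from equal-length aligned sequences, as used
#' to derive the PAM consensus from the 5' flanks of matched protospacers and
#' of newly acquired spacers.
#'
#' @param flanks Character vector of equal-length sequences over `{A,C,G,T}`.
#' @return Object of class `pfm`: list(counts = 4 x L matrix with rows
#'   A,C,G,T, n_sequences). Every column sums to `n_sequences`.
#' @export
build_pfm <- function(flanks) {
  if (length(flanks) == 0) stop("no sequences", call. = FALSE)
  flanks <- toupper(flanks)
  if (length(unique(nchar(flanks))) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  if (any(grepl("[^ACGT]", flanks)))
    stop("PFM alphabet is {A,C,G,T}", call. = FALSE)
  mat <- do.call(rbind, strsplit(flanks, ""))
  counts <- apply(mat, 2, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))))
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"),
                                   seq_len(ncol(mat))))
  structure(list(counts = counts, n_sequences = length(flanks)),
            class = "pfm")
}

#' Per-column consensus of a PFM
#' @param pfm A [build_pfm()] result.
#' @return Consensus string (ties broken A < C < G < T).
#' @export
pfm_consensus <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

#' Write a PFM as a tab-separated 4 x L matrix
#' @param pfm A `pfm`.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm"))
  write.table(pfm$counts, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d sequences x %d columns; consensus %s\n",
              x$n_sequences, ncol(x$counts), pfm_consensus(x)))
  print(x$counts)
  invisible(x)
}

# ---- Hamming matching ----------------------------------------------------

# Mismatch count of `pattern` against every window of `subject`.
# Returns an integer vector of length nchar(subject) - nchar(pattern) + 1;
# element i is the Hamming distance at 0-based offset i-1. Substitution-only.
hamming_profile <- function(subject, pattern) {
  n <- nchar(subject)
  k <- nchar(pattern)
  if (k > n) return(integer(0))
  s <- charToRaw(subject)
  p <- charToRaw(pattern)
  nw <- n - k + 1L
  mm <- integer(nw)
  idx <- seq_len(nw)
  for (i in seq_len(k)) mm <- mm + as.integer(s[idx + (i - 1L)] != p[i])
  mm
}

.as_seq_set <- function(targets) {
  if (inherits(targets, "DNAStringSet")) {
    out <- as.character(targets)
    names(out) <- sub("\\s.*$", "", names(targets))
    return(out)
  }
  if (inherits(targets, "ib_genome"))
    return(setNames(vapply(targets$records, `[[`, "", "sequence"),
                    names(targets$records)))
  if (inherits(targets, "genome_record"))
    return(setNames(targets$sequence, targets$contig_id))
  if (is.character(targets) && length(targets) == 1L && file.exists(targets) &&
      grepl("^>", readLines(targets, n = 1L, warn = FALSE)))
    return(.as_seq_set(Biostrings::readDNAStringSet(targets)))
  if (is.character(targets)) {
    if (is.null(names(targets)))
      names(targets) <- paste0("target", seq_along(targets))
    return(toupper(targets))
  }
  stop("unsupported target container", call. = FALSE)
}

#' Match a spacer against target sequences with mismatches
#'
#' Substitution-only (Hamming) matching of a spacer against every window on
#' both strands of each target, reporting the 5' flank (the 5 nt immediately
#' upstream of the matched protospacer on the matching strand, i.e. the
#' candidate PAM region) and its 3-nt core classification under `model`.
#'
#' @param spacer Spacer sequence, 5'->3' (length >= 8).
#' @param targets Named character vector, `DNAStringSet`, FASTA path,
#'   `genome_record`, or `ib_genome`.
#' @param max_mm Maximum number of mismatches.
#' @param model A [pam_model()] used to classify the flank core.
#' @return data.frame: target_id, offset (0-based forward-axis position of the
#'   leftmost base of the matched window), strand, mismatches, flank5,
#'   pam_core, pam_class (`core` / `permissive` / `none`); sorted by
#'   mismatches, then target, offset, strand.
#' @export
match_spacer <- function(spacer, targets, max_mm = 0L, model = pam_model()) {
  spacer <- toupper(spacer)
  if (nchar(spacer) < 8L) stop("spacer must be >= 8 nt", call. = FALSE)
  .check_dna(spacer)
  seqs <- .as_seq_set(targets)
  k <- nchar(spacer)
  rows <- list()
  for (tid in names(seqs)) {
    S <- seqs[[tid]]
    n <- nchar(S)
    if (k > n) next
    mm <- hamming_profile(S, spacer)
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      off <- hit - 1L
      flank <- substr(rep(S, length(off)), pmax(1L, off - 4L), off)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, offset = off, strand = "+",
        mismatches = mm[hit], flank5 = flank, stringsAsFactors = FALSE)
    }
    rc <- revcomp(S)
    mmr <- hamming_profile(rc, spacer)
    hit <- which(mmr <= max_mm)
    if (length(hit)) {
      q <- hit - 1L                    # 0-based offset on the rc string
      off <- n - q - k                 # leftmost forward-axis offset
      flank <- substr(rep(rc, length(q)), pmax(1L, q - 4L), q)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, offset = off, strand = "-",
        mismatches = mmr[hit], flank5 = flank, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), offset = integer(),
               strand = character(), mismatches = integer(),
               flank5 = character(), stringsAsFactors = FALSE)
  nf <- nchar(res$flank5)
  res$pam_core <- ifelse(nf >= 3L, substr(res$flank5, nf - 2L, nf),
                         NA_character_)
  res$pam_class <- ifelse(is.na(res$pam_core), "none",
                   ifelse(res$pam_core == model$core, "core",
                   ifelse(res$pam_core %in% model$permissive_set,
                          "permissive", "none")))
  res <- res[order(res$mismatches, res$target_id, res$offset, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- CRISPR array parsing ------------------------------------------------

#' Parse a CRISPR array into spacers
#'
#' Locates successive occurrences of the repeat (tolerating up to
#' `max_repeat_mm` substitutions, mirroring terminal-repeat variability) and
#' returns the ordered spacers between them. `n` spacers imply `n + 1` located
#' repeats.
#'
#' @param seq Assembled array sequence.
#' @param repeat_seq Repeat sequence (non-empty).
#' @param max_repeat_mm Substitutions tolerated per repeat copy (default 2).
#' @return Character vector of spacers, in array order.
#' @export
parse_crispr_array <- function(seq, repeat_seq, max_repeat_mm = 2L) {
  seq <- toupper(seq)
  repeat_seq <- toupper(repeat_seq)
  if (!nzchar(repeat_seq)) stop("repeat must be non-empty", call. = FALSE)
  k <- nchar(repeat_seq)
  mm <- hamming_profile(seq, repeat_seq)
  starts <- which(mm <= max_repeat_mm) - 1L
  if (length(starts) >= 2L) {
    # Greedy non-overlapping chain, preferring exacter matches at overlaps.
    keep <- integer(0)
    last_end <- -1L
    for (s in starts) {
      if (s >= last_end) {
        keep <- c(keep, s)
        last_end <- s + k
      }
    }
    starts <- keep
  }
  if (length(starts) < 2L)
    stop("not an array: fewer than 2 repeat occurrences found", call. = FALSE)
  spacers <- character(length(starts) - 1L)
  for (i in seq_len(length(starts) - 1L))
    spacers[i] <- substr(seq, starts[i] + k + 1L, starts[i + 1L])
  spacers
}
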