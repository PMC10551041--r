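# Guide design: the spacer-length functional switch, template-strand rule,
# positional binning, exclusion filters, and genome-scale library assembly.
#
# Strand convention: a guide that "targets the template strand" hybridizes to
# the template (non-coding) strand, so its protospacer and PAM are read from
# the gene's coding strand. For a gene on the forward strand the protospacer
# strand is "+"; for a minus-strand gene it is "-".

BIN_LEVELS <- c("upstream", "mid", "downstream")

# Recognition sites excluded from spacers by default (both orientations), so
# that every designed spacer is directly clonable by Golden Gate.
DEFAULT_EXCLUSION <- c("GGTCTC", "GAGACC",   # BsaI
                       "CGTCTC", "GAGACG")   # Esp3I

#' Guide design parameters
#'
#' Defaults follow the genome-scale tgRNA library design: 20-mer repression
#' spacers, three guides per gene binned over the template strand
#' (upstream/mid/downstream thirds of the CDS), with the repression/cleavage
#' functional switch at 26 nt (spacers of <= 26 nt repress; >= 27 nt license
#' Cas3 cleavage). The cleavage default of 30 nt is the shortest length shown
#' uniformly lethal on targeting; a 38-nt preset is used for editing in
#' E. coli.
#'
#' @param repression_len Repression (tgRNA) spacer length, nt.
#' @param cleavage_len Cleavage/editing spacer length, nt.
#' @param mode_boundary Longest repression length (default 26).
#' @param guides_per_gene Guides designed per gene (default 3).
#' @param strand_mode `"template"`, `"nontemplate"`, or `"both"`.
#' @param bins Number of positional bins (default 3).
#' @param specificity `"off"` or `"on"`; when on, candidates must pass the
#'   [offtarget_policy()] in `policy`.
#' @param policy An [offtarget_policy()] (used when `specificity = "on"`).
#' @param exclusion Motifs forbidden inside spacers (default: BsaI and Esp3I
#'   recognition sites, both orientations).
#' @param max_homopolymer Longest allowed single-base run (default 6).
#' @param arm_len Homology-arm length for editing designs, bp (default 600).
#' @return Object of class `design_params`.
#' @export
design_params <- function(repression_len = 20L, cleavage_len = 30L,
                          mode_boundary = 26L, guides_per_gene = 3L,
                          strand_mode = c("template", "nontemplate", "both"),
                          bins = 3L, specificity = c("on", "off"),
                          policy = offtarget_policy(),
                          exclusion = DEFAULT_EXCLUSION,
                          max_homopolymer = 6L, arm_len = 600L) {
  strand_mode <- match.arg(strand_mode)
  specificity <- match.arg(specificity)
  if (!(repression_len <= mode_boundary && mode_boundary < cleavage_len))
    stop("need repression_len <= mode_boundary < cleavage_len", call. = FALSE)
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  structure(list(repression_len = as.integer(repression_len),
                 cleavage_len = as.integer(cleavage_len),
                 mode_boundary = as.integer(mode_boundary),
                 guides_per_gene = as.integer(guides_per_gene),
                 strand_mode = strand_mode, bins = as.integer(bins),
                 specificity = specificity, policy = policy,
                 exclusion = toupper(exclusion),
                 max_homopolymer = as.integer(max_homopolymer),
                 arm_len = as.integer(arm_len)),
            class = "design_params")
}

#' Classify a spacer length as repression or cleavage
#'
#' The functional switch of the type I-B system: crRNAs with <= 26 nt of
#' complementarity guide Cascade-mediated transcriptional repression without
#' cleavage, while >= 27 nt recruits Cas3 and licenses DNA cleavage.
#'
#' @param length Spacer length(s), nt (>= 8).
#' @param boundary Switch point (default 26).
#' @return Character vector, `"repression"` or `"cleavage"`.
#' @export
#' @examples
#' classify_mode(26)  # repression
#' classify_mode(27)  # cleavage
classify_mode <- function(length, boundary = 26L) {
  if (any(length < 8L)) stop("spacer length must be >= 8 nt", call. = FALSE)
  ifelse(length <= boundary, "repression", "cleavage")
}

#' Truncation series of a full-length spacer
#'
#' Produces the PAM-proximal prefixes of a full spacer at the requested
#' lengths (default 30/25/20/15/11 nt, the characterization series).
#' Truncation removes PAM-distal (3') bases so every variant keeps the seed
#' next to the PAM and re-localizes to the same protospacer site.
#'
#' @param full_spacer Full-length spacer, 5'->3'.
#' @param lengths Truncation lengths (default `c(30, 25, 20, 15, 11)`).
#' @param boundary Mode switch point passed to [classify_mode()].
#' @return data.frame: spacer, length, mode.
#' @export
truncation_series <- function(full_spacer, lengths = c(30L, 25L, 20L, 15L, 11L),
                              boundary = 26L) {
  full_spacer <- toupper(full_spacer)
  if (max(lengths) > nchar(full_spacer))
    stop("requested length exceeds the full spacer (", nchar(full_spacer),
         " nt)", call. = FALSE)
  data.frame(spacer = substr(rep(full_spacer, length(lengths)), 1L, lengths),
             length = as.integer(lengths),
             mode = classify_mode(lengths, boundary),
             stringsAsFactors = FALSE)
}

.spacer_passes <- function(spacer, params) {
  if (any(vapply(params$exclusion, grepl, logical(1), x = spacer, fixed = TRUE)))
    return(FALSE)
  run <- params$max_homopolymer + 1L
  !grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", run, run, run, run), spacer)
}

# Extract the spacer for a protospacer whose first base sits at forward-axis
# position `proto_start` on `strand`, reading `len` bases 3'-ward.
.extract_spacer <- function(record, proto_start, strand, len) {
  L <- nchar(record$sequence)
  if (strand == "+") {
    if (proto_start + len > L) {
      if (record$topology != "circular") return(NA_character_)
      return(subsequence(record, proto_start, proto_start + len, "+"))
    }
    substr(record$sequence, proto_start + 1L, proto_start + len)
  } else {
    lo <- proto_start - len + 1L
    if (lo < 0L) {
      if (record$topology != "circular") return(NA_character_)
      return(subsequence(record, (lo %% L), (lo %% L) + len, "-"))
    }
    revcomp(substr(record$sequence, lo + 1L, proto_start + 1L))
  }
}

# Candidate table for one gene from a precomputed PAM site table.
.gene_candidates <- function(gene, record, sites, params) {
  len <- params$repression_len
  glen <- gene$end - gene$start
  proto_strand <- if (params$strand_mode == "template") gene$strand
                  else if (params$strand_mode == "nontemplate")
                    (if (gene$strand == "+") "-" else "+")
                  else c("+", "-")
  s <- sites[sites$strand %in% proto_strand, , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  # Protospacer must lie fully within the gene body; the PAM core may extend
  # upstream of the start codon (it is adjacent sequence, not guide sequence).
  if (gene$strand == "+") {
    ok <- s$strand == "+" &
      s$protospacer_start >= gene$start &
      s$protospacer_start + len <= gene$end
    rel <- (s$protospacer_start - gene$start) / glen
  } else {
    ok <- s$strand == "-" &
      s$protospacer_start <= gene$end - 1L &
      s$protospacer_start - len + 1L >= gene$start
    rel <- (gene$end - 1L - s$protospacer_start) / glen
  }
  if (params$strand_mode == "both") {
    ok_t <- if (gene$strand == "+")
      s$strand == "+" & s$protospacer_start >= gene$start &
        s$protospacer_start + len <= gene$end
    else
      s$strand == "-" & s$protospacer_start <= gene$end - 1L &
        s$protospacer_start - len + 1L >= gene$start
    ok_n <- if (gene$strand == "+")
      s$strand == "-" & s$protospacer_start <= gene$end - 1L &
        s$protospacer_start - len + 1L >= gene$start
    else
      s$strand == "+" & s$protospacer_start >= gene$start &
        s$protospacer_start + len <= gene$end
    ok <- ok_t | ok_n
    rel <- ifelse(s$strand == (if (gene$strand == "+") "+" else "-"),
                  (s$protospacer_start - gene$start) / glen,
                  (gene$end - 1L - s$protospacer_start) / glen)
    rel <- ifelse(gene$strand == "+",
                  ifelse(s$strand == "+",
                         (s$protospacer_start - gene$start) / glen,
                         (gene$end - 1L - s$protospacer_start) / glen),
                  ifelse(s$strand == "-",
                         (gene$end - 1L - s$protospacer_start) / glen,
                         (s$protospacer_start - gene$start) / glen))
  }
  s <- s[ok, , drop = FALSE]
  rel <- rel[ok]
  if (nrow(s) == 0) return(NULL)
  s$rel <- rel
  s$bin <- BIN_LEVELS[pmin(params$bins, floor(rel * params$bins) + 1L)]
  s$spacer <- vapply(seq_len(nrow(s)), function(i)
    .extract_spacer(record, s$protospacer_start[i], s$strand[i], len), "")
  s <- s[!is.na(s$spacer), , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  s[vapply(s$spacer, .spacer_passes, logical(1), params = params), ,
    drop = FALSE]
}

#' Design guides for one gene
#'
#' Splits the gene body into `params$bins` equal thirds along the coding
#' direction and, for each bin, picks the core-PAM candidate whose protospacer
#' start lies closest to the bin center among candidates passing the
#' exclusion, homopolymer, and (optionally) specificity filters. Ties break on
#' fewest off-target hits, then distance to the bin center, then coordinate.
#' Bins with no surviving candidate are reported as gaps.
#'
#' @param gene One row of the gene table (or a gene_id with `genome`).
#' @param genome An `ib_genome`.
#' @param params A [design_params()].
#' @param model A [pam_model()].
#' @param sites Optional precomputed [scan_pams()] table for the contig.
#' @return list(guides = data.frame, gaps = data.frame of unfilled bins).
#' @export
design_gene_guides <- function(gene, genome, params = design_params(),
                               model = pam_model(), sites = NULL) {
  stopifnot(inherits(genome, "ib_genome"))
  if (is.character(gene)) {
    gene <- genome$genes[genome$genes$gene_id == gene, , drop = FALSE]
    if (nrow(gene) != 1) stop("unknown gene", call. = FALSE)
  }
  record <- genome$records[[gene$contig_id]]
  empty <- data.frame(guide_id = character(), gene_id = character(),
                      contig_id = character(), spacer = character(),
                      length = integer(), mode = character(),
                      targeted_strand = character(), bin = character(),
                      pam_core = character(), strand = character(),
                      pam_start = integer(), protospacer_start = integer(),
                      offset_in_gene = numeric(), offtarget_n = integer(),
                      stringsAsFactors = FALSE)
  gap_row <- function(bins) if (length(bins)) data.frame(
    gene_id = gene$gene_id, bin = bins, stringsAsFactors = FALSE) else
    data.frame(gene_id = character(), bin = character(),
               stringsAsFactors = FALSE)
  if (gene$end - gene$start < params$repression_len + 3L) {
    warning("gene ", gene$gene_id, " shorter than spacer + PAM; skipped",
            call. = FALSE)
    return(list(guides = empty, gaps = gap_row(BIN_LEVELS[seq_len(params$bins)])))
  }
  if (is.null(sites)) sites <- scan_pams(record, model)
  cand <- .gene_candidates(gene, record, sites, params)
  if (is.null(cand) || nrow(cand) == 0)
    return(list(guides = empty, gaps = gap_row(BIN_LEVELS[seq_len(params$bins)])))
  if (params$specificity == "on") {
    rep_list <- lapply(seq_len(nrow(cand)), function(i)
      find_offtargets(list(spacer = cand$spacer[i],
                           contig_id = cand$contig_id[i],
                           strand = cand$strand[i],
                           offset = .proto_left(cand$protospacer_start[i],
                                                cand$strand[i],
                                                params$repression_len)),
                      genome, max_mm = params$policy$max_mm_reject,
                      policy = params$policy))
    cand$pass <- vapply(rep_list, `[[`, logical(1), "pass")
    cand$offtarget_n <- vapply(rep_list, function(r) nrow(r$hits), integer(1))
    cand <- cand[cand$pass, , drop = FALSE]
  } else {
    cand$offtarget_n <- NA_integer_
  }
  chosen <- list()
  gaps <- character(0)
  use_bins <- BIN_LEVELS[seq_len(params$bins)]
  for (bi in seq_len(params$bins)) {
    b <- use_bins[bi]
    cb <- cand[cand$bin == b, , drop = FALSE]
    if (nrow(cb) == 0) {
      gaps <- c(gaps, b)
      next
    }
    center <- (bi - 0.5) / params$bins
    dist <- abs(cb$rel - center)
    ot <- if (all(is.na(cb$offtarget_n))) rep(0L, nrow(cb)) else cb$offtarget_n
    ord <- order(ot, dist, cb$protospacer_start, cb$strand)
    chosen[[b]] <- cb[ord[1], , drop = FALSE]
  }
  if (length(chosen) == 0)
    return(list(guides = empty, gaps = gap_row(gaps)))
  g <- do.call(rbind, chosen)
  targeted <- if (params$strand_mode == "both") {
    ifelse(g$strand == gene$strand, "template", "nontemplate")
  } else params$strand_mode
  guides <- data.frame(
    guide_id = paste0(gene$gene_id, "_", g$bin),
    gene_id = gene$gene_id, contig_id = gene$contig_id,
    spacer = g$spacer, length = params$repression_len,
    mode = classify_mode(params$repression_len, params$mode_boundary),
    targeted_strand = targeted, bin = g$bin,
    pam_core = model$core, strand = g$strand,
    pam_start = g$pam_start, protospacer_start = g$protospacer_start,
    offset_in_gene = round(g$rel, 4), offtarget_n = g$offtarget_n,
    stringsAsFactors = FALSE)
  guides <- guides[order(match(guides$bin, BIN_LEVELS)), , drop = FALSE]
  rownames(guides) <- NULL
  list(guides = guides, gaps = gap_row(gaps))
}

# Leftmost forward-axis offset of a protospacer window.
.proto_left <- function(proto_start, strand, len) {
  if (strand == "+") proto_start else proto_start - len + 1L
}

#' Design a genome-scale guide library
#'
#' Runs [design_gene_guides()] over every annotated gene and aggregates
#' library coverage statistics. Deterministic: two runs on the same inputs
#' produce identical manifests.
#'
#' @param genome An `ib_genome`.
#' @param genes Optional subset of the gene table (default: all genes).
#' @param params A [design_params()]. Use `specificity = "off"` to reproduce
#'   raw genome-coverage numbers.
#' @param model A [pam_model()].
#' @return list(guides = manifest data.frame sorted by gene then bin,
#'   stats = list(genes_total, genes_targeted, genes_with_full_bins,
#'   total_guides, fraction_targeted, fraction_full_bins),
#'   gaps = data.frame of unfilled gene/bin pairs).
#' @export
design_library <- function(genome, genes = NULL, params = design_params(),
                           model = pam_model()) {
  stopifnot(inherits(genome, "ib_genome"))
  if (is.null(genes)) genes <- genome$genes
  stats0 <- list(genes_total = nrow(genes), genes_targeted = 0L,
                 genes_with_full_bins = 0L, total_guides = 0L,
                 fraction_targeted = 0, fraction_full_bins = 0)
  if (nrow(genes) == 0)
    return(list(guides = suppressWarnings(design_gene_guides(
                  data.frame(gene_id = "x", contig_id = NA, start = 0,
                             end = 0, strand = "+"),
                  genome, params, model))$guides[0, ],
                stats = stats0, gaps = data.frame(gene_id = character(),
                                                  bin = character())))
  site_cache <- lapply(genome$records, scan_pams, model = model)
  out_g <- vector("list", nrow(genes))
  out_gap <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    res <- suppressWarnings(design_gene_guides(
      gene, genome, params, model, sites = site_cache[[gene$contig_id]]))
    out_g[[i]] <- res$guides
    out_gap[[i]] <- res$gaps
  }
  guides <- do.call(rbind, out_g)
  gaps <- do.call(rbind, out_gap)
  guides <- guides[order(match(guides$gene_id, genes$gene_id),
                         match(guides$bin, BIN_LEVELS)), , drop = FALSE]
  rownames(guides) <- NULL
  per_gene <- table(factor(guides$gene_id, levels = genes$gene_id))
  stats <- list(
    genes_total = nrow(genes),
    genes_targeted = sum(per_gene > 0),
    genes_with_full_bins = sum(per_gene >= params$guides_per_gene),
    total_guides = nrow(guides),
    fraction_targeted = sum(per_gene > 0) / nrow(genes),
    fraction_full_bins = sum(per_gene >= params$guides_per_gene) / nrow(genes))
  list(guides = guides, stats = stats, gaps = gaps)
}

#' Write a guide manifest as TSV
#'
#' User-facing coordinates are 1-based inclusive (GenBank convention): the
#' reported `pam_pos` is the 1-based forward-axis position of the first PAM
#' core base as read on the protospacer strand.
#'
#' @param guides Manifest data.frame from [design_library()].
#' @param path Output path.
#' @export
write_manifest <- function(guides, path) {
  out <- guides
  out$pam_pos <- out$pam_start + 1L
  out$protospacer_pos <- out$protospacer_start + 1L
  out$pam_start <- NULL
  out$protospacer_start <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide manifest written by [write_manifest()]
#' @param path Manifest TSV path.
#' @return data.frame with internal 0-based coordinates restored.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if ("pam_pos" %in% names(m)) {
    m$pam_start <- m$pam_pos - 1L
    m$protospacer_start <- m$protospacer_pos - 1L
    m$pam_pos <- NULL
    m$protospacer_pos <- NULL
  }
  m
}

#' Design a cleavage crRNA plus homology arms for a deletion
#'
#' Picks a full-length (cleavage-mode) spacer inside the deletion interval and
#' homology arms immediately flanking it, then verifies that the simulated
#' post-deletion locus contains no residual target: no window within 1
#' mismatch of the spacer next to a permissive PAM survives, so the edited
#' locus is immune to re-cutting.
#'
#' @param genome An `ib_genome`.
#' @param contig_id Contig containing the deletion.
#' @param interval 0-based half-open deletion interval `c(start, end)`.
#' @param params A [design_params()] (uses `cleavage_len` and `arm_len`).
#' @param model A [pam_model()].
#' @return Object of class `editing_design`: list(spacer, length, mode,
#'   strand, pam_start, protospacer_start, deletion, upstream_arm,
#'   downstream_arm) with arm coordinates abutting the deletion exactly.
#' @export
design_editing <- function(genome, contig_id, interval,
                           params = design_params(), model = pam_model()) {
  stopifnot(inherits(genome, "ib_genome"))
  record <- genome$records[[contig_id]]
  if (is.null(record)) stop("unknown contig: ", contig_id, call. = FALSE)
  L <- nchar(record$sequence)
  s <- interval[1]; e <- interval[2]
  if (!(s >= 0 && s < e && e <= L))
    stop("deletion interval outside contig", call. = FALSE)
  len <- params$cleavage_len
  sites <- scan_pams(record, model)
  inside <- (sites$strand == "+" &
               sites$protospacer_start >= s &
               sites$protospacer_start + len <= e) |
            (sites$strand == "-" &
               sites$protospacer_start <= e - 1L &
               sites$protospacer_start - len + 1L >= s)
  cand <- sites[inside, , drop = FALSE]
  if (nrow(cand) == 0) {
    near <- sites$pam_start[order(abs(sites$pam_start - (s + e) / 2))]
    stop("no cleavage-length protospacer with a ", model$core,
         " PAM inside [", s, ",", e, "); nearest PAM core positions: ",
         paste(head(near, 5) + 1L, collapse = ", "), call. = FALSE)
  }
  center <- (s + e) / 2
  mid <- ifelse(cand$strand == "+", cand$protospacer_start + len / 2,
                cand$protospacer_start - len / 2)
  cand <- cand[order(abs(mid - center), cand$protospacer_start), , drop = FALSE]
  if (s - params$arm_len < 0 || e + params$arm_len > L)
    stop("homology arms of ", params$arm_len,
         " bp do not fit inside the contig", call. = FALSE)
  deleted <- paste0(substr(record$sequence, 1, s),
                    substr(record$sequence, e + 1, L))
  for (i in seq_len(nrow(cand))) {
    spacer <- .extract_spacer(record, cand$protospacer_start[i],
                              cand$strand[i], len)
    if (is.na(spacer) || !.spacer_passes(spacer, params)) next
    residual <- match_spacer(spacer, c(edited = deleted), max_mm = 1L, model)
    residual <- residual[residual$pam_class != "none", , drop = FALSE]
    if (nrow(residual) == 0) {
      return(structure(list(
        spacer = spacer, length = len,
        mode = classify_mode(len, params$mode_boundary),
        contig_id = contig_id, strand = cand$strand[i],
        pam_start = cand$pam_start[i],
        protospacer_start = cand$protospacer_start[i],
        deletion = c(start = s, end = e),
        upstream_arm = list(start = s - params$arm_len, end = s,
                            seq = substr(record$sequence,
                                         s - params$arm_len + 1L, s)),
        downstream_arm = list(start = e, end = e + params$arm_len,
                              seq = substr(record$sequence, e + 1L,
                                           e + params$arm_len))),
        class = "editing_design"))
    }
  }
  stop("every candidate spacer in the interval leaves a PAM-adjacent match ",
       "in the edited locus", call. = FALSE)
}

#' @export
print.editing_design <- function(x, ...) {
  cat(sprintf("<editing_design> delete [%d,%d) on %s; %d-nt %s spacer (%s strand), arms %d bp\n",
              x$deletion["start"], x$deletion["end"], x$contig_id, x$length,
              x$mode, x$strand, nchar(x$upstream_arm$seq)))
  invisible(x)
}
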