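# Synthetic fixtures: annotated micro-genomes with PAM sites planted per gene
# third, and spike-in screen FASTQs with recorded truth. Fully deterministic
# under the spec seed; truth tables are machine-readable TSVs so downstream
# tests can consume them.

#' Specification of a synthetic annotated micro-genome
#'
#' Defaults emulate a compact bacterial chromosome at desk scale: genes of
#' 300-1500 nt (uniform), ~45% GC (typical for Parageobacillus), alternating
#' strands, and one guaranteed core-PAM site per gene third on the coding
#' strand so the default three-bin design always has a candidate.
#'
#' @param n_genes Number of genes.
#' @param gene_len_range Uniform range of gene lengths, nt (rounded to
#'   codons).
#' @param intergenic_len Fixed intergenic spacer length, nt.
#' @param gc_fraction GC content of random sequence.
#' @param pams_per_bin Core-PAM sites planted per gene third (default 1).
#' @param topology Contig topology.
#' @param seed RNG seed; fully determines the output.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 10L, gene_len_range = c(300L, 1500L),
                        intergenic_len = 100L, gc_fraction = 0.45,
                        pams_per_bin = 1L,
                        topology = c("linear", "circular"), seed = 1L) {
  topology <- match.arg(topology)
  if (gene_len_range[1] < 150L)
    stop("genes must be >= 150 nt to plant one site per third", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intergenic_len = as.integer(intergenic_len),
                 gc_fraction = gc_fraction,
                 pams_per_bin = as.integer(pams_per_bin),
                 topology = topology, seed = as.integer(seed)),
            class = "genome_spec")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A random spacer-compatible 20-mer+ region: no Golden-Gate enzyme sites, no
# overlong homopolymers.
.clean_spacer <- function(len, gc, params) {
  repeat {
    s <- .random_dna(len, gc)
    if (.spacer_passes(s, params)) return(s)
  }
}

#' Generate a synthetic annotated micro-genome
#'
#' Builds `n_genes` ATG-initiated, stop-terminated genes on alternating
#' strands, plants `pams_per_bin` core-PAM sites (PAM + clean 20-nt
#' protospacer) at the center of each gene third on the coding strand, writes
#' the genome as a GenBank flat file plus a truth table of planted sites, and
#' returns the in-memory genome.
#'
#' @param spec A [genome_spec()].
#' @param dir Output directory (created if needed).
#' @param model A [pam_model()]; its core is what gets planted.
#' @param params A [design_params()]; planted protospacers pass its filters.
#' @return list(genome — `ib_genome`, genbank, truth_path, truth —
#'   data.frame: gene_id, bin, strand, pam_start, protospacer_start, spacer
#'   (0-based forward-axis coordinates matching [scan_pams()])).
#' @export
make_genome <- function(spec, dir = tempfile("genome"),
                        model = pam_model(), params = design_params()) {
  stopifnot(inherits(spec, "genome_spec"))
  proto_len <- params$repression_len
  if (spec$gene_len_range[1] < 6L * (proto_len + 3L))
    stop("infeasible spec: genes too short to plant a PAM + ", proto_len,
         "-nt protospacer per third", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    gc <- spec$gc_fraction
    pieces <- character(0)
    genes <- list()
    truth <- list()
    cursor <- 0L
    for (gi in seq_len(spec$n_genes)) {
      inter <- .random_dna(spec$intergenic_len, gc)
      pieces <- c(pieces, inter)
      cursor <- cursor + spec$intergenic_len
      L <- sample(seq(spec$gene_len_range[1], spec$gene_len_range[2], by = 3L), 1L)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      gene_id <- sprintf("SYN_%04d", gi)
      coding <- strsplit(paste0("ATG", .random_dna(L - 6L, gc), "TAA"),
                         "")[[1]]
      third <- L / 3
      for (bi in seq_len(3L)) {
        for (pi in seq_len(spec$pams_per_bin)) {
          # Protospacer start (0-based, coding axis) near the third's center,
          # shifted when several sites share a bin; clamped so PAM and
          # protospacer stay inside the gene body.
          q <- round((bi - 0.5) * third) + (pi - 1L) * (proto_len + 4L)
          q <- max(6L, min(q, L - 3L - proto_len))  # keep ATG and stop intact
          coding[(q - 2L):q] <- strsplit(model$core, "")[[1]]
          sp <- .clean_spacer(proto_len, gc, params)
          coding[(q + 1L):(q + proto_len)] <- strsplit(sp, "")[[1]]
          a <- cursor  # gene start on forward axis
          if (strand == "+") {
            pam_start <- a + q - 3L
            proto_start <- a + q
          } else {
            pam_start <- a + (L - 1L) - (q - 3L)
            proto_start <- a + (L - 1L) - q
          }
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gene_id, bin = BIN_LEVELS[bi], strand = strand,
            pam_start = pam_start, protospacer_start = proto_start,
            spacer = sp, stringsAsFactors = FALSE)
        }
      }
      coding <- paste(coding, collapse = "")
      pieces <- c(pieces, if (strand == "+") coding else revcomp(coding))
      genes[[gi]] <- data.frame(gene_id = gene_id, contig_id = "synctg1",
                                start = cursor, end = cursor + L,
                                strand = strand,
                                product = "synthetic protein",
                                stringsAsFactors = FALSE)
      cursor <- cursor + L
    }
    pieces <- c(pieces, .random_dna(spec$intergenic_len, gc))
    seq <- paste(pieces, collapse = "")
    rec <- genome_record("synctg1", seq, topology = spec$topology)
    genome <- structure(list(records = list(synctg1 = rec),
                             genes = do.call(rbind, genes)),
                        class = "ib_genome")
    truth <- do.call(rbind, truth)
    gb <- file.path(dir, "genome.gb")
    write_genome(genome, gb)
    truth_path <- file.path(dir, "genome_truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(genome = genome, genbank = gb, truth_path = truth_path,
         truth = truth)
  })
}

#' Specification of a simulated pooled screen
#'
#' Baseline abundances are uniform over the library; selected abundances are
#' proportional to per-guide fold changes (1 for unlisted guides). Reads are
#' drawn by seeded multinomial sampling at the stated depth, with an optional
#' per-base substitution error.
#'
#' @param manifest Library manifest (`guide_id`, `spacer`).
#' @param depth Total reads per pool.
#' @param enriched data.frame(guide_id, fold) of spiked guides (may be empty).
#' @param error_rate Per-base substitution probability (default 0).
#' @param anchor5,anchor3 Constant sequences flanking the spacer in each read.
#' @param seed RNG seed.
#' @return Object of class `screen_spec`.
#' @export
screen_spec <- function(manifest, depth = 1e6,
                        enriched = data.frame(guide_id = character(),
                                              fold = numeric()),
                        error_rate = 0,
                        anchor5 = "ACACTCTTTCCCTACACGAC",
                        anchor3 = "GTTCAGACGTGTGCTCTTCC",
                        seed = 1L) {
  stopifnot(all(c("guide_id", "spacer") %in% names(manifest)))
  if (nrow(enriched) && any(enriched$fold < 0))
    stop("fold changes must be >= 0", call. = FALSE)
  if (nrow(enriched) && !all(enriched$guide_id %in% manifest$guide_id))
    stop("enriched guide not in the library", call. = FALSE)
  structure(list(manifest = manifest, depth = as.numeric(depth),
                 enriched = enriched, error_rate = error_rate,
                 anchor5 = toupper(anchor5), anchor3 = toupper(anchor3),
                 seed = as.integer(seed)),
            class = "screen_spec")
}

.mutate_reads <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n <- nchar(reads[1])
  mat <- matrix(unlist(strsplit(reads, "")), nrow = length(reads),
                byrow = TRUE)
  hit <- which(matrix(runif(length(mat)) < rate, nrow = nrow(mat)))
  if (length(hit)) {
    repl <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    # Substitution errors: force a change at each hit position.
    same <- repl == mat[hit]
    while (any(same)) {
      repl[same] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
      same <- repl == mat[hit]
    }
    mat[hit] <- repl
  }
  apply(mat, 1, paste, collapse = "")
}

#' Simulate pooled-screen FASTQs with spike-in enrichment
#'
#' Writes `baseline.fastq` and `selected.fastq` (reads:
#' `anchor5 + spacer + anchor3`, read ids carrying guide provenance) plus a
#' per-guide truth table of sampled counts. At `error_rate = 0`,
#' [count_guides()] reproduces the truth exactly.
#'
#' @param spec A [screen_spec()].
#' @param dir Output directory.
#' @return list(baseline, selected — FASTQ paths, truth_path, truth —
#'   data.frame(guide_id, fold, baseline_true, selected_true)).
#' @export
make_screen_reads <- function(spec, dir = tempfile("screen")) {
  stopifnot(inherits(spec, "screen_spec"))
  m <- spec$manifest
  G <- nrow(m)
  if (spec$depth > 0 && spec$depth < G)
    stop("depth must be >= library size (or 0)", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    fold <- rep(1, G)
    if (nrow(spec$enriched))
      fold[match(spec$enriched$guide_id, m$guide_id)] <- spec$enriched$fold
    draw <- function(prob) {
      if (spec$depth == 0) return(integer(G))
      as.integer(rmultinom(1, size = spec$depth, prob = prob))
    }
    base_n <- draw(rep(1, G))
    sel_n <- draw(fold)
    emit <- function(counts, path, tag) {
      idx <- rep.int(seq_len(G), counts)
      if (length(idx) == 0L) return(write_fastq(character(0), path))
      reads <- paste0(spec$anchor5, m$spacer[idx], spec$anchor3)
      reads <- .mutate_reads(reads, spec$error_rate)
      names(reads) <- sprintf("%s_%s_%d", tag, m$guide_id[idx],
                              sequence(counts))
      write_fastq(reads, path)
    }
    base_path <- file.path(dir, "baseline.fastq")
    sel_path <- file.path(dir, "selected.fastq")
    emit(base_n, base_path, "b")
    emit(sel_n, sel_path, "s")
    truth <- data.frame(guide_id = m$guide_id, fold = fold,
                        baseline_true = base_n, selected_true = sel_n,
                        stringsAsFactors = FALSE)
    truth_path <- file.path(dir, "screen_truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(baseline = base_path, selected = sel_path,
         truth_path = truth_path, truth = truth)
  })
}

#' Random spacer library for screen simulations
#'
#' Generates `n` unique clean spacers (no Golden-Gate sites, no overlong
#' homopolymers) as a stand-alone library manifest for count/enrich tests
#' that do not need a genome.
#'
#' @param n Library size.
#' @param len Spacer length (default 20).
#' @param seed RNG seed.
#' @return data.frame(guide_id, spacer).
#' @export
random_library <- function(n, len = 20L, seed = 1L) {
  params <- design_params()
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    spacers <- character(n)
    i <- 0L
    while (i < n) {
      s <- .clean_spacer(len, 0.45, params)
      if (is.null(seen[[s]])) {
        assign(s, TRUE, envir = seen)
        i <- i + 1L
        spacers[i] <- s
      }
    }
    data.frame(guide_id = sprintf("g%04d", seq_len(n)), spacer = spacers,
               stringsAsFactors = FALSE)
  })
}
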