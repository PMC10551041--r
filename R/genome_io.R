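# Genome model and I/O.
#
# Internal coordinate convention: 0-based half-open intervals on the forward
# strand, everywhere. User-facing writers (manifests, BED, GenBank) convert at
# the boundary. Topology is explicit per contig; origin-wrapping intervals are
# legal only on circular contigs.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("illegal character in DNA sequence (alphabet is A/C/G/T/N): ",
         substr(seq[bad][1], 1, 40), call. = FALSE)
  invisible(seq)
}

#' Reverse complement
#'
#' Strict reverse complement over the alphabet `{A,C,G,T,N}`; vectorized.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("TTA")  # "TAA"
revcomp <- function(seq) {
  if (!is.character(seq)) stop("seq must be character", call. = FALSE)
  seq <- toupper(seq)
  .check_dna(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

#' Construct a genome record
#'
#' One contig: an identifier, its forward-strand sequence, and an explicit
#' topology. Bacterial chromosomes and plasmids are typically circular; the
#' topology is never inferred beyond the GenBank `circular` keyword.
#'
#' @param contig_id Contig identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (non-empty).
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(contig_id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty DNA string", call. = FALSE)
  .check_dna(sequence)
  structure(list(contig_id = contig_id, sequence = sequence,
                 topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n",
              x$contig_id, nchar(x$sequence), x$topology))
  invisible(x)
}

.record_length <- function(record) nchar(record$sequence)

#' Extract a subsequence, strand- and origin-aware
#'
#' Coordinates are 0-based half-open on the forward axis. On circular contigs
#' the interval may wrap the origin (`end` past the contig length); on linear
#' contigs wrapping is an error. `strand = "-"` returns the reverse complement.
#'
#' @param record A [genome_record()].
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return DNA string of length `end - start`.
#' @export
subsequence <- function(record, start, end, strand = "+") {
  stopifnot(inherits(record, "genome_record"))
  L <- .record_length(record)
  if (start < 0 || end <= start)
    stop("invalid interval [", start, ",", end, ")", call. = FALSE)
  if (end > L) {
    if (record$topology != "circular")
      stop("interval [", start, ",", end, ") wraps the origin of linear contig ",
           record$contig_id, call. = FALSE)
    if (end - start > L)
      stop("interval longer than contig", call. = FALSE)
    s <- paste0(substr(record$sequence, start + 1L, L),
                substr(record$sequence, 1L, end - L))
  } else {
    s <- substr(record$sequence, start + 1L, end)
  }
  if (strand == "-") s <- revcomp(s)
  s
}

# ---- GenBank flat-file parsing -------------------------------------------

# Parse a GenBank location string into (start, end, strand) in the internal
# convention. Handles complement(), join() (used for origin-wrapping genes on
# circular contigs), and partial-end markers < >.
.parse_gb_location <- function(loc, contig_len, circular) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- if (strand == "+") "-" else "+"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    ivs <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", trimws(p)))[[1]]
      if (length(m) != 3) return(NULL)
      c(as.integer(m[2]), as.integer(m[3]))
    })
    if (any(vapply(ivs, is.null, logical(1)))) return(NULL)
    # Origin wrap: join(a..L, 1..b) on a circular contig.
    if (length(ivs) == 2 && circular &&
        ivs[[1]][2] == contig_len && ivs[[2]][1] == 1) {
      return(list(start = ivs[[1]][1] - 1L,
                  end = contig_len + ivs[[2]][2], strand = strand))
    }
    # Otherwise take the envelope of the parts (compound CDS are rare in
    # bacteria; the envelope preserves the targeting interval).
    s <- min(vapply(ivs, `[`, integer(1), 1)) - 1L
    e <- max(vapply(ivs, `[`, integer(1), 2))
    return(list(start = s, end = e, strand = strand))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3)
    return(list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]),
                strand = strand))
  m <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
  if (length(m) == 2) {
    p <- as.integer(m[2])
    return(list(start = p - 1L, end = p, strand = strand))
  }
  NULL
}

.parse_genbank <- function(path, include_rna = FALSE) {
  lines <- readLines(path, warn = FALSE)
  # Split into records at "//" terminators.
  term <- grep("^//", lines)
  if (length(term) == 0) stop("not a GenBank flat file: ", path, call. = FALSE)
  starts <- c(1L, head(term, -1) + 1L)
  records <- list()
  genes <- list()
  feature_counts <- c(CDS = 0L, gene = 0L, other = 0L)
  synthesized <- 0L
  rna_types <- c("tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA")
  for (ri in seq_along(term)) {
    chunk <- lines[starts[ri]:term[ri]]
    locus_line <- grep("^LOCUS", chunk, value = TRUE)[1]
    if (is.na(locus_line)) stop("GenBank record missing LOCUS line", call. = FALSE)
    toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
    contig_id <- toks[2]
    circular <- any(tolower(toks) == "circular")
    # ACCESSION/VERSION preferred as contig id when present.
    ver <- grep("^VERSION", chunk, value = TRUE)
    if (length(ver)) {
      v <- strsplit(trimws(ver[1]), "\\s+")[[1]]
      if (length(v) >= 2) contig_id <- v[2]
    }
    ostart <- grep("^ORIGIN", chunk)
    if (length(ostart) == 0) stop("GenBank record has no ORIGIN", call. = FALSE)
    seq_lines <- chunk[(ostart[1] + 1L):(length(chunk) - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    seq <- chartr("U", "T", seq)
    if (grepl("[^ACGTN]", seq)) seq <- gsub("[^ACGTN]", "N", seq)
    rec <- genome_record(contig_id, seq,
                         topology = if (circular) "circular" else "linear")
    records[[contig_id]] <- rec
    fstart <- grep("^FEATURES", chunk)
    if (length(fstart)) {
      feat_lines <- chunk[(fstart[1] + 1L):(ostart[1] - 1L)]
      # Feature keys start at column 6; qualifiers/continuations at column 22.
      key_idx <- grep("^ {5}\\S", feat_lines)
      for (ki in seq_along(key_idx)) {
        i0 <- key_idx[ki]
        i1 <- if (ki < length(key_idx)) key_idx[ki + 1] - 1L else length(feat_lines)
        block <- feat_lines[i0:i1]
        key <- sub("^ {5}(\\S+).*", "\\1", block[1])
        if (key == "CDS") feature_counts["CDS"] <- feature_counts["CDS"] + 1L
        else if (key == "gene") feature_counts["gene"] <- feature_counts["gene"] + 1L
        else if (key != "source") feature_counts["other"] <- feature_counts["other"] + 1L
        wanted <- key == "CDS" || (include_rna && key %in% rna_types)
        if (!wanted) next
        # Location may continue over lines until the first qualifier.
        qual_start <- grep("^ {21}/", block)
        loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
        loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", block[1]),
                              if (loc_end >= 2) trimws(block[2:loc_end]) else NULL)),
                     collapse = "")
        parsed <- .parse_gb_location(loc, nchar(seq), circular)
        if (is.null(parsed)) {
          warning("unparseable location skipped: ", loc, call. = FALSE)
          next
        }
        if (parsed$end > nchar(seq) && !circular)
          stop("feature coordinates outside linear contig ", contig_id,
               ": ", loc, call. = FALSE)
        qual_txt <- paste(block, collapse = "\n")
        lt <- regmatches(qual_txt, regexec('/locus_tag="([^"]+)"', qual_txt))[[1]]
        if (length(lt) == 2) {
          gid <- lt[2]
        } else {
          synthesized <- synthesized + 1L
          gid <- sprintf("%s_feat%05d", contig_id, synthesized)
          warning("feature without locus_tag; synthesized id ", gid,
                  call. = FALSE)
        }
        prod <- regmatches(qual_txt, regexec('/product="([^"]*)"', qual_txt))[[1]]
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, contig_id = contig_id,
          start = parsed$start, end = parsed$end, strand = parsed$strand,
          product = if (length(prod) == 2) gsub("\n {21}", " ", prod[2]) else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               product = character(), stringsAsFactors = FALSE)
  list(records = records, genes = genes, feature_counts = feature_counts)
}

# ---- FASTA + GFF3 --------------------------------------------------------

.read_fasta_records <- function(path, topology = "linear") {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  recs <- lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]]), topology = topology))
  names(recs) <- ids
  recs
}

.read_gff3_genes <- function(path, records, include_rna = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      product = character(), stringsAsFactors = FALSE))
  f <- read.delim(text = lines, header = FALSE, sep = "\t",
                  quote = "", stringsAsFactors = FALSE)
  if (ncol(f) < 9) stop("malformed GFF3: ", path, call. = FALSE)
  names(f) <- c("seqid", "source", "type", "start", "end", "score",
                "strand", "phase", "attributes")
  keep_types <- c("CDS", if (include_rna) c("tRNA", "rRNA", "ncRNA"))
  f <- f[f$type %in% keep_types, , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      product = character(), stringsAsFactors = FALSE))
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
           character(1))
  }
  gid <- get_attr(f$attributes, "locus_tag")
  alt <- get_attr(f$attributes, "ID")
  missing <- is.na(gid)
  gid[missing] <- alt[missing]
  still <- is.na(gid)
  if (any(still)) {
    warning(sum(still), " features without locus_tag/ID; ids synthesized",
            call. = FALSE)
    gid[still] <- sprintf("feat%05d", which(still))
  }
  for (cid in unique(f$seqid)) {
    if (!cid %in% names(records))
      stop("GFF3 refers to unknown contig ", cid, call. = FALSE)
    L <- .record_length(records[[cid]])
    sel <- f$seqid == cid
    if (any(f$end[sel] > L) && records[[cid]]$topology != "circular")
      stop("GFF3 coordinates outside linear contig ", cid, call. = FALSE)
  }
  data.frame(gene_id = gid, contig_id = f$seqid,
             start = f$start - 1L, end = f$end, strand = f$strand,
             product = get_attr(f$attributes, "product"),
             stringsAsFactors = FALSE)
}

#' Read an annotated genome
#'
#' Reads either a GenBank flat file or a FASTA + GFF3 pair into the internal
#' genome model: a set of [genome_record()]s plus one gene table. A "gene" is
#' any CDS feature carrying a `locus_tag` (RNA features are included only with
#' `include_rna = TRUE`); features lacking a `locus_tag` get a synthesized id
#' with a warning. Coordinates are converted to 0-based half-open on the
#' forward strand.
#'
#' @param path GenBank flat file, or FASTA when `gff` is given.
#' @param gff Optional GFF3 annotation path (FASTA route).
#' @param include_rna Also keep tRNA/rRNA/ncRNA features.
#' @param topology Topology for FASTA contigs (GenBank records carry their
#'   own `circular` keyword).
#' @return An object of class `ib_genome`: list with `records` (named list of
#'   `genome_record`) and `genes` (data.frame: gene_id, contig_id, start, end,
#'   strand, product). `attr(genes, "feature_counts")` reports strict-CDS and
#'   all-feature counts.
#' @export
read_genome <- function(path, gff = NULL, include_rna = FALSE,
                        topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!is.null(gff)) {
    if (!file.exists(gff)) stop("no such file: ", gff, call. = FALSE)
    records <- .read_fasta_records(path, topology = topology)
    genes <- .read_gff3_genes(gff, records, include_rna = include_rna)
    fc <- c(CDS = sum(!is.na(genes$gene_id)), gene = 0L, other = 0L)
  } else {
    head1 <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("^>", head1))
      stop("FASTA input requires a GFF3 annotation via `gff=`", call. = FALSE)
    if (!grepl("^LOCUS", head1))
      stop("unrecognized genome format (expected GenBank LOCUS or FASTA '>'): ",
           path, call. = FALSE)
    parsed <- .parse_genbank(path, include_rna = include_rna)
    records <- parsed$records
    genes <- parsed$genes
    fc <- parsed$feature_counts
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
               collapse = ", "), call. = FALSE)
  attr(genes, "feature_counts") <- fc
  structure(list(records = records, genes = genes), class = "ib_genome")
}

#' @export
print.ib_genome <- function(x, ...) {
  cat(sprintf("<ib_genome> %d contig(s), %d gene(s)\n",
              length(x$records), nrow(x$genes)))
  for (r in x$records) print(r)
  invisible(x)
}

#' Gene table of a genome
#' @param genome An `ib_genome`.
#' @return The gene data.frame (0-based half-open coordinates).
#' @export
gene_models <- function(genome) {
  stopifnot(inherits(genome, "ib_genome"))
  genome$genes
}

#' Coding-strand sequence of one gene
#' @param genome An `ib_genome`.
#' @param gene_id Gene (locus_tag) identifier.
#' @return DNA string, 5'->3' on the coding strand.
#' @export
gene_seq <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id, call. = FALSE)
  subsequence(genome$records[[g$contig_id]], g$start, g$end, g$strand)
}

# ---- Writers -------------------------------------------------------------

#' Write a genome as a GenBank flat file
#'
#' Emits one record per contig with CDS features (1-based inclusive,
#' `complement()` for minus-strand genes) and the sequence in canonical
#' 60-column ORIGIN blocks. The output round-trips through [read_genome()].
#'
#' @param genome An `ib_genome`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "ib_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in genome$records) {
    L <- .record_length(rec)
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN 01-JAN-2026",
                       rec$contig_id, L, rec$topology), con)
    writeLines(sprintf("DEFINITION  synthetic construct %s.", rec$contig_id), con)
    writeLines(sprintf("ACCESSION   %s", rec$contig_id), con)
    writeLines(sprintf("VERSION     %s", rec$contig_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    g <- genome$genes[genome$genes$contig_id == rec$contig_id, , drop = FALSE]
    if (nrow(g)) {
      for (i in seq_len(nrow(g))) {
        if (g$end[i] > L) {  # origin-wrapping gene on a circular contig
          loc <- sprintf("join(%d..%d,1..%d)", g$start[i] + 1L, L, g$end[i] - L)
        } else {
          loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
        }
        if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     gene            %s", loc), con)
        writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
        writeLines(sprintf("     CDS             %s", loc), con)
        writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
        prod <- g$product[i]
        if (!is.na(prod))
          writeLines(sprintf("                     /product=\"%s\"", prod), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(rec$sequence)
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, L))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write contig sequences as FASTA
#' @param genome An `ib_genome`.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ib_genome"))
  ss <- Biostrings::DNAStringSet(
    setNames(vapply(genome$records, `[[`, "", "sequence"),
             vapply(genome$records, `[[`, "", "contig_id")))
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Write the gene table as GFF3
#' @param genome An `ib_genome`.
#' @param path Output path.
#' @export
write_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "ib_genome"))
  g <- genome$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (rec in genome$records)
    writeLines(sprintf("##sequence-region %s 1 %d", rec$contig_id,
                       .record_length(rec)), con)
  if (nrow(g)) {
    attrs <- sprintf("ID=%s;locus_tag=%s%s", g$gene_id, g$gene_id,
                     ifelse(is.na(g$product), "",
                            paste0(";product=", g$product)))
    writeLines(sprintf("%s\tcrisprib\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       g$contig_id, g$start + 1L, g$end, g$strand, attrs), con)
  }
  invisible(path)
}

#' Write genomic intervals as BED6
#'
#' @param df Data.frame with columns contig_id, start, end (0-based
#'   half-open), name, score, strand.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("contig_id", "start", "end", "name", "strand") %in% names(df)))
  score <- if ("score" %in% names(df)) df$score else 0
  out <- data.frame(df$contig_id, df$start, df$end, df$name, score, df$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
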