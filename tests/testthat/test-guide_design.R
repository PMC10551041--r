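test_that("classify_mode partitions exactly at the boundary", {
  expect_equal(classify_mode(26), "repression")
  expect_equal(classify_mode(27), "cleavage")
  expect_equal(classify_mode(11), "repression")
  for (L in 8:40)
    expect_equal(classify_mode(L) == "repression", L <= 26)
  expect_equal(classify_mode(25, boundary = 24), "cleavage")
  expect_error(classify_mode(7), ">= 8")
})

test_that("truncation_series keeps the PAM-proximal prefix", {
  set.seed(3)
  full <- rand_dna(30)
  tr <- truncation_series(full)
  expect_equal(tr$length, c(30L, 25L, 20L, 15L, 11L))
  expect_equal(tr$mode, c("cleavage", rep("repression", 4)))
  for (i in seq_len(nrow(tr)))
    expect_equal(tr$spacer[i], substr(full, 1, tr$length[i]))
  expect_equal(truncation_series(full, lengths = 30)$spacer, full)
  expect_error(truncation_series(full, lengths = 31), "exceeds")
})

test_that("every truncation variant re-localizes to the same site", {
  res <- make_genome(genome_spec(n_genes = 1, gene_len_range = c(600, 900),
                                 seed = 19))
  genome <- res$genome
  site <- res$truth[1, ]
  rec <- genome$records[[1]]
  full <- if (site$strand == "+")
    substr(rec$sequence, site$protospacer_start + 1,
           site$protospacer_start + 30)
  else
    revcomp(substr(rec$sequence, site$protospacer_start - 28,
                   site$protospacer_start + 1))
  left30 <- if (site$strand == "+") site$protospacer_start
            else site$protospacer_start - 29
  tr <- truncation_series(full)
  for (i in seq_len(nrow(tr))) {
    h <- match_spacer(tr$spacer[i], genome, max_mm = 0)
    h <- h[h$strand == site$strand, ]
    left <- if (site$strand == "+") site$protospacer_start
            else site$protospacer_start - tr$length[i] + 1
    expect_true(left %in% h$offset)
  }
})

test_that("design_gene_guides fills three bins on an engineered gene", {
  res <- make_genome(genome_spec(n_genes = 2, seed = 61))
  for (i in 1:2) {
    gene <- res$genome$genes[i, ]
    out <- design_gene_guides(gene, res$genome,
                              design_params(specificity = "off"))
    expect_equal(out$guides$bin, c("upstream", "mid", "downstream"))
    expect_equal(nrow(out$gaps), 0)
    expect_equal(unique(out$guides$mode), "repression")
    expect_equal(unique(out$guides$length), 20L)
    # Template-strand rule: protospacer read from the coding strand.
    expect_equal(unique(out$guides$strand), gene$strand)
  }
})

test_that("a gene with no PAM on the targeted strand yields a gap record", {
  # Gene of pure G on the coding strand: no TTA anywhere on it.
  set.seed(71)
  seq <- paste0(rand_dna(50), strrep("G", 300), rand_dna(50))
  genome <- structure(list(
    records = list(c1 = genome_record("c1", seq)),
    genes = data.frame(gene_id = "G1", contig_id = "c1", start = 50L,
                       end = 350L, strand = "+", product = NA,
                       stringsAsFactors = FALSE)), class = "ib_genome")
  out <- design_gene_guides(genome$genes[1, ], genome,
                            design_params(specificity = "off"))
  expect_equal(nrow(out$guides), 0)
  expect_equal(out$gaps$bin, c("upstream", "mid", "downstream"))
  # A too-short gene is skipped with a warning.
  genome$genes$end <- 60L
  expect_warning(out <- design_gene_guides(genome$genes[1, ], genome),
                 "shorter")
  expect_equal(nrow(out$guides), 0)
})

test_that("designed guides are self-consistent against the genome", {
  res <- make_genome(genome_spec(n_genes = 6, seed = 77))
  lib <- design_library(res$genome, params = design_params(specificity = "off"))
  expect_gt(nrow(lib$guides), 0)
  rec <- res$genome$records[[1]]
  for (i in seq_len(nrow(lib$guides))) {
    g <- lib$guides[i, ]
    # Genome lookup reproduces the spacer with the core PAM immediately 5'.
    sp <- subsequence(rec,
                      if (g$strand == "+") g$protospacer_start
                      else g$protospacer_start - g$length + 1,
                      if (g$strand == "+") g$protospacer_start + g$length
                      else g$protospacer_start + 1,
                      g$strand)
    expect_equal(sp, g$spacer)
    pam <- if (g$strand == "+")
      subsequence(rec, g$pam_start, g$pam_start + 3, "+")
    else
      subsequence(rec, g$pam_start - 2, g$pam_start + 1, "-")
    expect_equal(pam, "TTA")
    # match_spacer confirms a zero-mismatch hit at the recorded site.
    h <- match_spacer(g$spacer, res$genome, max_mm = 0)
    left <- if (g$strand == "+") g$protospacer_start
            else g$protospacer_start - g$length + 1
    expect_true(any(h$offset == left & h$strand == g$strand))
  }
})

test_that("design_library is deterministic and reports coverage stats", {
  res <- make_genome(genome_spec(n_genes = 10, seed = 101))
  p <- design_params(specificity = "off")
  lib1 <- design_library(res$genome, params = p)
  lib2 <- design_library(res$genome, params = p)
  expect_identical(lib1$guides, lib2$guides)
  expect_equal(lib1$stats$genes_targeted, 10)
  expect_equal(lib1$stats$total_guides, 30)
  expect_equal(lib1$stats$fraction_full_bins, 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_manifest(lib1$guides, f1)
  write_manifest(lib2$guides, f2)
  expect_identical(unname(md5sum(f1)), unname(md5sum(f2)))
  # Manifest round-trips through read_manifest.
  back <- read_manifest(f1)
  expect_equal(back$spacer, lib1$guides$spacer)
  expect_equal(back$pam_start, lib1$guides$pam_start)
  # Empty gene list gives zeroed stats.
  lib0 <- design_library(res$genome, genes = res$genome$genes[0, ], params = p)
  expect_equal(lib0$stats$total_guides, 0)
  expect_equal(lib0$stats$genes_total, 0)
})

test_that("relaxing the specificity policy never loses targeted genes", {
  res <- make_genome(genome_spec(n_genes = 8, seed = 55))
  on_ <- design_library(res$genome, params = design_params(specificity = "on"))
  off <- design_library(res$genome, params = design_params(specificity = "off"))
  expect_gte(off$stats$genes_targeted, on_$stats$genes_targeted)
  expect_gte(off$stats$total_guides, on_$stats$total_guides)
})

test_that("design_editing yields an immune locus with abutting arms", {
  res <- make_genome(genome_spec(n_genes = 3, gene_len_range = c(900, 1200),
                                 seed = 47))
  genome <- res$genome
  gene <- genome$genes[2, ]
  p <- design_params(arm_len = 150)
  ed <- design_editing(genome, gene$contig_id, c(gene$start, gene$end), p)
  expect_s3_class(ed, "editing_design")
  expect_equal(ed$mode, "cleavage")
  expect_equal(ed$length, 30)
  # Arms abut the deletion interval exactly.
  expect_equal(ed$upstream_arm$end, gene$start)
  expect_equal(ed$upstream_arm$start, gene$start - 150)
  expect_equal(ed$downstream_arm$start, gene$end)
  expect_equal(nchar(ed$upstream_arm$seq), 150)
  # Simulated deletion leaves no PAM-adjacent spacer match within 1 mm.
  rec <- genome$records[[1]]
  L <- nchar(rec$sequence)
  deleted <- paste0(substr(rec$sequence, 1, gene$start),
                    substr(rec$sequence, gene$end + 1, L))
  h <- match_spacer(ed$spacer, c(edited = deleted), max_mm = 1)
  expect_equal(nrow(h[h$pam_class != "none", ]), 0)
  # Interval with no internal cleavage-length site errors with context.
  expect_error(design_editing(genome, gene$contig_id,
                              c(gene$start, gene$start + 25), p),
               "nearest PAM")
})
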