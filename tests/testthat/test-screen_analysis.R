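test_that("count_guides conserves reads and recovers truth exactly", {
  lib <- random_library(30, seed = 5)
  sp <- screen_spec(lib, depth = 3000, seed = 8)
  res <- make_screen_reads(sp)
  ct <- count_guides(res$baseline, lib, anchor5 = TEST_ANCHOR5)
  expect_identical(as.integer(ct$counts), res$truth$baseline_true)
  expect_equal(ct$assigned + ct$unassigned, ct$total)
  expect_equal(ct$total, 3000L)
  # Empty FASTQ -> all-zero table.
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  ct0 <- count_guides(empty, lib, anchor5 = TEST_ANCHOR5)
  expect_equal(sum(ct0$counts), 0L)
  expect_equal(ct0$total, 0L)
})

test_that("spacer mismatch tolerance and unassignment reasons work", {
  lib <- random_library(10, seed = 6)
  good <- paste0(TEST_ANCHOR5, lib$spacer[1], "GTTCAG")
  mut_sp <- lib$spacer[2]
  substr(mut_sp, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut_sp, 5, 5))[1]
  mutant <- paste0(TEST_ANCHOR5, mut_sp, "GTTCAG")
  noanchor <- paste0(strrep("G", 20), lib$spacer[3], "GTTCAG")
  reads <- c(r1 = good, r2 = mutant, r3 = noanchor)
  ct0 <- count_guides(reads, lib, anchor5 = TEST_ANCHOR5, max_mm_spacer = 0)
  expect_equal(unname(ct0$counts[c("g0001", "g0002")]), c(1L, 0L))
  expect_equal(unname(ct0$reasons["no_spacer_match"]), 1L)
  expect_equal(unname(ct0$reasons["no_anchor"]), 1L)
  ct1 <- count_guides(reads, lib, anchor5 = TEST_ANCHOR5, max_mm_spacer = 1)
  expect_equal(unname(ct1$counts[c("g0001", "g0002")]), c(1L, 1L))
  # A read whose anchor itself carries one substitution is still located.
  mut_anchor <- TEST_ANCHOR5
  substr(mut_anchor, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                      substr(mut_anchor, 3, 3))[1]
  ct2 <- count_guides(c(r = paste0(mut_anchor, lib$spacer[4])), lib,
                      anchor5 = TEST_ANCHOR5)
  expect_equal(unname(ct2$counts["g0004"]), 1L)
  # Reverse-orientation reads are recovered with orient = "both".
  rcread <- revcomp(paste0(TEST_ANCHOR5, lib$spacer[5]))
  expect_equal(sum(count_guides(c(r = rcread), lib,
                                anchor5 = TEST_ANCHOR5)$counts), 0L)
  ctb <- count_guides(c(r = rcread), lib, anchor5 = TEST_ANCHOR5,
                      orient = "both")
  expect_equal(unname(ctb$counts["g0005"]), 1L)
})

test_that("ambiguous libraries are refused up front", {
  lib <- random_library(5, seed = 9)
  dup <- rbind(lib, data.frame(guide_id = "dup", spacer = lib$spacer[1]))
  expect_error(count_guides(character(0), dup, anchor5 = TEST_ANCHOR5),
               "ambiguous")
  near <- lib
  s <- lib$spacer[1]
  substr(s, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(s, 2, 2))[1]
  near$spacer[2] <- s
  expect_silent(count_guides(character(0), near, anchor5 = TEST_ANCHOR5,
                             max_mm_spacer = 0))
  expect_error(count_guides(character(0), near, anchor5 = TEST_ANCHOR5,
                            max_mm_spacer = 1), "ambiguous")
})

test_that("enrich matches the closed-form binomial oracle", {
  # Identical tables: all log2fc exactly zero.
  lib <- random_library(8, seed = 12)
  cts <- setNames(rep(100L, 8), lib$guide_id)
  e0 <- enrich(cts, cts)
  expect_equal(e0$log2fc, rep(0, 8))
  # Toy counts: baseline 10/1000, selected 100/1000 for one guide.
  b <- setNames(as.integer(c(10, rep(110, 9))), sprintf("g%d", 1:10))
  s <- setNames(as.integer(c(100, rep(100, 9))), sprintf("g%d", 1:10))
  e <- enrich(b, s, pseudocount = 0.5)
  B <- sum(b); S <- sum(s)
  # Oracle: doubled smaller tail computed by direct density summation.
  p0 <- (10 + 0.5) / (B + 1)
  d <- dbinom(0:S, S, p0)
  lower <- sum(d[0:100 + 1])
  upper <- sum(d[100:S + 1])
  expect_equal(e$p_value[e$guide_id == "g1"],
               min(1, 2 * min(lower, upper)), tolerance = 1e-12)
  expect_true(all(diff(e$q_value[order(e$p_value)]) >= -1e-15))
  expect_equal(sort(e$rank), 1:10)
  expect_error(enrich(b, s * 0L), "zero-total")
  # Permutation flag: exact conditional test vs direct hypergeometric
  # density summation at small counts.
  ep <- enrich(b, s, method = "permutation")
  t1 <- 10 + 100
  d <- dhyper(0:t1, S, B, t1)
  lower <- sum(d[0:100 + 1])
  upper <- sum(d[100:t1 + 1])
  expect_equal(ep$p_value[ep$guide_id == "g1"],
               min(1, 2 * min(lower, upper)), tolerance = 1e-12)
})

test_that("spiked guides dominate the ranking and top_hits recovers them", {
  lib <- random_library(200, seed = 14)
  spiked <- lib$guide_id[c(3, 50, 120)]
  sp <- screen_spec(lib, depth = 2e5,
                    enriched = data.frame(guide_id = spiked, fold = 50),
                    seed = 15)
  res <- make_screen_reads(sp)
  bl <- count_guides(res$baseline, lib, anchor5 = TEST_ANCHOR5)
  se <- count_guides(res$selected, lib, anchor5 = TEST_ANCHOR5)
  e <- enrich(bl, se)
  expect_setequal(top_hits(e, 3), spiked)
  expect_true(all(e$q_value[match(spiked, e$guide_id)] <= 0.05))
  expect_equal(top_hits(e, 1), e$guide_id[1])
  expect_warning(th <- top_hits(e, 1000), "truncated")
  expect_length(th, 200)
})

test_that("gene-level aggregation takes each gene's best guide", {
  res <- make_genome(genome_spec(n_genes = 4, seed = 16))
  lib <- design_library(res$genome,
                        params = design_params(specificity = "off"))$guides
  spiked <- lib$guide_id[lib$gene_id == lib$gene_id[4]][1]
  sp <- screen_spec(lib, depth = 5e4,
                    enriched = data.frame(guide_id = spiked, fold = 40),
                    seed = 18)
  resr <- make_screen_reads(sp)
  e <- enrich(count_guides(resr$baseline, lib, anchor5 = TEST_ANCHOR5),
              count_guides(resr$selected, lib, anchor5 = TEST_ANCHOR5))
  genes <- top_hits(e, 1, by = "gene", manifest = lib)
  expect_equal(genes, lib$gene_id[lib$guide_id == spiked])
})

test_that("ties in log2fc break stably by guide_id", {
  b <- setNames(rep(50L, 4), c("gB", "gA", "gD", "gC"))
  s <- setNames(rep(50L, 4), c("gB", "gA", "gD", "gC"))
  e <- enrich(b, s)
  expect_equal(e$guide_id, c("gA", "gB", "gC", "gD"))
})

test_that("null screens keep the BH-significant fraction within bounds", {
  # Count-level nulls (the FASTQ layer is exercised elsewhere): 20 seeded
  # multinomial draws at depth 1e6 over 1000 guides.
  fracs <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    b <- setNames(as.integer(rmultinom(1, 1e6, rep(1, 1000))),
                  sprintf("g%04d", 1:1000))
    s <- setNames(as.integer(rmultinom(1, 1e6, rep(1, 1000))),
                  sprintf("g%04d", 1:1000))
    e <- enrich(b, s)
    mean(e$q_value <= 0.05)
  }, numeric(1))
  expect_true(all(fracs <= 0.07))
})

test_that("all >= 10x spikes are recovered in top-k across 20 seeds", {
  ids <- sprintf("g%04d", 1:1000)
  spiked <- ids[1:6]
  for (i in 1:20) {
    set.seed(2000 + i)
    fold <- rep(1, 1000)
    fold[1:6] <- 10
    b <- setNames(as.integer(rmultinom(1, 1e6, rep(1, 1000))), ids)
    s <- setNames(as.integer(rmultinom(1, 1e6, fold)), ids)
    e <- enrich(b, s)
    expect_setequal(top_hits(e, 6), spiked)
  }
})
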