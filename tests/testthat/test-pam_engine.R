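test_that("scan_pams reports sites in the stated orientation", {
  rec <- genome_record("c", "TTAGGGGGG")
  s <- scan_pams(rec, strands = "+")
  expect_equal(nrow(s), 1)
  expect_equal(s$pam_start, 0)
  expect_equal(s$protospacer_start, 3)
  expect_equal(s$max_protospacer_len, 6)
  # Reverse-strand core: CCTAACC carries TTA on the minus strand.
  rec <- genome_record("c", "CCTAACC")
  s <- scan_pams(rec)
  expect_equal(s$strand, "-")
  # Oracle: scan the reverse complement and remap coordinates.
  rc <- genome_record("c", revcomp("CCTAACC"))
  s2 <- scan_pams(rc, strands = "+")
  L <- 7
  expect_equal(s$pam_start, L - 1 - s2$pam_start)
  expect_equal(s$protospacer_start, L - 1 - s2$protospacer_start)
})

test_that("scan_pams equals the naive substring count on random sequence", {
  set.seed(11)
  seq <- rand_dna(1000)
  rec <- genome_record("c", seq)
  s <- scan_pams(rec)
  expect_equal(sum(s$strand == "+"), naive_count(seq, "TTA"))
  expect_equal(sum(s$strand == "-"), naive_count(seq, "TAA"))
  expect_false(is.unsorted(s$pam_start[s$strand == "+"]))
})

test_that("scan_pams strand-mirror property holds on random sequences", {
  set.seed(12)
  for (i in 1:5) {
    seq <- rand_dna(400)
    L <- nchar(seq)
    a <- scan_pams(genome_record("c", seq))
    b <- scan_pams(genome_record("c", revcomp(seq)))
    mirror <- data.frame(strand = ifelse(b$strand == "+", "-", "+"),
                         pam_start = L - 1 - b$pam_start)
    mirror <- mirror[order(mirror$strand, mirror$pam_start), ]
    expect_equal(a$strand, mirror$strand)
    expect_equal(a$pam_start, mirror$pam_start)
  }
})

test_that("circular scanning finds origin-spanning cores", {
  # TA|...|T : core TTA spans the origin.
  rec <- genome_record("c", "TAGGGGGGT", "circular")
  s <- scan_pams(rec, strands = "+")
  expect_true(8 %in% s$pam_start)
  lin <- genome_record("c", "TAGGGGGGT", "linear")
  expect_false(8 %in% scan_pams(lin, strands = "+")$pam_start)
})

test_that("enumerate_pam_variants completes wildcard templates", {
  v64 <- enumerate_pam_variants("NNN")
  expect_length(v64, 64)
  expect_equal(anyDuplicated(v64), 0)
  expect_equal(v64[1], "AAA")
  v16 <- enumerate_pam_variants("NNTTA")
  expect_length(v16, 16)
  expect_true(all(substr(v16, 3, 5) == "TTA"))
  expect_equal(enumerate_pam_variants("TTA"), "TTA")
  for (tpl in c("N", "AN", "NAN")) {
    v <- enumerate_pam_variants(tpl)
    expect_length(v, 4^lengths(regmatches(tpl, gregexpr("N", tpl))))
    expect_equal(anyDuplicated(v), 0)
  }
  expect_error(enumerate_pam_variants("NZX"), "must be over")
})

test_that("build_pfm tallies columns and conserves column sums", {
  p <- build_pfm(rep("TTA", 5))
  expect_equal(unname(colSums(p$counts)), rep(5, 3))
  expect_equal(pfm_consensus(p), "TTA")
  p2 <- build_pfm(c("TTA", "CTA"))
  expect_equal(p2$counts["T", 1], 1L)
  expect_equal(p2$counts["C", 1], 1L)
  # Oracle: independent per-position tally of 100 random 5-mers.
  set.seed(31)
  seqs <- vapply(1:100, function(i) rand_dna(5), "")
  p3 <- build_pfm(seqs)
  for (j in 1:5) {
    col <- substr(seqs, j, j)
    for (b in c("A", "C", "G", "T"))
      expect_equal(unname(p3$counts[b, j]), sum(col == b))
  }
  # Adding one sequence increments every column sum by 1.
  p4 <- build_pfm(c(seqs, "ACGTA"))
  expect_equal(colSums(p4$counts), colSums(p3$counts) + 1)
  expect_error(build_pfm(c("TTA", "TT")), "same length")
})

test_that("match_spacer finds exact and mismatched hits with flanks", {
  set.seed(17)
  spacer <- rand_dna(20)
  target <- paste0(rand_dna(50), "GGTTA", spacer, rand_dna(40))
  h <- match_spacer(spacer, c(t1 = target))
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 55)
  expect_equal(h$mismatches, 0)
  expect_equal(h$flank5, "GGTTA")
  expect_equal(h$pam_class, "core")
  # One substitution: visible at max_mm 1, absent at 0.
  mut <- spacer
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(spacer, 10, 10))[1]
  expect_equal(nrow(match_spacer(mut, c(t1 = target), max_mm = 0)), 0)
  h1 <- match_spacer(mut, c(t1 = target), max_mm = 1)
  expect_equal(h1$mismatches, 1)
  # A spacer longer than the target yields an empty result.
  expect_equal(nrow(match_spacer(spacer, c(t1 = "ACGTACGTAC"))), 0)
})

test_that("match_spacer equals independent Hamming scans on random targets", {
  set.seed(23)
  target <- rand_dna(10000)
  spacer <- substr(target, 5001, 5020)
  got <- match_spacer(spacer, c(t = target), max_mm = 3)
  expect_equal(hit_key(got), hit_key(cbind(biostrings_hits(spacer, target, 3))))
  # Small case against the naive window-by-window loop, both strands.
  target <- rand_dna(300)
  spacer <- rand_dna(8)
  got <- match_spacer(spacer, c(t = target), max_mm = 2)
  plus <- naive_hamming_hits(target, spacer, 2)
  rcs <- naive_hamming_hits(revcomp(target), spacer, 2)
  minus <- data.frame(offset = nchar(target) - rcs$offset - 8,
                      mismatches = rcs$mismatches)
  expect_equal(hit_key(got[got$strand == "+", ]),
               hit_key(cbind(plus, strand = "+")))
  expect_equal(hit_key(got[got$strand == "-", ]),
               hit_key(cbind(minus, strand = "-")))
})

test_that("minus-strand flanks are read from the matching strand", {
  set.seed(29)
  spacer <- rand_dna(15)
  core <- paste0("AG", "TTA")
  insert <- revcomp(paste0(core, spacer))
  target <- paste0(rand_dna(30), insert, rand_dna(30))
  h <- match_spacer(spacer, c(t = target))
  expect_equal(h$strand, "-")
  expect_equal(h$flank5, "AGTTA")
  expect_equal(h$pam_class, "core")
})

test_that("parse_crispr_array recovers ordered spacers", {
  R <- TEST_REPEAT
  expect_equal(parse_crispr_array(paste0(R, "AAAA", R, "CCCC", R), R),
               c("AAAA", "CCCC"))
  expect_error(parse_crispr_array(paste0(R, "AAAA"), R), "not an array")
  # A repeat copy carrying one substitution is still located at max_mm 1.
  set.seed(37)
  spacers <- vapply(1:3, function(i) rand_dna(25), "")
  mutR <- R
  substr(mutR, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(R, 4, 4))[1]
  arr <- paste0(R, spacers[1], mutR, spacers[2], R, spacers[3], R)
  expect_equal(parse_crispr_array(arr, R, max_repeat_mm = 1), spacers)
})

test_that("array build/parse round-trips for random spacer sets", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(1:8, 1)
    spacers <- vapply(1:n, function(j) rand_dna(sample(c(20, 25), 1)), "")
    arr <- build_array(spacers, TEST_REPEAT)
    expect_equal(parse_crispr_array(arr$assembled, TEST_REPEAT), spacers)
  }
})
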