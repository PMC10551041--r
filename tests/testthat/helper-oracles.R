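# Independent oracles used across the suite. These deliberately avoid the
# production code paths: naive substring loops for small cases, and
# Biostrings (an independent C implementation) for larger Hamming scans.

suppressPackageStartupMessages({
  library(Biostrings)
  library(tools)   # md5sum
})

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Naive overlapping substring count.
naive_count <- function(seq, motif) {
  k <- nchar(motif)
  n <- nchar(seq)
  if (k > n) return(0L)
  sum(vapply(1:(n - k + 1), function(i) substr(seq, i, i + k - 1) == motif,
             logical(1)))
}

# Window-by-window Hamming scan of one strand; returns 0-based offsets and
# mismatch counts.
naive_hamming_hits <- function(seq, pattern, max_mm) {
  k <- nchar(pattern)
  n <- nchar(seq)
  if (k > n) return(data.frame(offset = integer(), mismatches = integer()))
  p <- strsplit(pattern, "")[[1]]
  hits <- lapply(1:(n - k + 1), function(i) {
    w <- strsplit(substr(seq, i, i + k - 1), "")[[1]]
    mm <- sum(w != p)
    if (mm <= max_mm) c(i - 1L, mm) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(data.frame(offset = integer(), mismatches = integer()))
  data.frame(offset = hits[, 1], mismatches = hits[, 2])
}

# Both-strand Hamming hit set via Biostrings, in match_spacer's coordinate
# convention (offset = leftmost forward-axis base of the window).
biostrings_hits <- function(spacer, seq, max_mm) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(spacer)
  k <- length(pat)
  n <- length(subj)
  out <- list()
  v <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
  if (length(v)) {
    st <- BiocGenerics::start(v)
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
    out$p <- data.frame(offset = st - 1L, strand = "+", mismatches = mm)
  }
  rc <- Biostrings::reverseComplement(subj)
  v <- Biostrings::matchPattern(pat, rc, max.mismatch = max_mm)
  if (length(v)) {
    st <- BiocGenerics::start(v)
    mm <- Biostrings::neditStartingAt(pat, rc, starting.at = st)
    out$m <- data.frame(offset = n - (st - 1L) - k, strand = "-",
                        mismatches = mm)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(offset = integer(), strand = character(),
                      mismatches = integer()))
  res <- res[order(res$strand, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Canonical form of a match_spacer result for set comparison.
hit_key <- function(df) {
  df <- df[order(df$strand, df$offset), c("offset", "strand", "mismatches"),
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Example flank configuration (synthetic sequences).
test_flanks <- function(enzyme = "BsaI")
  flank_config(prime5 = "ACACTCTTTCCCTACACGAC",
               prime3 = "GTTCAGACGTGTGCTCTTCC",
               enzyme = enzyme, overhang5 = "TAGT", overhang3 = "CGCA")

TEST_REPEAT <- "GTCGCACCCTTCATGGGTGCGACAAGAATC"
TEST_ANCHOR5 <- "ACACTCTTTCCCTACACGAC"
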