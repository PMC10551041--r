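---
title: "Methods and design notes for crisprib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for crisprib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprib)
```

# The system and the model

`crisprib` models guide design for the endogenous type I-B CRISPR-Cas
system of the thermophile *Parageobacillus thermoglucosidasius* (effectors
Cas3 and Cas5–8). Two experimentally established rules drive everything:

**PAM rule.** Target recognition requires the 3-nt core motif **TTA**
immediately 5′ of the protospacer on the protospacer-carrying strand.
Saturation mutagenesis of the five upstream positions shows that only
−3..−1 are constrained: the −5 and −4 positions are functionally
independent, and four core variants (CTA, TCA, TTG, TTT) retain weak
(orders-of-magnitude lower) interference activity. The package therefore
treats PAM recognition *categorically*: a 3-nt core (design), plus a
permissive set (off-target screening). No probabilistic PAM scoring is
attempted — the data supporting it do not exist for this system.

**Length-switch rule.** The crRNA spacer length selects the functional
mode: with ≤ 26 nt of complementarity, Cascade binds its target and
represses transcription without cleavage (these short guides are called
tgRNAs); with ≥ 27 nt, Cas3 is recruited and the target is degraded.
`classify_mode()` encodes this partition exactly: repression iff
`length <= boundary` with `boundary = 26`.

## Strand convention

"A guide targets the template strand" is convention-dependent wording; the
convention adopted here is: the crRNA *hybridizes to* the template
(non-coding) strand, so the **protospacer and its PAM are read from the
gene's coding strand**. For a forward-strand gene the protospacer strand is
`+`; for a reverse-strand gene it is `-`. This is the reading under which a
repressive guide whose PAM lies on the non-template strand of its reporter
behaves as observed. `strand_mode` in `design_params()` remains
configurable (`template`/`nontemplate`/`both`) because other systems and
other users may need the opposite convention.

## Truncation anchoring

Shortening a spacer removes PAM-**distal** (3′) bases and preserves the
PAM-proximal seed. This is the only anchoring under which an entire
truncation series (30/25/20/15/11 nt) keeps addressing the same protospacer
site, which is what the characterization experiments require.
`truncation_series()` therefore takes prefixes of the full spacer.

## Coordinates

Internally every interval is 0-based half-open on the forward strand; for a
minus-strand PAM site, `pam_start` is the forward-axis coordinate of the
base that is the first core base when read 5′→3′ on the minus strand, and
`protospacer_start` is the forward-axis coordinate of the first protospacer
base (positions *decrease* 3′-ward on the minus strand). User-facing
writers (manifests, BED, GenBank) convert to the 1-based inclusive GenBank
convention at the boundary. Circular topology is explicit per contig and
enables origin-wrapping intervals, PAM sites and genes.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `repression_len` | 20 | nt | the genome-scale tgRNA library is a 20-mer library; comfortably below the 26-nt switch |
| `mode_boundary` | 26 | nt | longest repressive length; 27 nt is the shortest cleaving length |
| `cleavage_len` | 30 | nt | shortest length shown uniformly lethal on targeting; a 38-nt editing preset exists for *E. coli* work |
| `guides_per_gene` / `bins` | 3 / 3 | — | one guide per third (upstream/mid/downstream) of the CDS |
| `exclusion` | BsaI + Esp3I sites | — | keeps every spacer directly clonable by Golden Gate in both the library (BsaI) and editing (Esp3I) workflows |
| `max_homopolymer` | 6 | nt | synthesis/sequencing robustness; common oligo-design practice |
| `arm_len` | 600 | bp | homology arms for allelic exchange; a common arm size, exposed in config since no value is prescribed |
| `max_mm_reject` | 1 | mismatches | a protospacer with a single mispair still supports interference, so 1-mm secondary sites are disqualifying |
| `pam_scope` | permissive_set | — | weak PAM variants retain activity, so they count for off-targets |
| pseudocount `c` | 0.5 | counts | Jeffreys-style shrinkage for CPM ratios and testable zero-baseline guides |

## Positional binning and tie-breaks

The gene body is split into `bins` equal thirds along the coding direction.
A candidate site is assigned to the third containing its protospacer start;
within each bin the chosen candidate is the one passing all filters that is
(1) lowest in off-target hits (when specificity is on), then (2) closest to
the bin center, then (3) smallest in coordinate. The full protospacer must
lie inside the gene body; the PAM core may extend upstream of the start
codon (it is adjacent sequence, not guide sequence) — this maximizes
coverage of short genes without targeting intergenic DNA.

## Specificity policy: dual default

The genome-coverage numbers a user reproduces with `specificity = "off"`
reflect raw PAM availability; the exact dropping rules behind any published
library are generally not recoverable, so coverage claims are lower-bound
checks. For *designing new* libraries the default is `specificity = "on"`:
a guide is rejected if a secondary site within 1 mismatch sits next to any
permissive PAM. The intended site is excluded by *coordinates*, never by
sequence, so spacers duplicated elsewhere in the genome are correctly
flagged. Truncated guides are screened at their truncated length — the
repressive species is the truncated crRNA itself, so its own off-target
space is what matters. Mismatch counting is positionally uniform
(substitution-only Hamming): there is no positional mismatch-tolerance data
for this system, and no indel evidence.

# Screen analysis model

Reads are amplicons: a constant 5′ anchor immediately precedes the spacer.
The anchor is located exact-first with a ≤ 1-mismatch fallback; the
fixed-length window after it is matched to the library at 0 or 1
substitutions (library ambiguity at the chosen tolerance is detected up
front and is an error, not a warning). Counting conserves reads:
assigned + unassigned = input, with per-reason tallies.

**Enrichment statistic.** No specific statistic is prescribed for calling
"significantly enriched" guides in this kind of screen, so the package uses
the simplest defensible model: for each guide, a two-sided binomial test
(doubled smaller tail, capped at 1) of the selected count against the
guide's baseline proportion, with the baseline proportion shrunk as
`(b + c)/(B + 2c)`, followed by Benjamini–Hochberg FDR correction. The
ordering places `q ≤ alpha` guides first by decreasing log2 fold change,
then the remainder by log2 fold change, with ties broken by `guide_id` for
byte-stable output. Treating the baseline proportion as fixed ignores its
sampling noise and makes the test mildly anti-conservative; empirically
(seeded null simulations at depth 10⁶ over 1,000 guides, run in the test
suite) the BH-significant fraction stays ≤ 3–4%, inside the ≤ 7% envelope
asserted by the tests. Gene-level scores take each gene's best guide
(validation in such screens is per-guide, so averaging would dilute real
hits). An exact permutation alternative (`enrich(..., method =
"permutation")`) conditions on each guide's pooled total, under which
label permutation over reads yields the hypergeometric null; it avoids the
plug-in baseline proportion at the cost of conditioning away depth
differences.

# Synthetic data: what it does and does not emulate

`make_genome()` builds ATG-initiated, stop-terminated genes (uniform
300–1500 nt, rounded to codons, ~45% GC, alternating strands) separated by
fixed-length intergenic spacers, and plants one core PAM plus a clean
20-nt protospacer at the center of each gene third on the coding strand.
Planted coordinates are recorded in a truth table in exactly the
`scan_pams()` coordinate convention. `make_screen_reads()` draws baseline
and selected pools by seeded multinomial sampling (selected probabilities
proportional to per-guide fold changes) and writes FASTQs whose read ids
carry guide provenance; the error model is substitution-only, matching the
matching model used everywhere else.

These generators deliberately do **not** emulate: codon usage or realistic
ORF content, operon structure, coverage or amplification biases, indel
sequencing errors, replicate structure, or plasmid copy-number dynamics. A
green test on synthetic data therefore establishes that the *computational
contracts* hold (coordinates, counting conservation, rank recovery,
determinism) — not that biological effect sizes are realistic.

Scaling note: the null-FDR and power invariants (20 seeds at depth 10⁶)
are run at the *count* level (seeded multinomials feeding `enrich()`
directly) to stay inside the test-time budget; the FASTQ layer is
exercised end-to-end at full depth once, which is sufficient because
counting at `error_rate = 0` is exact by construction and is asserted as
such.

# Numerical and degenerate-input choices

- PFM consensus ties break alphabetically (A < C < G < T), documented and
  stable.
- `enumerate_pam_variants()` returns lexicographic order; duplicates are
  impossible by construction but asserted in tests.
- Array parsing tolerates ≤ 2 substitutions per repeat copy by default
  (terminal repeats of natural arrays are variable); occurrences are
  chained greedily left-to-right without overlaps, and fewer than two
  located repeats is an error ("not an array"), not an empty result.
- Type IIS digestion reports duplex fragments with their staggered
  overhangs attached to the side *away* from the recognition site, so the
  released insert is exactly `overhang5 + spacer + overhang3` and fragment
  extents still partition the molecule.
- Deletion designs re-scan the simulated post-deletion locus and refuse any
  spacer leaving a ≤ 1-mismatch match next to a permissive PAM, so the
  edited locus is immune to re-cutting; candidates are tried center-outward
  and the error lists the nearest PAM positions when the interval has none.
- A gene shorter than spacer + PAM yields a warning and a gap record, not
  an error; a gene with no candidate in some bin yields a logged gap so
  library statistics distinguish "no PAM" from "filtered".
- All generators and the CLI thread a single seed; `with_seed()` gives each
  simulation a private RNG stream and restores the caller's state, so
  library calls never perturb user RNG.

# Known limitations

- No promoter/intergenic targeting mode: guides land inside CDS bodies
  only.
- No efficacy prediction (thermodynamics, secondary structure, machine
  learning): mode and PAM identity are the only activity model, because
  categorical activity is all that is established for this system.
- The off-target scanner is a naive exhaustive Hamming scan (fast enough at
  megabase × 10⁴-guide scale on one CPU); an indexed scanner is out of
  scope.
- Quantitative repression strength as a function of spacer length is
  deliberately not modelled; only the repression/cleavage partition is.
- GenBank writing covers the subset of the format the package itself emits
  (single-interval and origin-wrapping CDS features); compound `join()`
  locations read back as their envelope.
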