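---
title: "Methods: from raw small-RNA reads to miRNA tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw small-RNA reads to miRNA tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamir)
```

This vignette walks through the methods implemented by **clamir**, stage by
stage, with the small formulas and thresholds stated explicitly. The running
example uses the seeded synthetic generator so every chunk is reproducible
offline.

## 1. Cleaning and collapsing reads

`clean_reads()` removes the 3' adapter by locating the **leftmost exact
match of the adapter's first 7 nt** and truncating the read there; reads
without a seed match are kept whole. After trimming, a read is retained only
if every base in the *retained* region has Phred quality ≥ 20, contains no
`N`, and is 14–30 nt long. `U` is normalized to `T` and case is folded.

`collapse_tags()` merges identical retained sequences into *tags* with one
count column per library, ordered by pooled count (descending) then
sequence. `length_distribution()` summarizes raw counts, unique tags and
their ratio (redundancy) per length.

```{r}
reads <- tibble::tibble(
  id = c("r1", "r2"),
  sequence = c(paste0("ACGTACGTACGTACGTACGT", "TGGAATTCTCGGGTGCCAAGG"),
               "ACGTACGTACGTACGTACGT"),
  qualities = strrep("I", c(41, 20)))
clean_reads(reads, adapter3 = "TGGAATTCTCGGGTGCCAAGG")
```

## 2. RNA-class annotation and known miRNAs

`classify_tags()` assigns each tag the first class in the precedence
`rRNA > tRNA > snRNA > snoRNA > repeat > mRNA` whose reference contains the
tag as an exact substring on either strand; everything else is
`"unannotated"` and forms the mappable pool carried forward.

`match_known_mirnas()` identifies tags of 15–26 nt that match a mature
miRNA with **at most one substitution after at most 2 nt of total terminal
trimming or extension**. Each tag maps to at most one miRNA (fewest
substitutions, ties to the lexicographically smallest id), and the family
is derived by stripping the trailing variant letter (with a configurable
exception list, e.g. `miR166l` where the `l` is part of the name).

```{r}
tags <- collapse_tags(list(a = c("ACGTACGTACGTACGTACGT")))
classify_tags(tags, list(rRNA = c(r1 = "TTTACGTACGTACGTACGTACGTTT")))$class
```

## 3. Secondary structure and folding metrics

`fold_rna()` computes a minimum-free-energy secondary structure with a
compact nearest-neighbour model: stacking energies over the six canonical
pair steps, logarithmic hairpin/bulge/internal-loop penalties, and an
affine multibranch term, solved by a Zuker-style dynamic program (no
pseudoknots, minimum loop of 3). `structure_energy()` independently
re-scores any dot-bracket structure, which the test suite exploits as an
enumeration oracle on short sequences.

```{r}
f <- fold_rna("GGGGAAAACCCC")
f
glance(f)
```

From a fold the precursor metrics follow as closed forms:

* **AMFE** = |MFE| × 100 / length,
* **MFEI** = AMFE / (GC% ), i.e. AMFE divided by 100 × GC fraction.

```{r}
compute_metrics(mfe = -60, length = 100, gc = 0.5)
```

## 4. Novel miRNA calling

For each unannotated tag that maps to **exactly one genomic locus**,
`extract_precursor_candidates()` excises windows with 5'/3' flanks from
{20, 50, 100, 150} nt (all pairs with total window ≤ 300 nt). Each window
is folded and `evaluate_criteria()` applies six criteria:

1. the structure is a single stem-loop (one terminal loop);
2. the mature sequence sits entirely within one arm;
3. \> 18 stem pairs and no stem bulge ≥ 12 nt;
4. within the mature span: ≤ 8 nt of one-sided (biased) bulge, ≤ 4 biased
   errors in ≤ 2 biased bulges, ≤ 6 total errors;
5. \> 15 mature base pairs and ≥ 80% of the mature inside the stem;
6. MFE < 0 and MFEI strictly > 0.9.

`call_novel_mirnas()` additionally requires a pooled tag count strictly
greater than 50 across libraries, reports the best-scoring window per tag,
and numbers the calls by pooled abundance. A dinucleotide-preserving
shuffle (`dinucleotide_shuffle()`) is available for empirical folding
controls.

```{r}
st <- paste0(strrep("(", 25), strrep(".", 6), strrep(")", 25))
seqs <- substr(strrep("AG", 28), 1, 56)
evaluate_criteria(seqs, st, 1, 21, mfe = -50)[, c("overall", "mfei")]
```

## 5. Differential expression

Counts are normalized to **RPM** (count / library total × 10⁶; the total is
the library's identified miRNA reads). Three tests are computed per miRNA
on the 2×2 table of counts vs totals:

* `audic_claverie_p()` — the exact conditional test; `p(y | x)` is negative
  binomial with size `x + 1` and probability `N1 / (N1 + N2)`, evaluated in
  log space. The two-sided value is `min(1, 2·min(P(K ≤ y), P(K > y)))`,
  the convention under which `p(x, y, N1, N2) = p(y, x, N2, N1)` exactly.
* `fisher_exact_2x2()` — two-sided by the point-probability rule.
* `chi2_2x2()` — Pearson without continuity correction, 1 df.

`call_differential()` flags a miRNA when the gated p-value (default: the
minimum of the three) is below 0.001 **and** |log2(treatment RPM / control
RPM)| exceeds 1.0; zero RPM is replaced by a 0.01 floor inside the ratio
only. qPCR-style validation is supported with
`ddct_relative_expression()` (2^−ΔΔCt).

```{r}
audic_claverie_p(5, 0, 1e6, 1e6)
ddct_relative_expression(20, 15, 23, 15)
```

## 6. Target prediction

`score_duplex()` aligns a miRNA antiparallel to a candidate site (site
length within ±1 nt, at most one gap) and scores mismatches 1.0, G:U
wobbles 0.5 and gaps 1.0, **doubling penalties at miRNA positions 2–13**.
`predict_targets()` scans every transcript window, keeps sites scoring
≤ 4.0, and deduplicates overlapping windows to the best site.

```{r}
mi <- "TGGAGCTCCCTTCATTCCAAT"
rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(mi, "")[[1]]), collapse = ""))
score_duplex(mi, rc)[, 1:5]
```

## 7. Synthetic truth and recovery

`generate_reference()` builds a seeded genome with criteria-passing
hairpins constructed *arm-first* (sampled 20–24 nt mature, a
near-complementary star arm with two symmetric mismatches so the mature
maps uniquely, loop 4–8 nt) and verified **with the package's own
criteria checker** before planting; decoys are built to violate exactly
one named criterion and verified to pass no window.
`simulate_libraries()` draws three libraries from a miRNA / contaminant
(rRNA-dominated) / background mixture with planted 8-fold changes,
1-mismatch variants, sparse low-quality and `N` bases, appends the
adapter, and records exact expected tag counts. `evaluate_recovery()`
scores calls and DE results against that truth.

```{r, eval = FALSE}
truth <- generate_reference(synthetic_config(), seed = 7)
truth <- simulate_libraries(truth, depth = 1e5, seed = 7, dir = "sim")
run <- run_pipeline(pipeline_config(...))  # see README for the full config
evaluate_recovery(run$novel, truth, de = run$de[[2]], seed = 7)
```

## 8. Orchestration

`run_pipeline()` chains clean → collapse → classify → known → novel → DE →
targets, writes TSV/GFF3 outputs plus a `manifest.yaml` (version, config
hash, per-stage counts, per-library accounting `raw = clean + discarded`),
supports `resume = TRUE`, and is byte-deterministic for a fixed config. A
CLI with subcommands (`run`, `simulate`, `clean`, `collapse`, `classify`,
`known`, `novel`, `de`, `targets`, `report`) ships in `inst/cli/clamir.R`.
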