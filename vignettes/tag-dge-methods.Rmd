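---
title: "Tag-based digital gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based digital gene expression (DGE, the sequencing-era descendant of
SAGE) quantifies a transcriptome by counting short 3' tags rather than by
shotgun sequencing of whole transcripts. In the NlaIII/MmeI protocol,
cDNA bound to oligo(dT) beads is digested with NlaIII, which cuts at every
`CATG`; the retained 3'-most fragment is ligated to an adapter whose MmeI
site directs a second cut 17 bp downstream of the `CATG`. Each transcript
molecule therefore yields (at most) one 21 nt tag — `CATG` plus 17 bases —
taken from the 3'-most usable `CATG` site, and the number of times a tag is
sequenced is a direct count of transcript molecules. Sequencers deliver
these tags embedded in longer raw reads (49 nt here) that carry the 3'
adapter after the insert.

`tagdge` implements the complete computational side of such an experiment:

1. **Virtual tag library** (`build_tag_library`) — every possible
   `CATG`+17 nt tag on both strands of every reference transcript, the
   complete search space for mapping. Tags whose occurrences all fall in one
   gene are *unambiguous*; tags in two or more genes are *ambiguous*.
2. **QC filtering** (`filter_raw_tags`) — five ordered steps: adapter
   trimming; removal of empty (adapter-only) reads; removal of tags
   containing `N`; removal of tags seen exactly once; removal of tags of the
   wrong length or without the `CATG` anchor. Every discard is ledgered so
   that `raw = clean + discards` holds exactly.
3. **Mapping** (`map_tags`) — exact lookup first, then one substitution in
   the 17 nt variable region; per-gene counts accumulate the copy numbers of
   unambiguous tags and are scaled to tags per million clean tags (TPM).
4. **Differential expression** (`call_degs`) — the Audic–Claverie exact
   count test between two libraries, Benjamini–Hochberg FDR, and the
   conventional call thresholds (FDR < 0.001, |log2 ratio| ≥ 1).
5. **Enrichment** (`enrich_terms`) — upper-tail hypergeometric tests of a
   DE gene set against a term annotation.
6. **Reporting** (`build_library_report`) — the standard per-library
   summary table, with every percentage recomputed from integers by
   half-up rounding at the second decimal.

## The count statistic

For a gene with `x` tags in a library of `N1` clean tags and `y` tags in a
library of `N2`, the Audic–Claverie model gives the conditional law of `y`
given `x` under the null hypothesis of equal relative expression:

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}$$

This is a negative binomial with size `x + 1` and success probability
`N1/(N1+N2)` — the identity the test suite exploits for independent
verification. `ac_pmf` evaluates it in log space through `lgamma`, so
counts in the hundreds of thousands cannot overflow.

`ac_test` returns the doubled-tail two-sided p-value,
`min(1, 2 * min(P(K <= obs), P(K >= obs)))`. Two numerical points deserve
record:

* **Canonical orientation.** For a discrete law the doubled-tail recipe is
  not invariant under swapping the two libraries: the observed point's mass
  changes tails, and deep in the tail the difference is large relative to
  the p-value itself. The test therefore always conditions on the library
  with the higher observed rate and takes tails over the other count (ties
  broken by the larger count). This preserves the closed-form small-count
  values (e.g. `x = 3, y = 3, N1 = N2` gives `C(6,3)/2^7 = 0.15625` for the
  pmf, and `x = 100, y = 0` gives `2^-100` doubled) and makes the swap
  invariance exact rather than approximate.
* **Smallest-first summation.** In the canonical orientation the observed
  count sits at or below the conditional mean, so the smaller tail is a
  finite sum over `0:obs`. It is accumulated after sorting terms in
  increasing order, which keeps full relative precision for p-values far
  below machine epsilon; the larger tail is obtained by complementation,
  where absolute error is harmless. The same treatment is applied to the
  hypergeometric upper tail in `hypergeom_enrichment_p` (summed directly
  over `i = m .. min(n, M)` rather than via `1 - P(X < m)`).

The enrichment statistic is the classical over-representation test: with
`N` annotated background genes of which `n` are differentially expressed,
and a term carried by `M` background genes of which `m` are DE, the
p-value is `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`. GO-style results
are flagged on the raw p-value, pathway-style on the BH q-value —
both conventions appear in practice, so both thresholds are exposed.

## Mapping conventions

* Mismatches are allowed only in the 17 nt variable region. The `CATG`
  anchor is an enzymatic recognition site present by construction in both
  the tag and the reference site, so it is held fixed; this also keeps the
  1-mismatch neighbourhood at 51 variants per tag.
* Exact matches take absolute priority: a tag with any perfect-match hit
  never receives 1-mismatch hits. A tag with a unique perfect match plus
  mismatch neighbours in other genes is therefore unambiguous.
* Ambiguity is a gene-level notion: a tag hitting one gene at several
  positions, or on both strands of the same gene, is still "one tag, one
  gene". Hits to different genes on opposite strands do make a tag
  ambiguous (the conservative reading).
* Antisense unambiguous hits count toward a gene's expression — mapped-tag
  accounting in this protocol aggregates both strands, and roughly half of
  unambiguous distinct tags map antisense — but a per-strand breakdown
  (`count_sense`, `count_antisense`) is always reported so a sense-only
  analysis can be rerun from the same objects.
* The TPM denominator is the library's **total clean tags**, not its mapped
  tags: "tags per million clean tags" is a sequencing-depth normalisation,
  not a mapped-fraction one.

## DE calling thresholds

Genes with at least one unambiguous tag in either library form the tested
family; genes absent from both are untestable and are excluded before the
BH adjustment. For the log2 ratio only, zero TPM values are replaced by
0.01 so silent genes give a finite, large fold change (a gene with
TPM 10.24 against a silent partner reports log2 ratio 10). The default
call requires FDR < 0.001 and |log2 ratio| ≥ 1; the boundary convention
(`>=` on the ratio, strict `<` on the FDR) follows the commoner published
usage, and both cutoffs are arguments of `call_degs`.

## What the simulator emulates — and what it does not

`sim_config` fixes the study conditions for every synthetic experiment:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 1000 | desk-scale stand-in for a ~47k-unigene reference |
| `mean_length` / `length_sdlog` | 676 bp / 0.7 | log-normal lengths matching a typical short-read assembly (mean ≈ 676 bp, long right tail) |
| `gc_mean` / `gc_sd` | 0.42 / 0.05 | insect transcriptome GC (~42%) |
| `catg_fraction` | 0.95 | fraction of transcripts with a usable sense `CATG`+17 site; tag profiling cannot see the remainder |
| `depth` | 2e5 | raw reads per library (study-scale libraries are ~6e6; 2e5 keeps a full run in seconds while preserving per-gene counts in the tens-to-thousands) |
| `base_error_rate` | 0.005 | per-base substitution rate in the tag, a realistic short-read error rate |
| `adapter_only_rate`, `n_read_rate`, `singleton_rate` | 0.005 each | contaminant classes observed in real runs at the ~0.5% level each, giving a ≈98.5% clean fraction before error-induced singleton loss |
| `read_length` / adapter | 49 nt / fixed 28 nt | raw read layout: 21 nt tag + 3' adapter |

Truth tables (`simulate_truth`) draw baseline relative abundances from a
log-normal (sdlog 1.2, a realistically skewed expression distribution),
plant `n_de` genes at |log2 fold change| = 3 with randomised sign, and
floor planted genes' baseline abundance at 2e-4 (mean TPM well above 100)
so the recovery studies measure the caller, not the detection limit. The
recorded `log2fc` is the realised post-normalisation value, and `is_de`
is defined from it, so the truth labels are exact by construction.

Reads are generated from the truth: each biological read is the 3'-most
sense tag of a multinomially drawn gene — the molecular protocol captures
the 3' fragment, even though the reference library deliberately enumerates
*all* sites, so multi-site genes exercise the mapper. Contaminants are
injected at the configured rates with exact per-read truth labels, which
is what lets the QC tests assert discard accounting exactly.

Features of real data the simulator does **not** model: an incomplete or
mis-assembled reference (simulated reads always come from the reference,
so the large "unknown tag" fractions of real experiments — where a third
of clean tags match nothing — appear here only via double sequencing
errors); quality-score structure (qualities are written as constant
`I`, and the tag filters are sequence-based); PCR duplication bias;
indels; strand-specific artefacts. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to assembly artefacts.

## Numerical and degenerate-input choices

* Adapter trimming cuts at the leftmost full adapter occurrence, else at
  the longest read suffix equal to an adapter prefix of ≥ 5 bases (exact
  matching, no tolerance — errors are simulated in the tag, not the
  adapter). A biological tag whose own suffix happens to match ≥ 5 adapter
  bases can in principle be over-trimmed; at 4^-5 per gene this is rare
  and surfaces as a `bad_length` discard, never as silent corruption.
* The singleton filter runs on the post-trim, post-N multiset, before the
  length/anchor filter — the listed step order — so a wrong-length tag
  seen once is ledgered as a singleton, not as bad length.
* Copy-number histogram bins default to
  `[2,5], [6,10], [11,20], [21,50], [51,100], >100` and are configurable.
* The saturation grid is 20 evenly spaced depths by default; subsampling
  is without replacement from a single seeded permutation, so the curve is
  monotone by construction and reproducible.
* `percentage()` rounds half-up at the second decimal (with a 1e-9 guard
  against representation error); this convention reproduces every published
  summary-table percentage from its printed integers, which is asserted in
  the acceptance suite.
* Candidate tag sites containing non-ACGT letters are skipped and counted;
  empty references and duplicate gene ids are errors.
* All generators are pure functions of their configuration and seed;
  determinism (bit-identical FASTA/FASTQ/TSV on re-run) is tested.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence suites run on 200-gene synthetic transcriptomes
(~1,000 tag sites) against exhaustive brute-force scanners. Statistic
correctness covers the full `x, y ≤ 200` grid at library-size ratios
{0.5, 1, 2} and a structured hypergeometric grid up to `N = 500`, at
10 significant digits. Parameter recovery and null calibration use
1000-gene truths at 5e5 tags per library over 20 seeds — planted DE genes
(50 at |log2FC| = 3) must be recovered with sensitivity ≥ 0.9 and
empirical FDR ≤ 0.05, and the null type-I rate at 0.05 must sit within
±0.02. These study sizes were chosen so each suite completes in seconds
to a few minutes on one CPU while the binomial/multinomial noise floors
stay far below the asserted margins.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 500, depth = 1e5, seed = 7)
res <- run_dge_pipeline(cfg, n_de = 30)

res$reports$A          # per-library accounting table
summary(res$degs)      # tested / up / down under the default thresholds
head(res$enrichment)   # planted term should lead the ranking
plot(res$degs)         # MA-style view of the comparison
```

## Known limitations

* One library per condition: the AC test compares two libraries without
  biological replication, so its p-values reflect counting noise only.
  Replicate-aware models (negative binomial with dispersion estimation)
  are out of scope by design — with replicates, use an
  overdispersion-aware package instead.
* No multi-mapper rescue: ambiguous tags are counted as mapped but never
  redistributed to genes.
* Annotation is taken as given: term hierarchies are not propagated before
  enrichment testing.
* Only 3' adapter trimming is performed; a 5' adapter search is not
  implemented (empty inserts are still caught, since they begin with the
  3' adapter).
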