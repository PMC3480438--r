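# tagdge

Tag-based digital gene expression (DGE) analysis in R: an end-to-end,
ground-truth-tested implementation of the classic NlaIII/MmeI 21 bp tag
profiling pipeline against an assembled transcript reference.

## Who this is for

DGE/SAGE-style experiments quantify a transcriptome by sequencing one
short 3' tag per transcript molecule — `CATG` (the NlaIII site) plus the
17 downstream bases released by MmeI — and counting tags. `tagdge` is for
anyone who needs that computational pipeline as transparent, testable R
code: building the virtual library of all possible reference tags,
filtering raw 49 nt reads into clean tags, mapping with at most one
mismatch, quantifying genes in tags per million (TPM), calling
differential expression between two libraries, and testing term
enrichment of the called genes. A bundled simulator generates reference
transcriptomes, truth tables and raw tag libraries with known fold
changes, sequencing errors and contaminant reads, so every stage can be
validated against ground truth without any external data.

## The statistics at the core

**Audic–Claverie exact count test.** For a gene with counts *x*, *y* in
libraries of *N₁*, *N₂* clean tags, the null conditional law is

&nbsp;&nbsp;&nbsp;&nbsp;p(y | x) = (N₂/N₁)ʸ · (x+y)! / ( x! y! (1+N₂/N₁)^(x+y+1) )

(a negative binomial with size x+1 and prob N₁/(N₁+N₂)). The two-sided
p-value doubles the smaller conditional tail, evaluated in log space with
smallest-first summation so deep tails keep full relative precision.
Multiple testing is controlled by Benjamini–Hochberg FDR; the default call
is FDR < 0.001 and |log₂ ratio of TPM| ≥ 1, with zero TPM replaced by
0.01 in the ratio.

**Hypergeometric enrichment.** With *N* annotated background genes, *n*
of them differentially expressed, and a term carried by *M* genes of
which *m* are DE, the enrichment p-value is P(X ≥ m) for
X ~ Hypergeometric(N, M, n), BH-adjusted across terms.

## Worked example

```r
library(tagdge)

cfg <- sim_config(n_genes = 500, depth = 1e5, seed = 7)
res <- run_dge_pipeline(cfg, n_de = 30)

res$library
#> Reference tag library
#>   genes: 500 (474 tag-bearing)
#>   occurrences: 2493 sites, 2493 distinct tags (2493 unambiguous, 0 ambiguous)

res$reports$A
#> Library report 'A' (500 reference genes)
#>                                     total        %  distinct        %
#>   raw tags                        100,000              8,409
#>   clean tags                       92,427   92.43%     1,948
#>   all mapped                       92,427  100.00%     1,948  100.00%
#>   unambiguous mapped               92,427  100.00%     1,948  100.00%
#>   unknown                               0    0.00%         0    0.00%
#>   genes, all tags                     474   94.80%
#>   genes, unambiguous tags             474   94.80%

summary(res$degs)
#> Tested genes:   474
#> Up-regulated:   15
#> Down-regulated: 13
#> Library sizes:  92427 / 92634 clean tags
#> Thresholds:     FDR < 0.001, |log2 ratio| >= 1 (BH)

head(res$enrichment, 1)
#>   term_id  term_name   N  n  M  m      p_value      q_value significant
#> 1   T0001 term T0001 477 28  25 19 2.449810e-22 1.224905e-20        TRUE
```

Reading the output: 474 of the 500 simulated transcripts carry a usable
`CATG`+17 site, so only they can ever be seen by tag profiling. Of
100,000 raw reads, 92.43% survive the five QC filters (the losses are the
injected adapter-only/N/singleton contaminants plus error-generated
singleton tags); every clean tag maps because simulated reads always come
from the reference — real libraries show a large "unknown" fraction from
incomplete references. The caller flags 28 of the 30 planted fold
changes (15 up + 13 down in condition B), and the planted annotation term
`T0001` leads the enrichment ranking at p ≈ 2.4e-22.

Individual stages are available directly, e.g.:

```r
ac_pmf(3, 3, 1e6, 1e6)              # 0.15625  = C(6,3) / 2^7
ac_test(10, 40, 5e5, 5e5)           # 1.473772e-05
hypergeom_enrichment_p(10, 4, 5, 3) # 0.2619048 = 66/252
percentage(3770323, 5962735)        # 63.23 (half-up at 2 decimals)
```

## Documentation

The methods vignette (`vignettes/tag-dge-methods.Rmd`) documents the
generative model behind the simulator, the mapping and thresholding
conventions, the numerical choices in the tail computations, and known
limitations (single library per condition, no multi-mapper rescue, no GO
hierarchy propagation).
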