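# circensus

Consensus back-splice junction calling and circRNA characterisation for
paired tumour/normal RNA-seq cohorts.

## What problem this solves

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing: a downstream splice donor joins an upstream acceptor, and the
only direct sequencing evidence is reads spanning the non-colinear
back-splice junction (BSJ). Individual BSJ callers (find_circ,
circRNA_finder, CIRI2, CIRCexplorer2) disagree substantially — they use
different alignment heuristics, emit different file formats, and even
different coordinate conventions. Studies that profile the circRNA
repertoire of a tumour cohort therefore run several callers and keep only
junctions with multi-caller support.

`circensus` packages that workflow as tested, reusable R code for anyone
analysing multi-caller circRNA calls in a paired tumour / normal-adjacent
tissue (NAT) design:

* **Harmonisation** — parsers for the four callers' output dialects into a
  single 0-based half-open coordinate frame, with canonical display keys
  (`chrom:start|end:strand`, 1-based inclusive).
* **Consensus filtering** — a junction is kept in a sample when detected by
  ≥ 2 callers with a cross-caller mean of ≥ 2 BSJ reads, and enters the
  high-confidence catalogue when it survives in ≥ 5 samples within the
  tumour group or within the NAT group. All thresholds are parameters.
* **Quantification** — raw expression is the cross-caller mean read count;
  normalised expression is counts-per-million of total mapped reads.
* **Annotation** — host (parental) genes by coordinate intersection
  (GenomicRanges), with deterministic tie-breaking: same strand, then
  largest overlap, then smallest gene id; gene-level BSJ aggregation;
  1-Mb window density tracks; host biotype summaries.
* **Differential expression** — a transparent DESeq2-style core:
  median-of-ratios size factors, moderated method-of-moments NB dispersion,
  Wald statistic log2FC/SE against a t reference, Benjamini–Hochberg FDR,
  calls at fold change ≥ 1.5 and q < .05.
* **Hallmark activity** — a deterministic rank/ECDF re-implementation of the
  GSVA single-sample enrichment walk on gene-level back-splicing, plus
  hypergeometric over-representation tests.
* **Associations** — Spearman circRNA/host and circRNA/immune-abundance
  correlations with BH FDR over the requested family, the eight-region
  circRNA-vs-host change classification, median-split contingency tables
  with Pearson χ² (no continuity correction), two-group log-rank survival
  tests, and Wilcoxon rank-sum with median fold change.
* **Pan-cancer profiling** — exact-key overlap against a MiOncoCirc-style
  reference catalogue, per-type detection fractions and study-specific
  circRNA calls.
* **Synthetic data** — a fully seeded generator with planted truth
  (NB counts, spiked fold changes, per-caller sensitivities and
  caller-unique false positives, reference catalogue with known overlap,
  copula-linked immune/clinical tables) so the whole pipeline is testable
  without sequencing data.

## Worked example

```r
library(circensus)

bundle <- simulate_bundle(sim_config("reduced"), seed = 1, dir = "bundle")
cfg <- pipeline_config(outdir = "out",
                       caller_manifest = bundle$paths$caller_manifest,
                       sample_sheet = bundle$paths$sample_sheet,
                       gtf = bundle$paths$gtf, gmt = bundle$paths$gmt,
                       categories = bundle$paths$categories,
                       reference = bundle$paths$reference,
                       expression = bundle$paths$expression,
                       immune = bundle$paths$immune,
                       clinical = bundle$paths$clinical)
report <- run_pipeline(cfg)
```

On this 6-pair bundle (300 planted circRNAs) the run report counts are:

```
parse      n_calls = 12143     # harmonised junction calls, 4 callers x 12 samples
consensus  n_circ  = 205       # high-confidence catalogue entries
de         n_up = 10, n_down = 9
pancancer  n_overlap = 186, n_specific = 19
```

205 of the 300 planted junctions pass the consensus filters (the rest are
too weakly expressed to reach 2 mean reads in 5 samples — by design); none
of the 243 planted caller-unique false positives survive. The pan-cancer
report prints `percent_overlap = 90.7` against the planted 91.2% reference
overlap, and `percent_specific = 9.27`. The concordance summary shows the
eight-region classification of circRNA vs host-gene changes
(`direction  n  k_consistent  percent`), and `circ_immune_correlation.tsv`
recovers the planted positive correlation between the designated circRNA
and the "T cells CD4 memory activated" column (rho = 0.94 at 6 tumour
samples).

Single statistics work standalone, e.g. a clinicopathological 2×2 table
(low/high median-split expression vs lymph-node metastasis):

```r
pearson_chisq(rbind(c(10, 2), c(13, 25)))
#> $chi2   8.8596
#> $pvalue 0.0029
```

A command-line wrapper is included:

```sh
Rscript inst/cli/circensus.R simulate --out bundle --seed 1
Rscript inst/cli/circensus.R run-all --bundle bundle --out out
```

## Documentation

The methods vignette (`vignettes/circrnome-methods.Rmd`) describes the
statistical model, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and known
limitations.
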