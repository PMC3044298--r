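# funcoreg

Transcription factors (TFs) act on transcription; microRNAs act after it.
When a TF and a miRNA family (or two TFs, or two families) share an
unusually function-coherent set of target genes, the two regulators are
plausibly *coregulating* a biological process rather than overlapping by
chance. `funcoreg` finds such **function-enriched coregulation pairs** from
regulator→target edge lists, links them by the biological processes they
share, screens their upstream wiring for network motifs, and asks whether
their expression correlation differs between normal and tumour tissue.

## The statistic at the core

For a pair of regulators with shared target set *S* (|S| = n), count the
annotation instances of *S* over the GO level-2 biological-process terms
(the direct `is_a` children of `GO:0008150`), giving c₁…c_K plus an
*unannotated* pseudo-category; the genome-wide totals are M₁…M_K. The
profile surprise is the multivariate hypergeometric log-likelihood

L(S) = Σₖ ln C(Mₖ, cₖ) − ln C(Σₖ Mₖ, Σₖ cₖ),   L ≤ 0,

lower L = a more function-concentrated fingerprint. Because genes carry
multiple level-2 terms, L is used as a score, not an exact sampling
distribution: significance comes from an empirical null that redraws
N_perm = 10,000 same-size gene sets from the whole gene universe,
p = (1 + #{L_null ≤ L_obs}) / (1 + N_perm), followed by FDR control at
0.05 (Benjamini–Hochberg; Benjamini–Liu step-down available). Enriched
pairs are then expanded into per-term **functional linkages** (one-sided
Fisher's exact test, FDR-BL), assembled into coregulation multigraphs
(edges = GO terms), tested for upstream motifs (feed-forward loops, common
upstream regulators, upstream crosstalk) against 10,000 resampled
background pair sets at p < 0.001, and contrasted by Pearson expression
correlation (foreground vs background, per condition, two-sample KS).

## Worked example

The bundled synthetic generator states a small world — 2,000 genes, 20 TFs,
20 miRNA families, 12 level-2 terms, and 10 planted pairs that share 8
targets drawn from a single term's gene pool — and the pipeline recovers it:

```r
library(funcoreg)
out <- run_pipeline(list(out_dir = "demo", seed = 1,
                         permutations = 1000, resamples = 1000))
head(read.delim(file.path(out, "pairs.tsv")), 5)
```

```
 reg_a reg_b pair_kind n_shared    loglik      p_perm           q enriched
 FAM01  TF01    TF_MIR        8 -22.16107 0.000999001 0.005744256     TRUE
 FAM02  TF02    TF_MIR        8 -22.40633 0.000999001 0.005744256     TRUE
 FAM03  TF03    TF_MIR       11 -24.81389 0.000999001 0.005744256     TRUE
 FAM04  TF04    TF_MIR       11 -24.30326 0.000999001 0.005744256     TRUE
 FAM05  TF05    TF_MIR        9 -21.47460 0.000999001 0.005744256     TRUE
```

All 10 planted pairs hit the permutation floor p = 1/1001 and are flagged
enriched at FDR 0.05. Their top functional linkage is the planted term:

```
 reg_a reg_b       term           term_name     p_fisher            q
 FAM01  TF01 GO:1000001 synthetic process 1 3.276794e-08 3.571699e-06
 FAM02  TF02 GO:1000002 synthetic process 2 7.709576e-08 8.249919e-06
 FAM03  TF03 GO:1000003 synthetic process 3 3.053271e-07 2.914288e-05
```

and the expression contrast shows the planted normal-only correlation
(`correlation_summary.tsv`): mean foreground r = 0.53 vs background 0.07 in
normal samples (KS p = 9.0e-05), collapsing to −0.02 vs 0.03 in tumour
samples (KS p = 0.49) — coregulation present in normal tissue, lost in
tumour.

Other outputs per run: `network.graphml` / `network.sif` (coregulation
multigraph, GO term on each edge), `network_stats.json` (links per pair,
edge types per regulator, largest component), `motifs.tsv` (per-kind motif
counts, resampling p), `manifest.json` (config, input digests, seeds,
record counts — byte-reproducible given the same config and seed).

Command line: `Rscript inst/cli/funcoreg.R run --seed 1 --out-dir demo`
(subcommands `simulate`, `pairs`, `enrich`, `linkages`, `network`,
`motifs`, `expression`, `run`; flags `--permutations`, `--resamples`,
`--fdr`, `--motif-alpha`, `--min-shared`, `--fdr-method`, `--skip`,
`--config`).

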