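---
title: "funcoreg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{funcoreg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, every parameter that matters, what the synthetic world
does and does not establish, and the numerical/design choices made where
the design was genuinely open. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. The model

Regulation is represented as two bipartite layers over one gene universe:
TF → target edges (transcriptional layer) and miRNA-family → target edges
(post-transcriptional layer; mature miRNAs sharing a seed are collapsed to
one family regulator whose target set is the union of member target sets,
because seed-sharing matures hit the same sites and would otherwise produce
trivial "coregulation" among themselves). A **coregulation pair** is any
unordered regulator pair — TF–TF, TF–miRNA, or miRNA–miRNA — whose target
sets intersect in at least `min_shared` genes.

The question asked of each pair is not "do they share many targets?" but
"is the *functional profile* of the shared targets atypical?". The profile
is the count vector of the shared set over the GO level-2
biological-process terms — the direct `is_a` children of the BP root —
plus an *unannotated* pseudo-category, and it is scored by

$$L = \sum_k \ln\binom{M_k}{c_k} \;-\; \ln\binom{\sum_k M_k}{\sum_k c_k},$$

the log-probability of the observed instance counts under multivariate
hypergeometric sampling from the genome-wide totals $M_k$. $L \le 0$;
low $L$ means a concentrated, surprising fingerprint.

**Assumption made explicit.** Genes carry several level-2 terms, so
annotation instances are dependent and the multivariate hypergeometric is
*not* the exact sampling law of the profile. $L$ is therefore treated as a
surprise score only; calibration comes entirely from the permutation null,
which redraws same-size **gene** sets (not instances) from the universe and
hence respects the dependence. The empirical p-value uses the
Phipson–Smyth pseudocount, $p = (1 + \#\{L_{null} \le L_{obs}\})/(1 +
N_{perm})$, so $p$ is never 0 and its attainable minimum is exactly
$1/(N_{perm}+1)$. The tail direction is fixed at *low* likelihood: a
high-likelihood (ultra-typical) profile is not function-enriched under any
reading.

Because the null depends only on the set size $n$, null samples are cached
per $n$ within a run (pairs with equal shared-target counts reuse one null
sample), cutting cost by roughly the number of pairs per distinct size.
The calibration test in the acceptance suite deliberately spreads set
sizes so this sharing cannot mask a calibration failure.

## 2. From pairs to linkages, networks, motifs, expression

**Linkages.** For every enriched pair, each level-2 term with a nonzero
count in the shared set is tested by a one-sided Fisher's exact test
(hypergeometric upper tail, computed by direct log-space summation).
Zero-count terms are skipped — they cannot be enriched, and skipping them
is rejection-equivalent while shrinking the correction burden. The default
correction is the Benjamini–Liu step-down procedure with critical
constants $c_i = 1 - \left(1 - \min(1, m\alpha/(m-i+1))\right)^{1/(m-i+1)}$
("FDR-BL"; chosen for the higher-specificity networks), with
Benjamini–Hochberg available; the choice is recorded in the manifest.

**Networks.** Passing linkages form an undirected multigraph: nodes are
regulators, one parallel edge per (pair, GO term). The reported statistics
are links per connected pair (density of coregulation), mean distinct edge
terms per regulator (functional diversity), and the largest connected
component.

**Motifs.** The upstream network unions four directed edge sources: TF→TF
(a TF's gene inside another TF's target set), predicted TF→family edges,
TF→family edges propagated through host genes (an embedded precursor
shares its host's transcription unit, so a TF targeting the host is taken
to regulate the family), and family→TF. Five catalog patterns are counted
per pair: bidirectional/unidirectional FFLs (any A→B edge completes a
feed-forward loop through every shared target, by construction of the
pair), common upstream TF, common upstream TF *and* miRNA family, and
upstream crosstalk. The catalog is a declarative predicate registry, so
alternative readings of the ambiguous patterns can be added without code
changes; the bundled `COMMON_UP_TF_AND_MIR` requires both single-kind
motifs to hold for the same pair, one documented reading. Significance is
by resampling same-size pair sets from the background pool (all pairs
above `min_shared`, not all regulator pairs — configurable), upper tail
only, pseudocounted, per pair kind, at `alpha_motif`.

**Expression.** A TF's profile is its mRNA row; a family's profile is the
per-sample mean over measured members (the mean is a package choice — the
original analysis worked on mature probes pre-collapse; `max` is a config
alternative). Samples are pooled across tissues within a condition, since
one distribution per condition is reported. Pearson r uses pairwise
deletion; pairs with fewer than 3 complete observations, or with constant
profiles, are skipped and counted rather than erroring. Foreground
(enriched) vs background (same-kind, non-enriched — the inclusive reading
of an ambiguous "and/or" in the source protocol; the exclusive variant is
a config option) distributions are summarised by a two-sample KS test,
which is labelled an *addition*: the original work only plotted the
distributions.

## 3. Parameters

| parameter | default | units / notes |
| --- | --- | --- |
| `permutations` | 10000 | null gene-set draws per set size (protocol value) |
| `fdr` | 0.05 | FDR level for pairs and linkages (protocol value) |
| `resamples` | 10000 | background pair sets for motifs (protocol value) |
| `motif_alpha` | 0.001 | motif significance threshold on p_emp (protocol value) |
| `min_shared` | 3 | genes; package choice — a 1–2 gene profile is uninformative; settable to 1 |
| `fdr_method` | BH | pair-level correction; pooled over all pairs (per-kind optional) |
| `linkage_fdr_method` | BL | per-term correction, pooled over (pair, term) tests |
| `use_part_of` | TRUE | propagate annotations across part_of edges (GO guidance) |
| `seed` | 1 | expanded into independent per-stage streams, so skipping a stage does not shift downstream randomness |

Null universe: all genes seen in the annotation input **plus** all network
targets, including genes with no level-2 term (kept as the unannotated
pseudo-category). Keeping unannotated genes matches a
"whole-genome background" reading; annotated-only is available but the
source's own choice is unknowable, so this is flagged as a package
decision, not an assertion about the original analysis.

## 4. The synthetic world

`synthetic_config()` states one world and the tests never tune it:
2,000 genes (the TF genes among them), 20 TFs, 20 families, 12 level-2
terms of ≈250 genes (each gene draws 0–3 terms), 10 planted TF–family
pairs sharing 8 targets drawn from a single term's pool, background edges
as independent coin flips at 0.02 (≈40 targets per regulator — the same
order as the curated TF-target sets the method was built for, at 1/10
scale), expression with correlation 0.7 planted in 16 normal samples and
0.0 in 16 tumour samples across 8 cycled tissue labels, family members =
latent family signal + N(0, 0.15²) noise. The generator checks
feasibility (term pool ≥ planted overlap) *before* writing any file, and
asserts the planted overlaps on the written files afterwards.

What a green suite establishes: the scoring, calibration, FDR, linkage,
motif and correlation machinery recovers exactly the signal class it
claims to detect — term-coherent shared-target profiles, upstream motif
excess, condition-specific correlation — at realistic-for-desk-scale sizes,
deterministically. What it does not establish: behaviour on real GO DAG
topology (the toy ontology is two levels deep plus one grandchild tier),
real target-prediction noise (TargetScan-style seed biology is explicitly
out of scope), probe-level artefacts, or the original study's printed
counts, which depend on unbundled database snapshots.

## 5. Numerical and degenerate-case choices

- All combinatorics in log space (`lchoose`); the score is exact to
  1e-12 against a rational oracle on small instances and safe to
  $\sum M_k \approx 10^7$.
- Fisher tails sum point masses from the observed count upward with a
  max-shift to avoid underflow; `x = 0` returns exactly 1.
- Empty gene set → valid all-zero profile; empty network → `NA` statistics
  (markers, not exceptions); constant expression vector → `NA` correlation.
- Ties in FDR input are broken by stable input order; pair tables are
  emitted in canonical `reg_a < reg_b` lexicographic order, making every
  result file byte-reproducible for a given config and seed (numeric
  columns are printed through a fixed `%.10g`).
- Wall-clock timings are written to `timings.json`, kept out of
  `manifest.json` so the manifest itself is part of the determinism
  contract.
- Unmapped mature miRNAs are retained as singleton families (dropping them
  would silently delete regulators); the count is logged.
- TF self-targets are retained in shared-target sets (the protocol is
  silent; removal would be an undocumented filter).

## 6. Known limitations

- "Level 2" is defined as direct `is_a` children of the BP root, not a
  minimum-depth computation; multi-parent terms deeper in the DAG may
  reach several level-2 ancestors, which is intended behaviour.
- The Benjamini–Liu variant is implemented from its published step-down
  constants; the source protocol cites the procedure only by name, so the
  method is pluggable and the run manifest records which was used.
- Motif fractions reported on real data depend strongly on the
  completeness of the upstream edge set; with sparse upstream knowledge
  the resampling test loses power long before it loses validity.
- The expression contrast is correlational; no claim about cancer
  mechanism follows from a significant KS difference.
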