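# File formats

All tabular files are tab-delimited UTF-8 with LF line endings, a header
row, and `#`-prefixed comment lines ignored. Identifiers are opaque,
case-sensitive strings.

## Inputs

### Regulator targets (`read_regulator_targets`)
| column | content |
| --- | --- |
| `regulator_id` | TF gene symbol or miRNA family id |
| `regulator_kind` | `TF` or `MIRNA_FAMILY` (case-insensitive) |
| `target_gene` | target gene id |

Duplicate rows collapse silently (count logged).

### Mature miRNA targets (`collapse_families` input)
Columns `mature`, `target`. Matures are grouped into families via the
family map; unmapped matures become singleton families.

### Family map
Columns `mature`, `family`. Precursor names may appear in the `mature`
column so host-gene propagation can resolve precursors to families.

### Host map (`propagate_host_regulation`)
Columns `precursor`, `host_gene`.

### Predicted TF→miRNA regulation (`build_upstream_network`)
Columns `source` (TF id), `dest` (family id).

### Ontology (`read_ontology`)
OBO 1.2; only `[Term]` stanzas with `namespace: biological_process` are
kept; `is_a` and `relationship: part_of` edges are retained separately;
`is_obsolete: true` terms are dropped with a warning count.

### Annotations
Either GAF 2.x (`!` comments; columns 3 = gene symbol, 4 = qualifier,
5 = GO id, 7 = evidence, 9 = aspect; rows with a `NOT` qualifier or
aspect ≠ `P` are excluded; evidence codes optionally filtered) or a
two-column TSV `gene<TAB>term`.

### Expression matrix (`read_expression`)
First column `entity_id`, optional `entity_kind` (`mRNA` /
`mature_miRNA`), then one numeric column per sample. Missing values use
the configurable NA token (default `NA`). Metadata TSV: `sample_id`,
`tissue`, `condition` (`normal` / `tumor`).

### Pipeline config (`read_pipeline_config`)
DCF (`key: value` lines); keys as in `default_pipeline_config()`.

## Outputs

- `pairs.tsv` — `reg_a, reg_b, pair_kind, n_shared, loglik, p_perm, q,
  enriched` (canonical pair order `reg_a < reg_b`).
- `linkages.tsv` — `reg_a, reg_b, pair_kind, term, p_fisher, q, passed,
  term_name`.
- `motifs.tsv` — `motif_id, pair_kind, observed, fraction, null_mean,
  null_sd, null_max, p_emp, significant`.
- `correlation_summary.tsv` / `correlation_values.tsv` — per-(kind,
  condition) KS summary and raw foreground/background r values.
- `network.graphml` — undirected multigraph; node attribute `kind`, edge
  attribute `go_term`; parallel edges preserved. `network.sif` — lines
  `reg_a<TAB>term<TAB>reg_b`.
- `manifest.json` — config snapshot, per-stage seeds, input MD5 digests,
  package version, record counts (deterministic). `timings.json` —
  wall-clock per stage (not covered by the determinism contract).
- Synthetic bundle — the input files above plus `truth.json`
  (planted pairs/motifs/correlations and the generating config).
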