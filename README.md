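# lspanel

Detection of lineage-specific paralog retention after the teleost
whole-genome duplication.

## The problem

Teleost fish genomes went through a whole-genome duplication (the
teleost-specific genome duplication, TSGD or "3R") at the base of their
radiation, followed by diploidization: most duplicated genes returned to
single copy, but a substantial minority survive today as **ohnologs**
(WGD-derived paralog pairs). When a duplicate pair is kept in *every*
sampled genome of one superorder (e.g. Ostariophysi: zebrafish, cavefish)
but collapsed to a single copy in every genome of a second superorder
(e.g. Acanthopterygii: stickleback, pufferfish, medaka, tilapia), that
systematic contrast — a **lineage-specific paralog (LSP)** — is a deep
signature of differential diploidization, and the functional classes of
genes involved hint at how the two lineages diverged.

`lspanel` is a self-contained R implementation of the whole detection
procedure for people studying post-WGD gene retention:

* **Similarity search**: Smith–Waterman local alignment (affine gaps,
  BLOSUM62, Rcpp) with Karlin–Altschul E-values
  `E = m n 2^(−bits)`, `bits = (λS − ln K)/ln 2`, so the classical
  `E ≤ 1e-80` cutoff applies to internal searches; external 12-column
  tabular hit files (BLAST `-outfmt 6`) can be imported instead.
* **The filtering cascade**: within-seed-genome duplicate pairs →
  chimera/splice-variant/isoform exclusion (mutual coverage ≥ 0.5,
  length ratio ≤ 2) → different-chromosome criterion → single-ortholog
  test in every pre-WGD outgroup → reciprocally supported copy number in
  every panel species → two-lineage LSP call (`A_LSP`, `B_LSP`,
  `shared_duplicate`, `unresolved`).
* **Verification**: neighbor-joining trees on Poisson-corrected protein
  distances `d = −ln(1 − p)` with a duplication-precedes-speciation
  topology test, and a neighborhood-overlap synteny score.
* **Statistics**: per-chromosome LSP/TSGD ratios treated as
  pseudoreplicates (mean ± SE), Spearman rank correlation with a
  permutation p-value, and hypergeometric GO-slim enrichment with
  Benjamini–Hochberg control.
* **A synthetic panel generator** that emulates descent of a genome
  panel from a common ancestor through one WGD with lineage-stem and
  per-species paralog loss, consistent chromosome placement and Poisson
  peptide divergence — with ground-truth labels, so every stage is
  testable offline.

## Worked example

```r
library(lspanel)

cfg    <- sim_config(n_families = 100, seed = 11)   # stated defaults
panel  <- simulate_panel(cfg)                       # proteomes + truth
bundle <- run_pipeline(cfg$species_panel, panel)    # full cascade

table(bundle$families$call[is.na(bundle$families$duplicate_of)])
#>            A_LSP            B_LSP shared_duplicate
#>                2                8                8

table(panel$truth$true_class)
#>            A_LSP            B_LSP            noisy shared_duplicate
#>                2                8                1                8
#> shared_singleton
#>               81
```

The pipeline recovered every simulated LSP and shared duplicate; the one
`noisy` family (an extra single-species loss) was correctly *not* called
an LSP — systematic retention requires the full copy-number pattern.

```r
s <- summarize_panel(bundle, bundle$totals)
s$a$pct_tsgd; s$a$pct_lsp
#> [1] 18.2      # % of analyzed lineage-A genes that are TSGD paralogs
#> [1] 3.6       # % that are lineage-A LSPs

bundle$chromosome_stats$rho            # LSPs track TSGD density per
#> [1] 0.4266983                        # chromosome (no positional bias)
bundle$chromosome_stats$p_perm
#> [1] 0.00189981                       # permutation p (never exactly 0)

v <- verify_families(bundle)
mean(v$topology_pass)
#> [1] 1         # all LSP trees show duplication before speciation
```

Percentage arithmetic is exposed directly: `summarize_panel(4122, 19600)`
gives 21.0 (round-half-up to one decimal on the percent scale).

## Command line

```sh
Rscript exec/lspanel simulate --config sim.yaml --out-dir panel/
Rscript exec/lspanel run-all  --config sim.yaml --panel-dir panel/ --out-dir results/
Rscript exec/lspanel verify   --config sim.yaml --panel-dir panel/ --out-dir results/
```

Outputs: `tsgd_pairs.tsv`, `lsp_calls.tsv`, `chromosome_stats.tsv`,
`verification.tsv`, `summary.json`.

## Documentation

The methods vignette (`vignettes/lsp-detection-methods.Rmd`) describes
the model, the simulator's stated world and its limits, numerical
choices, and known limitations.
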