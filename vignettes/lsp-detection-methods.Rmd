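---
title: "Detecting lineage-specific ohnolog retention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific ohnolog retention: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lspanel)
```

## The question and the procedure

After a whole-genome duplication, diploidization removes most duplicate
genes. A duplicate pair that survives in *every* sampled genome of one
superorder while the other superorder keeps a single copy — a
lineage-specific paralog (LSP) — is evidence that the two lineages
resolved the same duplication differently. `lspanel` detects such
families in a two-lineage genome panel with pre-WGD outgroups, and ships
a simulator of exactly that evolutionary history so the detector can be
validated against known truth.

The cascade, run once from each lineage's seed genome:

1. **Duplicate pairs in the seed genome.** All-vs-all Smith–Waterman
   self-search; mutual hits at `E ≤ evalue_cutoff` (default 1e-80) form a
   graph, and only connected components of exactly two genes become
   candidate pairs. Components of three or more mutually similar genes
   are ambiguous for pair calling and are flagged and excluded rather
   than resolved arbitrarily.
2. **Artifact exclusion.** Annotation artifacts (chimeras, splice
   variants, isoforms) masquerade as duplicates; a pair is kept only if
   both alignment coverages reach `coverage_min` (default 0.5) and the
   peptide length ratio is at most `length_ratio_max` (default 2).
3. **Different chromosomes.** WGD-derived pairs occupy different
   chromosomes; tandem duplicates do not. The criterion is applied in
   the seed genome here and propagated to every species scored `2+`
   later (co-orthologs on one chromosome count as a single copy).
4. **Outgroup singleton test.** In every pre-WGD outgroup, both pair
   members must share one unique best hit, and that outgroup gene must
   hit no seed gene outside the pair. All configured outgroups must
   pass; this anchors the pair to a single pre-duplication locus.
5. **Copy number per panel species.** A target gene supports the family
   only reciprocally (its own best hit lands inside the seed pair).
   Above-cutoff hits without reciprocal support mark the species
   *ambiguous*, which demotes the family to `unresolved` — ambiguity
   must never inflate an LSP count.
6. **Classification.** `A_LSP` iff every lineage-A species carries two
   copies and every lineage-B species exactly one; `B_LSP` symmetric;
   `shared_duplicate` iff all carry two; anything else (a zero, a mixed
   pattern, an ambiguity) is `unresolved`. Species listed in
   `allow_missing_species` may have copy number 0 without demoting the
   family, accommodating incomplete assemblies or transcriptome-only
   species.

Families can only be discovered from a seed genome in which they are
duplicated, so lineage-A LSPs come from the seed-A pass and lineage-B
LSPs from the seed-B pass; shared duplicates surface in both passes and
are de-duplicated by their outgroup-ortholog key.

## Alignment scores and E-values

The internal aligner is plain Smith–Waterman with BLOSUM62 and affine
gap cost `gap_open + gap_extend · L` (11, 1), chosen to approximate
default BLASTp behaviour; the matrix ships as a plain-text data file and
`X` scores 0 against everything. Raw scores convert to bitscores with
the gapped-BLOSUM62 Karlin–Altschul constants (λ = 0.267, K = 0.041) and
to E-values as `E = m·n·2^(−bits)` over the search space of total query
× subject residues. Edge corrections and composition-based statistics
are deliberately out of scope: externally computed hit tables in the
12-column tabular dialect can be imported wherever exact BLAST
statistics matter. A k-mer seeding prefilter (shared 5-mers ≥ 2) limits
full dynamic programming to plausible homolog pairs; every *reported*
pair carries an exact full-DP score, and at the divergences of interest
(well below the reporting threshold) true homologs share hundreds of
seeds, so the filter does not change results — it is a compute
optimization, not a statistic.

Best-hit ties (equal bitscore) yield *no* best hit: a "single best hit"
criterion implies uniqueness, and conservative tie-breaking cannot
create false LSPs.

## The simulator's stated world

`sim_config()` fixes the generative story; the defaults are the package's
stated world and are not tuned per test:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 500 | ancestral gene families |
| `wgd_retention_prob` | 0.2 | pair survives the WGD (matches the ~80–85% duplicate loss of diploidization) |
| `loss_prob_a`, `loss_prob_b` | 0.4 | whole-lineage stem loss of one copy — the event that makes an LSP |
| `per_species_loss_prob` | 0.02 | extra independent single-species loss (noise; such families are labelled `noisy`) |
| `divergence_pre_split` | 0.1 | expected substitutions/site per copy, WGD → lineage split |
| `divergence_post_split` | 0.03 | expected substitutions/site, lineage split → each tip |
| `peptide_length` | 300 | residues per peptide |
| `n_chromosomes_per_species` | 25 | chromosomes per genome |

The panel layout mirrors the real study design: two lineage-A genomes,
four lineage-B genomes, two pre-WGD outgroups. With these defaults the
expected A-LSP fraction is
`wgd_retention_prob · (1 − loss_prob_a) · loss_prob_b ≈ 4.8%` of
families, the same order as the real headline fractions. Divergences are
chosen for testability, not for time-calibrated realism — no
divergence-calibrated substitution rates are published for this
procedure, so the defaults are set low enough that every true homolog
clears the 1e-80 cutoff with a wide margin, making "noiseless recovery"
a property of the *procedure*, not of a lucky threshold.

Mechanics worth knowing:

* Peptides evolve by a per-site Poisson substitution process whose
  marginal is applied directly: after `K ~ Poisson(d)` events a site is
  unchanged with probability `1/20 + (19/20)(−1/19)^K`, else uniform
  over the other 19 residues. Identity decays to the 1/20 random floor.
  No indels: the real pipeline treats length artifacts as exclusions,
  so simulating them is an extension, not a requirement.
* The two post-WGD copies are placed on a chromosome pair drawn once per
  family and inherited by every descendant species; gene order along a
  chromosome follows family index. This yields conserved synteny for
  the verification module. A lineage-stem loss keeps a randomly chosen
  copy, so the surviving singleton may sit on either chromosome of the
  pair — which is why `verify_families()` reports both the mean and the
  max synteny fraction over the two seed copies (only the copy on the
  ortholog's own chromosome is expected to retain its neighborhood).
* Outgroups never duplicate, by construction, and evolve
  `2·divergence_pre_split + divergence_post_split` from the ancestor so
  they are always the most distant leaves — rooting on them is safe.
* All randomness flows from the single config seed through private RNG
  streams; no stage touches the global RNG state.

**What a green test does not establish.** The simulator writes uniform
background residue frequencies, no rate heterogeneity, no gene
conversion, no indels, no assembly errors, no annotation noise, and
star-like within-lineage phylogeny. Perfect recovery on this world
validates the logic of the cascade (no false LSPs from correct inputs,
no losses from the bookkeeping), not its robustness to real genome
quality, which is why thresholds remain configurable and external hit
tables importable.

## Verification

The phylogenetic check asks one topological question: does the
duplication predate the speciations within the duplicate-bearing
lineage? Full Bayesian/ML machinery is consciously replaced by
neighbor joining on Poisson-corrected distances `d = −ln(1 − p)`
(capped at 7 when `p` approaches 1, the correction's domain boundary) —
a methodological simplification, not an equivalence claim; the question
is answerable at desk scale. After rooting on the first outgroup
ortholog, the copy-1 genes must form one clade and the copy-2 genes
another. Zero-length internal edges (< 1e-8) collapse to soft
polytomies, and the test passes if *some* resolution passes (a set
passes iff it is a union of complete child subtrees of its MRCA).
Copies are assigned to clades by distance to the two seed paralogs.

The synteny score replaces an interactive synteny browser with a local
neighborhood-overlap statistic: up to `window/2` flanking genes on each
side of a paralog copy, mapped through reciprocal best hits into the
single-copy ortholog's neighborhood; the shared fraction is normalized
by the achievable maximum, so genes near chromosome ends are not
penalized. No pass/fail threshold is imposed — no quantitative
conservation cutoff is published for this step, so fractions are
reported and thresholds left to the analyst.

## Statistics

* **Chromosome distribution.** The per-chromosome LSP/TSGD gene ratio is
  treated as a pseudoreplicate; the panel mean and `sd/√n` standard
  error are taken over chromosomes with at least one TSGD paralog
  (empty chromosomes are excluded and logged). Spearman's ρ between
  per-chromosome TSGD and LSP counts uses mid-ranks for ties and a
  permutation p-value `(1 + #{|ρ*| ≥ |ρ|})/(1 + N)` — reported "P = 0"
  values are really `p < 1/(1+N)`, since a permutation p-value cannot
  be exactly zero.
* **Enrichment.** Upper-tail hypergeometric p-values per term over a
  user-supplied annotation (gene → term, with an optional term → slim
  mapping applied as a reachability closure; cyclic mappings are an
  error; unmappable genes keep an `"unmapped"` bucket). The universe
  defaults to all genes analyzed, and is configurable — the original
  analysis used an external human GO background, which is not
  reproducible offline and is deliberately not bundled. Raw and
  Benjamini–Hochberg-adjusted values are both emitted because the
  upstream report does not state a correction; terms at
  `study_count ≤ 10` are kept in the table but flagged out of the
  report view, mirroring the "more than ten genes" reporting rule.

## Numerical and design choices

* Percentages are rounded half-up to one decimal on the percent scale
  (`4122/19600 → 21.0`), matching how headline fractions are printed;
  base R's round-half-even would give different last digits.
* Candidate pairs are derived from within-genome similarity
  (annotation-free) rather than from a database's paralog annotations,
  for self-containment; externally curated pair lists can be supplied
  through the hit-table import channel.
* Copy number `2+` requires co-orthologs on **different chromosomes** in
  the target species too — the WGD criterion extended consistently
  beyond the seed genome.
* Genes on unplaced scaffolds are dropped by default
  (`exclude_unplaced`, pattern-configurable), since the analysis is
  chromosome-level.
* Known printed-arithmetic inconsistencies upstream (family × 2 ≠ gene
  counts in one case; two different counts attached to the same
  percentage) are handled by always reporting families and genes as
  separate numbers rather than attempting to reproduce either figure.
* Infrastructure leans on mature packages (Biostrings for FASTA, ape
  for NJ/newick, Matrix for the seeding cross-product, stats for the
  hypergeometric tail and BH); the scientific cascade itself — filters,
  copy-number logic, classification, simulator, topology test, synteny
  score, E-value model — is implemented here.

## Limitations

* 2:2 ortholog quartets are paired by best hit only; post-WGD
  small-scale duplications are not modelled as a separate class.
* The E-value model omits BLAST's finite-size edge corrections; at the
  1e-80 working cutoff this is immaterial, but imported hit tables are
  preferred for borderline real-data statistics.
* The NJ topology test can fail at high divergence through
  distance-estimation noise even for true LSPs; it is a verification
  aid, not a gatekeeper (calls are not revoked on `topology_fail`,
  the status is reported).
* No GO DAG reasoning beyond the supplied slim mapping.
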