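#' Two-lineage panel configuration
#'
#' Defines the species panel (two post-WGD superorder lineages plus
#' pre-WGD outgroups), the seed genome of each lineage used for the
#' initial reciprocal duplicate screen, and the filtering thresholds.
#'
#' @param lineage_a,lineage_b nonempty, disjoint species label vectors.
#' @param outgroups nonempty vector of pre-WGD outgroup species; every
#'   outgroup must pass the singleton test.
#' @param seed_a,seed_b seed species (defaults: first of each lineage).
#' @param evalue_cutoff similarity threshold for all filtering stages
#'   (default 1e-80).
#' @param coverage_min minimum mutual alignment coverage for a duplicate
#'   pair to survive the isoform/chimera exclusion, in (0, 1].
#' @param length_ratio_max maximum peptide length ratio (> 1) for the
#'   same exclusion.
#' @param synteny_window total neighborhood size (genes) used by
#'   [synteny_score()].
#' @param seed master RNG seed for every stochastic stage.
#' @param exclude_unplaced drop genes whose chromosome label matches
#'   `unplaced_pattern` (chromosome-level analysis).
#' @param unplaced_pattern regular expression for scaffold labels.
#' @param allow_missing_species species allowed to have copy number 0
#'   without demoting a family to unresolved (incomplete assemblies or
#'   transcriptome-only species).
#' @return a `panel_config` list.
#' @export
panel_config <- function(lineage_a, lineage_b, outgroups,
                         seed_a = lineage_a[[1]], seed_b = lineage_b[[1]],
                         evalue_cutoff = 1e-80, coverage_min = 0.5,
                         length_ratio_max = 2, synteny_window = 10,
                         seed = 1L, exclude_unplaced = TRUE,
                         unplaced_pattern = "^(scaffold|contig|Un)",
                         allow_missing_species = character()) {
  lineage_a <- as.character(lineage_a)
  lineage_b <- as.character(lineage_b)
  outgroups <- as.character(outgroups)
  if (!length(lineage_a) || !length(lineage_b) || !length(outgroups))
    stop("lineage_a, lineage_b and outgroups must each be nonempty")
  all_sp <- c(lineage_a, lineage_b, outgroups)
  if (anyDuplicated(all_sp))
    stop("lineage_a, lineage_b and outgroups must be pairwise disjoint")
  if (!seed_a %in% lineage_a) stop("seed_a must belong to lineage_a")
  if (!seed_b %in% lineage_b) stop("seed_b must belong to lineage_b")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  if (coverage_min <= 0 || coverage_min > 1)
    stop("coverage_min must be in (0, 1]")
  if (length_ratio_max <= 1) stop("length_ratio_max must be > 1")
  if (synteny_window < 1) stop("synteny_window must be a positive integer")
  structure(list(
    lineage_a = lineage_a, lineage_b = lineage_b, outgroups = outgroups,
    seed_a = seed_a, seed_b = seed_b, evalue_cutoff = evalue_cutoff,
    coverage_min = coverage_min, length_ratio_max = length_ratio_max,
    synteny_window = as.integer(synteny_window), seed = as.integer(seed),
    exclude_unplaced = isTRUE(exclude_unplaced),
    unplaced_pattern = unplaced_pattern,
    allow_missing_species = as.character(allow_missing_species)),
    class = "panel_config")
}

#' Default synthetic panel layout
#'
#' Mirrors the real study design: two lineage-A genomes (as for the two
#' sequenced Ostariophysi genomes), four lineage-B genomes (as for the
#' four Acanthopterygii orders sampled) and two pre-WGD outgroups (as for
#' spotted gar and human).
#'
#' @param ... overrides passed to [panel_config()].
#' @export
default_panel <- function(...) {
  panel_config(lineage_a = c("A1", "A2"),
               lineage_b = c("B1", "B2", "B3", "B4"),
               outgroups = c("OG1", "OG2"), ...)
}

#' Synthetic-panel simulation configuration
#'
#' States the simulated world: `n_families` gene families descend from a
#' common ancestor through one whole-genome duplication. A family retains
#' both copies immediately post-WGD with probability `wgd_retention_prob`
#' (default 0.2, consistent with the ~80-85% duplicate loss during
#' diploidization). A retained pair collapses to a singleton on a whole
#' lineage's stem branch with probability `loss_prob_a` / `loss_prob_b`
#' (default 0.4 each), the event that creates lineage-specific paralogs;
#' `per_species_loss_prob` adds independent single-species losses
#' (noise). Peptides of length `peptide_length` evolve by Poisson
#' substitution: `divergence_pre_split` expected substitutions/site on
#' each copy's branch from the WGD to the lineage split and
#' `divergence_post_split` on each terminal branch (outgroups use
#' `2 * divergence_pre_split + divergence_post_split`).
#'
#' @param n_families number of simulated families.
#' @param n_chromosomes_per_species chromosomes per genome (>= 2 when any
#'   pair is retained; the two copies always land on different
#'   chromosomes).
#' @param peptide_length residues per peptide.
#' @param wgd_retention_prob,loss_prob_a,loss_prob_b,per_species_loss_prob
#'   probabilities in [0, 1], see description.
#' @param divergence_pre_split,divergence_post_split expected
#'   substitutions per site (>= 0).
#' @param species_panel a [panel_config()].
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 500L, n_chromosomes_per_species = 25L,
                       peptide_length = 300L, wgd_retention_prob = 0.2,
                       loss_prob_a = 0.4, loss_prob_b = 0.4,
                       per_species_loss_prob = 0.02,
                       divergence_pre_split = 0.1,
                       divergence_post_split = 0.03,
                       species_panel = default_panel(), seed = 1L) {
  probs <- c(wgd_retention_prob, loss_prob_a, loss_prob_b,
             per_species_loss_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (divergence_pre_split < 0 || divergence_post_split < 0)
    stop("divergences must be >= 0")
  if (n_families < 1) stop("n_families must be positive")
  if (peptide_length < 1) stop("peptide_length must be positive")
  stopifnot(inherits(species_panel, "panel_config"))
  structure(list(
    n_families = as.integer(n_families),
    n_chromosomes_per_species = as.integer(n_chromosomes_per_species),
    peptide_length = as.integer(peptide_length),
    wgd_retention_prob = wgd_retention_prob, loss_prob_a = loss_prob_a,
    loss_prob_b = loss_prob_b, per_species_loss_prob = per_species_loss_prob,
    divergence_pre_split = divergence_pre_split,
    divergence_post_split = divergence_post_split,
    species_panel = species_panel, seed = as.integer(seed)),
    class = "sim_config")
}

#' Read a configuration file (YAML or flat key: value)
#'
#' A `kind: panel` document maps onto [panel_config()], `kind: sim` onto
#' [sim_config()] (its `species_panel` block, if present, is itself a
#' panel document).
#'
#' @param path YAML file.
#' @return a `panel_config` or `sim_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  kind <- y$kind %||% if ("n_families" %in% names(y)) "sim" else "panel"
  y$kind <- NULL
  if (kind == "sim") {
    if (!is.null(y$species_panel)) {
      y$species_panel$kind <- NULL
      y$species_panel <- do.call(panel_config, y$species_panel)
    }
    do.call(sim_config, y)
  } else do.call(panel_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
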