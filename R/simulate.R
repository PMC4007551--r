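#' Mutate a peptide under a Poisson substitution model
#'
#' Each site receives `K ~ Poisson(expected_distance)` substitution
#' events; each event replaces the current residue by one of the other
#' 19 drawn uniformly. The per-site marginal of this chain is applied
#' directly: after `K` events the residue is unchanged with probability
#' `1/20 + (19/20) * (-1/19)^K`, otherwise uniform over the other 19.
#' Identity therefore decays towards the random expectation 1/20 as the
#' distance grows.
#'
#' @param sequence peptide string.
#' @param expected_distance expected substitutions per site (>= 0).
#' @param rng integer seed for a private RNG stream, or `NULL` to draw
#'   from the current stream (internal use).
#' @return mutated peptide of identical length.
#' @export
mutate_peptide <- function(sequence, expected_distance, rng = NULL) {
  if (expected_distance < 0) stop("expected_distance must be >= 0")
  run <- function() {
    chars <- strsplit(sequence, "")[[1]]
    L <- length(chars)
    k <- rpois(L, expected_distance)
    hit <- k > 0L
    if (any(hit)) {
      p_same <- 1 / 20 + (19 / 20) * (-1 / 19)^k[hit]
      change <- runif(sum(hit)) >= p_same
      idx <- which(hit)[change]
      if (length(idx)) {
        aa <- aa_alphabet()[1:20]
        for (i in idx) chars[i] <- sample(setdiff(aa, chars[i]), 1L)
      }
    }
    paste(chars, collapse = "")
  }
  if (is.null(rng)) run() else with_seed(rng, run())
}

# uniform-background random peptide over the 20 canonical residues
random_peptide <- function(length) {
  paste(sample(aa_alphabet()[1:20], length, replace = TRUE), collapse = "")
}

#' Simulate a post-WGD two-lineage genome panel with ground truth
#'
#' Generates `n_families` families descended from a common ancestor
#' through one whole-genome duplication, with lineage-stem and
#' per-species paralog loss, consistent chromosome placement (the two
#' copies of a family occupy the same chromosome pair in every species
#' that retains them; gene order along a chromosome follows family
#' index, giving conserved synteny), Poisson peptide divergence, and a
#' per-family ground-truth record. Outgroup genomes never duplicate.
#'
#' `true_class` is `A_LSP` iff every lineage-A species carries 2 copies
#' and every lineage-B species 1 (symmetrically `B_LSP`);
#' `shared_duplicate`/`shared_singleton` when both lineages match; any
#' additional single-species loss makes the family `noisy`.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (one [gene_table()] covering all species),
#'   `truth` (data.frame: family_id, post_wgd_state, lineage states,
#'   per-species copy-number columns `cn_<species>`, true_class) and
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$species_panel
  sp_a <- panel$lineage_a
  sp_b <- panel$lineage_b
  sp_og <- panel$outgroups
  ingroup <- c(sp_a, sp_b)
  n_chr <- config$n_chromosomes_per_species
  with_seed(config$seed, {
    fam <- sprintf("F%04d", seq_len(config$n_families))
    retained <- runif(config$n_families) < config$wgd_retention_prob
    if (any(retained) && n_chr < 2L)
      stop("n_chromosomes_per_species must be >= 2 to place a retained ",
           "pair on different chromosomes")
    gene_rows <- vector("list", config$n_families)
    truth_rows <- vector("list", config$n_families)
    d_og <- 2 * config$divergence_pre_split + config$divergence_post_split
    for (f in seq_len(config$n_families)) {
      anc <- random_peptide(config$peptide_length)
      chrs <- if (n_chr >= 2L) sample(n_chr, 2L) else c(1L, 1L)
      # trunk sequence of each post-WGD copy at the lineage split
      trunk <- c(mutate_peptide(anc, config$divergence_pre_split),
                 mutate_peptide(anc, config$divergence_pre_split))
      state_a <- state_b <- "singleton"
      keep_a <- keep_b <- 1L   # which copy survives a stem loss
      if (retained[f]) {
        state_a <- if (runif(1) < config$loss_prob_a) "singleton" else "duplicate"
        state_b <- if (runif(1) < config$loss_prob_b) "singleton" else "duplicate"
        keep_a <- sample(2L, 1L)
        keep_b <- sample(2L, 1L)
      }
      noisy <- FALSE
      cn <- setNames(integer(length(ingroup) + length(sp_og)),
                     c(ingroup, sp_og))
      rows <- list()
      for (sp in ingroup) {
        in_a <- sp %in% sp_a
        state <- if (in_a) state_a else state_b
        copies <- if (!retained[f]) 1L
          else if (state == "duplicate") c(1L, 2L)
          else if (in_a) keep_a else keep_b
        if (length(copies) == 2L &&
            runif(1) < config$per_species_loss_prob) {
          copies <- sample(copies, 1L)
          noisy <- TRUE
        }
        cn[sp] <- length(copies)
        for (cp in copies) {
          rows[[length(rows) + 1L]] <- list(
            gene_id = sprintf("%s_%s_c%d", fam[f], sp, cp), species = sp,
            chromosome = as.character(chrs[cp]), family = f, copy = cp,
            peptide = mutate_peptide(trunk[cp],
                                     config$divergence_post_split))
        }
      }
      for (sp in sp_og) {
        cn[sp] <- 1L
        rows[[length(rows) + 1L]] <- list(
          gene_id = sprintf("%s_%s_c1", fam[f], sp), species = sp,
          chromosome = as.character(chrs[1L]), family = f, copy = 1L,
          peptide = mutate_peptide(anc, d_og))
      }
      gene_rows[[f]] <- rows
      true_class <-
        if (noisy) "noisy"
        else if (!retained[f]) "shared_singleton"
        else if (state_a == "duplicate" && state_b == "singleton") "A_LSP"
        else if (state_b == "duplicate" && state_a == "singleton") "B_LSP"
        else if (state_a == "duplicate") "shared_duplicate"
        else "shared_singleton"
      truth_rows[[f]] <- c(
        list(family_id = fam[f],
             post_wgd_state = if (retained[f]) "retained_pair" else "singleton",
             lineage_a_state = if (retained[f]) state_a else "singleton",
             lineage_b_state = if (retained[f]) state_b else "singleton"),
        setNames(as.list(cn), paste0("cn_", names(cn))),
        list(true_class = true_class))
    }
    flat <- unlist(gene_rows, recursive = FALSE)
    g <- data.frame(
      gene_id = vapply(flat, `[[`, character(1), "gene_id"),
      species = vapply(flat, `[[`, character(1), "species"),
      chromosome = vapply(flat, `[[`, character(1), "chromosome"),
      family = vapply(flat, `[[`, integer(1), "family"),
      copy = vapply(flat, `[[`, integer(1), "copy"),
      peptide = vapply(flat, `[[`, character(1), "peptide"),
      stringsAsFactors = FALSE)
    # gene order along each chromosome follows family index
    g <- g[order(g$species, as.integer(g$chromosome), g$family, g$copy), ]
    spacing <- 3L * config$peptide_length + 1000L
    pos <- stats::ave(seq_len(nrow(g)),
                      paste(g$species, g$chromosome), FUN = seq_along)
    g$start <- (pos - 1L) * spacing + 1L
    g$end <- g$start + 3L * config$peptide_length - 1L
    g$strand <- rep(c("+", "-"), length.out = nrow(g))
    truth <- do.call(rbind, lapply(truth_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    list(genes = gene_table(g[c("gene_id", "species", "chromosome",
                                "start", "end", "strand", "peptide")]),
         truth = truth, config = config)
  })
}

#' Write / read a simulated panel on disk
#'
#' `write_panel()` emits one FASTA + gene-map TSV per species plus
#' `truth.tsv`; `read_panel()` loads them back into the in-memory layout
#' of [simulate_panel()] (without `config`).
#'
#' @param panel result of [simulate_panel()].
#' @param out_dir output directory (created if needed).
#' @export
write_panel <- function(panel, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(panel$genes$species)) {
    g <- gene_table(panel$genes[panel$genes$species == sp, , drop = FALSE])
    write_proteome(g, file.path(out_dir, paste0(sp, ".fa")),
                   file.path(out_dir, paste0(sp, ".genemap.tsv")))
  }
  if (!is.null(panel$truth))
    write.table(panel$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @rdname write_panel
#' @param dir directory written by [write_panel()].
#' @param species species labels to load (default: every `*.fa` present).
#' @export
read_panel <- function(dir, species = NULL) {
  if (is.null(species))
    species <- sub("\\.fa$", "", basename(Sys.glob(file.path(dir, "*.fa"))))
  gl <- lapply(species, function(sp)
    read_proteome(file.path(dir, paste0(sp, ".fa")),
                  file.path(dir, paste0(sp, ".genemap.tsv")), sp))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  list(genes = gene_table(do.call(rbind, lapply(gl, as.data.frame))),
       truth = truth)
}
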