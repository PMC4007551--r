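# stage wrapper: attach the failing stage's name to propagated errors
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

# hit-table cache over the panel; tables for the reverse direction are
# derived by transposition (Smith-Waterman scores are symmetric)
table_cache <- function(genes_by_species, search, precomputed = NULL) {
  env <- new.env(parent = emptyenv())
  get_table <- function(from, to) {
    key <- paste(from, to, sep = "->")
    if (!is.null(env[[key]])) return(env[[key]])
    if (!is.null(precomputed) && key %in% names(precomputed)) {
      env[[key]] <- precomputed[[key]]
      return(env[[key]])
    }
    rkey <- paste(to, from, sep = "->")
    if (!is.null(env[[rkey]])) {
      env[[key]] <- transpose_hit_table(env[[rkey]])
      return(env[[key]])
    }
    gf <- genes_by_species[[from]]
    gt <- genes_by_species[[to]]
    if (is.null(gf) || !nrow(gf)) stop("empty proteome for '", from, "'")
    if (is.null(gt) || !nrow(gt)) stop("empty proteome for '", to, "'")
    env[[key]] <- all_vs_all(gf, gt, search)
    env[[key]]
  }
  get_table
}

# one direction of the cascade: duplicate pairs in `seed_sp`, artifact
# and chromosome filters, outgroup singleton test, panel-wide copy
# numbers, LSP classification
screen_direction <- function(dir_label, seed_sp, config, genes_by_species,
                             get_table, search) {
  cutoff <- config$evalue_cutoff
  ingroup <- c(config$lineage_a, config$lineage_b)
  others <- setdiff(ingroup, seed_sp)
  seed_genes <- genes_by_species[[seed_sp]]
  glen <- setNames(nchar(seed_genes$peptide), seed_genes$gene_id)
  gchr <- setNames(seed_genes$chromosome, seed_genes$gene_id)
  gpep <- setNames(seed_genes$peptide, seed_genes$gene_id)

  self <- run_stage("self_search", get_table(seed_sp, seed_sp))
  dup <- run_stage("duplicate_pairs", find_duplicate_pairs(self, cutoff))
  counts <- c(candidate_pairs = nrow(dup$pairs))
  log_msg("info", "[", dir_label, "] candidate pairs: ", nrow(dup$pairs),
          " (", length(dup$flagged), " larger families flagged)")

  cand <- dup$pairs
  cand$drop_reason <- rep(NA_character_, nrow(cand))
  # chimera / splice-variant / isoform exclusion
  for (i in seq_len(nrow(cand))) {
    aln <- align_pair(gpep[[cand$gene_1[i]]], gpep[[cand$gene_2[i]]],
                      search$substitution_matrix,
                      search$gap_open, search$gap_extend)
    ex <- exclude_artifacts(aln, glen[[cand$gene_1[i]]],
                            glen[[cand$gene_2[i]]],
                            config$coverage_min, config$length_ratio_max)
    if (!ex$keep) cand$drop_reason[i] <- ex$reason
  }
  counts["after_artifact_exclusion"] <- sum(is.na(cand$drop_reason))
  # different-chromosome criterion in the seed genome
  same_chr <- is.na(cand$drop_reason) &
    gchr[cand$gene_1] == gchr[cand$gene_2]
  cand$drop_reason[same_chr] <- "same_chromosome"
  counts["after_chromosome_filter"] <- sum(is.na(cand$drop_reason))

  og_tables <- run_stage("outgroup_screen", {
    setNames(lapply(config$outgroups, function(og)
      list(to = get_table(seed_sp, og), from = get_table(og, seed_sp))),
      config$outgroups)
  })
  fam_rows <- list()
  for (i in seq_len(nrow(cand))) {
    if (!is.na(cand$drop_reason[i])) next
    pair <- c(cand$gene_1[i], cand$gene_2[i])
    ot <- outgroup_singleton_test(pair, og_tables, cutoff)
    if (!ot$pass) {
      cand$drop_reason[i] <- ot$reason
      next
    }
    cn <- setNames(vector("list", length(ingroup)), ingroup)
    cn[[seed_sp]] <- list(count = 2L, genes = pair,
                          chromosomes = unname(gchr[pair]),
                          ambiguous = FALSE)
    for (sp in others)
      cn[[sp]] <- copy_number(pair, get_table(seed_sp, sp),
                              get_table(sp, seed_sp),
                              genes_by_species[[sp]], cutoff)
    cls <- classify_lsp(list(copy_number = cn), config)
    row <- data.frame(
      family_id = sprintf("%s-%04d", toupper(dir_label),
                          length(fam_rows) + 1L),
      direction = dir_label, seed_species = seed_sp,
      gene_1 = pair[1], gene_2 = pair[2],
      chromosome_1 = unname(gchr[pair[1]]),
      chromosome_2 = unname(gchr[pair[2]]),
      outgroup_orthologs = paste(names(ot$orthologs), ot$orthologs,
                                 sep = ":", collapse = ";"),
      call = cls$call, reason = cls$reason %||% NA_character_,
      stringsAsFactors = FALSE)
    for (sp in ingroup) {
      row[[paste0("cn_", sp)]] <- cn[[sp]]$count
      row[[paste0("genes_", sp)]] <- paste(cn[[sp]]$genes, collapse = ",")
    }
    fam_rows[[length(fam_rows) + 1L]] <- row
  }
  counts["after_outgroup_test"] <- length(fam_rows)
  fam <- if (length(fam_rows)) do.call(rbind, fam_rows) else NULL
  counts["called_tsgd"] <- if (is.null(fam)) 0L else
    sum(fam$call %in% c("A_LSP", "B_LSP", "shared_duplicate"))
  counts["called_lsp"] <- if (is.null(fam)) 0L else
    sum(fam$call == paste0(toupper(dir_label), "_LSP"))
  log_msg("info", "[", dir_label, "] ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  list(families = fam, candidates = cand, counts = counts)
}

#' Run the full LSP-detection pipeline on a genome panel
#'
#' Executes the cascade from both seed genomes (lineage-A LSPs are
#' discovered from `seed_a`, lineage-B LSPs from `seed_b`), merges the
#' two directions (shared duplicates found twice are de-duplicated by
#' their outgroup orthologs), computes per-chromosome retention
#' statistics with a Spearman permutation test, and summarizes the
#' panel. Deterministic given `config$seed`; stage survivor counts are
#' logged and returned.
#'
#' @param config a [panel_config()].
#' @param input a panel directory (as written by [write_panel()]) or a
#'   list with element `genes` (a combined [gene_table()]).
#' @param search a [search_config()].
#' @param hit_tables optional named list of precomputed [hit_table()]s,
#'   keyed `"from->to"`, to use instead of the internal aligner.
#' @return a `result_bundle`: list with `families`, `candidates`,
#'   `chromosome_stats`, `summary`, `stage_counts`, `genes`, `config`
#'   and a `tables` accessor.
#' @export
run_pipeline <- function(config, input, search = search_config(),
                         hit_tables = NULL) {
  stopifnot(inherits(config, "panel_config"))
  genes <- run_stage("load_input", {
    g <- if (is.character(input)) read_panel(input)$genes else input$genes
    if (config$exclude_unplaced)
      g <- filter_unplaced(g, config$unplaced_pattern)
    g
  })
  species <- c(config$lineage_a, config$lineage_b, config$outgroups)
  genes_by_species <- setNames(lapply(species, function(sp)
    gene_table(genes[genes$species == sp, , drop = FALSE])), species)
  # a species with no genes is reported by the stage that first needs it
  get_table <- table_cache(genes_by_species, search, hit_tables)

  dir_a <- screen_direction("a", config$seed_a, config, genes_by_species,
                            get_table, search)
  dir_b <- screen_direction("b", config$seed_b, config, genes_by_species,
                            get_table, search)
  families <- rbind(dir_a$families, dir_b$families)
  if (is.null(families)) {
    ingroup <- c(config$lineage_a, config$lineage_b)
    families <- data.frame(
      family_id = character(), direction = character(),
      seed_species = character(), gene_1 = character(),
      gene_2 = character(), chromosome_1 = character(),
      chromosome_2 = character(), outgroup_orthologs = character(),
      call = character(), reason = character(), stringsAsFactors = FALSE)
    for (sp in ingroup) {
      families[[paste0("cn_", sp)]] <- integer()
      families[[paste0("genes_", sp)]] <- character()
    }
  }
  # shared duplicates surface from both seeds; de-duplicate on the
  # outgroup ortholog key, keeping the direction-a record
  families$duplicate_of <- rep(NA_character_, nrow(families))
  if (nrow(families)) {
    key <- families$outgroup_orthologs
    dup <- duplicated(key) & families$call == "shared_duplicate"
    families$duplicate_of[dup] <-
      families$family_id[match(key[dup], key)]
  }

  cutoff <- config$evalue_cutoff
  ab <- get_table(config$seed_a, config$seed_b)
  ba <- get_table(config$seed_b, config$seed_a)
  totals <- c(a = count_positive_hits(ab, cutoff),
              b = count_positive_hits(ba, cutoff))

  chrom <- run_stage("chromosome_stats", {
    per_dir <- lapply(list(a = dir_a, b = dir_b), function(d) {
      if (is.null(d$families)) return(NULL)
      f <- d$families
      called <- f$call %in% c("A_LSP", "B_LSP", "shared_duplicate")
      lsp <- f$call == paste0(toupper(f$direction[1]), "_LSP")
      chromosome_table(
        c(f$gene_1[called], f$gene_2[called]),
        c(f$gene_1[lsp], f$gene_2[lsp]),
        genes_by_species[[f$seed_species[1]]])
    })
    pooled <- do.call(rbind, lapply(per_dir, function(x)
      if (!is.null(x)) x$per_chromosome))
    rho <- tryCatch(
      spearman_perm(pooled$tsgd_count, pooled$lsp_count,
                    n_permutations = 10000L,
                    seed = stage_seed(config$seed, "spearman")),
      error = function(e) {
        log_msg("warn", "spearman unavailable: ", conditionMessage(e))
        list(rho = NA_real_, p_perm = NA_real_)
      })
    list(per_direction = per_dir, pooled = pooled,
         rho = rho$rho, p_perm = rho$p_perm)
  })

  bundle <- structure(list(
    families = families,
    candidates = list(a = dir_a$candidates, b = dir_b$candidates),
    chromosome_stats = chrom,
    stage_counts = list(a = dir_a$counts, b = dir_b$counts),
    totals = totals, genes = genes, config = config,
    tables = get_table), class = "result_bundle")
  bundle$summary <- if (all(totals > 0)) summarize_panel(bundle, totals)
    else NULL
  bundle
}

#' Write a result bundle to TSV + JSON files
#'
#' Emits `tsgd_pairs.tsv` (every surviving family with its seed pair and
#' copy numbers), `lsp_calls.tsv` (family_id, call, per-species copy
#' numbers, verification status, drop reason), `chromosome_stats.tsv`
#' and `summary.json`. Re-running an identical configuration reproduces
#' byte-identical files.
#'
#' @param bundle a `result_bundle`.
#' @param out_dir output directory.
#' @param verification optional data.frame from [verify_families()]
#'   merged into `lsp_calls.tsv`.
#' @export
write_result_bundle <- function(bundle, out_dir, verification = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  fam <- bundle$families
  tsv(fam, "tsgd_pairs.tsv")
  calls <- fam[c("family_id", "direction", "call", "reason",
                 grep("^cn_", names(fam), value = TRUE))]
  calls$verification_status <- rep("untested", nrow(calls))
  if (!is.null(verification)) {
    i <- match(calls$family_id, verification$family_id)
    ok <- !is.na(i)
    calls$verification_status[ok] <-
      ifelse(verification$topology_pass[i[ok]], "topology_pass",
             "topology_fail")
  }
  tsv(calls, "lsp_calls.tsv")
  chrom <- bundle$chromosome_stats$pooled
  tsv(chrom, "chromosome_stats.tsv")
  s <- bundle$summary
  json <- list(
    totals = as.list(bundle$totals),
    stage_counts = bundle$stage_counts,
    spearman = list(rho = bundle$chromosome_stats$rho,
                    p_perm = bundle$chromosome_stats$p_perm),
    summary = if (is.null(s)) NULL else unclass(s))
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Phylogenetic and synteny verification of called LSP families
#'
#' For every LSP-called family: builds a neighbor-joining tree on
#' Poisson-corrected distances over all family gene copies plus the
#' first outgroup ortholog, partitions the lineage copies by proximity
#' to the two seed paralogs, and applies
#' [duplication_topology_test()]; computes [synteny_score()] of each
#' seed paralog's neighborhood against the single-copy ortholog's
#' neighborhood in the opposite seed genome.
#'
#' @param bundle a `result_bundle` from [run_pipeline()].
#' @return data.frame: family_id, call, topology_pass, mean and max
#'   synteny shared fraction over the two seed copies (the copy on the
#'   single-copy ortholog's own chromosome carries the conserved
#'   neighborhood), newick string of the family tree.
#' @export
verify_families <- function(bundle) {
  config <- bundle$config
  genes <- bundle$genes
  pep <- setNames(genes$peptide, genes$gene_id)
  fam <- bundle$families
  fam <- fam[fam$call %in% c("A_LSP", "B_LSP") &
               is.na(fam$duplicate_of), , drop = FALSE]
  rows <- lapply(seq_len(nrow(fam)), function(i) {
    f <- fam[i, ]
    own <- if (f$direction == "a") config$lineage_a else config$lineage_b
    other_seed <- if (f$direction == "a") config$seed_b else config$seed_a
    dup_genes <- unique(unlist(strsplit(
      unlist(f[paste0("genes_", own)]), ",")))
    dup_genes <- dup_genes[nzchar(dup_genes)]
    og <- strsplit(strsplit(f$outgroup_orthologs, ";")[[1]][1], ":")[[1]][2]
    leaves <- unique(c(f$gene_1, f$gene_2, dup_genes, og))
    tree <- family_tree(pep[leaves])
    # assign each lineage copy to the nearer seed paralog
    others <- setdiff(leaves, c(f$gene_1, f$gene_2, og))
    d1 <- vapply(others, function(g)
      protein_distance(pep[[g]], pep[[f$gene_1]]), numeric(1))
    d2 <- vapply(others, function(g)
      protein_distance(pep[[g]], pep[[f$gene_2]]), numeric(1))
    copy1 <- c(f$gene_1, others[d1 <= d2])
    copy2 <- c(f$gene_2, others[d1 > d2])
    topo <- duplication_topology_test(tree, copy1, copy2, og)
    # synteny against the single-copy ortholog in the opposite seed
    single <- strsplit(f[[paste0("genes_", other_seed)]], ",")[[1]]
    syn <- syn_max <- NA_real_
    if (length(single) == 1L && nzchar(single)) {
      rbh <- reciprocal_best_hits(
        bundle$tables(f$seed_species, other_seed),
        bundle$tables(other_seed, f$seed_species))
      sc <- synteny_score(f$family_id, c(f$gene_1, f$gene_2), single,
                          genes, rbh, config$synteny_window,
                          f$seed_species, other_seed)
      syn <- mean(sc$shared_fraction, na.rm = TRUE)
      # only the copy on the ortholog's own chromosome is expected to
      # retain neighborhood conservation; the max identifies it
      syn_max <- suppressWarnings(max(sc$shared_fraction, na.rm = TRUE))
      if (!is.finite(syn_max)) syn_max <- NA_real_
    }
    data.frame(family_id = f$family_id, call = f$call,
               topology_pass = topo, synteny_mean_fraction = syn,
               synteny_max_fraction = syn_max,
               newick = ape::write.tree(tree), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), call = character(),
               topology_pass = logical(),
               synteny_mean_fraction = numeric(),
               synteny_max_fraction = numeric(), newick = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
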