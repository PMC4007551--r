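#' Candidate duplicate pairs within a seed genome
#'
#' Builds the graph of mutual above-cutoff self-hits (g1 != g2, both
#' directions at E <= cutoff) and reports connected components of size
#' exactly two as candidate TSGD pairs, with lexicographically ordered
#' ids. Components of three or more mutually similar genes are larger
#' families: ambiguous for pair calling, so they are flagged and
#' excluded.
#'
#' @param self_hits [hit_table()] of the seed proteome against itself.
#' @param cutoff E-value cutoff (default 1e-80).
#' @return list with `pairs` (data.frame gene_1, gene_2) and `flagged`
#'   (list of character vectors, the larger components).
#' @export
find_duplicate_pairs <- function(self_hits, cutoff = 1e-80) {
  h <- self_hits[self_hits$evalue <= cutoff &
                   self_hits$query_id != self_hits$subject_id, , drop = FALSE]
  key <- function(q, s) paste(pmin(q, s), pmax(q, s), sep = "\r")
  k <- key(h$query_id, h$subject_id)
  mutual <- unique(k[duplicated(k)])   # seen in both directions
  out <- list(pairs = data.frame(gene_1 = character(), gene_2 = character(),
                                 stringsAsFactors = FALSE),
              flagged = list())
  if (!length(mutual)) return(out)
  ends <- do.call(rbind, strsplit(mutual, "\r", fixed = TRUE))
  # connected components by union-find
  nodes <- unique(as.vector(ends))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (r in seq_len(nrow(ends))) {
    a <- find(match(ends[r, 1], nodes)); b <- find(match(ends[r, 2], nodes))
    if (a != b) parent[[b]] <- a
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  groups <- split(nodes, comp)
  sizes <- lengths(groups)
  pairs <- t(vapply(groups[sizes == 2L],
                    function(g) sort(g), character(2)))
  if (nrow(pairs)) {
    out$pairs <- data.frame(gene_1 = pairs[, 1], gene_2 = pairs[, 2],
                            stringsAsFactors = FALSE)
    out$pairs <- out$pairs[order(out$pairs$gene_1), , drop = FALSE]
    rownames(out$pairs) <- NULL
  }
  out$flagged <- unname(lapply(groups[sizes > 2L], sort))
  out
}

#' Chimera / splice-variant / isoform exclusion
#'
#' A candidate pair is kept iff both alignment coverages reach
#' `coverage_min` and the peptide length ratio does not exceed
#' `length_ratio_max`; otherwise the drop reason is recorded. This is
#' the alignment-based screen that removes annotation artifacts
#' masquerading as duplicates.
#'
#' @param alignment result of [align_pair()] for the two peptides.
#' @param len_1,len_2 peptide lengths.
#' @param coverage_min,length_ratio_max thresholds (see
#'   [panel_config()]).
#' @return list with `keep` (logical) and `reason` (`NA`, `"coverage"`
#'   or `"length_ratio"`).
#' @export
exclude_artifacts <- function(alignment, len_1, len_2, coverage_min = 0.5,
                              length_ratio_max = 2) {
  ratio <- max(len_1, len_2) / min(len_1, len_2)
  if (alignment$query_coverage < coverage_min ||
      alignment$subject_coverage < coverage_min)
    list(keep = FALSE, reason = "coverage")
  else if (ratio > length_ratio_max)
    list(keep = FALSE, reason = "length_ratio")
  else list(keep = TRUE, reason = NA_character_)
}

#' Pre-WGD outgroup singleton test
#'
#' A genuine WGD pair must trace to a single pre-duplication gene: in
#' every outgroup, both pair members must share the same unique best
#' outgroup hit, and that outgroup gene must have no above-cutoff hit to
#' any seed gene outside the pair.
#'
#' @param pair character vector of the two seed gene ids.
#' @param outgroup_tables named list (one entry per outgroup species) of
#'   lists with elements `to` (seed -> outgroup [hit_table()]) and
#'   `from` (outgroup -> seed).
#' @param cutoff E-value cutoff.
#' @return list with `pass`, `orthologs` (named character: outgroup
#'   species -> gene id) and `reason`.
#' @export
outgroup_singleton_test <- function(pair, outgroup_tables, cutoff = 1e-80) {
  if (!length(outgroup_tables) || is.null(names(outgroup_tables)))
    stop("outgroup_tables must be a named list with 'to' and 'from' tables")
  orth <- character()
  for (og in names(outgroup_tables)) {
    tt <- outgroup_tables[[og]]
    if (is.null(tt$to) || is.null(tt$from))
      stop("missing hit table(s) for outgroup '", og, "'")
    best <- best_hit_map(tt$to[tt$to$evalue <= cutoff, , drop = FALSE])
    b1 <- best[pair[1]]; b2 <- best[pair[2]]
    if (is.na(b1) || is.na(b2) || b1 != b2)
      return(list(pass = FALSE, orthologs = orth,
                  reason = paste0("outgroup_", og, "_no_common_best")))
    extra <- tt$from$subject_id[tt$from$query_id == b1 &
                                  tt$from$evalue <= cutoff]
    if (length(setdiff(extra, pair)))
      return(list(pass = FALSE, orthologs = orth,
                  reason = paste0("outgroup_", og, "_extra_seed_hit")))
    orth[og] <- unname(b1)
  }
  list(pass = TRUE, orthologs = orth, reason = NA_character_)
}

#' Copy number of a family in a non-seed panel species
#'
#' Reciprocally supported co-orthologs of the seed pair are counted: a
#' target gene supports the family iff some pair member hits it at
#' E <= cutoff and its own best hit lands inside the pair. The
#' different-chromosome criterion propagates: co-orthologs on a single
#' chromosome count as one copy (tandem-consistent, not WGD-consistent).
#' Above-cutoff hits without reciprocal support mark the species
#' ambiguous, which demotes the family to unresolved downstream.
#'
#' @param pair character vector of the two seed gene ids.
#' @param to_table seed -> target [hit_table()].
#' @param from_table target -> seed [hit_table()].
#' @param target_genes [gene_table()] of the target species (chromosome
#'   lookup).
#' @param cutoff E-value cutoff.
#' @return list with `count` (0, 1 or 2 meaning "2+"), `genes`,
#'   `chromosomes` and `ambiguous`.
#' @export
copy_number <- function(pair, to_table, from_table, target_genes,
                        cutoff = 1e-80) {
  cand <- unique(to_table$subject_id[to_table$query_id %in% pair &
                                       to_table$evalue <= cutoff])
  if (!length(cand))
    return(list(count = 0L, genes = character(), chromosomes = character(),
                ambiguous = FALSE))
  best <- best_hit_map(from_table[from_table$evalue <= cutoff, ,
                                  drop = FALSE])
  rec <- cand[!is.na(best[cand]) & best[cand] %in% pair]
  ambiguous <- length(setdiff(cand, rec)) > 0L
  chr <- target_genes$chromosome[match(rec, target_genes$gene_id)]
  n_chr <- length(unique(chr))
  count <- if (!length(rec)) 0L else if (n_chr >= 2L) 2L else 1L
  if (length(rec) > 1L && n_chr == 1L)
    log_msg("debug", "co-orthologs of (", pair[1], ",", pair[2],
            ") share one chromosome; scored as single copy")
  list(count = count, genes = sort(rec), chromosomes = unique(chr),
       ambiguous = ambiguous)
}

#' Two-lineage LSP classification of one family
#'
#' `A_LSP` iff every lineage-A species carries two copies (on different
#' chromosomes) and every lineage-B species exactly one; `B_LSP`
#' symmetrically; `shared_duplicate` iff every panel species carries
#' two. Any zero copy number (outside `allow_missing_species`), any
#' ambiguous species, or any mixed pattern yields `unresolved` -
#' systematic retention must not be inflated by ambiguity.
#'
#' @param family list with element `copy_number`: named list per ingroup
#'   species as returned by [copy_number()].
#' @param config a [panel_config()].
#' @return list with `call` and `reason`.
#' @export
classify_lsp <- function(family, config) {
  cn <- family$copy_number
  need <- c(config$lineage_a, config$lineage_b)
  missing <- setdiff(need, names(cn))
  if (length(missing))
    stop("copy_number missing for species: ", paste(missing, collapse = ", "))
  counts <- vapply(cn[need], function(x) as.integer(x$count), integer(1))
  amb <- vapply(cn[need], `[[`, logical(1), "ambiguous")
  if (any(amb))
    return(list(call = "unresolved", reason = "ambiguous_copy_number"))
  skip <- counts == 0L & names(counts) %in% config$allow_missing_species
  if (any(counts == 0L & !skip))
    return(list(call = "unresolved", reason = "missing_species"))
  a <- counts[setdiff(config$lineage_a, names(counts)[skip])]
  b <- counts[setdiff(config$lineage_b, names(counts)[skip])]
  if (all(a == 2L) && all(b == 2L))
    list(call = "shared_duplicate", reason = NA_character_)
  else if (all(a == 2L) && all(b == 1L))
    list(call = "A_LSP", reason = NA_character_)
  else if (all(b == 2L) && all(a == 1L))
    list(call = "B_LSP", reason = NA_character_)
  else list(call = "unresolved", reason = "mixed_pattern")
}

#' Panel summary with the headline percentages
#'
#' Percentages are `100 * count / total`, rounded half-up to one
#' decimal (so 4122 of 19600 genes is 21.0%).
#'
#' @param x either a `result_bundle` (see [run_pipeline()]) or a numeric
#'   count of paralog genes.
#' @param totals named numeric `c(a = ..., b = ...)` of total genes
#'   analyzed per direction, or a single total when `x` is a count.
#' @return for a count: list with `count`, `total`, `percent`. For a
#'   bundle: `panel_summary` list with per-direction gene counts, family
#'   counts and percentages.
#' @export
summarize_panel <- function(x, totals) {
  if (any(unlist(totals) <= 0)) stop("total genes analyzed must be positive")
  if (is.numeric(x))
    return(list(count = x, total = totals,
                percent = round_half_up(100 * x / totals, 1)))
  stopifnot(inherits(x, "result_bundle"))
  fam <- x$families
  per_dir <- lapply(c(a = "a", b = "b"), function(d) {
    f <- fam[fam$direction == d, , drop = FALSE]
    called <- f[f$call %in% c("A_LSP", "B_LSP", "shared_duplicate"), ,
                drop = FALSE]
    lsp <- f[f$call == paste0(toupper(d), "_LSP"), , drop = FALSE]
    total <- unname(totals[[d]])
    list(total_genes = total,
         tsgd_families = nrow(called),
         tsgd_paralog_genes = 2L * nrow(called),
         lsp_families = nrow(lsp),
         lsp_genes = 2L * nrow(lsp),
         pct_tsgd = round_half_up(100 * 2 * nrow(called) / total, 1),
         pct_lsp = round_half_up(100 * 2 * nrow(lsp) / total, 1))
  })
  structure(per_dir, class = "panel_summary")
}
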