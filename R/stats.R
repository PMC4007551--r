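#' Per-chromosome retention counts and pseudoreplicate ratios
#'
#' Counts TSGD paralog genes and LSP genes on each chromosome of one
#' seed genome (each gene of a family is counted on its own
#' chromosome), then treats the per-chromosome LSP/TSGD ratio as a
#' pseudoreplicate: the panel-level mean and standard error
#' (sd / sqrt(n)) are taken over chromosomes with at least one TSGD
#' paralog (empty chromosomes are excluded and logged).
#'
#' @param tsgd_genes character vector of TSGD paralog gene ids in this
#'   genome (both members of every called family).
#' @param lsp_genes subset of `tsgd_genes` belonging to LSP-called
#'   families.
#' @param genome [gene_table()] of the seed species.
#' @return list with `per_chromosome` (data.frame chromosome,
#'   tsgd_count, lsp_count, ratio), `mean_ratio`, `se_ratio`,
#'   `n_chromosomes`.
#' @export
chromosome_table <- function(tsgd_genes, lsp_genes, genome) {
  if (length(setdiff(lsp_genes, tsgd_genes)))
    stop("lsp_genes must be a subset of tsgd_genes")
  chr_of <- setNames(genome$chromosome, genome$gene_id)
  miss <- setdiff(tsgd_genes, names(chr_of))
  if (length(miss))
    stop("gene(s) absent from genome: ", paste(miss, collapse = ", "))
  chrs <- sort(unique(genome$chromosome))
  tsgd_count <- vapply(chrs, function(c)
    sum(chr_of[tsgd_genes] == c), integer(1))
  lsp_count <- vapply(chrs, function(c)
    sum(chr_of[lsp_genes] == c), integer(1))
  per <- data.frame(chromosome = chrs, tsgd_count = tsgd_count,
                    lsp_count = lsp_count,
                    ratio = ifelse(tsgd_count > 0, lsp_count / tsgd_count,
                                   NA_real_),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  use <- per$ratio[!is.na(per$ratio)]
  if (any(is.na(per$ratio)))
    log_msg("info", sum(is.na(per$ratio)),
            " chromosome(s) without TSGD paralogs excluded from ratio mean")
  list(per_chromosome = per,
       mean_ratio = if (length(use)) mean(use) else 0,
       se_ratio = if (length(use) > 1) sd(use) / sqrt(length(use)) else 0,
       n_chromosomes = length(use))
}

#' Spearman rank correlation with a permutation test
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks). The two-sided permutation p-value is
#' `(1 + #{|rho*| >= |rho|}) / (1 + n_permutations)` over random
#' permutations of `y`, so it can never be exactly zero - a reported
#' "P = 0" is really p below 1/(1 + n_permutations).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param n_permutations number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `rho` and `p_perm`.
#' @export
spearman_perm <- function(x, y, n_permutations = 10000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      r <- cor(rx, sample(ry))
      if (abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
    }
    list(rho = rho, p_perm = (1 + exceed) / (1 + n_permutations))
  })
}

#' Upper-tail hypergeometric term enrichment
#'
#' For each term, the p-value is the probability of drawing at least the
#' observed number of annotated study genes when sampling the study set
#' uniformly from the universe (classical one-sided Fisher/hypergeometric
#' enrichment). Benjamini-Hochberg q-values are attached. Terms with
#' `study_count <= min_genes` are excluded from the report view
#' (`in_report = FALSE`) but kept in the full table, mirroring the
#' "more than ten genes" reporting rule.
#'
#' @param study_genes character vector (must be a subset of the
#'   universe).
#' @param annotation data.frame with `gene_id`, `term_id` and optional
#'   `term_name`.
#' @param universe gene universe; default all genes in `annotation`.
#' @param min_genes report threshold (default 10; strictly-greater rule).
#' @return data.frame (term_id, term_name, study_count,
#'   background_count, p_value, q_value, in_report, gene_ids).
#' @export
hypergeometric_enrichment <- function(study_genes, annotation,
                                      universe = NULL, min_genes = 10L) {
  study_genes <- unique(study_genes)
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  missing <- setdiff(study_genes, universe)
  if (length(missing))
    stop("study gene(s) absent from universe: ",
         paste(missing, collapse = ", "))
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[c("term_id", "gene_id",
                      intersect("term_name", names(annotation)))])
  N <- length(universe)
  n <- length(study_genes)
  terms <- split(ann, ann$term_id)
  rows <- lapply(terms, function(t) {
    genes_k <- unique(t$gene_id)
    hits <- intersect(genes_k, study_genes)
    K <- length(genes_k); k <- length(hits)
    data.frame(
      term_id = t$term_id[1],
      term_name = if ("term_name" %in% names(t)) t$term_name[1]
        else NA_character_,
      study_count = k, background_count = K,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      gene_ids = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out$q_value <- bh_adjust(out$p_value)
  out$in_report <- out$study_count > min_genes
  rownames(out) <- NULL
  out[c("term_id", "term_name", "study_count", "background_count",
        "p_value", "q_value", "in_report", "gene_ids")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector in (0, 1].
#' @return q-values (same order as input), each >= its p-value.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Collapse fine GO terms onto their slim ancestors
#'
#' `slim_table` gives term -> slim edges (many-to-one or many-to-many,
#' possibly multi-level); each gene's fine terms are replaced by the
#' union of every slim term reachable through the edges. Genes whose
#' terms reach no slim term are retained under the `"unmapped"` bucket.
#' Cycles in the slim mapping are an error.
#'
#' @param term_assignments data.frame `gene_id`, `term_id`.
#' @param slim_table data.frame `term_id`, `slim_id`.
#' @return data.frame `gene_id`, `term_id` at slim level (deduplicated).
#' @export
map_to_slim <- function(term_assignments, slim_table) {
  from <- as.character(slim_table$term_id)
  to <- as.character(slim_table$slim_id)
  edges <- split(to, from)
  # cycle check: iteratively peel nodes with no outgoing edges
  remaining <- unique(c(from, to))
  ef <- from; et <- to
  repeat {
    sinks <- setdiff(remaining, unique(ef))
    if (!length(sinks)) break
    remaining <- setdiff(remaining, sinks)
    keep <- !(et %in% sinks)
    ef <- ef[keep]; et <- et[keep]
  }
  if (length(remaining)) stop("cyclic slim mapping detected")
  reach_one <- function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(edges[frontier], use.names = FALSE)),
                     seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  all_terms <- unique(as.character(term_assignments$term_id))
  reach <- setNames(lapply(all_terms, reach_one), all_terms)
  rows <- lapply(seq_len(nrow(term_assignments)), function(i) {
    slims <- reach[[as.character(term_assignments$term_id[i])]]
    if (!length(slims)) slims <- "unmapped"
    data.frame(gene_id = term_assignments$gene_id[i], term_id = slims,
               stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, rows))
}
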