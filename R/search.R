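#' Search configuration for the internal aligner
#'
#' @param evalue_max report threshold: every (query, subject) pair with
#'   E-value at or below it appears in the table.
#' @param gap_open,gap_extend affine gap penalties.
#' @param kmer_size,kmer_min_shared seeding prefilter: only pairs sharing
#'   at least `kmer_min_shared` exact `kmer_size`-mers are aligned by
#'   full dynamic programming. At the divergences this package targets
#'   (and at any E-value near the reporting threshold) true homologs
#'   share far more seeds than this; reported pairs always carry exact
#'   full-DP scores.
#' @param substitution_matrix scoring matrix; default [blosum62()].
#' @return list of search settings.
#' @export
search_config <- function(evalue_max = 1e-10, gap_open = 11, gap_extend = 1,
                          kmer_size = 5L, kmer_min_shared = 2L,
                          substitution_matrix = NULL) {
  list(evalue_max = evalue_max, gap_open = gap_open, gap_extend = gap_extend,
       kmer_size = as.integer(kmer_size),
       kmer_min_shared = as.integer(kmer_min_shared),
       substitution_matrix = substitution_matrix)
}

# k-mer seed prefilter: candidate (query, subject) index pairs sharing
# >= min_shared exact k-mers, via a sparse kmer-incidence cross-product
seed_candidates <- function(pep_q, pep_s, k, min_shared) {
  kmers <- function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  }
  kq <- lapply(pep_q, kmers)
  ks <- lapply(pep_s, kmers)
  common <- intersect(unique(unlist(kq, use.names = FALSE)),
                      unique(unlist(ks, use.names = FALSE)))
  if (!length(common)) return(list(qi = integer(), si = integer()))
  incidence <- function(kl, n_seq) {
    j <- rep(seq_along(kl), lengths(kl))
    i <- match(unlist(kl, use.names = FALSE), common)
    keep <- !is.na(i)
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                         dims = c(length(common), n_seq))
  }
  shared <- Matrix::crossprod(incidence(kq, length(pep_q)),
                              incidence(ks, length(pep_s)))
  tri <- Matrix::summary(shared)
  keep <- tri$x >= min_shared
  ord <- order(tri$i[keep], tri$j[keep])
  list(qi = tri$i[keep][ord], si = tri$j[keep][ord])
}

#' All-vs-all similarity search between two proteomes
#'
#' Smith-Waterman local alignment (affine gaps, BLOSUM62 by default) of
#' every seeded query/subject pair, with Karlin-Altschul E-values over
#' the search space m x n (total query x subject residues). One row per
#' pair; deterministic.
#'
#' @param genes_from,genes_to [gene_table()]s (queries and subjects).
#' @param config a [search_config()].
#' @return a [hit_table()] of pairs with E-value <= `config$evalue_max`.
#' @export
all_vs_all <- function(genes_from, genes_to, config = search_config()) {
  if (!nrow(genes_from) || !nrow(genes_to))
    stop("both proteomes must be nonempty")
  mat <- config$substitution_matrix %||% blosum62()
  m <- sum(nchar(genes_from$peptide))
  n <- sum(nchar(genes_to$peptide))
  cand <- seed_candidates(genes_from$peptide, genes_to$peptide,
                          config$kmer_size, config$kmer_min_shared)
  sf <- unique(genes_from$species)[1]
  st <- unique(genes_to$species)[1]
  if (!length(cand$qi))
    return(hit_table(empty_hits(), sf, st, m, n))
  aln <- .sw_batch_cpp(genes_from$peptide, genes_to$peptide,
                       cand$qi, cand$si, mat,
                       paste(rownames(mat), collapse = ""),
                       config$gap_open, config$gap_extend)
  bits <- bitscore(aln$score)
  ev <- estimate_evalue(bits, m, n)
  keep <- ev <= config$evalue_max & aln$length > 0
  aln <- aln[keep, , drop = FALSE]
  qlen <- nchar(genes_from$peptide)[cand$qi[keep]]
  slen <- nchar(genes_to$peptide)[cand$si[keep]]
  df <- data.frame(
    query_id = genes_from$gene_id[cand$qi[keep]],
    subject_id = genes_to$gene_id[cand$si[keep]],
    pident = 100 * aln$matches / aln$length,
    length = aln$length, mismatch = aln$mismatches, gapopen = aln$gapopens,
    qstart = aln$qstart, qend = aln$qend,
    sstart = aln$sstart, send = aln$send,
    evalue = ev[keep], bitscore = bits[keep],
    raw_score = aln$score,
    query_coverage = (aln$qend - aln$qstart + 1) / qlen,
    subject_coverage = (aln$send - aln$sstart + 1) / slen,
    stringsAsFactors = FALSE)
  df <- df[order(df$query_id, df$evalue, df$subject_id), , drop = FALSE]
  hit_table(df, sf, st, m, n)
}

# unique best subject per query by bitscore; ties yield no best hit
best_hit_map <- function(hits) {
  if (!nrow(hits)) return(character())
  sp <- split(seq_len(nrow(hits)), hits$query_id)
  out <- vapply(sp, function(i) {
    b <- hits$bitscore[i]
    top <- i[b == max(b)]
    if (length(top) == 1L) hits$subject_id[top] else NA_character_
  }, character(1))
  out[!is.na(out)]
}

#' Reciprocal best hits between two proteomes
#'
#' (a, b) is reported iff b is a's unique best subject (by bitscore) and
#' a is b's unique best subject in the opposite direction; bitscore ties
#' disqualify a gene (the "single best hit" must be unique). The output
#' is a partial matching: no gene appears twice.
#'
#' @param table_ab,table_ba [hit_table()]s in opposite directions over
#'   the same two proteomes.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(table_ab, table_ba) {
  fa <- attr(table_ab, "species_from"); ta <- attr(table_ab, "species_to")
  fb <- attr(table_ba, "species_from"); tb <- attr(table_ba, "species_to")
  if (!is.na(fa) && !is.na(fb) && (!identical(fa, tb) || !identical(ta, fb)))
    stop("hit tables are not opposite directions over the same proteomes")
  ab <- best_hit_map(table_ab)
  ba <- best_hit_map(table_ba)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  if (!length(ab) || !length(ba)) return(empty)
  ok <- !is.na(ba[ab]) & names(ab) == unname(ba[ab])
  a <- names(ab)[ok]
  if (!length(a)) return(empty)
  df <- data.frame(gene_a = a, gene_b = unname(ab[a]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$gene_a), , drop = FALSE]
}

# number of queries with >= 1 subject at E <= cutoff ("positive hits")
count_positive_hits <- function(hits, cutoff) {
  length(unique(hits$query_id[hits$evalue <= cutoff]))
}
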