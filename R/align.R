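#' Smith-Waterman local alignment of two peptides
#'
#' Maximum-scoring local alignment under a substitution matrix and affine
#' gap penalties (a gap of length L costs `gap_open + gap_extend * L`,
#' the BLAST "existence 11, extension 1" convention).
#'
#' @param seq_a,seq_b nonempty peptide strings over the 20-letter
#'   amino-acid alphabet plus `X` (`X` scores 0 against everything).
#' @param substitution_matrix numeric matrix with residue dimnames;
#'   default [blosum62()].
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with `raw_score`, 1-based aligned spans
#'   (`qstart`,`qend`,`sstart`,`send`), `length` (alignment columns),
#'   `matches`, `mismatches`, `gapopens`, `identity` (matches / columns),
#'   `query_coverage` and `subject_coverage` (aligned span / sequence
#'   length).
#' @export
align_pair <- function(seq_a, seq_b, substitution_matrix = NULL,
                       gap_open = 11, gap_extend = 1) {
  check_peptide(seq_a, "seq_a")
  check_peptide(seq_b, "seq_b")
  m <- if (is.null(substitution_matrix)) blosum62() else substitution_matrix
  r <- .sw_align_cpp(seq_a, seq_b, m, paste(rownames(m), collapse = ""),
                     gap_open, gap_extend)
  list(
    raw_score = r$score,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    length = r$length, matches = r$matches, mismatches = r$mismatches,
    gapopens = r$gapopens,
    identity = if (r$length > 0) r$matches / r$length else 0,
    query_coverage = if (r$length > 0)
      (r$qend - r$qstart + 1) / nchar(seq_a) else 0,
    subject_coverage = if (r$length > 0)
      (r$send - r$sstart + 1) / nchar(seq_b) else 0
  )
}

#' Needleman-Wunsch global alignment (end gaps penalized)
#'
#' Used for isoform screening and for distance estimation; returns the
#' gap-free column counts needed by [protein_distance()].
#'
#' @inheritParams align_pair
#' @return list with `raw_score`, `length`, `cols_nogap` (columns where
#'   both sequences have a residue), `matches_nogap`, `gapopens`.
#' @export
align_global <- function(seq_a, seq_b, substitution_matrix = NULL,
                         gap_open = 11, gap_extend = 1) {
  check_peptide(seq_a, "seq_a")
  check_peptide(seq_b, "seq_b")
  m <- if (is.null(substitution_matrix)) blosum62() else substitution_matrix
  r <- .nw_align_cpp(seq_a, seq_b, m, paste(rownames(m), collapse = ""),
                     gap_open, gap_extend)
  list(raw_score = r$score, length = r$length, cols_nogap = r$cols_nogap,
       matches_nogap = r$matches_nogap, gapopens = r$gapopens)
}

# Karlin-Altschul parameters for BLOSUM62 with affine gaps (11, 1),
# the values BLAST reports for gapped protein searches.
ka_params <- function() list(lambda = 0.267, K = 0.041)

#' Convert a raw alignment score to a bitscore
#'
#' `bits = (lambda * S - ln K) / ln 2` with the gapped BLOSUM62
#' Karlin-Altschul constants (lambda = 0.267, K = 0.041).
#'
#' @param raw_score numeric raw alignment score(s).
#' @return numeric bitscore(s).
#' @export
bitscore <- function(raw_score) {
  p <- ka_params()
  (p$lambda * raw_score - log(p$K)) / log(2)
}

#' Karlin-Altschul E-value from a bitscore and search-space size
#'
#' `E = m * n * 2^(-bits)`: linear in the search space, halved per
#' additional bit. This makes an E-value threshold such as 1e-80
#' applicable to internally computed searches.
#'
#' @param bits bitscore(s).
#' @param m total query residues in the search (>= 1).
#' @param n total subject residues in the search (>= 1).
#' @return E-value(s) >= 0.
#' @export
estimate_evalue <- function(bits, m, n) {
  if (any(m < 1) || any(n < 1)) stop("search space m, n must be >= 1")
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}
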