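#' Read a substitution score matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix layout (`#` comment
#' lines, a header row of residue letters, one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @return numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(header))))
  if (anyNA(vals)) stop("unparseable score matrix entry in ", path)
  dimnames(vals) <- list(rows, header)
  vals
}

#' BLOSUM62 matrix as shipped with the package
#'
#' The matrix is stored as a plain-text data file under `extdata`, not
#' hard-coded. Per package convention, `X` (unknown residue) scores 0
#' against every residue.
#'
#' @return numeric substitution matrix.
#' @export
blosum62 <- function() {
  if (is.null(.lspanel_env$blosum62)) {
    m <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "lspanel"))
    m["X", ] <- 0
    m[, "X"] <- 0
    .lspanel_env$blosum62 <- m
  }
  .lspanel_env$blosum62
}

# amino-acid alphabet accepted in peptides
aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

check_peptide <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a nonempty string")
  bad <- setdiff(strsplit(seq, "")[[1]], aa_alphabet())
  if (length(bad))
    stop(what, " contains residues outside the amino-acid alphabet: ",
         paste(unique(bad), collapse = ", "))
  invisible(seq)
}
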