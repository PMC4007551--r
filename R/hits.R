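#' Hit tables: directed pairwise similarity hits
#'
#' A `hit_table` is a data.frame in the standard 12-column tabular layout
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore) plus, when
#' computed internally, `raw_score`, `query_coverage` and
#' `subject_coverage`. Attributes `species_from`, `species_to` record the
#' direction and `m`, `n` the search space (total query/subject residues).
#' At most one row is stored per (query, subject) pair.
#'
#' @param df data.frame of hits.
#' @param species_from,species_to direction labels.
#' @param m,n search-space sizes in residues.
#' @return a `hit_table`.
#' @export
hit_table <- function(df, species_from = NA_character_,
                      species_to = NA_character_, m = NA_real_, n = NA_real_) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  df <- as.data.frame(df)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("hit table missing column(s): ", paste(missing, collapse = ", "))
  for (extra in c("raw_score", "query_coverage", "subject_coverage"))
    if (!extra %in% names(df)) df[[extra]] <- rep(NA_real_, nrow(df))
  df <- df[c(cols, "raw_score", "query_coverage", "subject_coverage")]
  if (anyDuplicated(df[c("query_id", "subject_id")]))
    stop("hit table has more than one row for a (query, subject) pair")
  if (any(df$evalue < 0)) stop("negative E-value in hit table")
  rownames(df) <- NULL
  structure(df, species_from = species_from, species_to = species_to,
            m = m, n = n, class = c("hit_table", "data.frame"))
}

#' Read/write hit tables in the 12-column tabular dialect
#'
#' `read_hit_table()` accepts externally computed searches (e.g. BLASTp
#' `-outfmt 6`); E-values in scientific notation are parsed as reals and
#' query/subject ids are preserved verbatim. `write_hit_table()` emits
#' the same dialect (no header), so write-then-read is the identity on
#' the 12 standard columns.
#'
#' @param path file path.
#' @param species_from,species_to optional direction labels.
#' @param m,n optional search-space sizes.
#' @return a [hit_table()].
#' @export
read_hit_table <- function(path, species_from = NA_character_,
                           species_to = NA_character_,
                           m = NA_real_, n = NA_real_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(hit_table(empty_hits(), species_from, species_to, m, n))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L))
    stop("line ", which(nc != 12L)[1], ": expected 12 tab-separated columns, found ",
         nc[nc != 12L][1])
  mat <- do.call(rbind, parts)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1], ": unparseable ", what, " '",
           mat[is.na(v), j][1], "'")
    v
  }
  df <- data.frame(
    query_id = mat[, 1], subject_id = mat[, 2],
    pident = num(3, "identity"), length = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")),
    gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "E-value"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  hit_table(df, species_from, species_to, m, n)
}

#' @rdname read_hit_table
#' @param hits a `hit_table` to write.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  df <- as.data.frame(hits)[cols]
  for (j in c("pident", "evalue", "bitscore"))
    df[[j]] <- vapply(df[[j]], format, character(1), digits = 15,
                      scientific = j == "evalue", trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(hits)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

# flip a hit table's direction (queries become subjects); scores are
# symmetric under Smith-Waterman so only spans/coverages swap
transpose_hit_table <- function(hits) {
  df <- as.data.frame(hits)
  out <- df
  out$query_id <- df$subject_id
  out$subject_id <- df$query_id
  out$qstart <- df$sstart
  out$qend <- df$send
  out$sstart <- df$qstart
  out$send <- df$qend
  out$query_coverage <- df$subject_coverage
  out$subject_coverage <- df$query_coverage
  hit_table(out, species_from = attr(hits, "species_to"),
            species_to = attr(hits, "species_from"),
            m = attr(hits, "n"), n = attr(hits, "m"))
}
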