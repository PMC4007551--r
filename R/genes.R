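#' Gene table: the panel's unit of analysis
#'
#' A `gene_table` is a data.frame with one row per protein-coding gene:
#' `gene_id` (unique), `species`, `chromosome`, `start`, `end` (1-based,
#' inclusive), `strand` (`+`/`-`) and `peptide` (amino-acid string over
#' the 20-letter alphabet plus `X`).
#'
#' @param df data.frame with the columns above.
#' @return validated `gene_table`.
#' @export
gene_table <- function(df) {
  cols <- c("gene_id", "species", "chromosome", "start", "end", "strand",
            "peptide")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("gene table missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[cols]
  df$gene_id <- as.character(df$gene_id)
  df$species <- as.character(df$species)
  df$chromosome <- as.character(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$peptide <- as.character(df$peptide)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  if (any(df$start < 1L)) stop("start coordinates must be >= 1")
  if (any(df$end < df$start)) stop("end must be >= start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  empty <- df$gene_id[!nzchar(df$peptide) | is.na(df$peptide)]
  if (length(empty))
    stop("empty peptide for gene(s): ", paste(empty, collapse = ", "))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", df$peptide)
  if (!all(ok))
    stop("peptide with residues outside the alphabet for gene(s): ",
         paste(df$gene_id[!ok], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read one species' proteome (FASTA + gene-map TSV)
#'
#' The gene map is a TSV with header
#' `gene_id species chromosome start end strand` (1-based inclusive
#' coordinates). Every FASTA record must be paired with exactly one map
#' row and vice versa; the result is sorted by (chromosome, start).
#'
#' @param fasta_path FASTA file of peptide sequences (record ids are the
#'   first whitespace-delimited token of each header).
#' @param genemap_path gene-map TSV; may contain several species.
#' @param species species label to extract.
#' @return a [gene_table()].
#' @export
read_proteome <- function(fasta_path, genemap_path, species) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  map <- read_gene_map(genemap_path)
  map <- map[map$species == species, , drop = FALSE]
  if (!nrow(map)) stop("no gene-map rows for species '", species, "'")
  if (anyDuplicated(map$gene_id))
    stop("duplicate gene_id in gene map: ",
         paste(unique(map$gene_id[duplicated(map$gene_id)]), collapse = ", "))
  no_map <- setdiff(ids, map$gene_id)
  if (length(no_map))
    stop("FASTA record(s) absent from gene map: ",
         paste(no_map, collapse = ", "))
  no_seq <- setdiff(map$gene_id, ids)
  if (length(no_seq))
    stop("gene-map row(s) without FASTA record: ",
         paste(no_seq, collapse = ", "))
  pep <- as.character(seqs)
  names(pep) <- ids
  map$peptide <- toupper(unname(pep[map$gene_id]))
  g <- gene_table(map)
  g[order(g$chromosome, g$start, g$gene_id), , drop = FALSE] |> gene_table()
}

#' @rdname read_proteome
#' @param genes a `gene_table` to write.
#' @export
write_proteome <- function(genes, fasta_path, genemap_path) {
  genes <- gene_table(genes)
  seqs <- Biostrings::AAStringSet(setNames(genes$peptide, genes$gene_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70)
  write_gene_map(genes, genemap_path)
  invisible(genes)
}

#' @rdname read_proteome
#' @export
read_gene_map <- function(genemap_path) {
  map <- read.delim(genemap_path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "species", "chromosome", "start", "end", "strand")
  missing <- setdiff(need, names(map))
  if (length(missing))
    stop("gene map missing column(s): ", paste(missing, collapse = ", "))
  map$start <- as.integer(map$start)
  map$end <- as.integer(map$end)
  map[need]
}

write_gene_map <- function(genes, genemap_path) {
  cols <- c("gene_id", "species", "chromosome", "start", "end", "strand")
  write.table(as.data.frame(genes)[cols], genemap_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(genes)
}

# drop genes on unplaced scaffolds (chromosome-level analysis only)
filter_unplaced <- function(genes, pattern) {
  keep <- !grepl(pattern, genes$chromosome)
  if (any(!keep))
    log_msg("info", sum(!keep), " gene(s) on unplaced scaffolds dropped")
  gene_table(genes[keep, , drop = FALSE])
}
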