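# shared fixtures: everything is generated in code at test time

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_pep <- function(n, seed = NULL) {
  draw <- function() paste(sample(AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else lspanel:::with_seed(seed, draw())
}

# minimal gene_table builder with sensible defaults
mk_genes <- function(gene_id, species = "sp", chromosome = "1",
                     start = seq(1, by = 2000, length.out = length(gene_id)),
                     peptide = NULL, strand = "+") {
  if (is.null(peptide))
    peptide <- vapply(seq_along(gene_id), function(i) rand_pep(60, i),
                      character(1))
  gene_table(data.frame(gene_id = gene_id, species = species,
                        chromosome = chromosome, start = start,
                        end = start + 180, strand = strand,
                        peptide = peptide, stringsAsFactors = FALSE))
}

# hand-built hit table rows with filler alignment columns
mk_hits <- function(query_id, subject_id, evalue, bitscore,
                    species_from = NA_character_,
                    species_to = NA_character_) {
  n <- length(query_id)
  hit_table(data.frame(
    query_id = query_id, subject_id = subject_id,
    pident = rep(95, n), length = rep(100L, n), mismatch = rep(5L, n),
    gapopen = rep(0L, n), qstart = rep(1L, n), qend = rep(100L, n),
    sstart = rep(1L, n), send = rep(100L, n),
    evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE),
    species_from = species_from, species_to = species_to)
}

# small noiseless panel most pipeline tests share (cached per session)
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_config(n_families = 30, per_species_loss_prob = 0,
                       seed = 42)
      cache <<- list(config = sc, panel = simulate_panel(sc))
    }
    cache
  }
})

quiet <- function(expr)
  withCallingHandlers(expr, message = function(m) invokeRestart("muffleMessage"))
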