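#' Poisson-corrected protein distance
#'
#' Globally aligns the two peptides and computes
#' `d = -ln(1 - p)` where `p` is the proportion of differing residues
#' among gap-free aligned columns. The correction's domain boundary
#' (p -> 1) is handled by capping at `cap` (default 7, i.e. p above
#' ~0.9991 is truncated).
#'
#' @param seq_a,seq_b peptide strings.
#' @param cap maximum reported distance.
#' @return distance >= 0.
#' @export
protein_distance <- function(seq_a, seq_b, cap = 7) {
  aln <- align_global(seq_a, seq_b)
  if (aln$cols_nogap == 0L) stop("no aligned residue columns")
  p <- 1 - aln$matches_nogap / aln$cols_nogap
  if (p >= 1 - exp(-cap)) return(cap)
  -log(1 - p)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (backed by \pkg{ape}); exact on additive
#' matrices. Three taxa are solved directly by the three-point
#' equations.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal,
#'   >= 3 labelled taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("distance matrix must be square with >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(d) == 3L) {
    # three-point equations: x_i = (d_ij + d_ik - d_jk) / 2
    x <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tr <- list(edge = cbind(rep(4L, 3L), 1:3), edge.length = pmax(x, 0),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  ape::nj(as.dist(d))
}

# rooted clade test tolerant of soft polytomies: S can form a clade in
# some resolution iff every child subtree of MRCA(S) is fully inside or
# fully outside S
can_be_clade <- function(tree, leaves) {
  tips <- match(leaves, tree$tip.label)
  if (anyNA(tips)) stop("leaf label(s) absent from tree")
  if (length(tips) <= 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  kids <- tree$edge[tree$edge[, 1] == mrca, 2]
  for (k in kids) {
    sub <- if (k <= length(tree$tip.label)) k
      else match(ape::extract.clade(tree, k)$tip.label, tree$tip.label)
    n_in <- sum(sub %in% tips)
    if (n_in != 0L && n_in != length(sub)) return(FALSE)
  }
  TRUE
}

#' Duplication-precedes-speciation topology test
#'
#' Roots the family tree on an outgroup gene and asks whether the copy-1
#' genes of all duplicate-bearing species form one clade and the copy-2
#' genes another - the signature of a duplication that predates the
#' speciations within the lineage (as opposed to independent recent
#' duplications). Zero-length internal edges (below `tol`) are collapsed
#' into soft polytomies; the test passes if some resolution passes. Any
#' additional outgroup genes in the tree must fall outside both copy
#' clades.
#'
#' @param tree unrooted `phylo` with unique leaf labels.
#' @param copy1_leaves,copy2_leaves leaf labels of the two paralog
#'   clades.
#' @param outgroup_leaf leaf to root on.
#' @param tol branch lengths below this collapse to polytomies.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
duplication_topology_test <- function(tree, copy1_leaves, copy2_leaves,
                                      outgroup_leaf, tol = 1e-8) {
  if (!outgroup_leaf %in% tree$tip.label)
    stop("outgroup leaf '", outgroup_leaf, "' absent from tree")
  if (any(c(copy1_leaves, copy2_leaves) == outgroup_leaf))
    stop("outgroup leaf cannot belong to a copy clade")
  rooted <- ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
  if (!is.null(rooted$edge.length))
    rooted <- ape::di2multi(rooted, tol = tol)
  can_be_clade(rooted, copy1_leaves) && can_be_clade(rooted, copy2_leaves)
}

#' Build a family tree from peptide sequences
#'
#' Pairwise Poisson-corrected distances + neighbor joining; a desk-scale
#' stand-in for full Bayesian/ML phylogenetics, answering only the
#' topological question the verification needs.
#'
#' @param peptides named character vector (names become leaf labels).
#' @return unrooted `phylo`.
#' @export
family_tree <- function(peptides) {
  n <- length(peptides)
  if (n < 3L) stop("need >= 3 sequences for a tree")
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- protein_distance(peptides[[i]], peptides[[j]])
  neighbor_joining(d)
}

# up to window/2 flanking genes on each side of a gene, same chromosome
neighborhood <- function(gene_id, genes, half_window) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' absent from gene table")
  chr <- genes$chromosome[i]
  on_chr <- genes[genes$chromosome == chr &
                    genes$species == genes$species[i], , drop = FALSE]
  on_chr <- on_chr[order(on_chr$start, on_chr$gene_id), , drop = FALSE]
  pos <- match(gene_id, on_chr$gene_id)
  lo <- max(1L, pos - half_window)
  hi <- min(nrow(on_chr), pos + half_window)
  setdiff(on_chr$gene_id[lo:hi], gene_id)
}

#' Neighborhood-overlap synteny score
#'
#' For each paralog copy in `species_x`, compares the copy's +-window/2
#' gene neighborhood with the neighborhood of the family's single-copy
#' ortholog in `species_y`, through a reciprocal-best-hit ortholog map.
#' `shared_fraction` = shared orthologous neighbors / achievable maximum
#' (the smaller of the two truncation-aware neighborhood sizes, so genes
#' near chromosome ends are normalized by what is attainable).
#'
#' @param family_id family label carried into the output.
#' @param copies_x character vector of paralog gene ids in `species_x`.
#' @param gene_y the single-copy ortholog id in `species_y`.
#' @param genes combined [gene_table()] covering both species.
#' @param ortholog_map data.frame `gene_a`, `gene_b` (e.g. from
#'   [reciprocal_best_hits()]), direction x -> y or y -> x.
#' @param window total neighborhood size in genes (window/2 per side).
#' @param species_x,species_y species labels.
#' @return data.frame (one row per copy) with class `synteny_score`:
#'   family_id, species_x, species_y, copy gene, window,
#'   shared_fraction.
#' @export
synteny_score <- function(family_id, copies_x, gene_y, genes, ortholog_map,
                          window, species_x, species_y) {
  half <- max(1L, as.integer(window) %/% 2L)
  fwd <- setNames(ortholog_map$gene_b, ortholog_map$gene_a)
  rev <- setNames(ortholog_map$gene_a, ortholog_map$gene_b)
  ny <- neighborhood(gene_y, genes, half)
  rows <- lapply(copies_x, function(gx) {
    nx <- neighborhood(gx, genes, half)
    mapped <- c(fwd[nx], rev[nx])
    mapped <- mapped[!is.na(mapped)]
    denom <- min(length(nx), length(ny))
    shared <- min(length(intersect(unique(mapped), ny)), denom)
    data.frame(family_id = family_id, species_x = species_x,
               species_y = species_y, gene = gx,
               window = as.integer(window),
               shared_fraction = if (denom > 0) shared / denom else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("synteny_score", "data.frame")
  out
}
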