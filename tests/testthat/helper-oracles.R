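# independent test oracles shared across files

# best local alignment score as the maximum, over all start cells, of a
# forward affine DP without the zero-floor reset (O(n^2 m^2) overall;
# feasible for sequences of <= 8 residues)
oracle_local_score <- function(a, b, S, go, ge) {
  ea <- match(strsplit(a, "")[[1]], rownames(S))
  eb <- match(strsplit(b, "")[[1]], rownames(S))
  n <- length(ea); m <- length(eb)
  NEG <- -1e9
  best <- 0
  for (i1 in 1:n) for (j1 in 1:m) {
    H <- matrix(NEG, n + 1, m + 1)
    E <- matrix(NEG, n + 1, m + 1)
    Fm <- matrix(NEG, n + 1, m + 1)
    H[i1, j1] <- 0   # fixed alignment start just before (i1, j1)
    for (i in i1:n) for (j in j1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
      Fm[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), Fm[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(H[i, j] + S[ea[i], eb[j]],
                             E[i + 1, j + 1], Fm[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# cherry containing tip `t` in an unrooted 4-taxon binary tree
quartet_partner <- function(tree, t) {
  tip <- match(t, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  sibs <- sibs[sibs <= length(tree$tip.label) & sibs != tip]
  if (length(sibs)) tree$tip.label[sibs] else NA_character_
}

# all permutations of 1..n (recursive; n <= 7)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- combinat_perms(n - 1)
  out <- list()
  for (p in smaller) for (pos in 0:(n - 1))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  lapply(out, as.integer)
}
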