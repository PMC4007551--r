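test_that("chromosome_table: pseudoreplicate mean and SE by hand", {
  genome <- mk_genes(paste0("g", 1:60), species = "S",
                     chromosome = rep(c("1", "2", "3"), each = 20),
                     start = rep(seq(1, by = 2000, length.out = 20), 3))
  # ratios 0.1, 0.2, 0.3 over three chromosomes
  tsgd <- paste0("g", c(1:10, 21:30, 41:50))
  lsp <- paste0("g", c(1, 21, 22, 41, 42, 43))
  ct <- chromosome_table(tsgd, lsp, genome)
  expect_equal(ct$per_chromosome$ratio, c(0.1, 0.2, 0.3))
  expect_equal(ct$mean_ratio, 0.2)
  expect_equal(ct$se_ratio, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(ct$se_ratio, 0.0577, tolerance = 1e-3)
  # zero LSPs
  ct0 <- chromosome_table(tsgd, character(), genome)
  expect_equal(ct0$mean_ratio, 0)
  expect_equal(ct0$se_ratio, 0)
  # chromosomes without TSGD genes are excluded from the mean
  ct1 <- quiet(chromosome_table(paste0("g", 1:10), paste0("g", 1:2), genome))
  expect_equal(ct1$n_chromosomes, 1L)
  expect_equal(ct1$mean_ratio, 0.2)
  expect_error(chromosome_table(tsgd, "g60", genome), "subset")
})

test_that("spearman: monotone extremes and the classical formula on all
          permutations up to n = 6", {
  expect_equal(spearman_perm(1:3, c(2, 4, 6), 100, 1)$rho, 1.0)
  expect_equal(spearman_perm(1:3, c(3, 2, 1), 100, 1)$rho, -1.0)
  expect_equal(spearman_perm(c(10, 20, 5, 8), c(3, 9, 1, 4), 0, 1)$rho, 0.8)
  expect_error(spearman_perm(rep(1, 4), 1:4), "constant")
  expect_error(spearman_perm(1:2, 1:2), "3 observations")
  # tie-free inputs: rho = 1 - 6*sum(d^2) / (n(n^2-1)) exactly
  for (n in 3:6) {
    x <- seq_len(n)
    perms <- lspanel:::with_seed(5, replicate(40, sample(n), simplify = FALSE))
    if (n <= 4)  # exhaustive for small n
      perms <- asplit(as.matrix(expand.grid(rep(list(1:n), n))), 1) |>
        Filter(f = function(p) !anyDuplicated(p))
    for (y in perms) {
      d2 <- sum((x - rank(y))^2)
      expect_equal(spearman_perm(x, as.numeric(y), 0, 1)$rho,
                   1 - 6 * d2 / (n * (n^2 - 1)))
    }
  }
  # permutation p never reports exactly zero and is valid
  r <- spearman_perm(1:10, (1:10)^2, 999, 7)
  expect_gt(r$p_perm, 0)
  expect_lte(r$p_perm, 1)
  expect_equal(r$rho, 1.0)
})

test_that("hypergeometric p matches exhaustive enumeration (universe <= 12)", {
  set.seed(9)
  for (rep in 1:12) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    universe <- paste0("u", 1:N)
    term_genes <- sample(universe, K)
    study <- sample(universe, n)
    ann <- data.frame(gene_id = term_genes, term_id = "T1",
                      stringsAsFactors = FALSE)
    res <- hypergeometric_enrichment(study, ann, universe = universe,
                                     min_genes = 0)
    k_obs <- length(intersect(study, term_genes))
    draws <- utils::combn(N, n)
    in_term <- universe %in% term_genes
    tail_count <- sum(apply(draws, 2, function(d) sum(in_term[d]) >= k_obs))
    expect_equal(res$p_value, tail_count / ncol(draws), tolerance = 1e-12)
  }
  # closed-form example: universe 10, term 5, study 3 all annotated
  universe <- paste0("u", 1:10)
  ann <- data.frame(gene_id = universe[1:5], term_id = "T1")
  r <- hypergeometric_enrichment(universe[1:3], ann, universe = universe,
                                 min_genes = 0)
  expect_equal(r$p_value, choose(5, 3) / choose(10, 3))
  # term annotating the whole universe -> p = 1
  ann_all <- data.frame(gene_id = universe, term_id = "T1")
  expect_equal(hypergeometric_enrichment(universe[1:4], ann_all,
                                         universe = universe,
                                         min_genes = 0)$p_value, 1)
  # zero study hits -> p = 1
  ann5 <- data.frame(gene_id = universe[1:5], term_id = "T1")
  expect_equal(hypergeometric_enrichment(universe[6:8], ann5,
                                         universe = universe,
                                         min_genes = 0)$p_value, 1)
  expect_error(hypergeometric_enrichment("ghost", ann5,
                                         universe = universe), "ghost")
})

test_that("enrichment is invariant to gene-order permutations and applies
          the more-than-min_genes reporting rule", {
  set.seed(21)
  universe <- paste0("g", 1:100)
  ann <- data.frame(
    gene_id = c(sample(universe, 40), sample(universe, 25)),
    term_id = rep(c("big", "small"), c(40, 25)),
    stringsAsFactors = FALSE)
  study <- sample(universe, 30)
  r1 <- hypergeometric_enrichment(study, ann, universe = universe)
  r2 <- hypergeometric_enrichment(sample(study), ann[sample(nrow(ann)), ],
                                  universe = universe)
  expect_equal(r1, r2)
  expect_equal(r1$in_report, r1$study_count > 10)
  expect_true(all(r1$q_value >= r1$p_value))
})

test_that("bh_adjust: hand step-up values and order equivariance", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.002, 0.5, 0.04, 0.8, 0.013)
  q <- bh_adjust(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("map_to_slim: union semantics, unmapped bucket, closure oracle,
          cycle detection", {
  slim <- data.frame(term_id = c("f1", "f2", "m1"),
                     slim_id = c("m1", "m1", "top"),
                     stringsAsFactors = FALSE)
  ta <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                   term_id = c("f1", "f2", "m1", "orphan"),
                   stringsAsFactors = FALSE)
  r <- map_to_slim(ta, slim)
  # two fine terms sharing a parent count once; multi-level reachability
  expect_setequal(r$term_id[r$gene_id == "gA"], c("m1", "top"))
  expect_setequal(r$term_id[r$gene_id == "gB"], "top")
  expect_equal(r$term_id[r$gene_id == "gC"], "unmapped")
  # transitive-closure oracle on a random 3-level DAG
  set.seed(12)
  terms <- paste0("t", 1:12)
  edges <- data.frame(term_id = terms[1:8],
                      slim_id = terms[pmin(12, 5 + sample(7, 8, TRUE))],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$term_id != edges$slim_id, ]
  adj <- matrix(FALSE, 12, 12, dimnames = list(terms, terms))
  adj[cbind(edges$term_id, edges$slim_id)] <- TRUE
  closure <- adj
  for (i in 1:12) closure <- closure | (closure %*% adj > 0)
  ta2 <- data.frame(gene_id = "g", term_id = terms[1:8])
  r2 <- map_to_slim(ta2, edges)
  oracle <- unique(unlist(lapply(terms[1:8], function(t)
    colnames(closure)[closure[t, ]])))
  got <- setdiff(r2$term_id, "unmapped")
  expect_setequal(got, oracle)
  cyc <- data.frame(term_id = c("a", "b"), slim_id = c("b", "a"))
  expect_error(map_to_slim(ta, cyc), "cyclic")
})
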