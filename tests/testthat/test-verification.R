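test_that("protein_distance: closed form, zero at identity, monotone", {
  s <- rand_pep(200, seed = 5)
  expect_equal(protein_distance(s, s), 0)
  # p = 0.1 over 200 gap-free columns -> -ln(0.9)
  chars <- strsplit(s, "")[[1]]
  idx <- seq(1, 200, by = 10)   # 20 sites = 10%
  chars[idx] <- vapply(chars[idx], function(c) setdiff(AA20, c)[1],
                       character(1))
  expect_equal(protein_distance(s, paste(chars, collapse = "")),
               -log(0.9), tolerance = 1e-12)
  # monotone in the substituted fraction
  ds <- vapply(c(5, 20, 40, 80), function(k) {
    ch <- strsplit(s, "")[[1]]
    i <- seq_len(k)
    ch[i] <- vapply(ch[i], function(c) setdiff(AA20, c)[1], character(1))
    protein_distance(s, paste(ch, collapse = ""))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("neighbor_joining: three-point closed form and validation", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl), c(2, 3, 7))   # (d12+d13-d23)/2 etc.
  asym <- d; asym[1, 2] <- 6
  expect_error(neighbor_joining(asym), "symmetric")
  bad <- d; diag(bad) <- c(0, 0.5, 0)
  expect_error(neighbor_joining(bad), "diagonal")
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers quartets from additive matrices (least-squares
          oracle over all three topologies)", {
  set.seed(31)
  for (rep in 1:25) {
    # random additive quartet AB|CD with positive branches
    x <- runif(5, 0.2, 2)  # A, B, C, D terminals + internal
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- x[1] + x[2]
    d["C", "D"] <- d["D", "C"] <- x[3] + x[4]
    d["A", "C"] <- d["C", "A"] <- x[1] + x[5] + x[3]
    d["A", "D"] <- d["D", "A"] <- x[1] + x[5] + x[4]
    d["B", "C"] <- d["C", "B"] <- x[2] + x[5] + x[3]
    d["B", "D"] <- d["D", "B"] <- x[2] + x[5] + x[4]
    # oracle: the split minimizing the quartet sum is the exact
    # least-squares topology on an additive matrix
    sums <- c(AB = d["A", "B"] + d["C", "D"],
              AC = d["A", "C"] + d["B", "D"],
              AD = d["A", "D"] + d["B", "C"])
    expect_equal(names(which.min(sums)), "AB")
    tr <- neighbor_joining(d)
    expect_equal(quartet_partner(tr, "A"), "B")
    # taxon-order permutation leaves the recovered split unchanged
    perm <- sample(4)
    tr2 <- neighbor_joining(d[perm, perm])
    expect_equal(quartet_partner(tr2, "A"), "B")
  }
})

test_that("duplication topology test separates ohnolog from independent
          duplication shapes", {
  # textbook ohnolog shape: (OG,((A1,B1),(A2,B2)))
  ohno <- ape::read.tree(
    text = "(OG:3,((A1:1,B1:1):1.5,(A2:1,B2:1):1.5):1);")
  expect_true(duplication_topology_test(ohno, c("A1", "B1"), c("A2", "B2"),
                                        "OG"))
  # independent recent duplications: (OG,((A1,A2),(B1,B2)))
  indep <- ape::read.tree(
    text = "(OG:3,((A1:1,A2:1):1.5,(B1:1,B2:1):1.5):1);")
  expect_false(duplication_topology_test(indep, c("A1", "B1"), c("A2", "B2"),
                                         "OG"))
  expect_error(duplication_topology_test(ohno, c("A1", "B1"), c("A2", "B2"),
                                         "ZZ"), "absent")
  # zero-length internal edge: soft polytomy, passes if some resolution does
  poly <- ape::read.tree(
    text = "(OG:3,((A1:1,B1:1):0,(A2:1,B2:1):1.5):1);")
  expect_true(duplication_topology_test(poly, c("A1", "B1"), c("A2", "B2"),
                                        "OG"))
})

test_that("noiseless simulated LSP families pass the topology test", {
  sp <- small_panel()
  b <- quiet(run_pipeline(sp$config$species_panel, sp$panel))
  v <- verify_families(b)
  expect_gt(nrow(v), 0L)
  expect_true(all(v$topology_pass))
  expect_true(all(grepl("^\\(", v$newick)))  # valid newick emitted
  # the copy sharing the ortholog's chromosome shows conserved synteny
  expect_true(all(v$synteny_max_fraction > 0.5, na.rm = TRUE))
})

test_that("synteny score: identical, disjoint and half-shared
          neighborhoods", {
  # species X: copies x0 on chr1 with neighbors; species Y: y0 with
  # orthologous neighborhood
  gx <- mk_genes(c(paste0("xl", 2:1), "x0", paste0("xr", 1:2)),
                 species = "X")
  gy <- mk_genes(c(paste0("yl", 2:1), "y0", paste0("yr", 1:2)),
                 species = "Y")
  genes <- gene_table(rbind(as.data.frame(gx), as.data.frame(gy)))
  full_map <- data.frame(
    gene_a = c(paste0("xl", 2:1), paste0("xr", 1:2)),
    gene_b = c(paste0("yl", 2:1), paste0("yr", 1:2)),
    stringsAsFactors = FALSE)
  s <- synteny_score("fam", "x0", "y0", genes, full_map, window = 4,
                     species_x = "X", species_y = "Y")
  expect_equal(s$shared_fraction, 1.0)
  # orthologs map elsewhere -> disjoint
  none_map <- data.frame(gene_a = full_map$gene_a,
                         gene_b = paste0("z", 1:4),
                         stringsAsFactors = FALSE)
  s0 <- synteny_score("fam", "x0", "y0", genes, none_map, window = 4,
                      species_x = "X", species_y = "Y")
  expect_equal(s0$shared_fraction, 0.0)
  # exactly 2 of 4 flanking orthologs shared -> 0.5
  half_map <- full_map
  half_map$gene_b[3:4] <- c("q1", "q2")
  s5 <- synteny_score("fam", "x0", "y0", genes, half_map, window = 4,
                      species_x = "X", species_y = "Y")
  expect_equal(s5$shared_fraction, 0.5)
  # symmetry under a symmetric ortholog map
  s_rev <- synteny_score("fam", "y0", "x0", genes, full_map, window = 4,
                         species_x = "Y", species_y = "X")
  expect_equal(s_rev$shared_fraction, s$shared_fraction)
})
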