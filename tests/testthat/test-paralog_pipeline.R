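test_that("find_duplicate_pairs: pairs, triangles and one-way hits", {
  # mutual pair + triangle component + one-way (non-mutual) edge
  ev <- 1e-100
  h <- mk_hits(
    c("p1", "p2", "t1", "t2", "t3", "t1", "t2", "t3", "x1"),
    c("p2", "p1", "t2", "t3", "t1", "t3", "t1", "t2", "x2"),
    rep(ev, 9), rep(400, 9), "S", "S")
  res <- find_duplicate_pairs(h, 1e-80)
  expect_equal(res$pairs,
               data.frame(gene_1 = "p1", gene_2 = "p2",
                          stringsAsFactors = FALSE))
  expect_equal(res$flagged, list(c("t1", "t2", "t3")))
  # cutoff excludes weak mutual pairs
  weak <- mk_hits(c("w1", "w2"), c("w2", "w1"), rep(1e-50, 2), rep(180, 2))
  expect_equal(nrow(find_duplicate_pairs(weak, 1e-80)$pairs), 0L)
})

test_that("exclude_artifacts applies coverage and length-ratio thresholds", {
  full <- list(query_coverage = 0.98, subject_coverage = 0.97)
  expect_true(exclude_artifacts(full, 300, 310, 0.5, 2)$keep)
  short <- list(query_coverage = 0.3, subject_coverage = 0.95)
  r <- exclude_artifacts(short, 300, 100, 0.5, 2)
  expect_false(r$keep)
  expect_equal(r$reason, "coverage")
  r2 <- exclude_artifacts(full, 500, 200, 0.5, 2)
  expect_false(r2$keep)
  expect_equal(r2$reason, "length_ratio")
})

test_that("outgroup_singleton_test demands one shared pre-WGD ortholog", {
  pair <- c("g1", "g2")
  to <- mk_hits(c("g1", "g2"), c("o1", "o1"), c(1e-95, 1e-92), c(320, 310),
                "S", "OG")
  from_ok <- mk_hits(c("o1", "o1"), c("g1", "g2"), c(1e-95, 1e-92),
                     c(320, 310), "OG", "S")
  r <- outgroup_singleton_test(pair, list(og = list(to = to, from = from_ok)))
  expect_true(r$pass)
  expect_equal(r$orthologs, c(og = "o1"))
  # pair members best-hitting different outgroup genes
  split_best <- mk_hits(c("g1", "g2"), c("o1", "o2"), c(1e-95, 1e-92),
                        c(320, 310), "S", "OG")
  expect_false(outgroup_singleton_test(
    pair, list(og = list(to = split_best, from = from_ok)))$pass)
  # outgroup gene also strongly hits a third seed gene
  from_bad <- mk_hits(c("o1", "o1", "o1"), c("g1", "g2", "g3"),
                      c(1e-95, 1e-92, 1e-85), c(320, 310, 290), "OG", "S")
  r3 <- outgroup_singleton_test(pair,
                                list(og = list(to = to, from = from_bad)))
  expect_false(r3$pass)
  expect_match(r3$reason, "extra_seed_hit")
  expect_error(outgroup_singleton_test(pair, list(og = list(to = to))),
               "missing hit table")
})

test_that("copy_number counts reciprocally supported co-orthologs per
          chromosome", {
  pair <- c("g1", "g2")
  tg <- mk_genes(c("t1", "t2", "t3"), species = "T",
                 chromosome = c("1", "5", "1"))
  to2 <- mk_hits(c("g1", "g2"), c("t1", "t2"), c(1e-95, 1e-93), c(320, 315),
                 "S", "T")
  from2 <- mk_hits(c("t1", "t2"), c("g1", "g2"), c(1e-95, 1e-93),
                   c(320, 315), "T", "S")
  r <- copy_number(pair, to2, from2, tg)
  expect_equal(r$count, 2L)
  expect_false(r$ambiguous)
  # single retained copy
  to1 <- mk_hits("g1", "t1", 1e-95, 320, "S", "T")
  from1 <- mk_hits("t1", "g1", 1e-95, 320, "T", "S")
  expect_equal(copy_number(pair, to1, from1, tg)$count, 1L)
  # two co-orthologs on one chromosome: tandem-consistent, scored 1
  to_t <- mk_hits(c("g1", "g2"), c("t1", "t3"), c(1e-95, 1e-93), c(320, 315),
                  "S", "T")
  from_t <- mk_hits(c("t1", "t3"), c("g1", "g2"), c(1e-95, 1e-93),
                    c(320, 315), "T", "S")
  expect_equal(quiet(copy_number(pair, to_t, from_t, tg))$count, 1L)
  # an above-cutoff hit without reciprocal support marks ambiguity
  to_amb <- mk_hits(c("g1", "g1"), c("t1", "t2"), c(1e-95, 1e-85),
                    c(320, 290), "S", "T")
  from_amb <- mk_hits(c("t1", "t2"), c("g1", "x9"), c(1e-95, 1e-85),
                      c(320, 290), "T", "S")
  r_amb <- copy_number(pair, to_amb, from_amb, tg)
  expect_equal(r_amb$count, 1L)
  expect_true(r_amb$ambiguous)
  # nothing above cutoff
  expect_equal(copy_number(pair, mk_hits("g1", "t1", 1e-10, 60, "S", "T"),
                           from1, tg)$count, 0L)
})

test_that("classify_lsp follows the systematic-retention rule", {
  cfg <- default_panel()
  cn <- function(counts, ambiguous = FALSE)
    lapply(counts, function(k) list(count = k, ambiguous = ambiguous))
  sp <- c(cfg$lineage_a, cfg$lineage_b)
  mk <- function(a, b) setNames(cn(c(a, b)), sp)
  expect_equal(classify_lsp(list(copy_number = mk(c(2, 2), c(1, 1, 1, 1))),
                            cfg)$call, "A_LSP")
  expect_equal(classify_lsp(list(copy_number = mk(c(1, 1), c(2, 2, 2, 2))),
                            cfg)$call, "B_LSP")
  expect_equal(classify_lsp(list(copy_number = mk(c(2, 2), c(2, 2, 2, 2))),
                            cfg)$call, "shared_duplicate")
  # systematicity violated
  expect_equal(classify_lsp(list(copy_number = mk(c(2, 1), c(1, 1, 1, 1))),
                            cfg)$call, "unresolved")
  # a zero demotes unless the species is explicitly allowed missing
  expect_equal(classify_lsp(list(copy_number = mk(c(2, 2), c(0, 1, 1, 1))),
                            cfg)$call, "unresolved")
  cfg_allow <- default_panel(allow_missing_species = "B1")
  expect_equal(classify_lsp(list(copy_number = mk(c(2, 2), c(0, 1, 1, 1))),
                            cfg_allow)$call, "A_LSP")
  # ambiguity demotes
  amb <- mk(c(2, 2), c(1, 1, 1, 1))
  amb$B2$ambiguous <- TRUE
  expect_equal(classify_lsp(list(copy_number = amb), cfg)$call, "unresolved")
  expect_error(classify_lsp(list(copy_number = amb[-1]), cfg), "missing")
})

test_that("summarize_panel percentage arithmetic (round half-up, 1 dp)", {
  expect_equal(summarize_panel(4122, 19600)$percent, 21.0)
  expect_equal(summarize_panel(3284, 17800)$percent, 18.4)
  expect_equal(summarize_panel(510, 19600)$percent, 2.6)
  expect_equal(summarize_panel(226, 17800)$percent, 1.3)
  expect_equal(summarize_panel(0, 1234)$percent, 0.0)
  expect_error(summarize_panel(5, 0), "positive")
})

test_that("LSP calls are disjoint and each gene joins at most one family", {
  sp <- small_panel()
  b <- quiet(run_pipeline(sp$config$species_panel, sp$panel))
  fam <- b$families
  expect_false(any(fam$call == "A_LSP" & fam$call == "B_LSP"))
  expect_equal(anyDuplicated(fam$family_id), 0L)
  per_dir <- split(fam, fam$direction)
  for (f in per_dir)
    expect_equal(anyDuplicated(c(f$gene_1, f$gene_2)), 0L)
})

test_that("tightening the E-value cutoff never creates families", {
  sp <- small_panel()
  cfgs <- lapply(c(1e-80, 1e-120, 1e-160),
                 function(e) default_panel(evalue_cutoff = e, seed = 1))
  n_fam <- vapply(cfgs, function(cfg)
    nrow(quiet(run_pipeline(cfg, sp$panel))$families), integer(1))
  expect_true(all(diff(n_fam) <= 0))
})
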