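test_that("extract_locus returns exact copies and errors on absent baits", {
  baits <- mlsa_baits()
  sim <- simulate_genome(simulation_params(contig_length = 30000, n_genes = 4,
                                           seed = 41))
  pf <- plant_feature(sim$genome, sim$ledger,
                      list(kind = "housekeeping", id = "gyrB",
                           seq = baits[["gyrB"]], strand = "-"))
  hit <- extract_locus(pf$genome, baits[["gyrB"]], "gyrB")
  expect_equal(hit$seq, baits[["gyrB"]])
  expect_equal(hit$strand, "-")
  expect_error(extract_locus(sim$genome, baits[["rpoD"]], "rpoD"),
               "rpoD")
})

test_that("a locus planted at 5% divergence is recovered in place", {
  baits <- mlsa_baits()
  sim <- simulate_genome(simulation_params(contig_length = 30000, n_genes = 4,
                                           seed = 42))
  mut <- with_seed(43, mutate_string(baits[["rpoB"]], 0.05))
  pf <- plant_feature(sim$genome, sim$ledger,
                      list(kind = "housekeeping", id = "rpoB", seq = mut))
  row <- pf$ledger[1, ]
  hit <- extract_locus(pf$genome, baits[["rpoB"]], "rpoB")
  overlap <- min(hit$end, row$end) - max(hit$start, row$start) + 1
  expect_gte(overlap / (row$end - row$start + 1), 0.90)
  expect_gt(hit$identity, 90)
})

test_that("NI is 100 on self, symmetric, and tracks divergence", {
  tx <- preset_taxonomy(seed = 44, d = 0.03)
  pa <- mlsa_profile(tx$strain_a, tx$baits, strain_id = "A")
  pb <- mlsa_profile(tx$strain_b, tx$baits, strain_id = "B")
  expect_equal(pairwise_ni(pa, pa), 100)
  ni <- pairwise_ni(pa, pb)
  expect_equal(ni, pairwise_ni(pb, pa))
  expect_lt(abs(ni - 97), 0.3)
})

test_that("species boundary calls follow the 97% MLSA rule", {
  expect_equal(classify_mlsa(100), "same_species")
  expect_equal(classify_mlsa(99), "same_species")
  expect_equal(classify_mlsa(96), "distinct_species")
  expect_equal(classify_mlsa(94), "distinct_species")
  # conspecificity requires exceeding the boundary
  expect_equal(classify_mlsa(97.0), "distinct_species")
  expect_equal(classify_mlsa(97.01), "same_species")
})

test_that("neighbor joining resolves three taxa by the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(45)
  for (i in 1:10) {
    truth <- ape::rtree(4 + (i %% 2))
    D <- stats::cophenetic(truth)
    est <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(est), ape::unroot(truth))), 0)
    # branch lengths on additive input are exact
    expect_equal(max(abs(stats::cophenetic(est)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-8)
  }
})

test_that("nj_tree matches the reference implementation on generic input", {
  set.seed(46)
  D <- as.matrix(stats::dist(matrix(runif(35), 7)))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_tree(D)),
                              ape::unroot(ape::nj(D)))), 0)
})

test_that("nj_tree rejects malformed distance matrices", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(D), "3")
  D3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(D3), "symmetric")
})

test_that("bootstrap supports are 100 for perfectly congruent signal", {
  diag_cols <- rbind(A = c("A", "C"), B = c("A", "C"),
                     C = c("C", "A"), D = c("C", "A"))
  M <- diag_cols[, rep(1:2, 10)]
  bs <- bootstrap_supports(M, n_replicates = 200, seed = 1)
  expect_true(all(bs$supports == 100))
  bs2 <- bootstrap_supports(M, n_replicates = 200, seed = 1)
  expect_identical(bs$supports, bs2$supports)
})

test_that("bootstrap supports are invariant to taxon input order", {
  set.seed(47)
  M <- matrix(sample(c("A", "C", "G", "T"), 5 * 60, replace = TRUE), 5, 60,
              dimnames = list(paste0("t", 1:5), NULL))
  M[2, ] <- M[1, ]; M[2, 1:6] <- "T" # give t1/t2 a real clade
  b1 <- bootstrap_supports(M, n_replicates = 100, seed = 9)
  b2 <- bootstrap_supports(M[c(3, 1, 5, 2, 4), ], n_replicates = 100, seed = 9)
  shared <- intersect(names(b1$supports), names(b2$supports))
  expect_true(length(shared) >= 1)
  expect_equal(b1$supports[shared], b2$supports[shared])
})
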