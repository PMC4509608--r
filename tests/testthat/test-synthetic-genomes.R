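test_that("identical seeds reproduce byte-identical genomes", {
  p <- simulation_params(contig_length = 20000, n_genes = 6, seed = 5)
  s1 <- simulate_genome(p)
  s2 <- simulate_genome(p)
  expect_identical(s1$genome$contigs, s2$genome$contigs)
  expect_identical(s1$genome$genes, s2$genome$genes)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("a gene-free genome still carries its contigs", {
  s <- simulate_genome(simulation_params(n_contigs = 2,
                                         contig_length = c(3000, 5000),
                                         n_genes = 0, seed = 1))
  expect_equal(nrow(s$genome$genes), 0)
  expect_equal(unname(nchar(s$genome$contigs)), c(3000, 5000))
})

test_that("realized GC content matches the requested fraction", {
  s <- simulate_genome(simulation_params(contig_length = 100000, n_genes = 0,
                                         gc_content = 0.60, seed = 2))
  gc <- sum(strsplit(s$genome$contigs[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.60), 0.01)
})

test_that("overfull gene requests raise a capacity error", {
  expect_error(simulate_genome(simulation_params(contig_length = 2000,
                                                 n_genes = 10, seed = 1)),
               "capacity")
})

test_that("genes never overlap and lie within contig bounds", {
  s <- simulate_genome(simulation_params(n_contigs = 2,
                                         contig_length = c(20000, 30000),
                                         n_genes = 25, seed = 9))
  g <- s$genome$genes
  for (cn in unique(g$contig)) {
    gc <- g[g$contig == cn, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
    expect_true(all(gc$end <= nchar(s$genome$contigs[[cn]])))
  }
})

test_that("divergence follows the substitute-to-a-different-base model", {
  s <- simulate_genome(simulation_params(contig_length = 200000, n_genes = 0,
                                         seed = 3))
  expect_identical(diverge(s$genome, 0, seed = 1)$contigs, s$genome$contigs)
  d1 <- diverge(s$genome, 0.05, seed = 8)
  d2 <- diverge(s$genome, 0.05, seed = 8)
  expect_identical(d1$contigs, d2$contigs)
  ident <- str_matches(s$genome$contigs[[1]], d1$contigs[[1]]) / 200000
  # expectation 1 - d; 200 kb gives a +/-0.2% band (>4 binomial sd)
  expect_lt(abs(ident - 0.95), 0.002)
})

test_that("realized substitution fraction stays within 3 binomial sd of d", {
  s <- simulate_genome(simulation_params(contig_length = 50000, n_genes = 0,
                                         seed = 4))
  for (d in c(0.01, 0.04, 0.08)) {
    dv <- diverge(s$genome, d, seed = round(100 * d))
    realized <- 1 - str_matches(s$genome$contigs[[1]], dv$contigs[[1]]) / 50000
    expect_lt(abs(realized - d), 3 * sqrt(d * (1 - d) / 50000))
  }
})

test_that("exact-count divergence is exactly controlled", {
  s <- simulate_genome(simulation_params(contig_length = 30000, n_genes = 0,
                                         seed = 6))
  dv <- diverge(s$genome, 0.03, seed = 7, exact = TRUE)
  realized <- 30000 - str_matches(s$genome$contigs[[1]], dv$contigs[[1]])
  expect_equal(realized, round(0.03 * 30000))
})

test_that("planted features are ledgered, in bounds, and protected from overlap", {
  sim <- simulate_genome(simulation_params(contig_length = 30000, n_genes = 5,
                                           seed = 11))
  pf <- plant_feature(sim$genome, sim$ledger,
                      list(kind = "cluster_gene", id = "x1",
                           seq = random_cds(600)))
  expect_equal(nrow(pf$ledger), 1)
  row <- pf$ledger[1, ]
  expect_lte(row$end, nchar(pf$genome$contigs[[row$contig]]))
  expect_true("x1" %in% pf$genome$genes$gene_id)
  # a second plant at the same spot must fail
  expect_error(plant_feature(pf$genome, pf$ledger,
                             list(kind = "cluster_gene", id = "x2",
                                  seq = random_cds(600), contig = row$contig,
                                  start = row$start)),
               "placement")
})

test_that("planted loci round-trip through their cognate detectors", {
  # hrp box + effector -> effector screen finds exactly the plant
  sim <- simulate_genome(simulation_params(contig_length = 80000, n_genes = 20,
                                           seed = 21))
  nterm <- "MKISSTQGKSTNQSSGTAKLSTNQGSSAKLVTSNQGSSTAKLSTQNGSSA"
  cds <- back_translate(paste0(nterm, random_protein(150, seed = 22)))
  pf <- plant_feature(sim$genome, sim$ledger,
                      list(kind = "effector", id = "eff1", seq = cds,
                           box = list(seq = "GGAACCTTTTTTTTTTTTTTTTCCACGTA",
                                      offset = 120L)))
  hits <- scan_hrp_boxes(pf$genome)
  expect_equal(hits$gene_id, "eff1")
  expect_equal(hits$pos, -120)
  called <- call_effectors(pf$genome)
  expect_identical(called$gene_id[called$verdict], "eff1")
})

test_that("genome round-trips through FASTA/GFF3 on disk", {
  sim <- simulate_genome(simulation_params(contig_length = 5000, n_genes = 3,
                                           seed = 31))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(sim$genome, fa, gff)
  back <- read_genome(fa, gff)
  expect_identical(back$contigs, sim$genome$contigs)
  expect_equal(back$genes$start, sim$genome$genes$start)
  expect_equal(back$genes$strand, sim$genome$genes$strand)
})
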