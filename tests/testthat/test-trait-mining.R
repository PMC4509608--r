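sch <- scoring_scheme("protein")

test_that("identical proteomes pair every protein with itself", {
  prots <- unrelated_proteins(6, 120, 601, "p")
  rb <- reciprocal_orthologs(prots, prots)
  expect_equal(nrow(rb), 6)
  expect_equal(rb$gene_a, rb$gene_b)
  expect_true(all(rb$e_forward <= 1e-5))
})

test_that("shuffled decoys yield no reciprocal orthologs", {
  prots <- unrelated_proteins(5, 150, 602, "p")
  decoys <- with_seed(603, vapply(prots, function(p)
    paste(sample(strsplit(p, "")[[1]]), collapse = ""), ""))
  names(decoys) <- paste0("d", seq_along(decoys))
  rb <- reciprocal_orthologs(prots, decoys)
  expect_equal(nrow(rb), 0)
})

test_that("planted one-to-one orthologs are recovered exactly", {
  a <- unrelated_proteins(5, 150, 604, "a")
  b <- vapply(seq_along(a), function(i) mutate_protein(a[[i]], 0.4,
                                                       seed = 605 + i), "")
  names(b) <- paste0("b", 1:5)
  extra <- unrelated_proteins(3, 150, 611, "junk")
  rb <- reciprocal_orthologs(a, c(b, extra))
  expect_equal(nrow(rb), 5)
  expect_equal(rb$gene_b[match(names(a), rb$gene_a)], names(b))
})

test_that("reciprocity is symmetric between the two proteomes", {
  a <- unrelated_proteins(4, 130, 612, "a")
  b <- vapply(a, function(p) mutate_protein(p, 0.35), "")
  names(b) <- paste0("b", 1:4)
  ab <- reciprocal_orthologs(a, b)
  ba <- reciprocal_orthologs(b, a)
  expect_setequal(paste(ab$gene_a, ab$gene_b),
                  paste(ba$gene_b, ba$gene_a))
})

test_that("cluster calling enforces the per-system minimum gene counts", {
  pc <- preset_clusters(seed = 61, sizes = c(T2SS_xcp = 4, T6SS = 5))
  cl2 <- call_clusters(pc$genome, pc$bundle$T2SS_xcp)
  expect_equal(sum(vapply(cl2, function(x) x$called, TRUE)), 1)
  cl6 <- call_clusters(pc$genome, pc$bundle$T6SS)
  expect_equal(sum(vapply(cl6, function(x) x$called, TRUE)), 1)

  pc3 <- preset_clusters(seed = 62, sizes = c(T2SS_xcp = 3))
  cl3 <- call_clusters(pc3$genome, pc3$bundle$T2SS_xcp)
  expect_equal(sum(vapply(cl3, function(x) x$called, TRUE)), 0)
  expect_gte(length(cl3), 1) # candidate still reported
  expect_equal(cl3[[1]]$n_members, 3)
})

test_that("hit genes split across contigs never form one cluster", {
  bundle <- default_bait_bundle()
  baits <- bundle$T6SS$proteins
  cds <- vapply(baits[1:5], function(p)
    back_translate(mutate_protein(p, 0.25, seed = 63)), "")
  mk_contig <- function(seqs, prefix) {
    gaps <- strrep("T", 200)
    contig <- paste0(gaps, paste0(seqs, gaps, collapse = ""))
    starts <- 201 + (seq_along(seqs) - 1) * (nchar(seqs)[1] + 200)
    list(contig = contig,
         genes = data.frame(gene_id = paste0(prefix, seq_along(seqs)),
                            contig = NA, start = starts,
                            end = starts + nchar(seqs) - 1, strand = "+",
                            stringsAsFactors = FALSE))
  }
  c1 <- mk_contig(cds[1:3], "x"); c2 <- mk_contig(cds[4:5], "y")
  c1$genes$contig <- "c1"; c2$genes$contig <- "c2"
  g <- annotated_genome(c(c1 = c1$contig, c2 = c2$contig),
                        rbind(c1$genes, c2$genes))
  cl <- call_clusters(g, bundle$T6SS)
  expect_true(all(!vapply(cl, function(x) x$called, TRUE)))
  expect_true(all(vapply(cl, function(x) x$n_members, 0L) <= 3))
})

test_that("tightening e_max never creates additional called clusters", {
  pc <- preset_clusters(seed = 64, sizes = c(T2SS_xcp = 4))
  n_called <- function(e) {
    bs <- pc$bundle$T2SS_xcp; bs$e_max <- e
    sum(vapply(call_clusters(pc$genome, bs), function(x) x$called, TRUE))
  }
  counts <- vapply(c(1e-3, 1e-5, 1e-20, 1e-60), n_called, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("OBL calls require strictly more than four distinct orthologs", {
  sets <- obl_bait_sets(1)
  sim <- simulate_genome(simulation_params(contig_length = 120000,
                                           n_genes = 15, seed = 65))
  g <- sim$genome; led <- sim$ledger
  for (i in 1:6) {
    pf <- plant_feature(g, led, list(
      kind = "cluster_gene", id = sprintf("obl_m%d", i),
      seq = back_translate(mutate_protein(sets[[1]]$proteins[[i]], 0.3,
                                          seed = 650 + i))))
    g <- pf$genome; led <- pf$ledger
  }
  found <- screen_obl(g, sets)
  expect_equal(length(found), 1)
  expect_gte(found[[1]]$n_distinct_baits, 5)

  # four orthologs only: reported nothing
  sim2 <- simulate_genome(simulation_params(contig_length = 120000,
                                            n_genes = 15, seed = 66))
  g2 <- sim2$genome; led2 <- sim2$ledger
  for (i in 1:4) {
    pf <- plant_feature(g2, led2, list(
      kind = "cluster_gene", id = sprintf("obl_m%d", i),
      seq = back_translate(mutate_protein(sets[[1]]$proteins[[i]], 0.3,
                                          seed = 660 + i))))
    g2 <- pf$genome; led2 <- pf$ledger
  }
  expect_equal(length(screen_obl(g2, sets)), 0)
  # and a genome without OBL genes is empty
  expect_equal(length(screen_obl(sim$genome, sets)), 0)
})

test_that("domain tagging enforces the C-terminal position when asked", {
  dom <- random_protein(90, seed = 671)
  body <- random_protein(260, seed = 672)
  cterm <- paste0(body, dom)
  nterm <- paste0(dom, body)
  prots <- c(ct = cterm, nt = nterm)
  res_any <- count_domain_tagged(prots, c(ex = dom), position = "any")
  expect_equal(res_any$count, 2)
  res_ct <- count_domain_tagged(prots, c(ex = dom), position = "cterm")
  expect_equal(res_ct$ids, "ct")
})

test_that("planted translocator-like proteins are counted among decoys", {
  dom <- random_protein(90, seed = 681)
  planted <- with_seed(682, vapply(1:10, function(i)
    paste0(random_protein(200), mutate_protein(dom, 0.2)), ""))
  names(planted) <- paste0("t5a_", 1:10)
  decoys <- unrelated_proteins(200, 290, 683, "bg")
  res <- count_domain_tagged(c(planted, decoys), c(ex = dom),
                             position = "cterm")
  expect_setequal(res$ids, names(planted))
})

test_that("TpsA/TpsB pairing respects adjacency, strand and contig", {
  genes <- data.frame(
    gene_id = c("b1", "a1", "b2", "a2", "b3"),
    contig = c("c1", "c1", "c1", "c2", "c2"),
    start = c(100, 1200, 8000, 100, 9000),
    end = c(1000, 2100, 8900, 1000, 9900),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  g <- annotated_genome(c(c1 = random_dna(10000), c2 = random_dna(10000)),
                        genes)
  res <- pair_tps(g, tpsB_ids = c("b1", "b2", "b3"), tpsA_ids = c("a1", "a2"))
  expect_equal(res$partner[res$gene_id == "b1"], "a1")
  expect_equal(res$status[res$gene_id == "b2"], "stand-alone")
  # a2 is adjacent to b3 by rank but on the other strand
  expect_equal(res$status[res$gene_id == "b3"], "stand-alone")
  expect_equal(res$status[res$gene_id == "a2"], "stand-alone")
})
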