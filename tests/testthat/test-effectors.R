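test_that("box scanning is coding-strand only and honors the mismatch budget", {
  sim <- simulate_genome(simulation_params(contig_length = 40000, n_genes = 8,
                                           seed = 71))
  box <- "GGAACCACGTACGTACGTACGTCCACGTA" # block1 + 16-nt spacer + block2
  cds <- random_cds(600)
  # plant on the minus strand: the box lies on that gene's coding strand
  pf <- plant_feature(sim$genome, sim$ledger,
                      list(kind = "effector", id = "e1", seq = cds,
                           strand = "-", box = list(seq = box, offset = 150L)))
  hits <- scan_hrp_boxes(pf$genome)
  expect_equal(hits$gene_id, "e1")
  expect_equal(hits$pos, -150)
  expect_equal(hits$mm1 + hits$mm2, 0)

  # the same arrangement is invisible to genes on the other strand: flip the
  # planted gene's annotation and the hit disappears
  g2 <- pf$genome
  g2$genes$strand[g2$genes$gene_id == "e1"] <- "+"
  expect_false("e1" %in% scan_hrp_boxes(g2)$gene_id)

  # one mutated block position exceeds a zero-mismatch budget
  mutbox <- box; substr(mutbox, 2, 2) <- "T"
  pf2 <- plant_feature(sim$genome, sim$ledger,
                       list(kind = "effector", id = "e2", seq = cds,
                            strand = "+", box = list(seq = mutbox,
                                                     offset = 150L)))
  expect_false("e2" %in% scan_hrp_boxes(pf2$genome)$gene_id)
  # ... but is tolerated with a one-mismatch budget
  lax <- hrp_box_model(max_mismatch = c(1, 1))
  expect_true("e2" %in% scan_hrp_boxes(pf2$genome, lax)$gene_id)
})

test_that("N-terminal features are computed per the composition rules", {
  p <- paste0("MKIS", strrep("ST", 4), "KKKK",
              paste(rep("SGTA", 8), collapse = ""), "AA")
  f <- nterm_profile(p)
  expect_true(f$aliphatic_pos34)
  expect_equal(f$acidic_first12, 0)

  # arithmetic: 6 Ser in a 50-residue window -> 0.12
  q <- paste0("MK", strrep("S", 6), strrep("A", 42))
  expect_equal(nterm_profile(q)$ser_frac, 0.12)

  # acidic count includes both D and E within the first 12 positions
  r <- paste0("MAADE", strrep("K", 10), strrep("G", 40))
  expect_equal(nterm_profile(r)$acidic_first12, 2)

  expect_error(nterm_profile("MKISSTQ"), "12")
  expect_error(nterm_profile(paste0("MKIS*", strrep("A", 20))), "amino")
})

test_that("the verdict is the conjunction of box and composition rules", {
  pe <- preset_effectors(seed = 72, n_background = 60, n_effectors = 3)
  res <- call_effectors(pe$genome, pe$model)
  truth <- pe$ledger$payload[pe$ledger$feature_kind == "effector"]
  expect_setequal(res$gene_id[res$verdict], truth)
  # trails reconstruct the verdict exactly
  ok <- res$pass_box & res$pass_ser & res$pass_polar & res$pass_acidic &
    res$pass_aliphatic
  expect_identical(res$verdict, !is.na(ok) & ok)

  # a compliant N-terminus without a promoter box is never called
  no_box <- res[res$gene_id %in% truth, ]
  expect_true(all(no_box$pass_box))
  g2 <- pe$genome
  led <- pe$ledger
  boxes <- led[led$feature_kind == "hrp_box", ]
  for (i in seq_len(nrow(boxes))) { # scrub the planted boxes
    b <- boxes[i, ]
    substr(g2$contigs[[b$contig]], b$start, b$end) <-
      strrep("T", b$end - b$start + 1)
  }
  res2 <- call_effectors(g2, pe$model)
  expect_equal(sum(res2$verdict), 0)
})

test_that("tightening any single threshold never adds candidates", {
  pe <- preset_effectors(seed = 73, n_background = 60, n_effectors = 3)
  base <- sum(call_effectors(pe$genome, pe$model)$verdict)
  tighter <- list(
    effector_rules(ser_min = 0.2),
    effector_rules(polar_min = 0.5),
    effector_rules(acidic_max = 0))
  for (r in tighter)
    expect_lte(sum(call_effectors(pe$genome, pe$model, r)$verdict), base)
  narrow <- hrp_box_model(promoter_window = 150)
  expect_lte(sum(call_effectors(pe$genome, narrow)$verdict), base)
})
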