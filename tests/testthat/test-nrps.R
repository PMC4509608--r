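test_that("domain strings validate labels and span ordering", {
  ds <- nrps_domain_string("p1", data.frame(
    domain = c("C", "A", "T"), start = c(1, 130, 400), end = c(120, 370, 470)))
  expect_equal(ds$domains$domain, c("C", "A", "T"))
  expect_error(nrps_domain_string("p1", data.frame(
    domain = c("C", "A"), start = c(1, 100), end = c(150, 300))),
    "overlap")
  expect_error(nrps_domain_string("p1", data.frame(
    domain = "Q", start = 1, end = 10)), "invalid")
})

test_that("the alignment fallback locates planted A domains", {
  ref <- nrps_reference()
  prot <- paste0(random_protein(60, seed = 91), ref$a_domain,
                 random_protein(80, seed = 92), a_domain_for("Lys"),
                 random_protein(40, seed = 93))
  ds <- parse_domain_string(annotation = NULL, proteins = c(p = prot))
  expect_equal(nrow(ds$p$domains), 2)
  expect_true(all(ds$p$domains$domain == "A"))
})

test_that("modularization cuts at condensation domains", {
  expect_equal(length(modularize(list())$modules), 0)
  sn <- synthetic_nrps(residues = c("Ser", "Lys"), epimerize = 2,
                       split = c(2), te = FALSE)
  asm <- modularize(parse_domain_string(sn$annotation))
  expect_equal(length(asm$modules), 2)
  expect_false(asm$modules[[1]]$epimerized)
  expect_true(asm$modules[[2]]$epimerized)

  sn7 <- synthetic_nrps() # seven-module pyoverdine layout over 3 proteins
  asm7 <- modularize(parse_domain_string(sn7$annotation))
  expect_equal(length(asm7$modules), 7)
  expect_true(asm7$has_te)
})

test_that("modules without exactly one A domain raise a structural warning", {
  ann <- data.frame(protein = "p", domain = c("C", "T", "C", "A", "T"),
                    start = c(1, 150, 300, 420, 700),
                    end = c(120, 230, 400, 680, 780),
                    stringsAsFactors = FALSE)
  expect_warning(asm <- modularize(parse_domain_string(ann)), "structural")
  expect_equal(sum(vapply(asm$modules, function(m) m$valid, TRUE)), 1)
})

test_that("residue prediction reads the signature code through alignment", {
  ref <- nrps_reference(); tab <- nrps_signature_table()
  # the reference itself carries its own (unlisted) code: nearest match only
  own <- predict_residue(ref$a_domain, ref, tab)
  expect_true(own$distance >= 0)
  # a planted Ser code is predicted exactly
  ser <- predict_residue(a_domain_for("Ser"), ref, tab)
  expect_equal(ser$residue, "Ser")
  expect_true(ser$exact)
  # Hamming-1 code resolves to the unique nearest entry, distance reported
  a1 <- a_domain_for("Orn")
  pos <- ref$signature_positions[1]
  code_char <- substr(a1, pos, pos)
  repl <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], code_char)[1]
  substr(a1, pos, pos) <- repl
  near <- predict_residue(a1, ref, tab)
  expect_equal(near$residue, "Orn")
  expect_equal(near$distance, 1)
  expect_false(near$exact)
  # low alignment coverage is refused
  expect_error(predict_residue(substr(ref$a_domain, 1, 100), ref, tab),
               "low-confidence")
})

test_that("peptides carry one residue per module and local stereochemistry", {
  sn <- synthetic_nrps(epimerize = 6)
  asm <- modularize(parse_domain_string(sn$annotation))
  pep <- predict_peptide(asm, sn$proteins)
  expect_equal(nrow(pep), 7)
  expect_equal(pep$residue, c("Ser", "Lys", "Gly", "Orn", "Lys", "Orn", "Ser"))
  expect_equal(pep$configuration, c("L", "L", "L", "L", "L", "D", "L"))
  expect_equal(attr(pep, "peptide"), "Ser-Lys-Gly-Orn-Lys-D-Orn-Ser")

  # removing the E domain flips only that module's configuration
  sn0 <- synthetic_nrps(epimerize = integer())
  pep0 <- predict_peptide(modularize(parse_domain_string(sn0$annotation)),
                          sn0$proteins)
  expect_equal(pep0$residue, pep$residue)
  expect_true(all(pep0$configuration == "L"))

  # empty assembly gives an empty peptide
  pe <- predict_peptide(modularize(list()), character(0))
  expect_equal(nrow(pe), 0)
  expect_equal(attr(pe, "peptide"), "")
})

test_that("synthetic assemblies round-trip through the whole NRPS stack", {
  sn <- synthetic_nrps(residues = c("Gly", "Orn", "Ala"), epimerize = 2,
                       split = c(1, 2))
  pep <- predict_peptide(modularize(parse_domain_string(sn$annotation)),
                        sn$proteins)
  expect_equal(pep$residue, sn$expected$residue)
  expect_equal(pep$configuration, sn$expected$configuration)
})
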