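#' Parameters for synthetic genome simulation
#'
#' The generator builds multi-contig genomes with non-overlapping gene
#' models laid out on a jittered grid, background intergenic sequence drawn
#' i.i.d. at the requested GC content, and gene sequences drawn from a
#' codon-uniform model (ATG start, uniform sense codons, random stop).
#' Identical seeds reproduce byte-identical genomes.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (scalar or vector;
#'   minimum 1000).
#' @param n_genes Total number of background gene models to plant.
#' @param gc_content Background GC fraction in \[0, 1\].
#' @param divergence Per-site substitution probability applied to the
#'   finished genome (0 = none); see [diverge()].
#' @param indel_rate Reserved; must be 0 (substitution-only model keeps
#'   identity expectations closed-form).
#' @param seed Integer seed; all randomness flows from it.
#' @param gene_length Gene model length in bp (multiple of 3).
#' @param min_intergenic Minimum intergenic gap enforced upstream of every
#'   gene, bp.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_contigs = 1, contig_length = 100000,
                              n_genes = 50, gc_content = 0.5,
                              divergence = 0, indel_rate = 0, seed = 1,
                              gene_length = 900, min_intergenic = 300) {
  stopifnot(n_contigs >= 1, all(contig_length >= 1000),
            n_genes >= 0, gc_content >= 0, gc_content <= 1,
            divergence >= 0, divergence <= 1,
            indel_rate >= 0, indel_rate <= 1,
            gene_length %% 3 == 0, gene_length >= 9)
  if (indel_rate > 0)
    stop("indel_rate > 0 is not supported: the substitution-only model is ",
         "required for closed-form identity expectations")
  contig_length <- rep_len(as.integer(contig_length), n_contigs)
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = contig_length,
                 n_genes = as.integer(n_genes), gc_content = gc_content,
                 divergence = divergence, indel_rate = indel_rate,
                 seed = as.integer(seed), gene_length = as.integer(gene_length),
                 min_intergenic = as.integer(min_intergenic)),
            class = "simulation_params")
}

empty_ledger <- function() {
  data.frame(feature_kind = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             payload = character(), stringsAsFactors = FALSE)
}

#' Simulate an annotated genome with a truth ledger
#'
#' @param params A [simulation_params()].
#' @return A list with elements `genome` (an [annotated_genome()]) and
#'   `ledger` (truth ledger data.frame; empty until features are planted
#'   with [plant_feature()]).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    contigs <- vapply(seq_len(params$n_contigs), function(i)
      random_dna(params$contig_length[i], params$gc_content), "")
    names(contigs) <- sprintf("contig%02d", seq_len(params$n_contigs))
    slot <- params$gene_length + params$min_intergenic
    capacity <- pmax(0L, params$contig_length %/% slot)
    if (sum(capacity) < params$n_genes)
      stop("capacity error: contigs too small to host ", params$n_genes,
           " genes of ", params$gene_length, " bp with ",
           params$min_intergenic, " bp spacing")
    # proportional allocation of genes to contigs, capped at capacity
    alloc <- pmin(capacity, round(params$n_genes * capacity / sum(capacity)))
    while (sum(alloc) < params$n_genes) {
      i <- which.max(capacity - alloc); alloc[i] <- alloc[i] + 1L
    }
    while (sum(alloc) > params$n_genes) {
      i <- which.max(alloc); alloc[i] <- alloc[i] - 1L
    }
    gene_tabs <- list()
    for (ci in seq_len(params$n_contigs)) {
      k <- alloc[ci]
      if (k == 0) next
      L <- params$contig_length[ci]
      pitch <- L %/% k
      jit_max <- pitch - slot
      jit <- if (jit_max > 0) sample.int(jit_max + 1L, k, replace = TRUE) - 1L
             else integer(k)
      starts <- (seq_len(k) - 1L) * pitch + params$min_intergenic + jit + 1L
      ends <- starts + params$gene_length - 1L
      strands <- sample(c("+", "-"), k, replace = TRUE)
      cds <- vapply(seq_len(k), function(i) random_cds(params$gene_length), "")
      ins <- cds
      if (any(strands == "-")) ins[strands == "-"] <- revcomp(cds[strands == "-"])
      # splice genes into the background with one paste (avoids repeated
      # whole-contig copies)
      bg <- contigs[ci]
      pieces <- character(2L * k + 1L)
      prev_end <- 0L
      for (i in seq_len(k)) {
        pieces[2L * i - 1L] <- substring(bg, prev_end + 1L, starts[i] - 1L)
        pieces[2L * i] <- ins[i]
        prev_end <- ends[i]
      }
      pieces[2L * k + 1L] <- substring(bg, prev_end + 1L, L)
      contigs[ci] <- paste(pieces, collapse = "")
      gene_tabs[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%04d", names(contigs)[ci], seq_len(k)),
        contig = names(contigs)[ci], start = starts, end = ends,
        strand = strands, stringsAsFactors = FALSE)
    }
    genes <- if (length(gene_tabs)) do.call(rbind, c(list(empty_genes()), gene_tabs))
             else empty_genes()
    genome <- annotated_genome(contigs, genes)
    if (params$divergence > 0)
      genome <- diverge(genome, params$divergence,
                        seed = child_seed(params$seed, 1))
    list(genome = genome, ledger = empty_ledger())
  })
}

#' Apply site-wise nucleotide divergence
#'
#' Each site is substituted to one of the three other bases (uniformly) with
#' probability `d`; each site mutates at most once, so the expected pairwise
#' identity against the input is exactly `1 - d`. With `exact = TRUE` the
#' number of substituted sites per contig is fixed at `round(d * length)`
#' (controlled divergence, used to build strain pairs at a known identity).
#' Gene coordinates are unchanged (substitution-only model).
#'
#' @param genome An [annotated_genome()].
#' @param d Per-site substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @param exact Fix the realized substitution count at `round(d * L)`.
#' @return The diverged [annotated_genome()].
#' @export
diverge <- function(genome, d, seed = 1, exact = FALSE) {
  stopifnot(d >= 0, d <= 1)
  if (d == 0) return(genome)
  contigs <- genome$contigs
  for (ci in seq_along(contigs)) {
    contigs[ci] <- with_seed(child_seed(seed, ci), {
      mutate_string(contigs[ci], d, exact)
    })
  }
  annotated_genome(contigs, genome$genes)
}

# Substitute sites in a DNA string; `exact` fixes the count at round(d*L).
mutate_string <- function(s, d, exact = FALSE, positions = NULL) {
  L <- nchar(s)
  idx <- if (!is.null(positions)) positions
         else if (exact) sample.int(L, round(d * L))
         else which(stats::runif(L) < d)
  if (!length(idx)) return(s)
  ch <- strsplit(s, "")[[1]]
  cur <- match(ch[idx], DNA_BASES)
  keep <- !is.na(cur) # leave N untouched
  idx <- idx[keep]; cur <- cur[keep]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  ch[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  paste(ch, collapse = "")
}

# Mutate exactly n_sites positions within [start, end] of one contig.
mutate_region <- function(genome, contig, start, end, n_sites, seed) {
  s <- genome$contigs[[contig]]
  with_seed(seed, {
    pos <- start - 1L + sample.int(end - start + 1L, n_sites)
    genome$contigs[[contig]] <- mutate_string(s, 0, positions = pos)
  })
  annotated_genome(genome$contigs, genome$genes)
}

occupied_intervals <- function(genome, ledger) {
  g <- genome$genes[, c("contig", "start", "end")]
  l <- ledger[, c("contig", "start", "end")]
  out <- rbind(g, l)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Plant a feature into a synthetic genome
#'
#' Writes a feature sequence into free (background) sequence, adds a gene
#' model when requested, and records the plant in the truth ledger. Features
#' never partially overwrite one another: overlap with an existing gene or
#' ledgered feature is a placement error. Effector plants additionally write
#' a promoter box upstream of the start codon on the coding strand and
#' ledger it as a separate `hrp_box` row.
#'
#' @param genome An [annotated_genome()].
#' @param ledger The truth ledger data.frame.
#' @param feature A list with elements: `kind` (one of "housekeeping",
#'   "cluster_gene", "effector", "hrp_box", "tbdp", "nrps"), `id`, `seq`
#'   (nucleotide sequence in coding orientation), optional `contig`, `start`
#'   (auto-placed first-fit when NULL), `strand` ("+"/"-"), `gene` (add a
#'   gene model; default TRUE except for "hrp_box"), `payload` (free-text
#'   evidence), and for effectors `box` = list(seq, offset) placing the box
#'   so its first base lies `offset` bp upstream of the start codon.
#' @param margin Free space demanded on both sides of the plant, bp.
#' @return A list with the updated `genome` and `ledger`.
#' @export
plant_feature <- function(genome, ledger, feature, margin = 60L) {
  kind <- feature$kind
  stopifnot(kind %in% c("housekeeping", "cluster_gene", "effector",
                        "hrp_box", "tbdp", "nrps"))
  seq <- toupper(feature$seq)
  len <- nchar(seq)
  strand <- feature$strand %||% "+"
  is_gene <- feature$gene %||% (kind != "hrp_box")
  box <- feature$box
  up_need <- if (!is.null(box)) box$offset else 0L

  occ <- occupied_intervals(genome, ledger)
  contig <- feature$contig
  start <- feature$start
  if (is.null(start)) {
    placed <- FALSE
    for (cn in (if (is.null(contig)) names(genome$contigs) else contig)) {
      L <- nchar(genome$contigs[[cn]])
      oc <- occ[occ$contig == cn, , drop = FALSE]
      bounds <- c(0L, rbind(oc$start - 1L, oc$end), L + 1L)
      gap_s <- bounds[seq(1, length(bounds), 2)] + 1L
      gap_e <- bounds[seq(2, length(bounds), 2)] - 1L + 1L
      gap_e <- pmin(gap_e, L)
      need <- len + 2L * margin + up_need
      ok <- which(gap_e - gap_s + 1L >= need)
      if (length(ok)) {
        g <- ok[1]
        start <- gap_s[g] + margin + (if (strand == "+") up_need else 0L)
        contig <- cn; placed <- TRUE; break
      }
    }
    if (!placed) stop("placement error: no free interval large enough for ",
                      kind, " '", feature$id %||% "?", "'")
  }
  end <- start + len - 1L
  L <- nchar(genome$contigs[[contig]])
  lo <- if (strand == "+") start - up_need else start
  hi <- if (strand == "+") end else end + up_need
  if (lo < 1 || hi > L)
    stop("placement error: feature outside contig bounds")
  oc <- occ[occ$contig == contig, , drop = FALSE]
  if (any(oc$start <= hi & oc$end >= lo))
    stop("placement error: overlaps an existing feature")

  ins <- if (strand == "+") seq else revcomp(seq)
  substr(genome$contigs[[contig]], start, end) <- ins

  new_rows <- data.frame(feature_kind = kind, contig = contig,
                         start = start, end = end, strand = strand,
                         payload = feature$payload %||% (feature$id %||% ""),
                         stringsAsFactors = FALSE)
  if (!is.null(box)) {
    wb <- nchar(box$seq)
    if (box$offset < wb) stop("box offset must be >= box length")
    if (strand == "+") {
      bs <- start - box$offset; be <- bs + wb - 1L
      substr(genome$contigs[[contig]], bs, be) <- toupper(box$seq)
    } else {
      be <- end + box$offset; bs <- be - wb + 1L
      substr(genome$contigs[[contig]], bs, be) <- revcomp(box$seq)
    }
    new_rows <- rbind(new_rows, data.frame(
      feature_kind = "hrp_box", contig = contig, start = bs, end = be,
      strand = strand, payload = feature$id %||% "", stringsAsFactors = FALSE))
  }

  genes <- genome$genes
  if (is_gene) {
    genes <- rbind(genes, data.frame(
      gene_id = feature$id %||% sprintf("planted_%04d", nrow(ledger) + 1L),
      contig = contig, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE))
  }
  list(genome = annotated_genome(genome$contigs, genes),
       ledger = rbind(ledger, new_rows))
}

# Substitute `frac` of residues to a random different amino acid.
mutate_protein <- function(p, frac, seed = NULL) {
  run <- function() {
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ch <- strsplit(p, "")[[1]]
    idx <- sample.int(length(ch), round(frac * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(aa20, ch[i]), 1)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- shipped synthetic bait / reference bundles -------------------------
## All reference sequences below are synthetic, generated from fixed
## internal seeds; substitute real FASTA bundles for real-genome analyses.

#' Synthetic MLSA locus baits
#'
#' Four housekeeping-locus bait sequences (16S rRNA, gyrB, rpoB, rpoD
#' stand-ins) generated deterministically. Lengths: 1500/1200/1200/900 bp.
#'
#' @return Named character vector in the fixed MLSA locus order.
#' @export
mlsa_baits <- function() {
  lens <- c(`16S_rRNA` = 1500L, gyrB = 1200L, rpoB = 1200L, rpoD = 900L)
  with_seed(40001, {
    out <- vapply(lens, function(l) random_cds(l), "")
    stats::setNames(out, names(lens))
  })
}

# Deterministic family of synthetic proteins: an ancestor mutated per member.
protein_family <- function(n, len, seed, prefix, within_divergence = 0.2) {
  with_seed(seed, {
    anc <- random_protein(len)
    out <- vapply(seq_len(n), function(i) mutate_protein(anc, within_divergence), "")
    stats::setNames(out, sprintf("%s%02d", prefix, seq_len(n)))
  })
}

# Unrelated random synthetic proteins.
unrelated_proteins <- function(n, len, seed, prefix) {
  with_seed(seed, {
    stats::setNames(vapply(seq_len(n), function(i) random_protein(len), ""),
                    sprintf("%s%02d", prefix, seq_len(n)))
  })
}

#' Default synthetic secretion-system bait bundle
#'
#' Bait sets for the five secretion-system screens, with the cluster-calling
#' minima used by the locus definitions: T2SS requires four or more bait-hit
#' genes, T6SS five or more; minima for T1SS/T3SS/T5SS loci are not fixed by
#' the field and default to a conservative three (flagged in reports).
#'
#' @return Named list of [bait_set()] objects.
#' @export
default_bait_bundle <- function() {
  list(
    T1SS_apr = bait_set("T1SS_apr", unrelated_proteins(4, 300, 50011, "apr"),
                        min_cluster_genes = 3),
    T2SS_xcp = bait_set("T2SS_xcp", unrelated_proteins(11, 300, 50012, "xcp"),
                        min_cluster_genes = 4),
    T3SS_rsp = bait_set("T3SS_rsp", unrelated_proteins(14, 300, 50013, "rsp"),
                        min_cluster_genes = 3),
    T6SS = bait_set("T6SS", unrelated_proteins(13, 300, 50014, "tss"),
                    min_cluster_genes = 5))
}

#' Synthetic O-antigen biosynthetic locus (OBL) bait sets
#'
#' One bait set per reference serotype locus; an OBL is called when a
#' cluster carries more than four distinct bait orthologs.
#'
#' @param n_serotypes Number of reference serotype loci.
#' @return Named list of [bait_set()] objects.
#' @export
obl_bait_sets <- function(n_serotypes = 3) {
  out <- lapply(seq_len(n_serotypes), function(i)
    bait_set(sprintf("OBL_serotype_%02d", i),
             unrelated_proteins(8, 280, 50100 + i, sprintf("obl%02d_", i)),
             min_cluster_genes = 5))
  stats::setNames(out, vapply(out, `[[`, "", "system_label"))
}

#' Synthetic TBDP bait set and ferric-pyoverdine receptor references
#'
#' `tbdp_baits()` returns a family of TonB-dependent receptor bait proteins;
#' `fpv_refs()` returns the six pyoverdine-receptor reference sequences
#' (FpvU-FpvZ stand-ins) forming a tight clade; `tbdp_exemplars()` returns
#' the short-form receptor body and its long form carrying the 70-residue
#' N-terminal signaling extension used to flag transducer-type receptors.
#'
#' @return Named character vectors (list for `tbdp_exemplars`).
#' @export
tbdp_baits <- function() {
  protein_family(6, 350, 50200, "tbdp", within_divergence = 0.35)
}

#' @rdname tbdp_baits
#' @export
fpv_refs <- function() {
  refs <- protein_family(6, 350, 50300, "Fpv", within_divergence = 0.35)
  names(refs) <- c("FpvU", "FpvV", "FpvW", "FpvX", "FpvY", "FpvZ")
  refs
}

#' @rdname tbdp_baits
#' @export
tbdp_exemplars <- function() {
  with_seed(50400, {
    body <- random_protein(300)
    ext <- random_protein(70)
    list(short_form = body, long_form = paste0(ext, body))
  })
}

## ---- presets ------------------------------------------------------------

# Compliant effector N-terminus: aliphatic at position 3, no acidic residues
# in the first 12, Ser and polar content comfortably above the screen
# thresholds. Randomized beyond the fixed first four residues.
compliant_nterm <- function() {
  repeat {
    p12 <- c("M", "K", "I", "S",
             sample(c("S", "T", "N", "Q", "G", "K", "R", "L"), 8, replace = TRUE))
    tail <- sample(c("S", "T", "N", "Q", "G", "A", "K", "R", "L", "V", "F"),
                   38, replace = TRUE,
                   prob = c(0.18, 0.12, 0.09, 0.09, 0.09, 0.08, 0.09, 0.06,
                            0.08, 0.06, 0.06))
    nt <- c(p12, tail)
    polar <- mean(nt %in% c("S", "T", "N", "Q", "G", "P", "C", "Y"))
    if (sum(nt == "S") / 50 >= 0.14 && polar >= 0.46) return(paste(nt, collapse = ""))
  }
}

#' Preset synthetic scenarios
#'
#' Ready-made study scenarios used throughout the tests and the acceptance
#' analyses:
#' \describe{
#'   \item{taxonomy}{A strain pair whose four MLSA loci differ at a
#'     controlled (exact-count) divergence `d`, with stochastically diverged
#'     background; used for NI / species-boundary recovery.}
#'   \item{effectors}{A genome with `n_background` codon-uniform background
#'     genes plus `n_effectors` planted effectors, each carrying an exact
#'     promoter box and a compliant N-terminus.}
#'   \item{clusters}{A genome with planted bait-homologous gene clusters of
#'     given sizes for each requested bait set.}
#' }
#'
#' @param seed Integer seed.
#' @param d Controlled MLSA locus divergence (taxonomy preset).
#' @param n_background,n_effectors Gene counts (effectors preset).
#' @param sizes Named integer vector of planted cluster sizes, names
#'   matching bait-set labels (clusters preset).
#' @param bundle Bait bundle for the clusters preset.
#' @return A list whose elements depend on the preset; always includes
#'   `genome` (or `strain_a`/`strain_b`) and `ledger`.
#' @export
preset_taxonomy <- function(seed = 1, d = 0.03) {
  baits <- mlsa_baits()
  sim <- simulate_genome(simulation_params(
    n_contigs = 1, contig_length = 60000, n_genes = 8, seed = seed))
  g <- sim$genome; led <- sim$ledger
  for (i in seq_along(baits)) {
    pf <- plant_feature(g, led, list(kind = "housekeeping",
                                     id = names(baits)[i],
                                     seq = baits[[i]], payload = names(baits)[i]))
    g <- pf$genome; led <- pf$ledger
  }
  b <- diverge(g, d, seed = child_seed(seed, 91))
  loci <- led[led$feature_kind == "housekeeping", , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    span <- loci[i, ]
    n_mut <- round(d * (span$end - span$start + 1))
    # restore the ancestral locus, then apply the controlled mutation count
    substr(b$contigs[[span$contig]], span$start, span$end) <-
      substring(g$contigs[[span$contig]], span$start, span$end)
    b <- mutate_region(b, span$contig, span$start, span$end, n_mut,
                       seed = child_seed(seed, 92 + i))
  }
  list(strain_a = g, strain_b = b, ledger = led, baits = baits, d = d)
}

#' @rdname preset_taxonomy
#' @export
preset_effectors <- function(seed = 1, n_background = 520, n_effectors = 20) {
  L <- (n_background + n_effectors) * 2400L + 10000L
  sim <- simulate_genome(simulation_params(
    n_contigs = 1, contig_length = L, n_genes = n_background, seed = seed))
  g <- sim$genome; led <- sim$ledger
  model <- hrp_box_model()
  with_seed(child_seed(seed, 7), {
    for (i in seq_len(n_effectors)) {
      nterm <- compliant_nterm()
      tail <- random_protein(250)
      cds <- back_translate(paste0(nterm, tail))
      spacer <- random_dna(16)
      b2 <- model$block2
      for (j in which(strsplit(b2, "")[[1]] == "N"))
        substr(b2, j, j) <- sample(DNA_BASES, 1)
      box <- paste0(model$block1, spacer, b2)
      strand <- sample(c("+", "-"), 1)
      pf <- plant_feature(g, led, list(
        kind = "effector", id = sprintf("eff%03d", i), seq = cds,
        strand = strand, box = list(seq = box, offset = 120L),
        payload = sprintf("eff%03d", i)))
      g <- pf$genome; led <- pf$ledger
    }
  })
  list(genome = g, ledger = led, model = model)
}

#' @rdname preset_taxonomy
#' @export
preset_clusters <- function(seed = 1, sizes = c(T2SS_xcp = 4),
                            bundle = default_bait_bundle()) {
  n_bg <- 30L
  L <- (n_bg + sum(sizes) + 4L) * 2400L
  sim <- simulate_genome(simulation_params(
    n_contigs = 1, contig_length = L, n_genes = n_bg, seed = seed))
  g <- sim$genome; led <- sim$ledger
  with_seed(child_seed(seed, 11), {
    for (lab in names(sizes)) {
      baits <- bundle[[lab]]$proteins
      for (i in seq_len(sizes[[lab]])) {
        prot <- mutate_protein(baits[[((i - 1) %% length(baits)) + 1]], 0.3)
        pf <- plant_feature(g, led, list(
          kind = "cluster_gene", id = sprintf("%s_m%02d", lab, i),
          seq = back_translate(prot), payload = lab))
        g <- pf$genome; led <- pf$ledger
      }
    }
  })
  list(genome = g, ledger = led, bundle = bundle, sizes = sizes)
}

# Proteome-level TBDP scenario: planted receptor-like proteins (derived from
# the baits) among unrelated decoys, with truth labels.
make_tbdp_proteome <- function(seed = 1, n_planted = 12, n_decoys = 40,
                               with_extension = integer()) {
  baits <- tbdp_baits()
  ex <- tbdp_exemplars()
  with_seed(seed, {
    planted <- vapply(seq_len(n_planted), function(i)
      mutate_protein(baits[[((i - 1) %% length(baits)) + 1]], 0.3), "")
    names(planted) <- sprintf("tb_planted%02d", seq_len(n_planted))
    for (i in with_extension)
      planted[i] <- paste0(substr(ex$long_form, 1, 70), planted[i])
    decoys <- stats::setNames(
      vapply(seq_len(n_decoys), function(i) random_protein(330), ""),
      sprintf("decoy%02d", seq_len(n_decoys)))
    list(proteome = c(planted, decoys),
         truth = names(planted), with_extension = names(planted)[with_extension])
  })
}
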