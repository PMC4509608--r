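#' Hrp/Rsp promoter box model
#'
#' Degenerate two-block promoter motif scanned upstream of start codons on
#' the coding strand: `block1 - spacer(15..17 nt) - block2`, with a
#' per-block mismatch budget ("N" positions in a block match anything and
#' never count as mismatches). The default consensus is a configurable
#' package assumption; the default mismatch budget is 0 per block, chosen
#' from the chance-hit calculus described in the methods vignette (a one-
#' mismatch budget admits roughly one false promoter per fifty genes, which
#' is incompatible with genome-wide effector counts in the low tens).
#'
#' @param block1,block2 Consensus blocks (IUPAC "N" = any base).
#' @param spacer Length-2 integer vector, min and max spacer length.
#' @param max_mismatch Length-2 integer vector, per-block mismatch budget.
#' @param promoter_window Scanned window upstream of the start codon, bp.
#' @return An object of class `hrp_box_model`.
#' @export
hrp_box_model <- function(block1 = "GGAACC", spacer = c(15L, 17L),
                          block2 = "CCACNNA", max_mismatch = c(0L, 0L),
                          promoter_window = 500L) {
  stopifnot(spacer[1] <= spacer[2], promoter_window > 0,
            all(max_mismatch >= 0))
  structure(list(block1 = toupper(block1), block2 = toupper(block2),
                 spacer = as.integer(spacer),
                 max_mismatch = as.integer(rep_len(max_mismatch, 2)),
                 promoter_window = as.integer(promoter_window)),
            class = "hrp_box_model")
}

# Mismatch counts of `block` at every start position of `window_chars`
# ("N" in the block matches anything).
block_mismatches <- function(window_chars, block) {
  bl <- strsplit(block, "")[[1]]
  w <- length(bl); n <- length(window_chars)
  if (n < w) return(integer())
  mm <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    if (bl[j] == "N") next
    mm <- mm + (window_chars[j:(n - w + j)] != bl[j])
  }
  mm
}

# Promoter window (coding strand, 5'->3', ending just before the start
# codon) for one gene; truncated at contig edges.
promoter_window_seq <- function(genome, gene_row, window) {
  L <- nchar(genome$contigs[[gene_row$contig]])
  if (gene_row$strand == "+") {
    s <- max(1L, gene_row$start - window); e <- gene_row$start - 1L
    if (e < s) return(list(seq = "", truncated = TRUE))
    list(seq = substring(genome$contigs[[gene_row$contig]], s, e),
         truncated = s > gene_row$start - window)
  } else {
    s <- gene_row$end + 1L; e <- min(L, gene_row$end + window)
    if (e < s) return(list(seq = "", truncated = TRUE))
    list(seq = revcomp(substring(genome$contigs[[gene_row$contig]], s, e)),
         truncated = e < gene_row$end + window)
  }
}

#' Scan promoters for Hrp/Rsp boxes
#'
#' Scans the promoter window of every gene (coding strand only) for
#' block1-spacer-block2 arrangements within the model's mismatch budget.
#'
#' @param genome An [annotated_genome()].
#' @param model A [hrp_box_model()].
#' @return data.frame with one row per hit: `gene_id`, `pos` (position of
#'   the first base of block1 relative to the start codon, e.g. -120),
#'   `mm1`, `mm2`, `spacer`, `truncated` (window clipped at a contig edge).
#' @export
scan_hrp_boxes <- function(genome, model = hrp_box_model()) {
  out <- list()
  w1 <- nchar(model$block1); w2 <- nchar(model$block2)
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    pw <- promoter_window_seq(genome, g, model$promoter_window)
    n <- nchar(pw$seq)
    if (n < w1 + model$spacer[1] + w2) next
    ch <- strsplit(pw$seq, "")[[1]]
    mm1 <- block_mismatches(ch, model$block1)
    cand <- which(mm1 <= model$max_mismatch[1])
    if (!length(cand)) next
    mm2 <- block_mismatches(ch, model$block2)
    for (p in cand) {
      for (sp in model$spacer[1]:model$spacer[2]) {
        q <- p + w1 + sp
        if (q > length(mm2)) next
        if (mm2[q] <= model$max_mismatch[2]) {
          out[[length(out) + 1L]] <- data.frame(
            gene_id = g$gene_id, pos = -(n - p + 1L),
            mm1 = mm1[p], mm2 = mm2[q], spacer = sp,
            truncated = pw$truncated, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), pos = integer(), mm1 = integer(),
                      mm2 = integer(), spacer = integer(), truncated = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' N-terminal composition features of a candidate effector
#'
#' Computes, over the first `min(50, length)` residues: the Ser fraction,
#' the polar fraction (polar set S,T,N,Q,G,P,C,Y), the count of acidic
#' residues (D/E) among the first 12 positions, and whether position 3 or 4
#' carries an aliphatic residue (I,L,V,A,P). Position 1 is the initiator
#' Met; indexing is 1-based on the translated protein.
#'
#' @param protein Protein sequence (length >= 12, standard residues).
#' @return An object of class `nterm_features` with fields `window`,
#'   `ser_frac`, `polar_frac`, `acidic_first12`, `aliphatic_pos34`.
#' @export
nterm_profile <- function(protein) {
  protein <- toupper(protein)
  if (nchar(protein) < 12) stop("protein shorter than 12 residues")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", protein))
    stop("protein contains non-amino-acid characters")
  w <- substr(protein, 1, min(50L, nchar(protein)))
  ch <- strsplit(w, "")[[1]]
  first12 <- ch[1:12]
  structure(list(
    window = w,
    ser_frac = mean(ch == "S"),
    polar_frac = mean(ch %in% c("S", "T", "N", "Q", "G", "P", "C", "Y")),
    acidic_first12 = sum(first12 %in% c("D", "E")),
    aliphatic_pos34 = any(ch[3:4] %in% c("I", "L", "V", "A", "P"))),
    class = "nterm_features")
}

#' Default thresholds for the effector N-terminal rules
#' @return Named list: `ser_min`, `polar_min`, `acidic_max`,
#'   `require_aliphatic`.
#' @export
effector_rules <- function(ser_min = 0.10, polar_min = 0.40, acidic_max = 1,
                           require_aliphatic = TRUE) {
  list(ser_min = ser_min, polar_min = polar_min, acidic_max = acidic_max,
       require_aliphatic = require_aliphatic)
}

#' Call type III effector candidates
#'
#' A gene is called when its promoter carries at least one Hrp/Rsp box AND
#' its N-terminus passes every enabled composition rule (Ser fraction,
#' polar fraction, few acidic residues among the first 12, aliphatic residue
#' at position 3 or 4). The per-rule pass/fail trail is retained so the
#' verdict is fully auditable. Genes whose translation contains internal
#' stops or is shorter than 12 residues are reported with NA features and
#' never called.
#'
#' @param genome An [annotated_genome()].
#' @param model A [hrp_box_model()].
#' @param rules Thresholds from [effector_rules()].
#' @return data.frame with one row per gene: box evidence, feature values,
#'   per-rule flags (`pass_box`, `pass_ser`, `pass_polar`, `pass_acidic`,
#'   `pass_aliphatic`) and `verdict`.
#' @export
call_effectors <- function(genome, model = hrp_box_model(),
                           rules = effector_rules()) {
  boxes <- scan_hrp_boxes(genome, model)
  prots <- proteome(genome)
  g <- genome$genes
  res <- lapply(seq_len(nrow(g)), function(i) {
    id <- g$gene_id[i]
    bx <- boxes[boxes$gene_id == id, , drop = FALSE]
    has_box <- nrow(bx) > 0
    p <- prots[[id]]
    feat <- if (!is.null(p) && nchar(p) >= 12 &&
                grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p))
      nterm_profile(p) else NULL
    if (is.null(feat)) {
      return(data.frame(gene_id = id, box_pos = if (has_box) bx$pos[1] else NA,
                        ser_frac = NA, polar_frac = NA, acidic_first12 = NA,
                        aliphatic_pos34 = NA, pass_box = has_box,
                        pass_ser = NA, pass_polar = NA, pass_acidic = NA,
                        pass_aliphatic = NA, verdict = FALSE,
                        stringsAsFactors = FALSE))
    }
    pass <- c(box = has_box,
              ser = feat$ser_frac >= rules$ser_min,
              polar = feat$polar_frac >= rules$polar_min,
              acidic = feat$acidic_first12 <= rules$acidic_max,
              aliphatic = !rules$require_aliphatic || feat$aliphatic_pos34)
    data.frame(gene_id = id, box_pos = if (has_box) bx$pos[1] else NA,
               ser_frac = feat$ser_frac, polar_frac = feat$polar_frac,
               acidic_first12 = feat$acidic_first12,
               aliphatic_pos34 = feat$aliphatic_pos34,
               pass_box = pass[["box"]], pass_ser = pass[["ser"]],
               pass_polar = pass[["polar"]], pass_acidic = pass[["acidic"]],
               pass_aliphatic = pass[["aliphatic"]], verdict = all(pass),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
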