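#' Identify TonB-dependent proteins (TBDPs) in a proteome
#'
#' Proteins whose best bait alignment passes `E <= e_max` and covers at
#' least `min_coverage` of the bait are recorded as TBDPs, one record per
#' protein.
#'
#' @param prots Named character vector of proteins (may be empty).
#' @param baits Named character vector of TBDP bait proteins (default: the
#'   shipped synthetic [tbdp_baits()]).
#' @param e_max Significance threshold (default 1e-5).
#' @param min_coverage Minimum fraction of the bait aligned (default 0.5).
#' @param scheme Protein [scoring_scheme()].
#' @return data.frame with `protein`, `bait`, `evalue`, `identity`,
#'   `coverage` (of the bait).
#' @export
identify_tbdps <- function(prots, baits = tbdp_baits(), e_max = 1e-5,
                           min_coverage = 0.5,
                           scheme = scoring_scheme("protein")) {
  stopifnot(length(baits) >= 1)
  prots <- as_named_seqs(prots)
  empty <- data.frame(protein = character(), bait = character(),
                      evalue = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (!length(prots)) return(empty)
  hits <- best_hits(prots, baits, scheme, e_max = e_max)
  hits <- hits[hits$target_coverage >= min_coverage, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  data.frame(protein = hits$query, bait = hits$target, evalue = hits$evalue,
             identity = hits$identity, coverage = hits$target_coverage,
             stringsAsFactors = FALSE)
}

#' Flag an N-terminal signaling extension on a TBDP
#'
#' TonB-dependent transducers carry a short N-terminal domain upstream of
#' the receptor body. The flag is true when the protein has at least
#' `min_extension` residues N-terminal of its best-hit span against the
#' short-form (body-only) exemplar, and those residues align to the
#' long-form exemplar's extension region at `min_identity` or better.
#'
#' @param protein Protein sequence.
#' @param exemplars A list with `short_form` and `long_form` sequences
#'   (default: the shipped synthetic [tbdp_exemplars()]).
#' @param min_extension Minimum unaligned N-terminal residues (default 50).
#' @param min_identity Percent identity required of the extension alignment
#'   (default 25).
#' @param scheme Protein [scoring_scheme()].
#' @return Logical flag.
#' @export
flag_signaling_extension <- function(protein, exemplars = tbdp_exemplars(),
                                     min_extension = 50, min_identity = 25,
                                     scheme = scoring_scheme("protein")) {
  body_hit <- align_local(protein, exemplars$short_form, scheme)
  nterm_len <- body_hit$query_span[["start"]] - 1L
  if (body_hit$raw_score <= 0 || nterm_len < min_extension) return(FALSE)
  # the long form's own extension: residues before its body match
  long_body <- align_local(exemplars$long_form, exemplars$short_form, scheme)
  ext_len <- long_body$query_span[["start"]] - 1L
  if (ext_len < 1) return(FALSE)
  ext_ref <- substr(exemplars$long_form, 1, ext_len)
  prefix <- substr(protein, 1, nterm_len)
  al <- align_local(prefix, ext_ref, scheme)
  al$raw_score > 0 && al$identity >= min_identity &&
    al$target_coverage >= 0.5
}

#' Assign ferric-pyoverdine receptor (FPV) clade membership
#'
#' All TBDPs are placed on a neighbor-joining tree together with the six
#' reference pyoverdine receptors (distances: 1 - fraction identity from
#' global protein alignments, so full-length architecture influences
#' placement). After midpoint rooting, the FPV clade is the smallest clade
#' containing all six references; TBDPs inside it are labelled FPV.
#'
#' @param tbdps Named character vector of TBDP protein sequences.
#' @param refs Named character vector of the six reference receptors
#'   (default: the shipped synthetic [fpv_refs()]).
#' @param scheme Protein [scoring_scheme()].
#' @return A list: `records` (data.frame `protein`, `clade`,
#'   `nearest_ref`), `tree` (the midpoint-rooted `phylo`).
#' @export
assign_fpv_clade <- function(tbdps, refs = fpv_refs(),
                             scheme = scoring_scheme("protein")) {
  tbdps <- as_named_seqs(tbdps); refs <- as_named_seqs(refs)
  if (length(refs) < 2) stop("configuration error: reference receptors missing")
  seqs <- c(tbdps, refs)
  if (length(seqs) < 4) stop("need at least 4 sequences for tree placement")
  if (any(duplicated(names(seqs)))) stop("duplicated sequence ids")
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_global(seqs[[i]], seqs[[j]], scheme)
    D[i, j] <- D[j, i] <- 1 - al$identity / 100
  }
  tree <- phangorn::midpoint(nj_tree(D))
  mrca <- ape::getMRCA(tree, names(refs))
  members <- ape::extract.clade(tree, mrca)$tip.label
  recs <- lapply(names(tbdps), function(id) {
    dref <- D[id, names(refs)]
    data.frame(protein = id,
               clade = if (id %in% members) "FPV" else "non-FPV",
               nearest_ref = names(refs)[which.min(dref)],
               stringsAsFactors = FALSE)
  })
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(protein = character(), clade = character(),
               nearest_ref = character(), stringsAsFactors = FALSE)
  list(records = records, tree = tree)
}
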