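#' Extract a housekeeping locus from a genome by bait alignment
#'
#' Locates the best-matching region of the genome against a locus bait
#' (seed-and-vote location followed by a bait-global alignment in the
#' candidate window; full local DP fallback when seeding finds nothing),
#' returns it reverse-complemented to bait orientation, and fails when the
#' best region does not reach the identity/coverage minima.
#'
#' @param genome An [annotated_genome()].
#' @param bait Locus reference nucleotide sequence.
#' @param locus_name Name used in error messages.
#' @param min_identity Minimum percent identity (default 70).
#' @param min_coverage Minimum fraction of the bait aligned (default 0.70).
#' @return A list: `seq` (extracted sequence, bait orientation), `contig`,
#'   `start`, `end`, `strand`, `identity`.
#' @export
extract_locus <- function(genome, bait, locus_name = "locus",
                          min_identity = 70, min_coverage = 0.70) {
  stopifnot(nzchar(bait))
  scheme <- scoring_scheme("nucleotide")
  idx <- ref_index(genome$contigs, k = 13L)
  loc <- seeded_locate(bait, idx)
  al <- NULL; strand <- "+"; win_off <- 0L; subj <- NULL
  if (!is.null(loc)) {
    subj_str <- if (loc$strand == "+") idx$fwd else idx$rc
    strand <- loc$strand
    len <- nchar(bait)
    ws <- max(1L, loc$diag - len %/% 5L)
    we <- min(nchar(subj_str), loc$diag + len + len %/% 5L)
    win_off <- ws - 1L
    al <- align_pair(bait, substr(subj_str, ws, we), scheme, "global-local",
                     locus_name, "genome")
  } else if (sum(nchar(genome$contigs)) <= 200000) {
    # small-genome fallback: full local DP on both strands of each contig
    best <- NULL
    for (cn in names(genome$contigs)) {
      for (st in c("+", "-")) {
        s <- if (st == "+") genome$contigs[[cn]] else revcomp(genome$contigs[[cn]])
        a <- align_local(bait, s, scheme, locus_name, cn)
        if (is.null(best) || a$raw_score > best$al$raw_score)
          best <- list(al = a, strand = st, contig = cn)
      }
    }
    if (!is.null(best) && best$al$identity >= min_identity &&
        best$al$query_coverage >= min_coverage) {
      a <- best$al
      return(list(seq = gsub("-", "", a$aligned_target), contig = best$contig,
                  start = a$target_span[["start"]], end = a$target_span[["end"]],
                  strand = best$strand, identity = a$identity))
    }
    al <- NULL
  }
  if (is.null(al) || al$identity < min_identity ||
      al$query_coverage < min_coverage)
    stop("locus missing: no qualifying hit for '", locus_name, "'")
  gs <- win_off + al$target_span[["start"]]
  ge <- win_off + al$target_span[["end"]]
  # map concatenated-string coordinates back to a contig
  if (strand == "-") { # position on the reverse-complemented concatenation
    gs2 <- idx$total - ge + 1L; ge2 <- idx$total - gs + 1L
    gs <- gs2; ge <- ge2
  }
  cp1 <- index_to_contig(idx, gs); cp2 <- index_to_contig(idx, ge)
  if (!identical(cp1$contig, cp2$contig))
    stop("locus missing: hit for '", locus_name, "' spans a contig boundary")
  list(seq = gsub("-", "", al$aligned_target), contig = cp1$contig,
       start = cp1$pos, end = cp2$pos, strand = strand,
       identity = al$identity)
}

#' Build an MLSA profile from a genome
#'
#' Extracts the four housekeeping loci (fixed order: 16S rRNA, gyrB, rpoB,
#' rpoD) with [extract_locus()] and concatenates them in that order.
#'
#' @param genome An [annotated_genome()] (or NULL when `loci` are given
#'   directly).
#' @param baits Named bait sequences in the fixed locus order (default:
#'   the shipped synthetic [mlsa_baits()]).
#' @param strain_id Strain identifier.
#' @param loci Optional pre-extracted named locus sequences (bypasses
#'   extraction).
#' @param ... Passed to [extract_locus()].
#' @return An object of class `mlsa_profile` with fields `strain_id`,
#'   `loci`, `concatenated`.
#' @export
mlsa_profile <- function(genome = NULL, baits = mlsa_baits(),
                         strain_id = "strain", loci = NULL, ...) {
  if (is.null(loci)) {
    stopifnot(inherits(genome, "annotated_genome"))
    loci <- lapply(seq_along(baits), function(i)
      extract_locus(genome, baits[[i]], names(baits)[i], ...)$seq)
    names(loci) <- names(baits)
  }
  loci <- lapply(loci, toupper)
  if (length(loci) != 4 || any(!nzchar(unlist(loci))))
    stop("MLSA profile requires all four loci")
  structure(list(strain_id = strain_id, loci = loci,
                 concatenated = paste(unlist(loci), collapse = "")),
            class = "mlsa_profile")
}

#' @export
print.mlsa_profile <- function(x, ...) {
  cat("<mlsa_profile>", x$strain_id, "-",
      paste(sprintf("%s(%d bp)", names(x$loci), nchar(unlist(x$loci))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise nucleotide identity of two MLSA profiles
#'
#' Each locus pair is globally aligned separately (so locus length
#' differences cannot shift columns across locus boundaries) and the NI is
#' 100 x identical columns / aligned columns pooled over the four loci.
#' Profiles are ordered canonically by strain id before alignment, making
#' the value exactly symmetric.
#'
#' @param p,q [mlsa_profile()] objects.
#' @return Percent nucleotide identity (NI).
#' @export
pairwise_ni <- function(p, q) {
  stopifnot(inherits(p, "mlsa_profile"), inherits(q, "mlsa_profile"))
  if (!identical(names(p$loci), names(q$loci))) stop("locus sets differ")
  if (p$strain_id > q$strain_id) { tmp <- p; p <- q; q <- tmp }
  scheme <- scoring_scheme("nucleotide")
  ident <- 0; cols <- 0
  for (ln in names(p$loci)) {
    al <- align_global(p$loci[[ln]], q$loci[[ln]], scheme, p$strain_id, q$strain_id)
    w <- nchar(al$aligned_query)
    ident <- ident + al$identity * w / 100
    cols <- cols + w
  }
  100 * ident / cols
}

#' MLSA species-boundary classification
#'
#' Strains are called the same species when their concatenated nucleotide
#' identity strictly exceeds the 97 percent MLSA species boundary; an NI at
#' or below the boundary is a distinct-species call (conspecificity must
#' exceed the boundary, the conservative reading for taxonomic claims).
#'
#' @param ni Percent nucleotide identity in \[0, 100\].
#' @param boundary Species boundary, percent (default 97).
#' @return "same_species" or "distinct_species".
#' @export
classify_mlsa <- function(ni, boundary = 97) {
  stopifnot(ni >= 0, ni <= 100)
  if (ni > boundary) "same_species" else "distinct_species"
}

#' Pairwise NI matrix over a set of MLSA profiles
#'
#' @param profiles List of [mlsa_profile()] objects.
#' @return Symmetric matrix of NI values (100 on the diagonal).
#' @export
ni_matrix <- function(profiles) {
  ids <- vapply(profiles, `[[`, "", "strain_id")
  n <- length(profiles)
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out[i, j] <- out[j, i] <- pairwise_ni(profiles[[i]], profiles[[j]])
  out
}

#' Distance matrix from MLSA profiles
#'
#' Plain p-distances `1 - NI/100` from per-locus global alignments, the
#' input for neighbor-joining.
#'
#' @param profiles List of [mlsa_profile()] objects.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mlsa_distances <- function(profiles) {
  1 - ni_matrix(profiles) / 100
}
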