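#' Bait set for trait mining
#'
#' A labelled bundle of bait proteins with the minimum bait-hit gene count
#' required to call a cluster of that system and the E-value threshold for
#' a significant bait hit.
#'
#' @param system_label System name (e.g. "T2SS_xcp", "T6SS",
#'   "OBL_serotype_01").
#' @param proteins Named character vector of bait protein sequences.
#' @param min_cluster_genes Minimum bait-hit genes for a called cluster
#'   (>= 1). Locus definitions: four or more for T2SS, five or more for
#'   T6SS; three (a flagged conservative default) for systems whose minimum
#'   is not fixed by the field.
#' @param e_max Bait-hit significance threshold (default 1e-5).
#' @return An object of class `bait_set`.
#' @export
bait_set <- function(system_label, proteins, min_cluster_genes = 3,
                     e_max = 1e-5) {
  stopifnot(min_cluster_genes >= 1, e_max > 0, length(proteins) >= 1)
  structure(list(system_label = system_label,
                 proteins = as_named_seqs(proteins),
                 min_cluster_genes = as.integer(min_cluster_genes),
                 e_max = e_max),
            class = "bait_set")
}

#' Reciprocal best-hit orthologs between two proteomes
#'
#' Two proteins are called orthologs when each is the other's best
#' similarity hit and both directions pass `E <= e_max` (the e-value < 1e-5
#' orthology rule).
#'
#' @param proteome_a,proteome_b Named character vectors of proteins.
#' @param scheme A protein [scoring_scheme()].
#' @param e_max E-value threshold for both directions.
#' @return data.frame with `gene_a`, `gene_b`, `e_forward`, `e_reverse`,
#'   `reciprocal` (always TRUE for returned rows).
#' @export
reciprocal_orthologs <- function(proteome_a, proteome_b,
                                 scheme = scoring_scheme("protein"),
                                 e_max = 1e-5) {
  proteome_a <- as_named_seqs(proteome_a)
  proteome_b <- as_named_seqs(proteome_b)
  if (!length(proteome_a) || !length(proteome_b)) stop("empty proteome")
  S <- score_matrix(proteome_a, proteome_b, scheme)
  na <- sum(nchar(proteome_a)); nb <- sum(nchar(proteome_b))
  ma <- nchar(proteome_a); mb <- nchar(proteome_b)
  best_ab <- apply(S, 1, which.max)
  best_ba <- apply(S, 2, which.max)
  rows <- list()
  for (i in seq_along(proteome_a)) {
    j <- best_ab[i]
    if (best_ba[j] != i) next
    ef <- evalue(S[i, j], ma[i], nb, scheme)
    er <- evalue(S[i, j], mb[j], na, scheme)
    if (ef <= e_max && er <= e_max)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = names(proteome_a)[i], gene_b = names(proteome_b)[j],
        e_forward = ef, e_reverse = er, reciprocal = TRUE,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_forward = numeric(), e_reverse = numeric(),
                      reciprocal = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Call bait-homologous gene clusters
#'
#' Genes with a significant bait hit (`E <= e_max`) are grouped when they
#' lie on the same contig separated by at most `max_intergenic_genes`
#' non-hit genes; a group is a called cluster of the bait set's system when
#' it contains at least `min_cluster_genes` members. Sub-threshold groups
#' are reported as candidates with verdict "not-called".
#'
#' @param genome An [annotated_genome()].
#' @param baits A [bait_set()].
#' @param max_intergenic_genes Maximum non-hit genes tolerated inside a
#'   cluster (default 5; configurable, clusters are local loci).
#' @param scheme Protein [scoring_scheme()].
#' @return A list of `gene_cluster` objects (fields: `system_label`,
#'   `members`, `bait_hits`, `contig`, `span`, `n_members`, `called`).
#' @export
call_clusters <- function(genome, baits, max_intergenic_genes = 5,
                          scheme = scoring_scheme("protein")) {
  prots <- proteome(genome)
  if (!length(prots)) return(list())
  prots <- prots[grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", prots)]
  if (!length(prots)) return(list())
  hits <- best_hits(prots, baits$proteins, scheme, e_max = baits$e_max)
  g <- genome$genes
  g$rank <- stats::ave(seq_len(nrow(g)), g$contig, FUN = seq_along)
  g <- g[g$gene_id %in% hits$query, , drop = FALSE]
  if (!nrow(g)) return(list())
  out <- list()
  for (cn in unique(g$contig)) {
    gc <- g[g$contig == cn, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    grp <- cumsum(c(1, diff(gc$rank) > max_intergenic_genes + 1))
    for (k in unique(grp)) {
      mem <- gc[grp == k, , drop = FALSE]
      bh <- hits[match(mem$gene_id, hits$query), "target"]
      out[[length(out) + 1L]] <- structure(list(
        system_label = baits$system_label,
        members = mem$gene_id,
        bait_hits = stats::setNames(bh, mem$gene_id),
        contig = cn,
        span = c(start = min(mem$start), end = max(mem$end)),
        n_members = nrow(mem),
        called = nrow(mem) >= baits$min_cluster_genes),
        class = "gene_cluster")
    }
  }
  out
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s %s:%d-%d, %d member(s), %s\n",
              x$system_label, x$contig, x$span[["start"]], x$span[["end"]],
              x$n_members, if (x$called) "called" else "not-called"))
  invisible(x)
}

#' Screen for O-antigen biosynthetic loci (OBL)
#'
#' Mines the genome with one bait set per reference serotype locus; a
#' cluster is called an OBL when it codes for more than four distinct bait
#' orthologs (strictly more than four). When conserved flanking-marker
#' baits (himD/wbpM orthologs) are supplied, their presence within or
#' adjacent to the cluster (within `marker_slack` genes) is annotated.
#'
#' @param genome An [annotated_genome()].
#' @param obl_sets Named list of serotype [bait_set()] objects.
#' @param markers Optional named character vector of flanking-marker bait
#'   proteins (e.g. himD, wbpM).
#' @param marker_slack Gene-rank slack for marker adjacency.
#' @param ... Passed to [call_clusters()].
#' @return List of called `gene_cluster` objects, each with
#'   `n_distinct_baits` and, when markers are given, `flanking_markers`.
#' @export
screen_obl <- function(genome, obl_sets, markers = NULL, marker_slack = 3,
                       ...) {
  out <- list()
  for (bs in obl_sets) {
    cl <- call_clusters(genome, bs, ...)
    for (x in cl) {
      x$n_distinct_baits <- length(unique(x$bait_hits))
      x$called <- x$n_distinct_baits > 4
      if (!x$called) next
      if (!is.null(markers)) {
        mh <- best_hits(proteome(genome), markers,
                        scoring_scheme("protein"), e_max = bs$e_max)
        g <- genome$genes
        near <- g$gene_id[g$contig == x$contig &
                            g$start >= x$span[["start"]] - marker_slack * 1500 &
                            g$end <= x$span[["end"]] + marker_slack * 1500]
        x$flanking_markers <- unique(mh$target[mh$query %in% near])
      }
      out[[length(out) + 1L]] <- x
    }
  }
  out
}

#' Count proteins tagged by a domain exemplar
#'
#' Alignment-to-exemplar domain detection (in place of profile HMMs):
#' a protein is counted when its best local alignment to any exemplar
#' reaches `min_identity` percent identity over at least `min_coverage` of
#' the exemplar, with an optional positional constraint (e.g. the T5a
#' translocator domain must sit at the C-terminus).
#'
#' @param prots Named character vector of proteins.
#' @param exemplars Named character vector of domain exemplar sequences.
#' @param label Domain label for the report.
#' @param min_identity Percent identity threshold (default 25).
#' @param min_coverage Exemplar coverage threshold (default 0.60).
#' @param position "any", "cterm" or "nterm".
#' @param terminal_slack Residues of slack allowed between the domain hit
#'   and the enforced terminus.
#' @param scheme Protein [scoring_scheme()].
#' @return A list: `label`, `count`, `ids`, `table` (per-protein evidence).
#' @export
count_domain_tagged <- function(prots, exemplars, label = "domain",
                                min_identity = 25, min_coverage = 0.60,
                                position = c("any", "cterm", "nterm"),
                                terminal_slack = 30,
                                scheme = scoring_scheme("protein")) {
  position <- match.arg(position)
  prots <- as_named_seqs(prots); exemplars <- as_named_seqs(exemplars)
  rows <- list()
  for (i in seq_along(prots)) {
    best <- NULL
    for (j in seq_along(exemplars)) {
      al <- align_local(prots[[i]], exemplars[[j]], scheme,
                        names(prots)[i], names(exemplars)[j])
      if (is.null(best) || al$raw_score > best$raw_score) best <- al
    }
    ok <- best$identity >= min_identity && best$target_coverage >= min_coverage
    if (ok && position == "cterm")
      ok <- nchar(prots[[i]]) - best$query_span[["end"]] <= terminal_slack
    if (ok && position == "nterm")
      ok <- best$query_span[["start"]] - 1 <= terminal_slack
    if (ok)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = names(prots)[i], exemplar = best$target_id,
        identity = best$identity, coverage = best$target_coverage,
        hit_start = best$query_span[["start"]],
        hit_end = best$query_span[["end"]], stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), exemplar = character(),
               identity = numeric(), coverage = numeric(),
               hit_start = integer(), hit_end = integer(),
               stringsAsFactors = FALSE)
  list(label = label, count = nrow(tab), ids = tab$protein, table = tab)
}

#' Pair two-partner secretion substrates (TpsA) with transporters (TpsB)
#'
#' TpsA/TpsB genes are paired when they lie on the same contig and strand
#' with at most `max_intervening` genes between them (operon adjacency).
#' TpsB transporters with no pairable substrate are flagged stand-alone;
#' unpaired TpsA are likewise reported.
#'
#' @param genome An [annotated_genome()].
#' @param tpsB_ids,tpsA_ids Gene ids of domain-tagged TpsB / TpsA hits.
#' @param max_intervening Maximum genes between the pair (default 2).
#' @return data.frame with `gene_id`, `role` ("TpsA"/"TpsB"), `partner`
#'   (NA when unpaired), `status` ("paired" or "stand-alone").
#' @export
pair_tps <- function(genome, tpsB_ids, tpsA_ids, max_intervening = 2) {
  g <- genome$genes
  g$rank <- stats::ave(seq_len(nrow(g)), g$contig, FUN = seq_along)
  info <- function(id) g[g$gene_id == id, , drop = FALSE]
  partner_of <- stats::setNames(rep(NA_character_, length(tpsB_ids)), tpsB_ids)
  taken <- character()
  for (b in tpsB_ids) {
    gb <- info(b)
    if (!nrow(gb)) next
    cand <- setdiff(tpsA_ids, taken)
    for (a in cand) {
      ga <- info(a)
      if (!nrow(ga)) next
      if (identical(ga$contig, gb$contig) && identical(ga$strand, gb$strand) &&
          abs(ga$rank - gb$rank) <= max_intervening + 1) {
        partner_of[b] <- a; taken <- c(taken, a); break
      }
    }
  }
  rows_b <- data.frame(gene_id = tpsB_ids, role = "TpsB",
                       partner = unname(partner_of),
                       status = ifelse(is.na(partner_of), "stand-alone", "paired"),
                       stringsAsFactors = FALSE)
  back <- stats::setNames(names(partner_of), partner_of)
  rows_a <- data.frame(gene_id = tpsA_ids, role = "TpsA",
                       partner = unname(back[tpsA_ids]),
                       status = ifelse(tpsA_ids %in% partner_of, "paired",
                                       "stand-alone"),
                       stringsAsFactors = FALSE)
  rbind(rows_b, rows_a)
}
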