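#' Pairwise sequence alignment
#'
#' Optimal global (Needleman-Wunsch) and local (Smith-Waterman) alignment
#' with affine gap penalties, computed via the dynamic-programming engine in
#' Biostrings. Results carry the raw score, percent identity over aligned
#' columns (gap columns count against identity), query/target coverage, the
#' aligned spans and an approximate Karlin-Altschul E-value computed with
#' `m = length(a)`, `n = length(b)`.
#'
#' Tie-breaking among co-optimal alignments follows the engine's
#' deterministic traceback, so identical inputs always yield identical
#' output.
#'
#' @param a,b Sequences (single character strings) in the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param query_id,target_id Optional sequence identifiers.
#' @return An object of class `pairwise_alignment` with fields
#'   `query_id`, `target_id`, `aligned_query`, `aligned_target`, `raw_score`,
#'   `identity` (percent), `query_coverage`, `target_coverage`, `evalue`,
#'   `query_span`, `target_span` (1-based inclusive starts/ends).
#' @export
align_global <- function(a, b, scheme = scoring_scheme("nucleotide"),
                         query_id = "query", target_id = "target") {
  align_pair(a, b, scheme, "global", query_id, target_id)
}

#' @rdname align_global
#' @export
align_local <- function(a, b, scheme = scoring_scheme("nucleotide"),
                        query_id = "query", target_id = "target") {
  align_pair(a, b, scheme, "local", query_id, target_id)
}

check_alphabet <- function(x, mode) {
  ok <- if (mode == "nucleotide") grepl("^[ACGTNacgtn]+$", x)
        else grepl("^[ACDEFGHIKLMNPQRSTVWYXacdefghiklmnpqrstvwyx]+$", x)
  if (!all(nzchar(x))) stop("empty sequence")
  if (!all(ok)) stop("sequence contains characters outside the ", mode, " alphabet")
  invisible(TRUE)
}

subst_matrix <- function(scheme) {
  if (scheme$mode == "protein") {
    get(data(list = scheme$matrix, package = "Biostrings",
             envir = environment()), envir = environment())
  } else {
    Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                             mismatch = scheme$mismatch,
                                             baseOnly = FALSE)
  }
}

as_xstring <- function(x, mode) {
  if (mode == "protein") Biostrings::AAString(toupper(x))
  else Biostrings::DNAString(toupper(x))
}

align_pair <- function(a, b, scheme, type, query_id, target_id) {
  check_alphabet(a, scheme$mode); check_alphabet(b, scheme$mode)
  pa <- Biostrings::pairwiseAlignment(
    as_xstring(a, scheme$mode), as_xstring(b, scheme$mode),
    substitutionMatrix = subst_matrix(scheme),
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend,
    type = type)
  wrap_alignment(pa, nchar(a), nchar(b), scheme, query_id, target_id)
}

wrap_alignment <- function(pa, m, n, scheme, query_id, target_id) {
  aq <- as.character(Biostrings::pattern(pa))
  at <- as.character(Biostrings::subject(pa))
  s <- Biostrings::score(pa)
  if (nzchar(aq)) {
    ids <- 100 * str_matches(aq, at) / nchar(aq)
    qs <- Biostrings::start(Biostrings::pattern(pa))
    qe <- Biostrings::end(Biostrings::pattern(pa))
    ts <- Biostrings::start(Biostrings::subject(pa))
    te <- Biostrings::end(Biostrings::subject(pa))
  } else { # empty local alignment
    ids <- 0; qs <- qe <- ts <- te <- 0L; s <- max(0, s)
  }
  structure(list(
    query_id = query_id, target_id = target_id,
    aligned_query = aq, aligned_target = at,
    raw_score = s, identity = ids,
    query_coverage = if (qe >= qs && qs > 0) (qe - qs + 1) / m else 0,
    target_coverage = if (te >= ts && ts > 0) (te - ts + 1) / n else 0,
    evalue = evalue(s, m, n, scheme),
    query_span = c(start = qs, end = qe),
    target_span = c(start = ts, end = te)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s\n  score %.1f  identity %.1f%%  E %.3g\n",
              x$query_id, x$target_id, x$raw_score, x$identity, x$evalue))
  invisible(x)
}

# Score matrix (local alignment by default) between two named sequence sets,
# batched per target for speed. Rows = queries, cols = targets.
score_matrix <- function(queries, targets, scheme, type = "local") {
  qs <- if (scheme$mode == "protein") Biostrings::AAStringSet(toupper(queries))
        else Biostrings::DNAStringSet(toupper(queries))
  sm <- subst_matrix(scheme)
  out <- matrix(NA_real_, length(queries), length(targets),
                dimnames = list(names(queries), names(targets)))
  for (j in seq_along(targets)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      qs, as_xstring(targets[[j]], scheme$mode),
      substitutionMatrix = sm,
      gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend,
      type = type, scoreOnly = TRUE)
  }
  out
}

#' Best similarity hit per query
#'
#' For each query sequence, finds the highest-scoring local alignment among
#' the targets whose E-value (against the whole target set, i.e.
#' `n = sum(nchar(targets))`) passes `e_max`. Ties are broken by earlier
#' target in input order, then lexicographic target id.
#'
#' @param queries,targets Named character vectors of sequences.
#' @param scheme A [scoring_scheme()].
#' @param e_max E-value threshold; hits with `E > e_max` are discarded.
#' @return A data.frame with one row per query that has a qualifying hit:
#'   `query`, `target`, `score`, `evalue`, `identity`, `query_coverage`,
#'   `target_coverage`, `query_start`, `query_end`, `target_start`,
#'   `target_end`.
#' @export
best_hits <- function(queries, targets, scheme = scoring_scheme("protein"),
                      e_max = 1e-5) {
  queries <- as_named_seqs(queries); targets <- as_named_seqs(targets)
  if (!length(queries) || !length(targets)) stop("empty sequence set")
  S <- score_matrix(queries, targets, scheme)
  n_db <- sum(nchar(targets))
  m <- nchar(queries)
  rows <- list()
  ord <- order(seq_along(targets), names(targets)) # input order, id as tiebreak key
  for (i in seq_along(queries)) {
    E <- evalue_vec(S[i, ], m[i], n_db, scheme)
    ok <- which(E <= e_max)
    if (!length(ok)) next
    best <- ok[order(-S[i, ok], ord[ok])][1]
    al <- align_local(queries[[i]], targets[[best]], scheme,
                      names(queries)[i], names(targets)[best])
    rows[[length(rows) + 1L]] <- data.frame(
      query = names(queries)[i], target = names(targets)[best],
      score = S[i, best], evalue = E[best], identity = al$identity,
      query_coverage = al$query_coverage, target_coverage = al$target_coverage,
      query_start = al$query_span[["start"]], query_end = al$query_span[["end"]],
      target_start = al$target_span[["start"]], target_end = al$target_span[["end"]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query = character(), target = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), query_coverage = numeric(),
                      target_coverage = numeric(),
                      query_start = integer(), query_end = integer(),
                      target_start = integer(), target_end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

evalue_vec <- function(S, m, n, scheme) {
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * S)
}

as_named_seqs <- function(x) {
  nm <- names(x)
  x <- as.character(x) # drops names
  if (!is.null(nm) && length(nm) == length(x)) names(x) <- nm
  if (is.null(names(x)) && length(x))
    names(x) <- paste0("seq", seq_along(x))
  x
}

#' Export alignment hits as a 12-column tab-separated table
#'
#' Standard hit-table layout: query, target, percent identity, alignment
#' length, mismatches, gap openings, query start/end, target start/end,
#' E-value, bit-like raw score.
#'
#' @param hits A list of `pairwise_alignment` objects.
#' @param path Output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  rows <- lapply(hits, function(h) {
    len <- nchar(h$aligned_query)
    gaps <- sum(strsplit(h$aligned_query, "")[[1]] == "-") +
      sum(strsplit(h$aligned_target, "")[[1]] == "-")
    matches <- if (len) round(h$identity * len / 100) else 0
    data.frame(query = h$query_id, target = h$target_id,
               identity = round(h$identity, 2), length = len,
               mismatches = len - matches - gaps, gaps = gaps,
               q_start = h$query_span[["start"]], q_end = h$query_span[["end"]],
               t_start = h$target_span[["start"]], t_end = h$target_span[["end"]],
               evalue = signif(h$evalue, 3), score = h$raw_score,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- k-mer seeded location of near-identical regions (genome scale) ----

# Concatenate contigs (N-spacer) into one searchable string per strand and
# index every k-mer. Used by the seeded ANIb mode and locus extraction.
ref_index <- function(contigs, k = 13) {
  spacer <- strrep("N", k)
  fwd <- paste(contigs, collapse = spacer)
  offs <- cumsum(c(1, head(nchar(contigs) + k, -1)))
  idx_str <- function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1), k:L)
  }
  rc <- revcomp(fwd)
  list(k = k, fwd = fwd, rc = rc,
       kmers_fwd = idx_str(fwd), kmers_rc = idx_str(rc),
       contig = names(contigs), offset = offs, lengths = nchar(contigs),
       total = nchar(fwd))
}

# Map a position in the concatenated forward string back to (contig, pos).
index_to_contig <- function(index, pos) {
  i <- findInterval(pos, index$offset)
  list(contig = index$contig[i], pos = pos - index$offset[i] + 1L)
}

# Locate `query` in the indexed reference by seed-and-vote: sample k-mers of
# the query, look them up on both strands, and take the modal diagonal. A
# minimum number of concordant votes is demanded (2 for strided seeding, 3
# after dense seeding) so isolated chance k-mer matches between unrelated
# sequences never nominate a diagonal. Returns NULL when no diagonal earns
# enough support.
seeded_locate <- function(query, index, stride = 48L, min_votes = 2L,
                          min_votes_dense = 3L) {
  k <- index$k
  L <- nchar(query)
  if (L < k) return(NULL)
  vote <- function(starts) {
    seeds <- substring(query, starts, starts + k - 1L)
    hit_f <- match(seeds, index$kmers_fwd)
    hit_r <- match(seeds, index$kmers_rc)
    diag_f <- hit_f - starts + 1L
    diag_r <- hit_r - starts + 1L
    list(f = diag_f[!is.na(diag_f)], r = diag_r[!is.na(diag_r)])
  }
  pick <- function(v, need) {
    top <- function(d) if (length(d)) sort(table(d), decreasing = TRUE)[1] else NULL
    tf <- top(v$f); tr <- top(v$r)
    use_rc <- is.null(tf) || (!is.null(tr) && tr > tf)
    d <- if (use_rc) tr else tf
    if (is.null(d) || as.integer(d) < need) return(NULL)
    list(strand = if (use_rc) "-" else "+",
         diag = as.integer(names(d)), votes = as.integer(d))
  }
  res <- pick(vote(seq(1L, L - k + 1L, by = stride)), min_votes)
  if (is.null(res)) # dense pass: non-overlapping seeds keep votes independent
    res <- pick(vote(seq(1L, L - k + 1L, by = k)), min_votes_dense)
  res
}
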