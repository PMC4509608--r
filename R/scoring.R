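#' Scoring schemes for pairwise alignment and E-value statistics
#'
#' A scoring scheme bundles the substitution scores, affine gap penalties and
#' the Karlin-Altschul constants (K, lambda) used to convert raw local
#' alignment scores into E-values. Defaults follow common similarity-search
#' practice: BLOSUM62 with gap open -11 / extend -1 for proteins, and
#' match +2 / mismatch -3 with gap open -5 / extend -2 for nucleotides, so
#' thresholds such as E < 1e-5 behave familiarly.
#'
#' Karlin-Altschul constants are looked up from a small shipped table for
#' the known (scores, gap) combinations; for other combinations the mode's
#' default constants are used and the resulting E-values are approximate
#' (they remain exactly monotone in score and linear in search space, which
#' is what the thresholding procedures rely on).
#'
#' @param mode "nucleotide" or "protein".
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein mode).
#' @param matrix Protein substitution matrix name (only "BLOSUM62" ships).
#' @param gap_open,gap_extend Gap penalties as (non-positive) scores; a gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @param karlin_K,karlin_lambda Optional overrides for the E-value
#'   constants; both must be positive.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 2, mismatch = -3,
                           matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           karlin_K = NULL, karlin_lambda = NULL) {
  mode <- match.arg(mode)
  if (is.null(gap_open)) gap_open <- if (mode == "protein") -11 else -5
  if (is.null(gap_extend)) gap_extend <- if (mode == "protein") -1 else -2
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be supplied as scores (<= 0)")
  kl <- karlin_constants(mode, match, mismatch, matrix, gap_open, gap_extend)
  if (!is.null(karlin_K)) kl$K <- karlin_K
  if (!is.null(karlin_lambda)) kl$lambda <- karlin_lambda
  if (kl$K <= 0 || kl$lambda <= 0) stop("karlin_K and karlin_lambda must be > 0")
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 karlin_K = kl$K, karlin_lambda = kl$lambda),
            class = "scoring_scheme")
}

# Shipped Karlin-Altschul constants (gapped values from standard
# similarity-search statistics; the 1/-1 entry is the ungapped closed form
# lambda = ln 3).
karlin_constants <- function(mode, match, mismatch, matrix, gap_open, gap_extend) {
  if (mode == "protein") return(list(K = 0.041, lambda = 0.267))
  if (match == 2 && mismatch == -3) return(list(K = 0.41, lambda = 0.625))
  if (match == 1 && mismatch == -1) return(list(K = 0.333, lambda = log(3)))
  list(K = 0.41, lambda = 0.625)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>", x$mode, "\n")
  if (x$mode == "nucleotide")
    cat("  match", x$match, "mismatch", x$mismatch, "\n")
  else cat("  matrix", x$matrix, "\n")
  cat("  gap open", x$gap_open, "extend", x$gap_extend,
      "| K", x$karlin_K, "lambda", x$karlin_lambda, "\n")
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments with score at least `S` when
#' searching a query of length `m` against a database of total length `n`:
#' `E = K * m * n * exp(-lambda * S)`. Monotone decreasing in S and linear
#' in m and n.
#'
#' @param S Raw alignment score.
#' @param m Query length (>= 1).
#' @param n Database (total target) length (>= 1).
#' @param scheme A [scoring_scheme()] supplying K and lambda.
#' @return The E-value (non-negative scalar).
#' @export
evalue <- function(S, m, n, scheme) {
  stopifnot(is.finite(S), m >= 1, n >= 1)
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * S)
}
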