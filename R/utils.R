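# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons; the background gene model draws codons uniformly
# from this set.
sense_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never clobbers user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_cds <- function(x) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Amino-acid frequencies implied by uniform sense-codon usage.
codon_uniform_aa_freq <- function() {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(sense_codons())))
  tab <- table(aa)
  as.numeric(tab) / sum(tab) -> p
  stats::setNames(p, names(tab))
}

random_protein <- function(n, seed = NULL) {
  gen <- function() {
    f <- codon_uniform_aa_freq()
    paste(sample(names(f), n, replace = TRUE, prob = f), collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Random coding sequence: ATG + uniform sense codons + stop. `len` in bp,
# multiple of 3, >= 9.
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  body <- sample(sense_codons()[-which(sense_codons() == "ATG")],
                 len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# Back-translate a protein into a CDS using one deterministic codon per
# amino acid (no stop appended unless add_stop).
back_translate <- function(protein, add_stop = TRUE) {
  codons <- sense_codons()
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(codons)))
  pick <- vapply(split(codons, aa), `[`, "", 1L)
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(chars, names(pick))
  if (length(bad)) stop("cannot back-translate residues: ", paste(bad, collapse = ","))
  out <- paste(pick[chars], collapse = "")
  if (add_stop) paste0(out, "TAA") else out
}

# Fast per-position comparison of two equal-length strings.
str_matches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra == rb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
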