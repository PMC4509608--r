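#' NRPS domain string
#'
#' Validated, ordered domain annotation of one NRPS protein. Allowed domain
#' labels: C (condensation), A (adenylation), T (thiolation), E
#' (epimerization), TE (thioesterase). Spans are residue coordinates,
#' 1-based inclusive, non-overlapping and ordered.
#'
#' @param protein_id Protein identifier.
#' @param domains data.frame with columns `domain`, `start`, `end`.
#' @return An object of class `nrps_domain_string`.
#' @export
nrps_domain_string <- function(protein_id, domains) {
  stopifnot(all(c("domain", "start", "end") %in% names(domains)))
  if (!all(domains$domain %in% c("C", "A", "T", "E", "TE")))
    stop("invalid domain label(s): ",
         paste(setdiff(domains$domain, c("C", "A", "T", "E", "TE")),
               collapse = ","))
  domains <- domains[order(domains$start), , drop = FALSE]
  if (nrow(domains) > 1 &&
      any(domains$start[-1] <= domains$end[-nrow(domains)]))
    stop("overlapping domain spans in ", protein_id)
  rownames(domains) <- NULL
  structure(list(protein_id = protein_id, domains = domains),
            class = "nrps_domain_string")
}

#' Parse an NRPS domain annotation table
#'
#' Primary input is a precomputed domain annotation (protein, domain,
#' start, end). A motif fallback locates A domains by repeated local
#' alignment against the reference A-domain exemplar when no annotation is
#' available (approximate; annotation input is preferred).
#'
#' @param annotation data.frame with columns `protein`, `domain`, `start`,
#'   `end`; or NULL to use the fallback.
#' @param proteins Named protein sequences (fallback mode, and residue
#'   prediction).
#' @param reference Reference A-domain sequence for the fallback.
#' @param min_identity Fallback A-domain detection threshold (percent).
#' @return A named list of [nrps_domain_string()] objects.
#' @export
parse_domain_string <- function(annotation = NULL, proteins = NULL,
                                reference = nrps_reference()$a_domain,
                                min_identity = 40) {
  if (!is.null(annotation)) {
    stopifnot(all(c("protein", "domain", "start", "end") %in% names(annotation)))
    sp <- split(annotation, annotation$protein)
    out <- lapply(names(sp), function(p)
      nrps_domain_string(p, sp[[p]][, c("domain", "start", "end")]))
    names(out) <- names(sp)
    return(out[unique(annotation$protein)])
  }
  stopifnot(!is.null(proteins))
  proteins <- as_named_seqs(proteins)
  scheme <- scoring_scheme("protein")
  out <- lapply(names(proteins), function(pn) {
    p <- proteins[[pn]]
    doms <- data.frame(domain = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
    masked <- p
    repeat {
      al <- align_local(masked, reference, scheme)
      if (al$raw_score <= 0 || al$identity < min_identity ||
          al$target_coverage < 0.6) break
      s <- al$query_span[["start"]]; e <- al$query_span[["end"]]
      doms <- rbind(doms, data.frame(domain = "A", start = s, end = e,
                                     stringsAsFactors = FALSE))
      substr(masked, s, e) <- strrep("X", e - s + 1L)
    }
    nrps_domain_string(pn, doms)
  })
  stats::setNames(out, names(proteins))
}

#' Cut NRPS domain strings into modules
#'
#' Domains are concatenated in the given protein order and cut at each C
#' domain boundary; each module collects its following A, T and optional E
#' domain, and a terminal TE closes the assembly. A leading segment before
#' the first C that carries an A domain is the initiation module. Modules
#' with zero or multiple A domains raise a structural warning and are
#' skipped from the peptide.
#'
#' @param domain_strings Named list of [nrps_domain_string()] objects.
#' @param protein_order Character vector giving the assembly-line order of
#'   the proteins (default: list order).
#' @return An object of class `nrps_assembly`: `modules` (list with
#'   `index`, `protein`, `domains`, `a_start`, `a_end`, `epimerized`,
#'   `valid`), `protein_order`, `has_te`.
#' @export
modularize <- function(domain_strings, protein_order = names(domain_strings)) {
  if (!length(domain_strings))
    return(structure(list(modules = list(), protein_order = character(),
                          has_te = FALSE), class = "nrps_assembly"))
  flat <- do.call(rbind, lapply(protein_order, function(p) {
    ds <- domain_strings[[p]]
    if (is.null(ds)) return(NULL)
    if (!nrow(ds$domains)) return(NULL)
    cbind(protein = p, ds$domains, stringsAsFactors = FALSE)
  }))
  if (is.null(flat) || !nrow(flat))
    return(structure(list(modules = list(), protein_order = protein_order,
                          has_te = FALSE), class = "nrps_assembly"))
  cut_at <- which(flat$domain == "C")
  starts <- if (length(cut_at) && cut_at[1] == 1) cut_at else c(1L, cut_at)
  ends <- c(starts[-1] - 1L, nrow(flat))
  modules <- list()
  idx <- 0L
  for (s in seq_along(starts)) {
    seg <- flat[starts[s]:ends[s], , drop = FALSE]
    a_rows <- which(seg$domain == "A")
    # terminal TE-only segments (no A) are release machinery, not a module
    if (!length(a_rows) && all(seg$domain %in% c("TE", "T", "E"))) next
    idx <- idx + 1L
    valid <- length(a_rows) == 1
    if (!valid)
      warning("structural warning: module ", idx, " has ", length(a_rows),
              " A domains; skipped from peptide")
    modules[[idx]] <- list(
      index = idx,
      protein = seg$protein[1],
      domains = seg$domain,
      a_start = if (valid) seg$start[a_rows] else NA_integer_,
      a_end = if (valid) seg$end[a_rows] else NA_integer_,
      epimerized = "E" %in% seg$domain,
      valid = valid)
  }
  structure(list(modules = modules, protein_order = protein_order,
                 has_te = "TE" %in% flat$domain),
            class = "nrps_assembly")
}

#' @export
print.nrps_assembly <- function(x, ...) {
  cat(sprintf("<nrps_assembly> %d module(s) over %d protein(s)%s\n",
              length(x$modules), length(x$protein_order),
              if (x$has_te) ", TE-terminated" else ""))
  for (m in x$modules)
    cat(sprintf("  module %d [%s]: %s%s\n", m$index, m$protein,
                paste(m$domains, collapse = "-"),
                if (m$epimerized) "  (epimerized)" else ""))
  invisible(x)
}

#' Shipped A-domain reference and substrate signature table
#'
#' `nrps_reference()` returns the synthetic reference A-domain (240
#' residues), the fixed positions of the ten pocket-lining signature
#' residues (relative to the reference), and synthetic C/T/E/TE domain
#' exemplars used by the assembly generator. `nrps_signature_table()` maps
#' ten-residue signature codes to substrate residues for the amino acids of
#' the fluorescent-Pseudomonas pyoverdines (Ser, Lys, Gly, Orn) plus common
#' decoys. Both are synthetic, deterministic stand-ins for curated
#' references; substitute curated tables for real annotations.
#'
#' @return `nrps_reference()`: list with `a_domain`, `signature_positions`,
#'   `exemplars`. `nrps_signature_table()`: data.frame `code`, `residue`.
#' @export
nrps_reference <- function() {
  with_seed(60001, {
    a_domain <- random_protein(240)
    positions <- sort(sample(20:220, 10))
    exemplars <- list(C = random_protein(120), T = random_protein(80),
                      E = random_protein(150), TE = random_protein(90))
    list(a_domain = a_domain, signature_positions = positions,
         exemplars = exemplars)
  })
}

#' @rdname nrps_reference
#' @export
nrps_signature_table <- function() {
  residues <- c("Ser", "Lys", "Gly", "Orn", "Ala", "Thr", "Asp", "Glu",
                "Leu", "Val")
  with_seed(60002, {
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    codes <- vapply(residues, function(r)
      paste(sample(aa20, 10, replace = TRUE), collapse = ""), "")
    data.frame(code = unname(codes), residue = residues,
               stringsAsFactors = FALSE)
  })
}

# A-domain carrying the signature code of `residue` at the reference
# signature positions.
a_domain_for <- function(residue, ref = nrps_reference(),
                         table = nrps_signature_table()) {
  code <- table$code[table$residue == residue]
  if (!length(code)) stop("no signature code for residue ", residue)
  a <- ref$a_domain
  ch <- strsplit(code, "")[[1]]
  for (k in seq_along(ref$signature_positions))
    substr(a, ref$signature_positions[k], ref$signature_positions[k]) <- ch[k]
  a
}

#' Predict the substrate residue of an adenylation domain
#'
#' Globally aligns the A-domain sequence to the reference A-domain, reads
#' the residues at the ten signature positions (fixed relative to the
#' reference), and looks the ten-residue code up in the signature table:
#' exact match first, else the nearest code by Hamming distance (distance
#' reported; ties resolved to the first table entry).
#'
#' @param a_seq A-domain sequence.
#' @param ref Reference bundle from [nrps_reference()].
#' @param table Signature table from [nrps_signature_table()].
#' @param scheme Protein [scoring_scheme()].
#' @return A list: `residue`, `code`, `distance` (Hamming), `exact`.
#' @export
predict_residue <- function(a_seq, ref = nrps_reference(),
                            table = nrps_signature_table(),
                            scheme = scoring_scheme("protein")) {
  stopifnot(nrow(table) >= 1)
  al <- align_global(a_seq, ref$a_domain, scheme)
  if (al$target_coverage < 0.6 ||
      (nchar(gsub("-", "", al$aligned_target)) / nchar(ref$a_domain)) < 0.6)
    stop("low-confidence: A-domain alignment covers < 60% of the reference")
  # walk the alignment; record query residues at reference signature positions
  qc <- strsplit(al$aligned_query, "")[[1]]
  tc <- strsplit(al$aligned_target, "")[[1]]
  ref_pos <- cumsum(tc != "-")
  code <- vapply(ref$signature_positions, function(p) {
    col <- which(ref_pos == p & tc != "-")[1]
    if (is.na(col)) "-" else qc[col]
  }, "")
  code <- paste(code, collapse = "")
  hd <- vapply(table$code, function(tcode)
    sum(strsplit(tcode, "")[[1]] != strsplit(code, "")[[1]]), 0)
  best <- which.min(hd)
  list(residue = table$residue[best], code = code,
       distance = unname(hd[best]), exact = hd[best] == 0)
}

#' Predict the NRPS peptide chain with stereochemistry
#'
#' One residue per valid module (via [predict_residue()] on the module's A
#' domain); the configuration is D where the module carries an E domain
#' (with `dual_ce = TRUE`, an E in the next module's leading C/E pair also
#' epimerizes the current residue), else L.
#'
#' @param assembly An [modularize()] result.
#' @param proteins Named protein sequences of the assembly line.
#' @param ref,table Reference bundle and signature table.
#' @param dual_ce Attribute a downstream dual C/E domain to the preceding
#'   module (default FALSE).
#' @return data.frame `position`, `residue`, `configuration`; attribute
#'   `peptide` holds the formatted chain (e.g.
#'   "Ser-Lys-Gly-Orn-Lys-D-Orn-Ser").
#' @export
predict_peptide <- function(assembly, proteins, ref = nrps_reference(),
                            table = nrps_signature_table(), dual_ce = FALSE) {
  stopifnot(inherits(assembly, "nrps_assembly"))
  proteins <- as_named_seqs(proteins)
  mods <- Filter(function(m) m$valid, assembly$modules)
  if (!length(mods)) {
    out <- data.frame(position = integer(), residue = character(),
                      configuration = character(), stringsAsFactors = FALSE)
    attr(out, "peptide") <- ""
    return(out)
  }
  rows <- list()
  for (k in seq_along(mods)) {
    m <- mods[[k]]
    a_seq <- substr(proteins[[m$protein]], m$a_start, m$a_end)
    pr <- predict_residue(a_seq, ref, table)
    epi <- m$epimerized
    if (dual_ce && k < length(mods) && "E" %in% mods[[k + 1]]$domains &&
        "C" %in% mods[[k + 1]]$domains)
      epi <- epi || TRUE
    rows[[k]] <- data.frame(position = k, residue = pr$residue,
                            configuration = if (epi) "D" else "L",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "peptide") <- paste(
    ifelse(out$configuration == "D", paste0("D-", out$residue), out$residue),
    collapse = "-")
  out
}

#' Generate a synthetic NRPS assembly line
#'
#' Builds NRPS proteins as concatenations of the shipped domain exemplars
#' with A domains carrying the signature codes of the requested residues,
#' split across proteins as specified, plus the matching domain-annotation
#' table and the expected peptide. The default layout mirrors a
#' seven-module pyoverdine peptide synthetase (Ser-Lys-Gly-Orn-Lys-Orn-Ser)
#' split over three proteins.
#'
#' @param residues Residue per module, in order.
#' @param epimerize Integer positions of modules carrying an E domain.
#' @param split Number of modules per protein (sums to
#'   `length(residues)`).
#' @param te Append a terminal TE domain (default TRUE).
#' @return A list: `proteins`, `annotation` (data.frame protein, domain,
#'   start, end), `expected` (residue/configuration data.frame).
#' @export
synthetic_nrps <- function(residues = c("Ser", "Lys", "Gly", "Orn", "Lys",
                                        "Orn", "Ser"),
                           epimerize = integer(), split = c(2, 2, 3),
                           te = TRUE) {
  stopifnot(sum(split) == length(residues))
  ref <- nrps_reference(); ex <- ref$exemplars
  ann <- list(); proteins <- character()
  mod_i <- 0L
  for (p in seq_along(split)) {
    pid <- sprintf("nrps%02d", p)
    seqp <- ""; pos <- 0L
    add <- function(dom, s) {
      ann[[length(ann) + 1L]] <<- data.frame(
        protein = pid, domain = dom, start = pos + 1L,
        end = pos + nchar(s), stringsAsFactors = FALSE)
      seqp <<- paste0(seqp, s); pos <<- pos + nchar(s)
    }
    for (m in seq_len(split[p])) {
      mod_i <- mod_i + 1L
      add("C", ex$C)
      add("A", a_domain_for(residues[mod_i], ref))
      add("T", ex$T)
      if (mod_i %in% epimerize) add("E", ex$E)
      if (te && mod_i == length(residues)) add("TE", ex$TE)
    }
    proteins[pid] <- seqp
  }
  expected <- data.frame(
    position = seq_along(residues), residue = residues,
    configuration = ifelse(seq_along(residues) %in% epimerize, "D", "L"),
    stringsAsFactors = FALSE)
  list(proteins = proteins, annotation = do.call(rbind, ann),
       expected = expected)
}
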