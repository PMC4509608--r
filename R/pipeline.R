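#' Validate and default a pipeline run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming them), checks
#' that every referenced path resolves, validates thresholds and fills
#' defaults.
#'
#' Recognized keys: `genomes` (list of `{id, fasta, gff3}`), `stages`
#' (subset of ani, mlsa, effectors, traits, tbdp), `seed`, `outdir`,
#' `thresholds` (`e_max`, `ani_fragment_length`, `ani_min_identity`,
#' `ani_min_coverage`, `max_intergenic_genes`).
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("genomes", "stages", "seed", "outdir", "thresholds")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  th_known <- c("e_max", "ani_fragment_length", "ani_min_identity",
                "ani_min_coverage", "max_intergenic_genes")
  th <- raw$thresholds %||% list()
  extra_th <- setdiff(names(th), th_known)
  if (length(extra_th))
    stop("unknown threshold key(s): ", paste(extra_th, collapse = ", "))
  defaults <- list(e_max = 1e-5, ani_fragment_length = 1020,
                   ani_min_identity = 30, ani_min_coverage = 0.70,
                   max_intergenic_genes = 5)
  th <- utils::modifyList(defaults, th)
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative")
  if (th$e_max <= 0) stop("e_max must be > 0")
  genomes <- raw$genomes %||% list()
  for (g in genomes) {
    if (is.null(g$id) || is.null(g$fasta)) stop("each genome needs id and fasta")
    if (!file.exists(g$fasta)) stop("unresolvable path: ", g$fasta)
    if (!is.null(g$gff3) && !file.exists(g$gff3))
      stop("unresolvable path: ", g$gff3)
  }
  stages <- raw$stages %||% c("ani", "effectors", "traits")
  bad <- setdiff(stages, c("ani", "mlsa", "effectors", "traits", "tbdp"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(genomes = genomes, stages = stages,
                 seed = raw$seed %||% 1L,
                 outdir = raw$outdir %||% "pseudomine_out",
                 thresholds = th),
            class = "run_config")
}

log_line <- function(log, ...) {
  c(log, paste0(format(length(log) + 1), "\t", paste0(...)))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), round(m, 3), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative pipeline over a set of genomes
#'
#' Executes the enabled stages per genome, assembles the cross-genome trait
#' matrix (trait x genome; cells are counts) and the taxonomy tables (NI
#' matrix when MLSA runs, ANIb matrix with 94/95 verdicts), and writes
#' plain-text outputs (TSV/JSON) to the output directory. A stage failure
#' isolates that genome and stage; the run continues and the error is
#' recorded in the error manifest. Every decision-bearing threshold
#' application is logged.
#'
#' @param config A `run_config` from [validate_config()], or an equivalent
#'   list; `genomes` entries may alternatively carry an in-memory `genome`
#'   ([annotated_genome()]) instead of file paths.
#' @param bait_bundle Named list of [bait_set()] objects for the traits
#'   stage (default [default_bait_bundle()]).
#' @param mlsa_bait_seqs MLSA locus baits (default [mlsa_baits()]).
#' @param write_outputs Write TSV/JSON files under `config$outdir`.
#' @return A list: `traits` (matrix), `ani` (matrix or NULL), `ni` (matrix
#'   or NULL), `effectors`, `clusters`, `tbdp` (per-genome lists), `errors`
#'   (manifest data.frame), `log` (character vector of threshold
#'   applications).
#' @export
run_all <- function(config, bait_bundle = default_bait_bundle(),
                    mlsa_bait_seqs = mlsa_baits(), write_outputs = TRUE) {
  log <- character(); errors <- empty_manifest()
  genomes <- list()
  for (g in config$genomes) {
    genomes[[g$id]] <- if (!is.null(g$genome)) g$genome
                       else read_genome(g$fasta, g$gff3)
  }
  th <- config$thresholds
  if (!length(genomes)) {
    warning("empty genome list: nothing to do")
    res <- list(traits = matrix(numeric(), 0, 0), ani = NULL, ni = NULL,
                effectors = list(), clusters = list(), tbdp = list(),
                errors = errors, log = log)
    if (write_outputs) write_report(res, config)
    return(invisible(res))
  }

  effectors <- list(); clusters <- list(); tbdp <- list()
  for (id in names(genomes)) {
    gm <- genomes[[id]]
    if ("effectors" %in% config$stages) {
      r <- try_stage(id, "effectors", errors, function() {
        call_effectors(gm)
      })
      errors <- r$errors; effectors[[id]] <- r$value
      log <- log_line(log, id, "\teffectors\tbox=exact-consensus; ",
                      "ser>=0.10 polar>=0.40 acidic<=1 aliphatic(3|4)")
    }
    if ("traits" %in% config$stages) {
      r <- try_stage(id, "traits", errors, function() {
        lapply(bait_bundle, function(bs)
          call_clusters(gm, bs, max_intergenic_genes = th$max_intergenic_genes))
      })
      errors <- r$errors; clusters[[id]] <- r$value
      for (bs in bait_bundle)
        log <- log_line(log, id, "\tclusters\t", bs$system_label,
                        ": min_genes=", bs$min_cluster_genes,
                        " e_max=", bs$e_max)
    }
    if ("tbdp" %in% config$stages) {
      r <- try_stage(id, "tbdp", errors, function() {
        identify_tbdps(proteome(gm))
      })
      errors <- r$errors; tbdp[[id]] <- r$value
      log <- log_line(log, id, "\ttbdp\te_max=1e-05 coverage>=0.5")
    }
  }

  ani <- NULL
  if ("ani" %in% config$stages && length(genomes) >= 2) {
    ani <- ani_matrix(genomes, fragment_length = th$ani_fragment_length,
                      min_identity = th$ani_min_identity,
                      min_coverage = th$ani_min_coverage)
    log <- log_line(log, "all\tani\tfragment=", th$ani_fragment_length,
                    " retain: id>=", th$ani_min_identity,
                    "% cov>=", th$ani_min_coverage)
  }
  ni <- NULL
  if ("mlsa" %in% config$stages && length(genomes) >= 2) {
    profs <- list()
    for (id in names(genomes)) {
      r <- try_stage(id, "mlsa", errors, function()
        mlsa_profile(genomes[[id]], mlsa_bait_seqs, strain_id = id))
      errors <- r$errors
      if (!is.null(r$value)) profs[[id]] <- r$value
    }
    if (length(profs) >= 2) ni <- ni_matrix(profs)
    log <- log_line(log, "all\tmlsa\tboundary=97 (same species requires NI>97)")
  }

  traits <- trait_matrix(genomes, effectors, clusters, tbdp)
  res <- list(traits = traits, ani = ani, ni = ni, effectors = effectors,
              clusters = clusters, tbdp = tbdp, errors = errors, log = log)
  if (write_outputs) write_report(res, config)
  invisible(res)
}

empty_manifest <- function() {
  data.frame(genome = character(), stage = character(), error = character(),
             stringsAsFactors = FALSE)
}

try_stage <- function(id, stage, errors, fn) {
  value <- tryCatch(fn(), error = function(e) {
    errors <<- rbind(errors, data.frame(genome = id, stage = stage,
                                        error = conditionMessage(e),
                                        stringsAsFactors = FALSE))
    NULL
  })
  list(value = value, errors = errors)
}

# Cross-genome trait matrix: rows are traits, columns genomes, cells counts.
trait_matrix <- function(genomes, effectors, clusters, tbdp) {
  ids <- names(genomes)
  trait_names <- c("effectors",
                   if (length(clusters)) {
                     labs <- unique(unlist(lapply(clusters, names)))
                     paste0("clusters_", labs)
                   },
                   if (length(tbdp)) "tbdps")
  m <- matrix(0, length(trait_names), length(ids),
              dimnames = list(trait_names, ids))
  for (id in ids) {
    if (!is.null(effectors[[id]]))
      m["effectors", id] <- sum(effectors[[id]]$verdict)
    for (lab in names(clusters[[id]] %||% list())) {
      cl <- clusters[[id]][[lab]]
      m[paste0("clusters_", lab), id] <-
        sum(vapply(cl, function(x) x$called, TRUE))
    }
    if (!is.null(tbdp[[id]])) m["tbdps", id] <- nrow(tbdp[[id]])
  }
  m
}

write_report <- function(res, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  od <- config$outdir
  write_matrix_tsv(res$traits, file.path(od, "trait_matrix.tsv"))
  if (!is.null(res$ani)) {
    write_matrix_tsv(res$ani, file.path(od, "ani_matrix.tsv"))
    verd <- res$ani
    ids <- rownames(verd)
    vd <- do.call(rbind, lapply(seq_along(ids), function(i)
      do.call(rbind, lapply(seq_along(ids), function(j) {
        if (j <= i || !is.finite(verd[i, j])) return(NULL)
        cl <- classify_anib(verd[i, j])
        data.frame(a = ids[i], b = ids[j], ani = round(verd[i, j], 3),
                   verdict_94 = cl$verdict_94, verdict_95 = cl$verdict_95,
                   stringsAsFactors = FALSE)
      }))))
    if (!is.null(vd)) write_tsv(vd, file.path(od, "ani_verdicts.tsv"))
  }
  if (!is.null(res$ni)) write_matrix_tsv(res$ni, file.path(od, "ni_matrix.tsv"))
  for (id in names(res$effectors))
    if (!is.null(res$effectors[[id]]))
      write_tsv(res$effectors[[id]],
                file.path(od, paste0("effectors_", id, ".tsv")))
  jsonlite::write_json(
    list(traits = as.data.frame(res$traits),
         errors = res$errors, log = res$log),
    file.path(od, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(od, "thresholds.log"))
  invisible(od)
}
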