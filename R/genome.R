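#' Annotated genome container
#'
#' The universal input of every pipeline stage: a set of contigs plus gene
#' models with 1-based inclusive coordinates and strand, mirroring the GFF3
#' convention.
#'
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` ("+" or "-"). May have zero rows.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(contigs, genes = empty_genes()) {
  contigs <- as_named_seqs(contigs)
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes)) {
    if (!all(genes$contig %in% names(contigs)))
      stop("gene on unknown contig")
    len <- nchar(contigs)[genes$contig]
    if (any(genes$start < 1 | genes$end > len | genes$start > genes$end))
      stop("gene coordinates outside contig bounds")
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  }
  genes <- genes[order(match(genes$contig, names(contigs)), genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(contigs = contigs, genes = genes), class = "annotated_genome")
}

empty_genes <- function() {
  data.frame(gene_id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %d contig(s), %s bp, %d gene model(s)\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Extract gene (CDS) sequences in coding orientation
#'
#' @param genome An [annotated_genome()].
#' @return Named character vector of nucleotide sequences, one per gene,
#'   reverse-complemented for minus-strand genes.
#' @export
gene_seqs <- function(genome) {
  g <- genome$genes
  if (!nrow(g)) return(stats::setNames(character(), character()))
  out <- substring(genome$contigs[g$contig], g$start, g$end)
  neg <- g$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  stats::setNames(out, g$gene_id)
}

#' Translate all gene models into a proteome
#'
#' @param genome An [annotated_genome()].
#' @return Named character vector of protein sequences (terminal stop
#'   removed).
#' @export
proteome <- function(genome) {
  cds <- gene_seqs(genome)
  if (!length(cds)) return(cds)
  stats::setNames(translate_cds(cds), names(cds))
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Gene models are taken from GFF3 records of type "gene" or "CDS"
#' (1-based inclusive coordinates per the GFF3 standard).
#'
#' @param fasta Path to a contig FASTA file.
#' @param gff3 Optional path to a GFF3 annotation file.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(fasta, gff3 = NULL) {
  contigs <- as.character(Biostrings::readDNAStringSet(fasta))
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genes <- empty_genes()
  if (!is.null(gff3)) {
    gr <- rtracklayer::import(gff3, format = "gff3")
    gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
    if (length(gr)) {
      ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
        paste0("gene", seq_along(gr))
      genes <- data.frame(gene_id = ids,
                          contig = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          stringsAsFactors = FALSE)
      genes$strand[!genes$strand %in% c("+", "-")] <- "+"
    }
  }
  annotated_genome(contigs, genes)
}

#' Write an annotated genome (and optional truth ledger) to disk
#'
#' Writes contigs as FASTA, gene models as GFF3 and, when supplied, the
#' synthetic-genome truth ledger as TSV.
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff3 Output paths.
#' @param ledger Optional truth ledger data.frame.
#' @param ledger_path Output TSV path for the ledger.
#' @export
write_genome <- function(genome, fasta, gff3 = NULL, ledger = NULL,
                         ledger_path = NULL) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(gff3)) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(g$start, g$end),
      strand = g$strand)
    gr$type <- rep("gene", nrow(g))
    gr$ID <- g$gene_id
    rtracklayer::export(gr, gff3, format = "gff3")
  }
  if (!is.null(ledger) && !is.null(ledger_path))
    utils::write.table(ledger, ledger_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(genome)
}
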