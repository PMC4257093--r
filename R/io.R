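# File format plumbing: GFF3 gene tables, BLAST-tabular similarity,
# subsystem (presence/copy) matrices.

# GFF3 -> gene data.frame (1-based inclusive, as in the file)
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(
    id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = as.character(gr$protein_id),
    stringsAsFactors = FALSE
  )
}

write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "gutresp"
  gr$ID <- genes$id
  gr$protein_id <- genes$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a pairwise protein similarity table
#'
#' BLAST-tabular style input with columns `query`, `subject`, `bitscore`,
#' `evalue` (header optional if columns are in this order). Only the best
#' HSP per ordered (query, subject) pair is retained: highest bitscore,
#' lowest e-value on ties.
#'
#' @param x path to a TSV file, or a data.frame with the four columns.
#' @return data.frame with one row per ordered pair, class
#'   `gutresp_similarity`.
#' @export
read_similarity <- function(x) {
  if (is.character(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("query", "subject", "bitscore", "evalue") %in% names(x))) {
    names(x)[1:4] <- c("query", "subject", "bitscore", "evalue")
  }
  if (any(x$evalue < 0)) stop("negative e-values in similarity table",
                              call. = FALSE)
  # best HSP per ordered pair
  o <- order(x$query, x$subject, -x$bitscore, x$evalue)
  x <- x[o, , drop = FALSE]
  keep <- !duplicated(x[, c("query", "subject")])
  x <- x[keep, c("query", "subject", "bitscore", "evalue")]
  rownames(x) <- NULL
  class(x) <- c("gutresp_similarity", "data.frame")
  x
}

#' Write / read the genome-by-reductase subsystem matrix
#'
#' The "subsystem sheet": an integer matrix of copy numbers with genomes as
#' rows and reductase types as columns, serialized as TSV with a `genome_id`
#' first column. A write/read round trip reproduces the matrix exactly.
#'
#' @param presence integer matrix, rownames genome ids, colnames reductases.
#' @param path file path.
#' @return `write_subsystem_matrix` returns `path` invisibly;
#'   `read_subsystem_matrix` returns the integer matrix.
#' @export
write_subsystem_matrix <- function(presence, path) {
  df <- data.frame(genome_id = rownames(presence), presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subsystem_matrix
#' @export
read_subsystem_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$genome_id
  m
}

#' Write exchange edges
#'
#' @param edges data.frame from [infer_exchange_network()].
#' @param path output path (TSV or GraphML depending on the function).
#' @return `path`, invisibly.
#' @export
write_exchange_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_exchange_tsv
#' @export
write_exchange_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    edges[, c("producer", "consumer", "metabolite")], directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
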