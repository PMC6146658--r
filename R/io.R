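# Readers/writers for the on-disk interchange formats. All tables are
# tab-separated UTF-8 with '#' comment lines; genomic coordinates are 1-based
# inclusive. Readers validate and reject rather than silently coerce.

read_tsv_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix object
#'
#' Container for an FPKM gene-by-sample matrix with sample metadata. Exactly
#' one condition must be labelled as the control.
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param samples data.frame with columns `sample`, `condition`, `replicate`.
#' @param control name of the control condition (default "control").
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, samples, control = "control") {
  stopifnot(is.matrix(fpkm), is.data.frame(samples))
  if (is.null(rownames(fpkm))) stop("fpkm must have gene ids as rownames")
  if (anyDuplicated(rownames(fpkm)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(fpkm)[duplicated(rownames(fpkm))]), collapse = ", "))
  if (!all(c("sample", "condition", "replicate") %in% names(samples)))
    stop("sample metadata needs columns sample, condition, replicate")
  if (!setequal(colnames(fpkm), samples$sample))
    stop("sample metadata does not match matrix columns")
  samples <- samples[match(colnames(fpkm), samples$sample), , drop = FALSE]
  if (!control %in% samples$condition)
    stop("no condition labelled as control ('", control, "')")
  bad <- which(!is.finite(fpkm) | fpkm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite FPKM at gene ", rownames(fpkm)[bad[1, 1]],
         ", sample ", colnames(fpkm)[bad[1, 2]])
  structure(list(fpkm = fpkm, samples = samples, control = control),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$fpkm), "genes x", ncol(x$fpkm), "samples;",
      "conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Treatment conditions of an expression matrix
#'
#' @param em an `expression_matrix`.
#' @return character vector of non-control conditions in stable order.
#' @export
treatments <- function(em) {
  setdiff(unique(em$samples$condition), em$control)
}

#' Read an expression matrix from TSV
#'
#' Expects a gene-by-sample FPKM table (first column `gene_id`) and a sample
#' metadata sidecar mapping sample to condition and replicate.
#'
#' @param path path to the FPKM TSV.
#' @param meta_path path to the sample metadata TSV
#'   (columns sample, condition, replicate).
#' @param control control condition name.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path, meta_path, control = "control") {
  tab <- read_tsv_table(path)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  ids <- as.character(tab$gene_id)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0)
      stop("non-numeric FPKM at gene ", ids[bad[1]], ", sample ", names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  meta <- read_tsv_table(meta_path)
  names(meta)[names(meta) == "treatment"] <- "condition"
  expression_matrix(m, meta, control = control)
}

#' Write an expression matrix (FPKM table + metadata sidecar)
#'
#' @param em an `expression_matrix`.
#' @param path output path for the FPKM TSV.
#' @param meta_path output path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, meta_path) {
  tab <- data.frame(gene_id = rownames(em$fpkm), em$fpkm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(tab, path)
  write_tsv_table(em$samples, meta_path)
  invisible(path)
}

#' Read an edge list into a graph
#'
#' Two- or three-column TSV (source, target, optional weight). Self-loops are
#' dropped and counted; duplicate edges are collapsed keeping the maximum
#' weight.
#'
#' @param path path to the edge-list TSV.
#' @param directed logical.
#' @return an `igraph` graph with attributes `self_loops_dropped` and
#'   `duplicates_collapsed`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(graph_from_edges(data.frame(from = character(0), to = character(0)),
                            directed = directed))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  header <- 0L
  if (tolower(parts[[1]][1]) %in% c("from", "source", "node1")) {
    parts <- parts[-1]; nfield <- nfield[-1]; lineno <- lineno[-1]; header <- 1L
  }
  bad <- which(nfield < 2)
  if (length(bad) > 0)
    stop("malformed edge row at line ", lineno[bad[1]], " (fewer than 2 fields)")
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3) suppressWarnings(as.numeric(p[3])) else 1
  }, 0.0)
  if (anyNA(w)) stop("malformed weight at line ", lineno[which(is.na(w))[1]])
  graph_from_edges(data.frame(from = from, to = to, weight = w,
                              stringsAsFactors = FALSE), directed = directed)
}

#' Write a graph as an edge-list TSV
#'
#' @param graph an `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  df <- igraph::as_data_frame(graph, what = "edges")
  if (!"weight" %in% names(df)) df$weight <- 1
  write_tsv_table(df[, c("from", "to", "weight")], path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write promoter sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
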