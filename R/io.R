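# Plain-text readers/writers for the tabular formats the pipeline consumes:
# qPCR plate CSV, dilution CSV, expression TSV, BED-like positions, and
# SEG-like copy-number segments.

#' Read a qPCR plate CSV
#'
#' Columns `assay,sample,replicate,ct`; an empty `ct` field is an
#' undetermined (censored) well and becomes `NA`.
#' @param path file path.
#' @return data.frame.
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("assay", "sample", "replicate", "ct") %in% names(d)))
  d$ct <- suppressWarnings(as.numeric(d$ct))
  d
}

#' Write a qPCR plate CSV
#' @param plate data.frame (`assay`, `sample`, `replicate`, `ct`).
#' @param path file path.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, na = "")
}

#' Read a dilution-series CSV (`assay,quantity_pg,ct`)
#' @param path file path.
#' @return data.frame.
#' @export
read_dilution_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("assay", "quantity_pg", "ct") %in% names(d)))
  d$ct <- suppressWarnings(as.numeric(d$ct))
  d
}

#' Read a genes x samples expression TSV (first column = gene id)
#' @param path file path.
#' @return numeric matrix with gene ids as row names.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1L]]
  m
}

#' Write a genes x samples expression TSV
#' @param expression numeric matrix with gene ids as row names.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  d <- data.frame(gene = rownames(expression), expression,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read BED-like gene positions (chrom, start, end, gene; 0-based half-open)
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_positions_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(d[, 1:4], c("chrom", "start", "end", "gene"))
}

#' Read SEG-like copy-number segments
#'
#' Tab-separated with header: `sample`, `chrom`, `start`, `end`, `seg_mean`
#' (0-based half-open).
#' @param path file path.
#' @return data.frame.
#' @export
read_segments_seg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "chrom", "start", "end", "seg_mean") %in%
                  names(d)))
  d
}
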