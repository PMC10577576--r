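#' Read and write beta matrices as TSV
#'
#' GEO-series-matrix-style layout: first column `probe_id`, remaining columns
#' one sample each.
#'
#' @param path TSV file.
#' @return numeric matrix with probe rownames.
#' @export
read_beta_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_beta_tsv
#' @param beta probes x samples matrix.
#' @export
write_beta_tsv <- function(beta, path) {
  out <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write the probe annotation table
#'
#' Columns: `probe_id`, `chr`, `pos`, `relation`, `island_id`, `genes`,
#' `on_450k`, `on_epic`.
#'
#' @param path CSV file.
#' @export
read_annotation_csv <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chr = "character"))
  ann$genes[is.na(ann$genes)] <- ""
  ann$island_id[is.na(ann$island_id)] <- ""
  ann
}

#' @rdname read_annotation_csv
#' @param annotation annotation data.frame.
#' @export
write_annotation_csv <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
}

#' Read/write the sample sheet
#'
#' @param path TSV file.
#' @return validated sheet with derived `phenotype` (see [as_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  as_sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an external differential-expression gene list
#'
#' Two-column TSV: `gene`, `direction` (`up`/`down`).
#'
#' @param path TSV file.
#' @export
read_de_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "direction") %in% names(tab)),
            all(tab$direction %in% c("up", "down")))
  tab
}
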