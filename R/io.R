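#' Read / write tidy cytokine panels
#'
#' Panels are tab-separated with columns `donor_id`, `condition_id`,
#' `analyte`, `concentration_pg_ml`.
#'
#' @param path File path.
#' @return `read_panel()` returns the panel `data.frame`.
#' @export
read_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_panel(panel)
}

#' @rdname read_panel
#' @param panel Panel `data.frame`.
#' @export
write_panel <- function(panel, path) {
  assert_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write expression matrices with sample metadata
#'
#' The expression matrix is written as genes x samples TSV (gene names in
#' the first column), the metadata as a separate TSV keyed by `sample_id`.
#'
#' @param path Expression TSV path.
#' @param metadata_path Optional metadata TSV path.
#' @return `read_expression()` returns `list(expr, metadata)`.
#' @export
read_expression <- function(path, metadata_path = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(d[, -1, drop = FALSE])
  rownames(expr) <- d[[1]]
  metadata <- if (!is.null(metadata_path))
    utils::read.delim(metadata_path, stringsAsFactors = FALSE) else NULL
  list(expr = expr, metadata = metadata)
}

#' @rdname read_expression
#' @param expr Genes x samples matrix.
#' @param metadata Optional per-sample `data.frame`.
#' @export
write_expression <- function(expr, path, metadata = NULL,
                             metadata_path = NULL) {
  d <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata) && !is.null(metadata_path))
    utils::write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (set name -> genes).
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
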