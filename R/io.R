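# readers and writers for the external formats: feature tables (TSV/BIOM),
# sample metadata, taxonomy, distance matrices, edge lists, Newick trees

#' Read a taxa-by-samples feature table
#'
#' TSV dialect: first column taxon ids, header row of sample ids. BIOM
#' (JSON, version 1) is read through the biomformat package. Cells must be
#' non-negative integers; offending cells are named in the error.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return validated count matrix.
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to read BIOM files")
    x <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- ids
  }
  bad <- which(is.na(x) | x < 0 | abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid cell at taxon '", rownames(x)[bad[1, 1]], "', sample '",
         colnames(x)[bad[1, 2]], "': counts must be non-negative integers")
  validate_count_table(x)
  storage.mode(x) <- "integer"
  x
}

#' Write a feature table
#'
#' @param table count matrix.
#' @param path output file.
#' @param format `"tsv"` or `"biom"` (JSON).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to write BIOM files")
    biomformat::write_biom(biomformat::make_biom(table), path)
  } else {
    df <- data.frame(taxon_id = rownames(table), table, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `animal_id`, `group`, `day`; `phase` is
#' derived from `day` when absent (pretreatment < 0, treatment inside the
#' window, recovery after). Group labels must be CON, ABX or ABXFT.
#'
#' @param path TSV file (or a data.frame to validate in place).
#' @param treatment_window inclusive treatment-day window.
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path, treatment_window = c(0, 6)) {
  md <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal_id", "group", "day")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$group), c("CON", "ABX", "ABXFT"))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!"phase" %in% names(md)) md$phase <- phase_of_day(md$day, treatment_window)
  md
}

#' Read a QIIME2 two-column taxonomy TSV
#'
#' @param path TSV with feature ids and semicolon-delimited lineages in the
#'   first two columns.
#' @return data.frame with `feature_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("feature_id", "lineage"))
}

#' Write a symmetric distance matrix as QIIME2-compatible TSV
#'
#' @param dm symmetric matrix with sample ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path TSV file.
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an association edge list as TSV
#'
#' @param edges an `association_edges` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association network as GraphML
#'
#' Strong edges only, with median correlation, credible bounds and sign as
#' edge attributes, for use in external network tools.
#'
#' @param edges an `association_edges` table.
#' @param path output file.
#' @param strong_only write only strong edges (default).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path, strong_only = TRUE) {
  e <- if (strong_only) edges[edges$strong, , drop = FALSE] else edges
  nodes <- unique(c(e$taxon_i, e$taxon_j))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="rho" for="edge" attr.name="rho_median" attr.type="double"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="int"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', nodes),
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="rho">%.6f</data><data key="sign">%d</data></edge>'),
            e$taxon_i, e$taxon_j, e$rho_median, as.integer(e$sign)),
    "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
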