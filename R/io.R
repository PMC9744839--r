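## Plain-text readers/writers for the pipeline's exchange formats:
## feature x sample TSV matrices, GMT gene sets, BED6 intervals,
## MAF-like mutation tables. All coordinates are 0-based half-open.

#' Read a feature-by-sample TSV matrix
#'
#' First column is the feature identifier, remaining columns are samples.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m matrix with rownames (features) and colnames (samples).
#' @param path output path.
#' @param id_col name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes. Empty
#' member fields are dropped.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(l, 1, 60))
    members <- f[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (recycled "na" otherwise).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a BED6 interval file (0-based half-open)
#' @param path file path.
#' @return data.frame with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(dt) < 4) stop("expected at least 4 BED columns")
  names(dt)[1:4] <- c("chrom", "start", "end", "name")
  if (ncol(dt) >= 6) names(dt)[5:6] <- c("score", "strand")
  else { dt$score <- 0; dt$strand <- "+" }
  dt[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Write intervals as BED6
#' @param df data.frame with chrom, start, end, name and optionally
#'   score, strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "+"
  data.table::fwrite(df[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
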