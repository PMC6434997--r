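#' Construct an expression matrix container
#'
#' A lightweight container for a genes x samples matrix of log2 expression
#' values. Row names are gene identifiers, column names sample identifiers;
#' both must be unique and all values finite.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param scale Declared scale of `values`, `"log2"` (the internal standard)
#'   or `"linear"`. Linear input is log2(x + 1)-transformed on construction.
#' @return An object of class `"expression_matrix"`: the log2 matrix with a
#'   `scale` attribute fixed at `"log2"`.
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (scale == "linear") values <- log2(values + 1)
  structure(values, class = c("expression_matrix", "matrix", "array"),
            scale = "log2")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x), ncol(x)))
  cat("samples:", paste(utils::head(colnames(x), 6), collapse = ", "),
      if (ncol(x) > 6) "..." else "", "\n")
  invisible(x)
}

gene_ids <- function(mat) rownames(mat)
sample_ids <- function(mat) colnames(mat)

#' Read a tab-delimited expression table
#'
#' Expects a header row of sample ids and a first column of gene ids. Rows
#' containing any non-finite value are dropped (with a message giving the
#' count). With `scale_hint = "auto"`, a matrix maximum above 30 is taken as
#' evidence of linear-scale intensities and the values are
#' log2(x + 1)-transformed; no plausible log2 microarray intensity exceeds 30.
#'
#' @param path Path to a tab-delimited text file.
#' @param scale_hint `"auto"` (default), `"log2"`, or `"linear"`.
#' @return An [expression_matrix()] on the log2 scale.
#' @export
read_expression_table <- function(path, scale_hint = c("auto", "log2", "linear")) {
  scale_hint <- match.arg(scale_hint)
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing expression table: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, fill = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyDuplicated(colnames(vals))) stop("duplicate sample ids in ", path)
  rownames(vals) <- ids
  bad <- !apply(is.finite(vals), 1L, all)
  if (any(bad)) {
    message(sum(bad), " gene row(s) with non-finite values dropped")
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0) stop("no complete gene rows in ", path)
  scale <- scale_hint
  if (scale == "auto") {
    scale <- if (max(vals) > 30) "linear" else "log2"
  }
  expression_matrix(vals, scale = scale)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect used by the Gene Expression Omnibus: the
#' expression table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` sentinel lines, and `!Sample_*` header lines
#' carry per-sample metadata (titles, characteristics) as tab-separated,
#' usually quoted, fields. Metadata are returned verbatim (unquoted) so the
#' caller can build a sample annotation by hand.
#'
#' @param path Path to a series-matrix text file.
#' @param scale_hint Passed through to the expression-scale logic of
#'   [read_expression_table()]; default `"auto"`.
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `sample_meta` (named list of character vectors, one per `!Sample_` key).
#' @export
read_series_matrix <- function(path, scale_hint = "auto") {
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    stop("series-matrix table sentinels missing or malformed in ", path)
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  sample_meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- sub("^!Sample_", "", parts[1])
    val <- unquote(parts[-1])
    if (key %in% names(sample_meta)) {
      # repeated keys (e.g. characteristics_ch1) accumulate rows
      m <- rbind(sample_meta[[key]], val, deparse.level = 0)
      dimnames(m) <- NULL
      sample_meta[[key]] <- m
    } else {
      sample_meta[[key]] <- val
    }
  }
  tbl <- lines[(begin + 1):(end - 1)]
  if (length(tbl) < 2) stop("empty series-matrix table in ", path)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(gsub('"', "", tbl, fixed = TRUE), tmp)
  mat <- read_expression_table(tmp, scale_hint = scale_hint)
  list(matrix = mat, sample_meta = sample_meta)
}

.canon_organ <- c(brain = "brain", spleen = "spleen")
.canon_group <- c(eae = "EAE", control = "control", ctrl = "control",
                  naive = "control")

#' Read and validate a sample annotation table
#'
#' A tab-delimited file with columns `sample_id`, `mouse_id`, `strain`,
#' `organ`, `group`. Organ tokens are normalized to lowercase `brain`/`spleen`
#' and group tokens to `EAE`/`control` (accepting `ctrl` and `naive` for
#' controls). Each (mouse, organ) pair may occur once: a mouse contributes at
#' most one sample per organ.
#'
#' @param path Path to the annotation TSV.
#' @return A validated `data.frame` of class `"sample_annotation"`.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", fill = FALSE)
  sample_annotation(df)
}

#' Validate a sample annotation data frame
#'
#' @param df Data frame with columns `sample_id`, `mouse_id`, `strain`,
#'   `organ`, `group`.
#' @return The normalized annotation, class `"sample_annotation"`.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "mouse_id", "strain", "organ", "group")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  organ <- .canon_organ[tolower(df$organ)]
  if (anyNA(organ)) {
    stop("unknown organ token(s): ",
         paste(unique(df$organ[is.na(organ)]), collapse = ", "))
  }
  group <- .canon_group[tolower(df$group)]
  if (anyNA(group)) {
    stop("unknown group token(s): ",
         paste(unique(df$group[is.na(group)]), collapse = ", "))
  }
  df$organ <- unname(organ)
  df$group <- unname(group)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  key <- paste(df$mouse_id, df$organ)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, organ) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Collapse probe-level rows to gene symbols
#'
#' When several probes map to one symbol, the probe with the highest mean
#' expression is kept — the common microarray convention. Probes absent from
#' the mapping are retained under their probe id unless `drop_unmapped`.
#'
#' @param mat An [expression_matrix()].
#' @param mapping Named character vector, probe id -> symbol.
#' @param drop_unmapped Drop probes with no symbol? Default `FALSE`.
#' @return An [expression_matrix()] with one row per symbol.
#' @export
collapse_probes_to_symbols <- function(mat, mapping, drop_unmapped = FALSE) {
  if (length(mapping) == 0) stop("empty probe-to-symbol mapping")
  sym <- mapping[rownames(mat)]
  mapped <- !is.na(sym)
  if (!any(mapped)) stop("mapping covers no probe in the matrix")
  keep_rows <- character(0)
  new_ids <- character(0)
  if (any(mapped)) {
    means <- rowMeans(mat[mapped, , drop = FALSE])
    per_sym <- split(names(means), unname(sym[mapped]))
    best <- vapply(per_sym, function(p) p[which.max(means[p])], character(1))
    keep_rows <- unname(best)
    new_ids <- names(best)
  }
  if (!drop_unmapped && any(!mapped)) {
    keep_rows <- c(keep_rows, rownames(mat)[!mapped])
    new_ids <- c(new_ids, rownames(mat)[!mapped])
  }
  ord <- order(match(keep_rows, rownames(mat)))
  out <- mat[keep_rows[ord], , drop = FALSE]
  rownames(out) <- new_ids[ord]
  expression_matrix(unclass(out), scale = "log2")
}

#' Write a result table as deterministic TSV
#'
#' Tab-delimited, UTF-8, `"\n"` line endings, columns in the order given;
#' doubles rendered with 6 significant digits. An empty data frame yields a
#' header-only file.
#'
#' @param df Data frame of homogeneous records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  df <- as.data.frame(df)
  fmt <- lapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 6, format = "g") else as.character(col)
  })
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df) > 0) {
    body <- do.call(paste, c(fmt, sep = "\t"))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write an expression matrix as a tab-delimited table
#'
#' Inverse of [read_expression_table()]: header row of sample ids, first
#' column `gene_id`, values with 6 significant digits.
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write_result_table(df, path)
}
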