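#' Annotation tables for subjects and variants
#'
#' A `meta_table` carries ordered categorical/numerical annotation columns
#' keyed by subject or variant (SNV) identifier, mirroring the
#' two-header-line tab-delimited annotation dialect: first header line with
#' column names, second header line declaring each column `CATEGORICAL` or
#' `NUMERICAL`, identifiers in the first column. Subject annotations are
#' rendered as meta-information columns beside the haplotype grid; variant
#' annotations as meta-information rows below it.
#'
#' @param ids character vector of identifiers (unique).
#' @param data data frame of annotation columns, one row per id; character
#'   columns for categorical data, numeric for numerical.
#' @param kinds character vector, one of `"categorical"`/`"numerical"` per
#'   column of `data`.
#' @param axis `"subject"` or `"variant"`.
#' @return an object of class `meta_table`.
#' @examples
#' meta_table(c("S1", "S2"),
#'            data.frame(Population = c("CEU", "YRI"), Age = c(31, 44)),
#'            kinds = c("categorical", "numerical"), axis = "subject")
#' @export
meta_table <- function(ids, data, kinds, axis = c("subject", "variant")) {
  axis <- match.arg(axis)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("meta ids must be unique", call. = FALSE)
  stopifnot(is.data.frame(data), nrow(data) == length(ids))
  kinds <- tolower(as.character(kinds))
  if (length(kinds) != ncol(data) ||
      !all(kinds %in% c("categorical", "numerical"))) {
    stop("kinds must give 'categorical' or 'numerical' for every column",
         call. = FALSE)
  }
  for (ci in seq_along(data)) {
    if (kinds[ci] == "numerical") {
      v <- data[[ci]]
      if (!is.numeric(v)) {
        stop("column '", names(data)[ci],
             "' declared numerical but holds non-numeric values",
             call. = FALSE)
      }
      if (any(is.infinite(v))) {
        stop("numerical meta values must be finite", call. = FALSE)
      }
    } else {
      data[[ci]] <- as.character(data[[ci]])
    }
  }
  rownames(data) <- NULL
  structure(list(axis = axis, ids = ids, data = data, kinds = kinds),
            class = "meta_table")
}

#' Number of annotation columns in a meta table
#' @param meta a [meta_table] or `NULL`.
#' @return integer count (0 for `NULL`).
#' @export
n_meta <- function(meta) {
  if (is.null(meta)) return(0L)
  stopifnot(inherits(meta, "meta_table"))
  ncol(meta$data)
}

#' Look up one annotation column, aligned to a set of identifiers
#'
#' @param meta a [meta_table].
#' @param column column name.
#' @param ids identifiers to align to; ids absent from the table give `NA`.
#' @return vector of values in the order of `ids`.
#' @export
meta_values <- function(meta, column, ids = meta$ids) {
  stopifnot(inherits(meta, "meta_table"))
  ci <- match(column, names(meta$data))
  if (is.na(ci)) {
    stop("unknown meta column: '", column, "'", call. = FALSE)
  }
  meta$data[[ci]][match(as.character(ids), meta$ids)]
}

meta_kind <- function(meta, column) {
  ci <- match(column, names(meta$data))
  if (is.na(ci)) stop("unknown meta column: '", column, "'", call. = FALSE)
  meta$kinds[ci]
}

#' @export
print.meta_table <- function(x, ...) {
  cat(sprintf("meta_table (%s axis): %d ids, %d column(s)\n",
              x$axis, length(x$ids), ncol(x$data)))
  if (ncol(x$data)) {
    cat(paste0("  ", names(x$data), " [", x$kinds, "]", collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Read a two-header-line annotation file
#'
#' Parses the tab-delimited annotation dialect: line 1 holds column names
#' (first column = identifier column), line 2 declares `CATEGORICAL` or
#' `NUMERICAL` for each annotation column (case-insensitive; a leading
#' declaration for the identifier column is tolerated and ignored), and
#' every following line holds an identifier plus its values. Empty cells and
#' `NA` are read as absent values. Plain or gzip-compressed input.
#'
#' @param path file path.
#' @param axis `"subject"` or `"variant"`.
#' @return a [meta_table].
#' @export
read_meta <- function(path, axis = c("subject", "variant")) {
  axis <- match.arg(axis)
  lines <- read_lines_maybe_gz(path)
  if (length(lines) < 2L) {
    stop("meta file needs two header lines: ", path, call. = FALSE)
  }
  split_tab <- function(x) strsplit(x, "\t", fixed = TRUE)
  header <- split_tab(lines[1L])[[1L]]
  kinds_raw <- split_tab(lines[2L])[[1L]]
  col_names <- header[-1L]
  n_cols <- length(col_names)
  if (length(kinds_raw) == n_cols + 1L) kinds_raw <- kinds_raw[-1L]
  if (length(kinds_raw) != n_cols) {
    stop("kind declaration line has ", length(kinds_raw),
         " entries for ", n_cols, " annotation column(s): ", path,
         call. = FALSE)
  }
  kinds <- tolower(trimws(kinds_raw))
  bad <- !kinds %in% c("categorical", "numerical")
  if (any(bad)) {
    stop("unknown kind token(s) in ", path, ": ",
         paste(unique(kinds_raw[bad]), collapse = ", "),
         " (expected CATEGORICAL or NUMERICAL)", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  cells <- split_tab(body)
  ids <- vapply(cells, `[`, character(1L), 1L)
  data <- as.data.frame(
    matrix(NA_character_, nrow = length(ids), ncol = n_cols,
           dimnames = list(NULL, col_names)),
    stringsAsFactors = FALSE)
  for (r in seq_along(cells)) {
    row <- cells[[r]][-1L]
    length(row) <- n_cols
    data[r, ] <- row
  }
  for (ci in seq_len(n_cols)) {
    v <- data[[ci]]
    v[!is.na(v) & (v == "" | v == "NA")] <- NA_character_
    if (kinds[ci] == "numerical") {
      num <- suppressWarnings(as.numeric(v))
      bad_row <- which(!is.na(v) & is.na(num))
      if (length(bad_row)) {
        stop("non-numeric value '", v[bad_row[1L]],
             "' in numerical column '", col_names[ci],
             "' (id ", ids[bad_row[1L]], "): ", path, call. = FALSE)
      }
      data[[ci]] <- num
    } else {
      data[[ci]] <- v
    }
  }
  meta_table(ids, data, kinds, axis)
}

#' Write a two-header-line annotation file
#'
#' Inverse of [read_meta()]: absent values are written as empty cells.
#'
#' @param meta a [meta_table].
#' @param path output file path.
#' @param id_name header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path, id_name = "ID") {
  stopifnot(inherits(meta, "meta_table"))
  header <- paste(c(id_name, names(meta$data)), collapse = "\t")
  kinds <- paste(c("ID", toupper(meta$kinds)), collapse = "\t")
  body <- vapply(seq_along(meta$ids), function(r) {
    vals <- vapply(meta$data[r, , drop = FALSE], function(v) {
      if (is.na(v)) "" else as.character(v)
    }, character(1L))
    paste(c(meta$ids[r], vals), collapse = "\t")
  }, character(1L))
  writeLines(c(header, kinds, body), path)
  invisible(path)
}

read_lines_maybe_gz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
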