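#' Coerce a data frame to a validated expression table
#'
#' An expression table is a tibble whose first column, `gene_id`, holds unique
#' feature identifiers and whose remaining columns hold finite numeric
#' expression values, one column per sample. The attribute `value_scale`
#' records whether values are raw counts (`"linear_counts"`) or on a log-like
#' signal scale (`"log_signal"`).
#'
#' @param df A data frame with a `gene_id` column (or identifiers in the first
#'   column) and one numeric column per sample.
#' @param value_scale `"linear_counts"` or `"log_signal"`.
#' @return A tibble of class `expr_tbl`.
#' @export
as_expression <- function(df, value_scale = c("log_signal", "linear_counts")) {
  value_scale <- match.arg(value_scale)
  nm <- names(df)
  dup_nm <- unique(nm[duplicated(nm)])
  if (length(dup_nm) > 0) {
    stop("duplicate sample ids: ", paste(dup_nm, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (ncol(df) < 2) {
    stop("expression table needs a gene_id column and at least one sample column",
         call. = FALSE)
  }
  if (!"gene_id" %in% names(df)) names(df)[1] <- "gene_id"
  df <- dplyr::relocate(df, "gene_id")
  df$gene_id <- as.character(df$gene_id)

  dup_g <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  samp <- names(df)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  for (s in samp) {
    v <- df[[s]]
    if (!is.numeric(v)) {
      stop("non-numeric values in sample column '", s, "'", call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop("non-finite value at gene '", df$gene_id[bad], "', sample '", s,
           "' (missing values are rejected, not imputed)", call. = FALSE)
    }
  }
  structure(df, value_scale = value_scale,
            class = c("expr_tbl", class(df)))
}

#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' The delimiter is auto-detected from tab or comma unless given.
#'
#' @param path Path to a TSV/CSV file.
#' @param transform `"none"` to keep values as stored, `"log2_plus1"` to apply
#'   `log2(x + 1)` elementwise (the table is then on the log-signal scale).
#' @param value_scale Scale of the *stored* values; ignored when
#'   `transform = "log2_plus1"`.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return An expression tibble (see [as_expression()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t3", "g2\t1\t1"), tf)
#' read_expression(tf, transform = "log2_plus1")
#' @export
read_expression <- function(path, transform = c("none", "log2_plus1"),
                            value_scale = c("log_signal", "linear_counts"),
                            delim = NULL) {
  transform <- match.arg(transform)
  value_scale <- match.arg(value_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  names(df)[1] <- "gene_id"
  for (s in names(df)[-1]) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !is.na(df[[s]]))
    if (length(bad) > 0) {
      stop("non-numeric cell at row ", bad[1], " (gene '", df$gene_id[bad[1]],
           "'), column '", s, "': '", df[[s]][bad[1]], "'", call. = FALSE)
    }
    df[[s]] <- v
  }
  if (transform == "log2_plus1") {
    neg <- vapply(df[-1], function(v) any(v < 0), logical(1))
    if (any(neg)) stop("log2_plus1 transform requires nonnegative values", call. = FALSE)
    df[-1] <- lapply(df[-1], function(v) log2(v + 1))
    value_scale <- "log_signal"
  }
  as_expression(df, value_scale = value_scale)
}

#' Write an expression table to delimited text
#'
#' Mirrors [read_expression()]: header of sample ids, first column `gene_id`.
#'
#' @param expr An expression tibble.
#' @param path Output path.
#' @param delim Field delimiter (tab by default).
#' @param digits Significant digits for real values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = "\t", digits = 6) {
  df <- tibble::as_tibble(expr)
  df[-1] <- lapply(df[-1], function(v) {
    if (all(v == round(v))) v else signif(v, digits)
  })
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

# matrix view: genes x samples with dimnames
expr_matrix <- function(expr) {
  m <- as.matrix(tibble::as_tibble(expr)[-1])
  rownames(m) <- expr$gene_id
  m
}

expr_samples <- function(expr) names(expr)[-1]

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat("# expression table: ", nrow(x), " genes x ", ncol(x) - 1L,
      " samples (", attr(x, "value_scale"), ")\n", sep = "")
  NextMethod()
}
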