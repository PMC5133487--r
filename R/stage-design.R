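#' Build a stage design from sample annotations
#'
#' A stage design maps each sample to one level of an ordered ordinal stage
#' variable (index 1 = initial/control, index K = terminal/acute). The
#' ordering is always supplied by the caller: it encodes clinical progression
#' that an alphabetical sort of labels cannot express.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param stage Character vector of stage labels, one per sample.
#' @param stage_order Ordered character vector of the K >= 2 stage levels.
#' @return A tibble of class `stage_design` with columns `sample_id`,
#'   `stage` (factor with levels in progression order) and `stage_code`
#'   (integer rank 1..K).
#' @examples
#' stage_design(paste0("s", 1:6), rep(c("Control", "Acute"), each = 3),
#'              c("Control", "Acute"))
#' @export
stage_design <- function(sample_id, stage, stage_order) {
  sample_id <- as.character(sample_id)
  stage <- as.character(stage)
  stage_order <- as.character(stage_order)
  if (length(stage_order) < 2) stop("need at least 2 stage levels", call. = FALSE)
  if (anyDuplicated(stage_order)) stop("duplicated stage levels in stage_order", call. = FALSE)
  if (length(sample_id) != length(stage)) stop("sample_id and stage lengths differ", call. = FALSE)
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup) > 0) stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  unknown <- !stage %in% stage_order
  if (any(unknown)) {
    stop("samples with stage labels not in stage_order: ",
         paste(sprintf("%s (%s)", sample_id[unknown], stage[unknown]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(stage, levels = stage_order))
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    stop("empty stage ", paste(empty, collapse = ", "),
         ": every level in stage_order needs at least one sample", call. = FALSE)
  }
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    warning("stages with fewer than 3 samples: ", paste(small, collapse = ", "),
            call. = FALSE)
  }
  f <- factor(stage, levels = stage_order)
  out <- tibble::tibble(sample_id = sample_id, stage = f,
                        stage_code = as.integer(f))
  structure(out, class = c("stage_design", class(out)))
}

#' Read a two-column sample-to-stage annotation file
#'
#' @param path Delimited text with columns sample id and stage label
#'   (header optional, auto-detected).
#' @param stage_order Ordered stage levels, initial to terminal.
#' @param delim Field delimiter; `NULL` auto-detects tab/comma.
#' @return A [stage_design()] tibble.
#' @export
read_stage_design <- function(path, stage_order, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) stop("stage annotation needs two columns (sample_id, stage)", call. = FALSE)
  # drop a header row if present
  if (tolower(df[[1]][1]) %in% c("sample_id", "sample", "id")) df <- df[-1, ]
  stage_design(df[[1]], df[[2]], stage_order)
}

#' Write a stage design as two-column TSV
#' @param design A stage design.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_design <- function(design, path) {
  readr::write_tsv(tibble::tibble(sample_id = design$sample_id,
                                  stage = as.character(design$stage)),
                   path, progress = FALSE)
  invisible(path)
}

#' Merge stage levels into coarser ones
#'
#' Collapses levels of an existing design (for instance grouping disease
#' subtypes into low- and high-risk stages) while preserving every sample.
#'
#' @param design A stage design.
#' @param merge_map Named character vector `old level -> new level`, covering
#'   every original level.
#' @param new_order Ordered levels of the merged design.
#' @return A [stage_design()] tibble with the merged ordering.
#' @export
merge_stages <- function(design, merge_map, new_order) {
  old_levels <- levels(design$stage)
  missing <- setdiff(old_levels, names(merge_map))
  if (length(missing) > 0) {
    stop("merge_map is missing original levels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(unname(merge_map), new_order)
  if (length(extra) > 0) {
    stop("merged labels absent from new_order: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  stage_design(design$sample_id, unname(merge_map[as.character(design$stage)]),
               new_order)
}

#' Restrict an expression table and a stage design to their shared samples
#'
#' Both objects are cut down to the intersection of their sample ids and the
#' expression columns are reordered to follow the design (by stage, then by
#' annotation order within stage). Dropped samples are reported via `message()`.
#'
#' @param expr An expression tibble.
#' @param design A stage design.
#' @return A list with elements `expr` and `design`, aligned sample-for-sample.
#' @export
align_samples <- function(expr, design) {
  es <- expr_samples(expr)
  shared <- intersect(es, design$sample_id)
  if (length(shared) < 2) {
    stop("fewer than 2 samples shared between expression table and stage design",
         call. = FALSE)
  }
  dropped_e <- setdiff(es, shared)
  dropped_d <- setdiff(design$sample_id, shared)
  if (length(dropped_e) > 0)
    message("dropping ", length(dropped_e), " expression sample(s) without stage: ",
            paste(dropped_e, collapse = ", "))
  if (length(dropped_d) > 0)
    message("dropping ", length(dropped_d), " annotated sample(s) without expression: ",
            paste(dropped_d, collapse = ", "))

  d <- design[design$sample_id %in% shared, ]
  d <- d[order(d$stage_code, match(d$sample_id, design$sample_id)), ]
  new_design <- stage_design(d$sample_id, as.character(d$stage), levels(design$stage))

  e <- tibble::as_tibble(expr)[c("gene_id", new_design$sample_id)]
  new_expr <- as_expression(e, value_scale = attr(expr, "value_scale"))
  list(expr = new_expr, design = new_design)
}

#' @export
print.stage_design <- function(x, ...) {
  cat("# stage design: ", nrow(x), " samples in ", nlevels(x$stage),
      " ordered stages (", paste(levels(x$stage), collapse = " < "), ")\n", sep = "")
  NextMethod()
}

# per-stage sample counts, in progression order
stage_counts <- function(design) {
  as.integer(table(design$stage))
}
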