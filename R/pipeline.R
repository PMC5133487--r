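#' Configuration for a full screen-and-pattern run
#'
#' Bundles every tunable of the pipeline: the inputs, the stage ordering
#' (and optional stage merging), the gamma screen parameters, the SOM grid
#' and schedule, and one global seed that fans out to per-phase streams
#' (permutations use `seed + 1`, SOM initialization `seed + 2`) so phases
#' can be re-run independently yet reproducibly.
#'
#' @param expression Path to an expression table, or an expression tibble.
#' @param stages Path to a two-column stage annotation, or a
#'   [stage_design()].
#' @param stage_order Ordered stage levels (required when `stages` is a
#'   path).
#' @param out_dir Output directory for the result tables and manifest.
#' @param merge_map,new_order Optional stage merging (see [merge_stages()]).
#' @param transform `"auto"` applies `log2(x + 1)` when the loaded values
#'   look like linear counts/RPKM (all nonnegative with a maximum above 50,
#'   or an in-memory table flagged `linear_counts`); `"log2_plus1"` forces
#'   it; `"none"` disables it.
#' @param gamma A [gamma_params()] list.
#' @param grid SOM grid `(rows, cols)`.
#' @param som_epochs SOM batch epochs.
#' @param min_fraction Main-pattern membership fraction.
#' @param sd_method Standardization denominator, `"population"` or
#'   `"sample"`.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(expression, stages, stage_order = NULL, out_dir = NULL,
                       merge_map = NULL, new_order = NULL,
                       transform = c("auto", "log2_plus1", "none"),
                       gamma = gamma_params(), grid = c(3, 3),
                       som_epochs = 100, min_fraction = 0.05,
                       sd_method = "population", seed = 20121221) {
  transform <- match.arg(transform)
  structure(list(expression = expression, stages = stages,
                 stage_order = stage_order, out_dir = out_dir,
                 merge_map = merge_map, new_order = new_order,
                 transform = transform, gamma = gamma, grid = grid,
                 som_epochs = som_epochs, min_fraction = min_fraction,
                 sd_method = sd_method, seed = as.integer(seed)),
            class = "run_config")
}

phase_step <- function(phase, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", phase, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole stage-trend pipeline
#'
#' Loads (or takes) the expression table and stage design, aligns them,
#' optionally merges stages, screens every gene with the fuzzy gamma
#' statistic, profiles and clusters the selected genes on a SOM, annotates
#' each pattern with its half-change point, and (when `out_dir` is set)
#' writes the gamma table, pattern membership, pattern summaries, codebook
#' and a JSON manifest. Identical configuration and inputs give identical
#' outputs; on error, partially written outputs are removed.
#'
#' @param config A [run_config()].
#' @return A list with `screen`, `profiles`, `model`, `patterns`,
#'   `manifest` (invisibly returns the same list when writing to disk).
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(phase) {
    t1 <- proc.time()[["elapsed"]]
    timings[[phase]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  expr <- phase_step("load", {
    if (is.character(config$expression)) {
      e <- read_expression(config$expression, transform = "none")
      v <- as.matrix(tibble::as_tibble(e)[-1])
      # "auto": nonnegative values reaching past 50 look like counts/RPKM,
      # not log signal
      looks_linear <- min(v) >= 0 && max(v) > 50
      scale <- if (config$transform == "log2_plus1" ||
                   (config$transform == "auto" && looks_linear))
        "linear_counts" else "log_signal"
      as_expression(tibble::as_tibble(e), value_scale = scale)
    } else config$expression
  })
  design <- phase_step("load", {
    if (is.character(config$stages)) {
      if (is.null(config$stage_order)) stop("stage_order is required with a stage file")
      read_stage_design(config$stages, config$stage_order)
    } else config$stages
  })
  if (config$transform %in% c("auto", "log2_plus1") &&
      attr(expr, "value_scale") == "linear_counts") {
    df <- tibble::as_tibble(expr)
    df[-1] <- lapply(df[-1], function(v) log2(v + 1))
    expr <- as_expression(df, value_scale = "log_signal")
  }
  checksums <- if (is.character(config$expression)) {
    as.list(tools::md5sum(c(expression = config$expression,
                            stages = config$stages)))
  } else NULL
  tick("load")

  if (!is.null(config$merge_map)) {
    design <- phase_step("merge_stages",
                         merge_stages(design, unlist(config$merge_map), config$new_order))
  }
  al <- phase_step("align", align_samples(expr, design))
  expr <- al$expr; design <- al$design
  tick("align")

  gpar <- config$gamma
  gpar$seed <- config$seed + 1L
  screen <- phase_step("screen_genes", screen_genes(expr, design, gpar))
  tick("screen")

  sel <- screen$gene_id[screen$selected]
  model <- NULL; profiles <- NULL; patterns <- NULL
  if (length(sel) > 0) {
    profiles <- phase_step("profile",
                           standardize_and_orient(expr, design, sel,
                                                  sd_method = config$sd_method))
    model <- phase_step("train_som",
                        train_som(profiles, grid = config$grid,
                                  n_epochs = config$som_epochs,
                                  seed = config$seed + 2L))
    patterns <- phase_step("summarize",
                           summarize_patterns(model, profiles,
                                              min_fraction = config$min_fraction))
  }
  tick("pattern")

  manifest <- list(
    package = "stagetrend",
    version = as.character(utils::packageVersion("stagetrend")),
    config = serialize_config(config),
    input_checksums = checksums,
    stage_levels = levels(design$stage),
    samples_per_stage = as.list(stats::setNames(stage_counts(design),
                                                levels(design$stage))),
    n_genes_tested = nrow(screen),
    n_genes_undefined = sum(is.na(screen$gamma)),
    n_genes_selected = length(sel),
    unit_sizes = if (!is.null(model)) model$unit_sizes else integer(0),
    n_main_patterns = if (!is.null(patterns)) sum(patterns$main) else 0L,
    timings_sec = as.list(timings))

  result <- list(screen = screen, profiles = profiles, model = model,
                 patterns = patterns, manifest = manifest)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir,
                           stage_levels = levels(design$stage))
  }
  result
}

serialize_config <- function(config) {
  list(expression = if (is.character(config$expression)) config$expression else "<in-memory>",
       stages = if (is.character(config$stages)) config$stages else "<in-memory>",
       stage_order = config$stage_order,
       merge_map = as.list(config$merge_map), new_order = config$new_order,
       transform = config$transform,
       gamma = unclass(config$gamma), grid = config$grid,
       som_epochs = config$som_epochs, min_fraction = config$min_fraction,
       sd_method = config$sd_method, seed = config$seed)
}

write_pipeline_outputs <- function(result, out_dir, stage_levels) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("[write] ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    f <- file.path(out_dir, "gamma.tsv")
    readr::write_tsv(tibble::as_tibble(result$screen), f, progress = FALSE)
    written <- c(written, f)

    if (!is.null(result$model)) {
      memb <- dplyr::left_join(
        result$model$assignments,
        tibble::as_tibble(result$profiles)[c("gene_id", "orientation")],
        by = "gene_id")
      memb <- dplyr::left_join(
        memb, tibble::as_tibble(result$screen)[c("gene_id", "gamma")],
        by = "gene_id")
      f <- file.path(out_dir, "membership.tsv")
      readr::write_tsv(memb, f, progress = FALSE)
      written <- c(written, f)

      pat <- tibble::as_tibble(result$patterns)
      prof <- do.call(rbind, pat$stage_profile)
      colnames(prof) <- paste0("mean_z_", stage_levels)
      pat <- dplyr::bind_cols(
        dplyr::select(pat, -"gene_ids", -"stage_profile"),
        tibble::as_tibble(prof))
      f <- file.path(out_dir, "patterns.tsv")
      readr::write_tsv(pat, f, progress = FALSE)
      written <- c(written, f)

      cb <- tibble::as_tibble(as.data.frame(result$model$codebook))
      names(cb) <- paste0("pos", seq_len(ncol(cb)))
      cb <- dplyr::bind_cols(tibble::tibble(unit = seq_len(nrow(cb))), cb)
      f <- file.path(out_dir, "codebook.tsv")
      readr::write_tsv(cb, f, progress = FALSE)
      written <- c(written, f)
    }
    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, f)
  }, error = on_fail)
  invisible(written)
}
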