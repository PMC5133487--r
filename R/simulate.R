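#' Configuration for the staged RNA-seq simulator
#'
#' Defaults reproduce the validation design: 1000 genes over 18 samples in 6
#' stages of 3 replicates, with 200 trend genes split evenly over four
#' archetypes (up-early, up-late, down-early, down-late), each spanning a
#' total fold change of 4 from first to last stage.
#'
#' @param n_genes Total number of genes (default 1000).
#' @param n_stages Number K of ordered stages (default 6).
#' @param reps_per_stage Replicates per stage (default 3).
#' @param trend_counts Named counts of trend genes per archetype; names must
#'   be among `up_early`, `up_late`, `down_early`, `down_late` (default 50
#'   each).
#' @param total_fold Cumulative fold change F > 1 from first to last stage
#'   (default 4).
#' @param alpha_early,alpha_late Exponents of the change schedule
#'   `s(k) = ((k - 1) / (K - 1)) ^ alpha`; a concave schedule
#'   (`alpha_early = 0.5`) front-loads the change, a convex one
#'   (`alpha_late = 2`) back-loads it.
#' @param baseline `"parametric_nb"` draws each gene's counts from a
#'   negative binomial with a log-normal mean (meanlog 4, sdlog 2 on the
#'   count scale) and gamma-distributed dispersion (shape 2, scale 0.15);
#'   `"template_resample"` resamples counts from rows of a user template.
#' @param template Optional expression tibble of counts for
#'   `"template_resample"` (needs at least `n_genes` rows).
#' @param mean_log_mean,mean_log_sd Log-normal parameters of the gene mean.
#' @param disp_shape,disp_scale Gamma parameters of the per-gene NB
#'   dispersion.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_stages = 6, reps_per_stage = 3,
                       trend_counts = c(up_early = 50, up_late = 50,
                                        down_early = 50, down_late = 50),
                       total_fold = 4, alpha_early = 0.5, alpha_late = 2,
                       baseline = c("parametric_nb", "template_resample"),
                       template = NULL,
                       mean_log_mean = 4, mean_log_sd = 2,
                       disp_shape = 2, disp_scale = 0.15, seed = 1) {
  baseline <- match.arg(baseline)
  archetypes <- c("up_early", "up_late", "down_early", "down_late")
  if (is.null(names(trend_counts)) || !all(names(trend_counts) %in% archetypes)) {
    stop("trend_counts must be named with archetypes: ",
         paste(archetypes, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_genes >= 1, n_stages >= 2, reps_per_stage >= 1,
            all(trend_counts >= 0), sum(trend_counts) <= n_genes,
            total_fold > 1, alpha_early > 0, alpha_late > 0)
  if (baseline == "template_resample") {
    if (is.null(template)) stop("template_resample needs a template matrix", call. = FALSE)
    if (nrow(template) < n_genes) {
      stop("template has ", nrow(template), " rows but n_genes = ", n_genes, call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, n_stages = n_stages,
                 reps_per_stage = reps_per_stage,
                 trend_counts = trend_counts[intersect(archetypes, names(trend_counts))],
                 total_fold = total_fold, alpha_early = alpha_early,
                 alpha_late = alpha_late, baseline = baseline,
                 template = template, mean_log_mean = mean_log_mean,
                 mean_log_sd = mean_log_sd, disp_shape = disp_shape,
                 disp_scale = disp_scale, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-stage fold multipliers for a trend archetype
#'
#' The change schedule is `s(k) = ((k - 1) / (K - 1)) ^ alpha`, rising from
#' 0 at the first stage to 1 at the last; up archetypes use multipliers
#' `F ^ s(k)` and down archetypes their reciprocals, so the first-stage
#' multiplier is always 1 and the last is F (up) or 1/F (down). Early
#' archetypes use the concave exponent, late ones the convex exponent.
#'
#' @param archetype One of `up_early`, `up_late`, `down_early`, `down_late`.
#' @param K Number of stages.
#' @param total_fold Total fold F > 1.
#' @param alpha_early,alpha_late Schedule exponents.
#' @return Numeric vector of K multipliers, strictly monotone in stage.
#' @export
trend_multipliers <- function(archetype, K, total_fold = 4,
                              alpha_early = 0.5, alpha_late = 2) {
  archetype <- match.arg(archetype, c("up_early", "up_late", "down_early", "down_late"))
  if (total_fold <= 1) stop("total_fold must exceed 1", call. = FALSE)
  if (K < 2) stop("need at least 2 stages", call. = FALSE)
  alpha <- if (grepl("early$", archetype)) alpha_early else alpha_late
  s <- ((seq_len(K) - 1) / (K - 1))^alpha
  if (grepl("^up", archetype)) total_fold^s else total_fold^(-s)
}

# Draws the stage-free baseline; assumes the RNG is already seeded by the
# caller. Returns the count matrix plus the per-gene NB parameters needed
# for trend injection.
draw_baseline <- function(config) {
  n_samp <- config$n_stages * config$reps_per_stage
  gene_id <- sprintf("G%04d", seq_len(config$n_genes))
  sample_id <- sprintf("S%02d_%d",
                       rep(seq_len(config$n_stages), each = config$reps_per_stage),
                       rep(seq_len(config$reps_per_stage), config$n_stages))
  if (config$baseline == "parametric_nb") {
    mu <- stats::rlnorm(config$n_genes, meanlog = config$mean_log_mean,
                        sdlog = config$mean_log_sd)
    disp <- stats::rgamma(config$n_genes, shape = config$disp_shape,
                          scale = config$disp_scale)
    counts <- matrix(stats::rnbinom(config$n_genes * n_samp,
                                    mu = rep(mu, n_samp),
                                    size = rep(1 / disp, n_samp)),
                     nrow = config$n_genes, ncol = n_samp)
    list(counts = counts, gene_id = gene_id, sample_id = sample_id,
         mu = mu, disp = disp)
  } else {
    tm <- expr_matrix(config$template)
    rows <- sample.int(nrow(tm), config$n_genes, replace = FALSE)
    counts <- t(vapply(rows, function(r) {
      sample(tm[r, ], n_samp, replace = TRUE)
    }, numeric(n_samp)))
    list(counts = counts, gene_id = gene_id, sample_id = sample_id,
         mu = NULL, disp = NULL)
  }
}

baseline_to_expr <- function(bl) {
  m <- bl$counts
  dimnames(m) <- NULL
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- bl$sample_id
  as_expression(dplyr::bind_cols(tibble::tibble(gene_id = bl$gene_id), df),
                value_scale = "linear_counts")
}

#' Simulate a stage-free baseline count matrix
#'
#' Draws the no-trend counts only: every gene's expectation is constant
#' across samples. Used directly for null-calibration experiments and as
#' the first step of [simulate_dataset()].
#'
#' @param config A [sim_config()].
#' @return An expression tibble of counts (`value_scale = "linear_counts"`).
#' @export
simulate_baseline <- function(config) {
  set.seed(config$seed)
  baseline_to_expr(draw_baseline(config))
}

#' Simulate a staged RNA-seq dataset with ground-truth trend genes
#'
#' Generates the baseline, randomly selects the trend genes, and redraws
#' their counts stage by stage with the archetype's per-stage fold
#' multiplier applied to the gene mean (negative-binomial redraw in
#' parametric mode, Poisson redraw around the scaled resampled value in
#' template mode). All remaining genes keep constant expectation across
#' stages. Identical configurations (including the seed) give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (counts), `design` (a [stage_design()] with
#'   stages `S1 < ... < SK`) and `truth`, a tibble with `gene_id`,
#'   `archetype` (`"null"` for untouched genes) and a list-column
#'   `multipliers` of per-stage expected fold multipliers (all 1 for null
#'   genes).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  bl <- draw_baseline(config)
  K <- config$n_stages
  reps <- config$reps_per_stage
  stage_of_col <- rep(seq_len(K), each = reps)

  n_trend <- sum(config$trend_counts)
  archetype <- rep("null", config$n_genes)
  mult <- rep(list(rep(1, K)), config$n_genes)
  if (n_trend > 0) {
    trend_idx <- sample.int(config$n_genes, n_trend)
    labels <- rep(names(config$trend_counts), config$trend_counts)
    for (t in seq_len(n_trend)) {
      g <- trend_idx[t]
      archetype[g] <- labels[t]
      m <- trend_multipliers(labels[t], K, config$total_fold,
                             config$alpha_early, config$alpha_late)
      mult[[g]] <- m
      if (config$baseline == "parametric_nb") {
        bl$counts[g, ] <- stats::rnbinom(K * reps,
                                         mu = bl$mu[g] * m[stage_of_col],
                                         size = 1 / bl$disp[g])
      } else {
        bl$counts[g, ] <- stats::rpois(K * reps,
                                       lambda = bl$counts[g, ] * m[stage_of_col])
      }
    }
  }
  design <- stage_design(bl$sample_id, paste0("S", stage_of_col),
                         paste0("S", seq_len(K)))
  truth <- tibble::tibble(gene_id = bl$gene_id, archetype = archetype,
                          multipliers = mult)
  list(expr = baseline_to_expr(bl), design = design, truth = truth)
}

#' Score a detection run against simulation ground truth
#'
#' @param truth The `truth` tibble from [simulate_dataset()].
#' @param screen A `gamma_screen` result on the same genes (its `selected`
#'   column defines the detected set).
#' @param model Optional `som_patterns` object fitted to the selected genes;
#'   enables per-archetype pattern purity.
#' @return A list of class `detection_metrics`: `detected`, `tp`, `fp`,
#'   `fn`, `tn`, `precision` (fraction of detected genes that are true trend
#'   genes; `NA` when nothing is detected), `accuracy` (whole-gene-set
#'   classification accuracy `(TP + TN) / n`), and `purity`, a tibble with
#'   the fraction of each archetype's detected members that share its
#'   majority SOM unit (`NULL` without `model`).
#' @export
evaluate_detection <- function(truth, screen, model = NULL) {
  if (!setequal(truth$gene_id, screen$gene_id)) {
    stop("truth and screen cover different gene universes", call. = FALSE)
  }
  df <- dplyr::left_join(tibble::as_tibble(screen)[c("gene_id", "selected")],
                         tibble::as_tibble(truth)[c("gene_id", "archetype")],
                         by = "gene_id")
  is_trend <- df$archetype != "null"
  tp <- sum(df$selected & is_trend)
  fp <- sum(df$selected & !is_trend)
  fn <- sum(!df$selected & is_trend)
  tn <- sum(!df$selected & !is_trend)
  detected <- tp + fp

  purity <- NULL
  if (!is.null(model)) {
    asg <- model$assignments
    pd <- df |>
      dplyr::filter(.data$selected, is_trend) |>
      dplyr::inner_join(asg, by = "gene_id") |>
      dplyr::group_by(.data$archetype) |>
      dplyr::summarise(n_detected = dplyr::n(),
                       majority_unit = as.integer(names(which.max(table(.data$unit)))),
                       purity = max(table(.data$unit)) / dplyr::n(),
                       .groups = "drop")
    purity <- pd
  }
  structure(list(detected = detected, tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = if (detected > 0) tp / detected else NA_real_,
                 accuracy = (tp + tn) / nrow(df),
                 purity = purity),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("# detection vs ground truth: ", x$detected, " detected (TP ", x$tp,
      ", FP ", x$fp, ", FN ", x$fn, ")\n", sep = "")
  cat("  precision ", format(x$precision, digits = 4),
      ", classification accuracy ", format(x$accuracy, digits = 4), "\n", sep = "")
  if (!is.null(x$purity)) {
    cat("  archetype purity:\n")
    print(x$purity)
  }
  invisible(x)
}
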