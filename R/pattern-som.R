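#' Standardize, orient and intensity-sort selected gene profiles
#'
#' Each gene is z-scored across samples (mean 0, standard deviation 1;
#' population denominator by default), oriented ascending when its raw mean
#' expression in the last stage is strictly higher than in the first stage
#' and descending otherwise, and its standardized values are then sorted by
#' intensity in that direction, carrying the sample stages along. The sort
#' lets samples swap positions by signal so that a few noisy samples do not
#' break an otherwise monotone profile. Per-stage means of the unsorted
#' z-scores are kept for trend annotation, sign-flipped for descending genes
#' so that every profile rises on a common scale.
#'
#' @param expr Expression tibble aligned to `design`.
#' @param design A [stage_design()].
#' @param gene_ids Genes to profile (default: all genes in `expr`); normally
#'   the selected set from [screen_genes()].
#' @param sd_method `"population"` (divide by the n-denominator standard
#'   deviation) or `"sample"` (n - 1).
#' @return A tibble of class `oriented_profiles`, one row per gene, with
#'   list-columns `sorted` (sorted z-scores, length n), `sorted_stage`
#'   (stage labels carried through the sort) and `stage_means` (length-K
#'   oriented per-stage means).
#' @export
standardize_and_orient <- function(expr, design, gene_ids = NULL,
                                   sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  samp <- expr_samples(expr)
  if (!setequal(samp, design$sample_id)) {
    stop("expression samples and design samples differ; run align_samples() first",
         call. = FALSE)
  }
  design <- design[match(samp, design$sample_id), ]
  X <- expr_matrix(expr)
  if (is.null(gene_ids)) gene_ids <- rownames(X)
  miss <- setdiff(gene_ids, rownames(X))
  if (length(miss) > 0) stop("unknown gene ids: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- X[gene_ids, , drop = FALSE]

  stages <- design$stage
  K <- nlevels(stages)
  first <- which(as.integer(stages) == 1)
  last <- which(as.integer(stages) == K)
  n <- ncol(X)

  rows <- purrr::map(seq_along(gene_ids), function(g) {
    x <- X[g, ]
    s <- if (sd_method == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
    if (s <= 0) {
      stop("zero-variance gene '", gene_ids[g],
           "' cannot be standardized (exclude it upstream)", call. = FALSE)
    }
    z <- (x - mean(x)) / s
    asc <- mean(x[last]) > mean(x[first])
    ord <- order(z, decreasing = !asc)
    sm <- tapply(z, stages, mean)
    if (!asc) sm <- -sm
    tibble::tibble(gene_id = gene_ids[g],
                   orientation = if (asc) "ascending" else "descending",
                   sorted = list(unname(z[ord])),
                   sorted_stage = list(as.character(stages)[ord]),
                   stage_means = list(as.vector(sm)))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, stage_levels = levels(stages), n_samples = n,
            sd_method = sd_method,
            class = c("oriented_profiles", class(out)))
}

# genes x n matrix of the sorted profiles
profile_matrix <- function(profiles) {
  m <- do.call(rbind, profiles$sorted)
  rownames(m) <- profiles$gene_id
  m
}

#' Train a batch self-organizing map on sorted gene profiles
#'
#' Codebook vectors are initialized from a random sample of input rows and
#' updated by batch training: each epoch assigns every profile to its
#' best-matching unit (BMU, nearest codebook vector in Euclidean distance,
#' ties to the lowest unit index) and replaces each codebook vector by the
#' Gaussian-neighborhood-weighted mean of all profiles, with the
#' neighborhood radius on the rectangular grid shrinking linearly from
#' `max(grid) / 2` to 0.5 over the epochs. Training is deterministic given
#' the seed.
#'
#' @param profiles An `oriented_profiles` tibble (or a numeric matrix of
#'   profiles in rows).
#' @param grid Integer pair `(rows, cols)` of the unit grid (default 3 x 3,
#'   allowing up to 9 candidate patterns).
#' @param n_epochs Number of batch epochs (default 100).
#' @param radius Initial and final neighborhood radius; defaults to
#'   `c(max(grid) / 2, 0.5)`.
#' @param seed Integer seed for the codebook initialization.
#' @return An object of class `som_patterns` with the codebook
#'   (units x profile length), the per-gene unit assignments, unit sizes and
#'   the quantization-error trace.
#' @export
train_som <- function(profiles, grid = c(3, 3), n_epochs = 100,
                      radius = NULL, seed = NULL) {
  X <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (nrow(X) < 1) stop("no profiles to cluster", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("row", seq_len(nrow(X)))
  if (ncol(X) < 2) stop("profiles need length >= 2", call. = FALSE)
  stopifnot(length(grid) == 2, all(grid >= 1), n_epochs >= 1)
  U <- grid[1] * grid[2]
  if (is.null(radius)) radius <- c(max(grid) / 2, 0.5)

  # unit coordinates on the rectangular grid, unit index running row-major
  coords <- as.matrix(expand.grid(col = seq_len(grid[2]), row = seq_len(grid[1])))
  ud2 <- as.matrix(stats::dist(coords))^2   # squared inter-unit grid distances

  if (!is.null(seed)) set.seed(seed)
  init_rows <- sample.int(nrow(X), U, replace = nrow(X) < U)
  M <- X[init_rows, , drop = FALSE]
  rownames(M) <- NULL

  radii <- if (n_epochs == 1) radius[1] else
    seq(radius[1], radius[2], length.out = n_epochs)
  qe <- numeric(n_epochs)
  xs <- rowSums(X^2)
  for (e in seq_len(n_epochs)) {
    D <- outer(xs, rowSums(M^2), "+") - 2 * X %*% t(M)   # genes x units, squared
    bmu <- max.col(-D, ties.method = "first")
    H <- exp(-ud2 / (2 * radii[e]^2))
    W <- H[, bmu, drop = FALSE]                          # units x genes weights
    M <- (W %*% X) / rowSums(W)
    D <- outer(xs, rowSums(M^2), "+") - 2 * X %*% t(M)
    bmu <- max.col(-D, ties.method = "first")
    qe[e] <- mean(sqrt(pmax(D[cbind(seq_len(nrow(X)), bmu)], 0)))
  }

  assignments <- tibble::tibble(
    gene_id = rownames(X), unit = bmu,
    dist = sqrt(pmax(D[cbind(seq_len(nrow(X)), bmu)], 0)))
  structure(list(codebook = M, grid = grid, topology = "rectangular",
                 assignments = assignments,
                 unit_sizes = tabulate(bmu, nbins = U),
                 n_epochs = n_epochs, radius = radius, seed = seed,
                 quantization_error = qe),
            class = "som_patterns")
}

#' @export
print.som_patterns <- function(x, ...) {
  cat("# self-organizing map: ", x$grid[1], "x", x$grid[2],
      " rectangular grid, ", nrow(x$assignments), " profiles, ",
      sum(x$unit_sizes > 0), " populated units\n", sep = "")
  cat("  unit sizes: ", paste(x$unit_sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-gene unit assignments of a trained SOM
#' @param x A `som_patterns` object.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `unit`, `dist` (distance to the BMU).
#' @method tidy som_patterns
#' @export
tidy.som_patterns <- function(x, ...) x$assignments

#' One-row training summary of a SOM
#' @param x A `som_patterns` object.
#' @param ... Unused.
#' @return One-row tibble: grid, genes, populated units, final quantization
#'   error.
#' @method glance som_patterns
#' @export
glance.som_patterns <- function(x, ...) {
  tibble::tibble(grid_rows = x$grid[1], grid_cols = x$grid[2],
                 n_genes = nrow(x$assignments),
                 n_units_used = sum(x$unit_sizes > 0),
                 n_epochs = x$n_epochs,
                 quantization_error = x$quantization_error[x$n_epochs])
}

#' Plot SOM codebook profiles on the unit grid
#' @param object A `som_patterns` object.
#' @param ... Unused.
#' @return A ggplot object, one facet per unit with its member count.
#' @method autoplot som_patterns
#' @export
autoplot.som_patterns <- function(object, ...) {
  cb <- object$codebook
  df <- tidyr::expand_grid(unit = seq_len(nrow(cb)), pos = seq_len(ncol(cb)))
  df$value <- as.vector(t(cb))
  df$label <- sprintf("unit %d (n = %d)", df$unit, object$unit_sizes[df$unit])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~label, nrow = object$grid[1]) +
    ggplot2::labs(x = "intensity-sorted sample position",
                  y = "codebook value (z units)") +
    ggplot2::theme_minimal()
}

#' Total change and half-change point of a stage profile
#'
#' For a per-stage mean profile (pre-oriented to rise), delta is the total
#' range max - min, and the half-change position is the smallest stage
#' coordinate t in `[1, K]` at which the piecewise-linear interpolation of
#' the profile first reaches `min + delta / 2`. Patterns reaching half of
#' their total change in the first half of the stage axis
#' (`position <= (K + 1) / 2`) are classified early, the rest late. A flat
#' profile (delta = 0) is reported at position 1, early, and flagged.
#'
#' @param stage_profile Numeric vector of per-stage means, length K >= 2.
#' @return List with `delta`, `position`, `trend_class`, `flat`.
#' @examples
#' compute_half_change(c(0, 0.9, 0.95, 1))  # crosses early, ~1.56
#' @export
compute_half_change <- function(stage_profile) {
  K <- length(stage_profile)
  if (K < 2) stop("need at least 2 stages", call. = FALSE)
  if (any(!is.finite(stage_profile))) stop("profile must be finite", call. = FALSE)
  delta <- max(stage_profile) - min(stage_profile)
  if (delta == 0) {
    return(list(delta = 0, position = 1, trend_class = "early", flat = TRUE))
  }
  thr <- min(stage_profile) + delta / 2
  if (stage_profile[1] >= thr) {
    pos <- 1
  } else {
    k <- which(stage_profile[-1] >= thr & stage_profile[-K] < thr)[1]
    pos <- k + (thr - stage_profile[k]) / (stage_profile[k + 1] - stage_profile[k])
  }
  list(delta = delta, position = pos,
       trend_class = if (pos <= (K + 1) / 2) "early" else "late",
       flat = FALSE)
}

#' Summarize SOM units as stage-trend patterns
#'
#' Builds one summary row per populated unit: its member genes, the mean of
#' their oriented per-stage profiles, the total change delta, the
#' interpolated stage position where half of that change is reached, and the
#' resulting early/late trend class. Units holding at least `min_fraction`
#' of all clustered genes are flagged as main patterns.
#'
#' @param model A `som_patterns` object.
#' @param profiles The `oriented_profiles` tibble the map was trained on.
#' @param min_fraction Minimum member fraction for a unit to count as a main
#'   pattern (default 0.05).
#' @return A tibble of class `pattern_summary`, one row per populated unit:
#'   `unit`, `n_genes`, `main`, `n_up`, `n_down`, `delta`,
#'   `half_change_position`, `trend_class`, `flat`, and list-columns
#'   `gene_ids` and `stage_profile`.
#' @export
summarize_patterns <- function(model, profiles, min_fraction = 0.05) {
  asg <- model$assignments
  if (!setequal(asg$gene_id, profiles$gene_id)) {
    stop("model assignments and profiles cover different genes", call. = FALSE)
  }
  stage_levels <- attr(profiles, "stage_levels")
  total <- nrow(asg)
  joined <- dplyr::left_join(asg, tibble::as_tibble(profiles), by = "gene_id")
  out <- joined |>
    dplyr::group_by(.data$unit) |>
    dplyr::group_modify(function(d, key) {
      prof <- colMeans(do.call(rbind, d$stage_means))
      hc <- compute_half_change(prof)
      tibble::tibble(n_genes = nrow(d),
                     n_up = sum(d$orientation == "ascending"),
                     n_down = sum(d$orientation == "descending"),
                     delta = hc$delta,
                     half_change_position = hc$position,
                     trend_class = hc$trend_class,
                     flat = hc$flat,
                     gene_ids = list(d$gene_id),
                     stage_profile = list(prof))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(main = .data$n_genes >= min_fraction * total,
                  .after = "n_genes")
  structure(out, stage_levels = stage_levels, min_fraction = min_fraction,
            class = c("pattern_summary", class(out)))
}

#' Plot mean stage profiles of SOM patterns
#' @param object A `pattern_summary` tibble.
#' @param main_only Plot only main patterns (default TRUE).
#' @param ... Unused.
#' @return A ggplot of per-stage mean z profiles, one line per pattern, with
#'   the half-change position marked.
#' @method autoplot pattern_summary
#' @export
autoplot.pattern_summary <- function(object, main_only = TRUE, ...) {
  levels <- attr(object, "stage_levels")
  df <- tibble::as_tibble(object)
  if (main_only) df <- dplyr::filter(df, .data$main)
  long <- df |>
    dplyr::mutate(pattern = sprintf("unit %d (%s, n = %d)",
                                    .data$unit, .data$trend_class, .data$n_genes)) |>
    dplyr::select("pattern", "unit", "half_change_position", "stage_profile") |>
    tidyr::unnest_longer("stage_profile", values_to = "mean_z") |>
    dplyr::group_by(.data$pattern) |>
    dplyr::mutate(stage = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$mean_z,
                                     colour = .data$pattern)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$half_change_position,
                                     colour = .data$pattern),
                        linetype = 3, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = seq_along(levels), labels = levels) +
    ggplot2::labs(x = "stage", y = "mean oriented z-score", colour = NULL) +
    ggplot2::theme_minimal()
}
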