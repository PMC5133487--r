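#' Parameters for the gamma stage screen
#'
#' @param r_fraction Fraction of each gene's interquartile range used as the
#'   fuzzy tie tolerance r (default 0.10). With `r_fraction = 0` the
#'   statistic reduces to the classical crisp Goodman-Kruskal gamma.
#' @param similarity_family Fuzzy strict-order family; only `"linear"` (a
#'   ramp from 0 at `b - a <= 0` to 1 at `b - a >= r`) is implemented.
#' @param t_norm Aggregation of the two per-pair order degrees; only `"min"`.
#' @param n_permutations Number of stage-label permutations B for the
#'   permutation p-value (default 1000).
#' @param gamma_threshold Select genes with `|gamma|` strictly above this
#'   (default 0.50).
#' @param fdr_threshold Select genes with BH-adjusted q strictly below this
#'   (default 0.05).
#' @param m_total Total number of tests used in the BH adjustment; defaults
#'   to the number of genes with a defined gamma. Set it to the platform
#'   size (e.g. all array probesets) to adjust against features that were
#'   never screened.
#' @param r_y_fraction Tolerance fraction applied to the stage codes
#'   (default 0: stages are compared crisply, so gamma is invariant to any
#'   strictly increasing recoding of the stage ranks).
#' @param seed Integer seed for the permutation stream; `NULL` uses the
#'   session RNG state.
#' @return A list of class `gamma_params`.
#' @export
gamma_params <- function(r_fraction = 0.10, similarity_family = "linear",
                         t_norm = "min", n_permutations = 1000,
                         gamma_threshold = 0.50, fdr_threshold = 0.05,
                         m_total = NULL, r_y_fraction = 0, seed = NULL) {
  similarity_family <- match.arg(similarity_family, "linear")
  t_norm <- match.arg(t_norm, "min")
  stopifnot(r_fraction >= 0, r_y_fraction >= 0,
            n_permutations >= 1, gamma_threshold >= 0,
            fdr_threshold > 0, fdr_threshold < 1)
  if (!is.null(m_total)) stopifnot(m_total >= 1)
  structure(list(r_fraction = r_fraction, similarity_family = similarity_family,
                 t_norm = t_norm, n_permutations = as.integer(n_permutations),
                 gamma_threshold = gamma_threshold, fdr_threshold = fdr_threshold,
                 m_total = m_total, r_y_fraction = r_y_fraction, seed = seed),
            class = "gamma_params")
}

#' Fuzzy degree to which one value strictly precedes another
#'
#' With tolerance `r = 0` this is the crisp indicator of `b > a`. With
#' `r > 0` the degree ramps linearly: 0 when `b <= a`, 1 when `b - a >= r`,
#' so differences smaller than r count only partially as an ordering.
#'
#' @param a,b Numeric vectors (recycled).
#' @param r Nonnegative tolerance.
#' @return Degrees in `[0, 1]`.
#' @examples
#' strict_order_degree(0, 0.05, r = 0.1)  # 0.5, halfway up the ramp
#' @export
strict_order_degree <- function(a, b, r) {
  if (any(r < 0)) stop("tolerance r must be nonnegative", call. = FALSE)
  d <- b - a
  if (length(r) == 1 && r == 0) return(as.numeric(d > 0))
  ifelse(r == 0, as.numeric(d > 0), pmin(1, pmax(0, d / r)))
}

# n x n matrix A with A[i, j] = degree(x_i strictly below x_j)
order_degree_matrix <- function(x, r) {
  d <- outer(x, x, FUN = function(a, b) b - a)
  if (r == 0) {
    array(as.numeric(d > 0), dim = dim(d))
  } else {
    # keep the matrix first in pmin/pmax: they take attributes (dims) from
    # their first argument
    pmin(pmax(d, 0) / r, 1)
  }
}

#' Fuzzy concordance and discordance masses of two paired vectors
#'
#' Sums, over all ordered pairs i != j, the min-t-norm combination of the
#' strict-order degrees of x and y in the same direction (concordance C) and
#' in opposite directions (discordance D). With both tolerances 0 these are
#' exactly twice the classical concordant/discordant pair counts (each
#' unordered pair is visited in both orders); gamma is unaffected by the
#' doubling.
#'
#' @param x,y Numeric vectors of equal length n >= 2.
#' @param r_x,r_y Nonnegative tolerances for x and y.
#' @return Named numeric vector `c(C = ..., D = ...)`.
#' @export
fuzzy_pair_masses <- function(x, y, r_x = 0, r_y = 0) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite", call. = FALSE)
  Ax <- order_degree_matrix(x, r_x)
  Ay <- order_degree_matrix(y, r_y)
  # each ordered pair contributes through its ascending and its descending
  # orientation; only one can be nonzero, so this doubles the unordered count
  c(C = sum(pmin(Ax, Ay)) + sum(pmin(t(Ax), t(Ay))),
    D = sum(pmin(Ax, t(Ay))) + sum(pmin(t(Ax), Ay)))
}

#' Goodman-Kruskal gamma of a gene against ordinal stage codes
#'
#' gamma = (C - D) / (C + D) over the fuzzy pair masses, with the gene-side
#' tolerance set to `r_fraction` times the gene's interquartile range
#' (linear-interpolation percentiles) and the stage side compared crisply by
#' default. A gene whose masses are both zero (for example a constant gene)
#' has no defined gamma and is flagged `undefined = TRUE`.
#'
#' @param x Numeric expression vector.
#' @param y Ordinal stage codes aligned to `x`.
#' @param params A [gamma_params()] list (uses `r_fraction`, `r_y_fraction`).
#' @param r_x Override the computed gene tolerance (mainly internal).
#' @return List with `gamma`, `C`, `D`, `r_x`, `undefined`.
#' @export
gamma_statistic <- function(x, y, params = gamma_params(), r_x = NULL) {
  if (length(unique(y)) < 2) {
    stop("need at least 2 distinct stage codes to correlate against", call. = FALSE)
  }
  if (is.null(r_x)) r_x <- params$r_fraction * stats::IQR(x, type = 7)
  r_y <- params$r_y_fraction * stats::IQR(y, type = 7)
  m <- fuzzy_pair_masses(x, y, r_x = r_x, r_y = r_y)
  tot <- m[["C"]] + m[["D"]]
  list(gamma = if (tot > 0) (m[["C"]] - m[["D"]]) / tot else NA_real_,
       C = m[["C"]], D = m[["D"]], r_x = r_x, undefined = tot <= 0)
}

#' Two-sided permutation p-value for an observed gamma
#'
#' Compares `|gamma|` of the observed pairing against B uniform random
#' permutations of the stage labels, with the add-one estimator
#' `p = (1 + #\{|gamma_b| >= |gamma_obs|\}) / (B + 1)`, so p is never 0 and
#' the smallest attainable value is `1 / (B + 1)`. The gene tolerance r_x is
#' computed once from x and reused for every permutation. A permutation with
#' zero total pair mass is counted as an exceedance (conservative).
#'
#' @inheritParams gamma_statistic
#' @param seed Optional integer seed.
#' @return List with `p`, `gamma`, `C`, `D`.
#' @export
permutation_pvalue <- function(x, y, params = gamma_params(), seed = params$seed) {
  obs <- gamma_statistic(x, y, params)
  if (obs$undefined) return(list(p = NA_real_, gamma = NA_real_, C = obs$C, D = obs$D))
  if (!is.null(seed)) set.seed(seed)
  B <- params$n_permutations
  n <- length(x)
  r_y <- params$r_y_fraction * stats::IQR(y, type = 7)
  if (r_y == 0) {
    eng <- perm_engine_crisp(x, y, obs$r_x)
    gb <- perm_gammas(eng, B)
  } else {
    Ax <- order_degree_matrix(x, obs$r_x)
    Ay <- order_degree_matrix(y, r_y)
    gb <- vapply(seq_len(B), function(b) {
      p <- sample.int(n)
      Cp <- sum(pmin(Ax, Ay[p, p]))
      Dp <- sum(pmin(Ax, t(Ay[p, p])))
      if (Cp + Dp > 0) (Cp - Dp) / (Cp + Dp) else Inf
    }, numeric(1))
  }
  exceed <- sum(abs(gb) >= abs(obs$gamma) - 1e-12)
  list(p = (1 + exceed) / (B + 1), gamma = obs$gamma, C = obs$C, D = obs$D)
}

# Precomputed structures for fast permutation of a crisp ordinal y against a
# fuzzy x. Because the stage side is binary, min(A, B) = A * B, so each
# permuted mass is a sum of entries of the gene's order-degree matrix at
# permuted pair positions.
perm_engine_crisp <- function(x, y, r_x) {
  n <- length(x)
  A <- order_degree_matrix(x, r_x)
  cmp <- outer(y, y, "<")               # cmp[i, j]: y_i strictly below y_j
  ii <- row(cmp)[cmp]
  jj <- col(cmp)[cmp]
  # stored masses double the one-orientation sums, matching fuzzy_pair_masses
  list(a = as.vector(A), n = n, ii = ii, jj = jj,
       C = 2 * sum(A[cbind(ii, jj)]), D = 2 * sum(A[cbind(jj, ii)]))
}

# gamma for B random relabelings; permutations with zero mass map to Inf so
# they always count as exceedances upstream
perm_gammas <- function(eng, B) {
  n <- eng$n
  m <- length(eng$ii)
  Q <- matrix(0L, nrow = B, ncol = n)
  for (b in seq_len(B)) Q[b, ] <- sample.int(n)
  Qi <- Q[, eng$ii, drop = FALSE]
  Qj <- Q[, eng$jj, drop = FALSE]
  Cb <- rowSums(matrix(eng$a[Qi + (Qj - 1L) * n], nrow = B))
  Db <- rowSums(matrix(eng$a[Qj + (Qi - 1L) * n], nrow = B))
  tot <- Cb + Db
  ifelse(tot > 0, (Cb - Db) / tot, Inf)
}

#' Benjamini-Hochberg q-values against a configurable total test count
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (m p_(j) / j)` clipped to 1,
#' where m may exceed the number of observed p-values: features that were
#' never tested contribute no p-value but still inflate m (e.g. adjusting a
#' screened subset against the whole measuring platform).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m_total Total number of tests; defaults to `length(p_values)`.
#' @return Vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values, m_total = length(p_values)) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m_total < sum(ok)) stop("m_total smaller than the number of p-values", call. = FALSE)
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH", n = m_total)
  out
}

#' Screen every gene for a monotone trend along ordered stages
#'
#' Computes for each gene the fuzzy Goodman-Kruskal gamma against the stage
#' codes, a two-sided permutation p-value, and a BH q-value, then flags genes
#' with `|gamma| > gamma_threshold` and `q < fdr_threshold` as selected.
#' Genes with undefined gamma (zero total pair mass) are kept in the table
#' with an `undefined` direction and are never selected. Permutations for
#' successive genes are drawn from one seeded stream in input gene order, so
#' a run is fully reproducible from `params$seed`.
#'
#' @param expr An expression tibble (see [as_expression()]), already aligned
#'   to `design` (see [align_samples()]).
#' @param design A [stage_design()] covering the expression samples.
#' @param params A [gamma_params()] list.
#' @return A tibble of class `gamma_screen`, one row per gene:
#'   `gene_id`, `gamma`, `C`, `D`, `p_perm`, `q_fdr`, `direction`
#'   (`"up"`/`"down"`/`"undefined"`), `selected`.
#' @export
screen_genes <- function(expr, design, params = gamma_params()) {
  samp <- expr_samples(expr)
  if (!identical(samp, design$sample_id)) {
    if (!setequal(samp, design$sample_id)) {
      stop("expression samples and design samples differ; run align_samples() first",
           call. = FALSE)
    }
    design <- design[match(samp, design$sample_id), ]
  }
  y <- design$stage_code
  if (length(unique(y)) < 2) {
    stop("need at least 2 distinct stages to screen against", call. = FALSE)
  }
  X <- expr_matrix(expr)
  n <- ncol(X)
  B <- params$n_permutations
  if (!is.null(params$seed)) set.seed(params$seed)

  r_y <- params$r_y_fraction * stats::IQR(y, type = 7)
  G <- nrow(X)
  gam <- Cm <- Dm <- p <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    x <- X[g, ]
    r_x <- params$r_fraction * stats::IQR(x, type = 7)
    if (r_y == 0) {
      eng <- perm_engine_crisp(x, y, r_x)
      Cm[g] <- eng$C; Dm[g] <- eng$D
      tot <- eng$C + eng$D
      if (tot > 0) {
        gam[g] <- (eng$C - eng$D) / tot
        gb <- perm_gammas(eng, B)
        p[g] <- (1 + sum(abs(gb) >= abs(gam[g]) - 1e-12)) / (B + 1)
      }
    } else {
      res <- permutation_pvalue(x, y, params, seed = NULL)
      gam[g] <- res$gamma; Cm[g] <- res$C; Dm[g] <- res$D; p[g] <- res$p
    }
  }

  m_total <- if (is.null(params$m_total)) sum(!is.na(p)) else params$m_total
  q <- fdr_adjust(p, m_total = m_total)
  direction <- dplyr::case_when(is.na(gam) ~ "undefined",
                                gam > 0 ~ "up",
                                gam < 0 ~ "down",
                                TRUE ~ "undefined")
  selected <- !is.na(gam) & abs(gam) > params$gamma_threshold &
    !is.na(q) & q < params$fdr_threshold
  out <- tibble::tibble(gene_id = rownames(X), gamma = gam, C = Cm, D = Dm,
                        p_perm = p, q_fdr = q, direction = direction,
                        selected = selected)
  structure(out, params = params, n_samples = n,
            stage_levels = levels(design$stage),
            class = c("gamma_screen", class(out)))
}

#' @export
print.gamma_screen <- function(x, ...) {
  cat("# gamma stage screen: ", nrow(x), " genes, ",
      sum(x$selected), " selected (", sum(is.na(x$gamma)), " undefined)\n", sep = "")
  NextMethod()
}

#' One-row summary of a gamma screen
#'
#' @param x A `gamma_screen` tibble.
#' @param ... Unused.
#' @return A one-row tibble: genes tested/undefined/selected, up/down counts
#'   among selected, and the thresholds used.
#' @method glance gamma_screen
#' @export
glance.gamma_screen <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(n_genes = nrow(x),
                 n_undefined = sum(is.na(x$gamma)),
                 n_selected = sum(x$selected),
                 n_up = sum(x$selected & x$direction == "up"),
                 n_down = sum(x$selected & x$direction == "down"),
                 gamma_threshold = p$gamma_threshold,
                 fdr_threshold = p$fdr_threshold,
                 n_permutations = p$n_permutations)
}

#' Volcano-style view of a gamma screen
#'
#' Plots each gene's gamma against -log10 of its BH q-value, with the
#' selection thresholds drawn and selected genes highlighted.
#'
#' @param object A `gamma_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gamma_screen
#' @export
autoplot.gamma_screen <- function(object, ...) {
  p <- attr(object, "params")
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$gamma))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma,
                                   y = -log10(.data$q_fdr),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * p$gamma_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p$fdr_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Goodman-Kruskal gamma vs stage",
                  y = expression(-log[10] ~ "FDR q"), colour = "selected") +
    ggplot2::theme_minimal()
}
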