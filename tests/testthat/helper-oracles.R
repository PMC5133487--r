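# Independent brute-force oracles and small fixture builders.

# double-loop fuzzy pair masses with scalar ramp degrees and min t-norm;
# every ordered pair is scored in its ascending and descending orientation,
# so crisp masses are twice the unordered pair counts
oracle_fuzzy_masses <- function(x, y, r_x, r_y) {
  n <- length(x)
  deg <- function(a, b, r) {
    if (r == 0) as.numeric(b > a) else min(1, max(0, (b - a) / r))
  }
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    C <- C + min(deg(x[i], x[j], r_x), deg(y[i], y[j], r_y)) +
      min(deg(x[j], x[i], r_x), deg(y[j], y[i], r_y))
    D <- D + min(deg(x[i], x[j], r_x), deg(y[j], y[i], r_y)) +
      min(deg(x[j], x[i], r_x), deg(y[i], y[j], r_y))
  }
  2 * c(C = C, D = D)
}

# classical crisp Goodman-Kruskal gamma by unordered pair counting
oracle_crisp_gamma <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  if (C + D == 0) NA_real_ else (C - D) / (C + D)
}

# textbook BH step-up with configurable total test count m
oracle_bh <- function(p, m) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- Inf
  for (k in rev(seq_len(n))) {
    prev <- min(prev, m * p[o[k]] / k)
    q[o[k]] <- min(1, prev)
  }
  q
}

# tiny staged expression fixture: `strong` genes rise linearly over stages,
# the rest are stage-free noise
make_fixture <- function(n_noise = 20, n_strong = 2, K = 6, reps = 3, seed = 42) {
  set.seed(seed)
  n <- K * reps
  stage <- rep(seq_len(K), each = reps)
  ids <- c(sprintf("trend%02d", seq_len(n_strong)),
           sprintf("noise%02d", seq_len(n_noise)))
  vals <- rbind(
    t(vapply(seq_len(n_strong), function(i) stage + stats::rnorm(n, 0, 0.1),
             numeric(n))),
    matrix(stats::rnorm(n_noise * n), nrow = n_noise, ncol = n))
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- sprintf("samp%02d", seq_len(n))
  expr <- as_expression(dplyr::bind_cols(tibble::tibble(gene_id = ids), df))
  design <- suppressWarnings(
    stage_design(sprintf("samp%02d", seq_len(n)),
                 paste0("St", stage), paste0("St", seq_len(K))))
  list(expr = expr, design = design)
}

expr_values <- function(e) as.matrix(tibble::as_tibble(e)[-1])

# log2(x + 1) view of a count expression table
log_counts <- function(expr) {
  df <- tibble::as_tibble(expr)
  df[-1] <- lapply(df[-1], function(v) log2(v + 1))
  as_expression(df, value_scale = "log_signal")
}
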