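test_that("standardization, orientation and sorting follow the profile rules", {
  vals <- rbind(c(2, 4, 6, 8, 10, 12),   # rising
                c(12, 10, 8, 6, 4, 2),   # falling
                c(1, 2, 3, 3, 2, 1))     # equal first/last stage means
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- paste0("s", 1:6)
  expr <- as_expression(dplyr::bind_cols(tibble::tibble(gene_id = c("up", "down", "flat")), df))
  design <- suppressWarnings(
    stage_design(paste0("s", 1:6), rep(c("A", "B", "C"), each = 2),
                 c("A", "B", "C")))
  pr <- standardize_and_orient(expr, design)

  expect_identical(pr$orientation, c("ascending", "descending", "descending"))
  expect_false(is.unsorted(pr$sorted[[1]]))
  expect_false(is.unsorted(rev(pr$sorted[[2]])))
  # z-scores use the population (n-denominator) convention
  z <- (c(2, 4, 6) - 4) / sqrt(mean((c(2, 4, 6) - 4)^2))
  expect_equal(z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  for (k in 1:3) {
    zz <- pr$sorted[[k]]
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(zz^2)), 1, tolerance = 1e-9)
  }
  # sorting permutes, never alters, the standardized values
  x <- as.numeric(vals[1, ])
  expect_equal(sort(pr$sorted[[1]]),
               sort((x - mean(x)) / sqrt(mean((x - mean(x))^2))))

  # descending stage means are flipped so both trends rise together
  expect_equal(pr$stage_means[[1]], pr$stage_means[[2]], tolerance = 1e-12)

  const <- as_expression(dplyr::bind_cols(tibble::tibble(gene_id = "c0"),
                                          df[1, ] * 0 + 5))
  expect_error(standardize_and_orient(const, design), "c0")
})

test_that("sign-flipping a gene flips orientation but not oriented stage means", {
  fx <- make_fixture(n_noise = 5, n_strong = 2, seed = 13)
  pr <- standardize_and_orient(fx$expr, fx$design)
  df <- tibble::as_tibble(fx$expr)
  df[-1] <- lapply(df[-1], function(v) -v)
  pr2 <- standardize_and_orient(as_expression(df), fx$design)
  flip <- c(ascending = "descending", descending = "ascending")
  expect_identical(pr2$orientation, unname(flip[pr$orientation]))
  for (k in seq_len(nrow(pr))) {
    expect_equal(pr2$stage_means[[k]], pr$stage_means[[k]], tolerance = 1e-12)
  }
})

# four well-separated prototype shapes over n sorted positions
prototype_profiles <- function(n_genes, n = 18, noise = 0.15, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  shapes <- rbind(sqrt(t), t^3, -sqrt(t), -t^3)
  shapes <- t(apply(shapes, 1, function(s) (s - mean(s)) / stats::sd(s)))
  lab <- rep(1:4, length.out = n_genes)
  X <- shapes[lab, ] + matrix(rnorm(n_genes * n, 0, noise), nrow = n_genes)
  rownames(X) <- paste0("g", seq_len(n_genes))
  list(X = X, lab = lab)
}

test_that("the SOM separates four prototype curves with high purity", {
  stats <- vapply(1:10, function(s) {
    pp <- prototype_profiles(40, seed = 100 + s)
    m <- train_som(pp$X, grid = c(3, 3), seed = s)
    tab <- table(pp$lab, m$assignments$unit)
    # fraction of genes falling in their prototype's majority unit
    c(purity = sum(apply(tab, 1, max)) / 40,
      populated = sum(m$unit_sizes > 0))
  }, numeric(2))
  expect_gte(mean(stats["purity", ]), 0.95)
  expect_true(all(stats["populated", ] >= 4))
})

test_that("SOM training traces and assignments are internally consistent", {
  pp <- prototype_profiles(30, seed = 7)
  m <- train_som(pp$X, grid = c(3, 3), seed = 2)
  # quantization error no worse at the end than after the first epoch
  expect_lte(m$quantization_error[m$n_epochs], m$quantization_error[1])
  expect_equal(sum(m$unit_sizes), 30)
  # Voronoi property: assigned unit is the closest codebook vector
  for (g in seq_len(nrow(pp$X))) {
    d <- sqrt(colSums((t(m$codebook) - pp$X[g, ])^2))
    expect_equal(m$assignments$unit[g], unname(which.min(d)))
    expect_equal(m$assignments$dist[g], unname(min(d)), tolerance = 1e-8)
  }
  # determinism
  m2 <- train_som(pp$X, grid = c(3, 3), seed = 2)
  expect_identical(m$codebook, m2$codebook)
  expect_identical(m$assignments, m2$assignments)

  td <- tidy(m); gl <- glance(m)
  expect_equal(nrow(td), 30)
  expect_equal(gl$n_genes, 30)
})

test_that("a single profile is quantized exactly", {
  x <- matrix(seq(-1, 1, length.out = 10), nrow = 1)
  m <- train_som(x, grid = c(3, 3), seed = 1)
  u <- m$assignments$unit[1]
  expect_equal(as.numeric(m$codebook[u, ]), as.numeric(x), tolerance = 1e-6)
  expect_error(train_som(x[0, , drop = FALSE]), "no profiles")
})

test_that("a 1x2 SOM recovers the 2-means partition on separated archetypes", {
  agree <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- rbind(matrix(rnorm(10 * 8, -2, 0.3), nrow = 10),
               matrix(rnorm(10 * 8, 2, 0.3), nrow = 10))
    m <- train_som(X, grid = c(1, 2), seed = s)
    km <- stats::kmeans(X, centers = 2, nstart = 25)
    tab <- table(m$assignments$unit, km$cluster)
    (max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])) / 20
  }, numeric(1))
  expect_true(all(agree == 1))
})

test_that("half-change points match hand interpolation and classify trends", {
  lin <- compute_half_change(seq(0, 1, length.out = 6))
  expect_equal(lin$position, 3.5)
  expect_identical(lin$trend_class, "early")   # boundary goes to early

  hc1 <- compute_half_change(c(0, 0.9, 0.95, 1.0))
  expect_equal(hc1$position, 1 + 0.5 / 0.9, tolerance = 1e-12)
  expect_identical(hc1$trend_class, "early")

  hc2 <- compute_half_change(c(0, 0.05, 0.1, 1.0))
  expect_equal(hc2$position, 3 + 0.4 / 0.9, tolerance = 1e-12)
  expect_identical(hc2$trend_class, "late")

  flat <- compute_half_change(rep(0.3, 5))
  expect_true(flat$flat)
  expect_equal(flat$position, 1)
  expect_identical(flat$trend_class, "early")

  expect_error(compute_half_change(1), "at least 2")

  # affine equivariance of the position
  set.seed(3)
  for (rep in 1:20) {
    pr <- cumsum(runif(5))
    base <- compute_half_change(pr)
    tr <- compute_half_change(2.7 * pr - 13)
    expect_equal(tr$position, base$position, tolerance = 1e-9)
    expect_equal(tr$delta, 2.7 * base$delta, tolerance = 1e-9)
  }
})

test_that("pattern summaries partition the genes and annotate trends", {
  fx <- make_fixture(n_noise = 0, n_strong = 12, seed = 77)
  pr <- standardize_and_orient(fx$expr, fx$design)
  m <- train_som(pr, grid = c(2, 2), n_epochs = 40, seed = 3)
  ps <- summarize_patterns(m, pr, min_fraction = 0.05)
  expect_equal(sum(ps$n_genes), 12)
  expect_setequal(unlist(ps$gene_ids), pr$gene_id)
  expect_true(all(ps$delta >= 0))
  expect_true(all(ps$half_change_position >= 1 &
                    ps$half_change_position <= 6))
  expect_true(all(ps$trend_class %in% c("early", "late")))

  # all-identical genes collapse into one populated unit
  df <- tibble::as_tibble(fx$expr)[rep(1, 10), ]
  df$gene_id <- paste0("dup", 1:10)
  same <- as_expression(df)
  pr2 <- standardize_and_orient(same, fx$design)
  m2 <- train_som(pr2, grid = c(3, 3), seed = 4)
  expect_equal(sum(m2$unit_sizes > 0), 1)
})
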