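test_that("strict order degree is a crisp indicator at r = 0 and a ramp otherwise", {
  expect_equal(strict_order_degree(1, 2, 0), 1)
  expect_equal(strict_order_degree(2, 1, 0), 0)
  expect_equal(strict_order_degree(1, 1, 0), 0)
  expect_equal(strict_order_degree(0, 0.05, 0.1), 0.5)
  expect_equal(strict_order_degree(0, 0.2, 0.1), 1)
  expect_equal(strict_order_degree(0.2, 0, 0.1), 0)
  expect_error(strict_order_degree(0, 1, -1), "nonnegative")
})

test_that("pair masses match hand enumeration on crisp examples", {
  expect_equal(fuzzy_pair_masses(1:4, 1:4), c(C = 12, D = 0))
  # one inverted unordered pair (2,3) out of six
  expect_equal(fuzzy_pair_masses(c(1, 3, 2, 4), 1:4), c(C = 10, D = 2))
  expect_error(fuzzy_pair_masses(1:3, 1:4), "lengths differ")
})

test_that("fuzzy pair masses equal the double-loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(3:25, 1)
    x <- rnorm(n)
    y <- sample(rep(1:4, length.out = n))
    r_x <- runif(1, 0, 1.5) * sample(0:1, 1)   # half the cases crisp
    r_y <- runif(1, 0, 0.8) * sample(0:1, 1)
    got <- fuzzy_pair_masses(x, y, r_x, r_y)
    expect_equal(got, oracle_fuzzy_masses(x, y, r_x, r_y), tolerance = 1e-12)
  }
})

test_that("gamma is 1 for monotone genes, undefined for constants, antisymmetric", {
  y <- rep(1:3, each = 2)
  expect_equal(gamma_statistic(1:6, y)$gamma, 1)
  expect_equal(gamma_statistic(6:1, y)$gamma, -1)

  const <- gamma_statistic(rep(2, 6), y)
  expect_true(const$undefined)
  expect_true(is.na(const$gamma))

  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(12)
    yy <- sample(rep(1:4, each = 3))
    g <- gamma_statistic(x, yy)$gamma
    expect_equal(gamma_statistic(-x, yy)$gamma, -g, tolerance = 1e-12)
    expect_true(abs(g) <= 1 + 1e-12)
  }
  expect_error(gamma_statistic(1:4, rep(1, 4)), "distinct stage")
})

test_that("crisp gamma equals the classical pair-counting oracle", {
  set.seed(77)
  p0 <- gamma_params(r_fraction = 0)
  for (rep in 1:150) {
    n <- sample(4:25, 1)
    x <- sample(rnorm(n))                      # continuous, no x ties
    y <- sample(rep(1:5, length.out = n))
    expect_equal(gamma_statistic(x, y, p0)$gamma, oracle_crisp_gamma(x, y),
                 tolerance = 1e-12)
  }
})

test_that("masses are continuous in r near 0 for tie-free data", {
  set.seed(12)
  x <- rnorm(10); y <- rep(1:5, 2)
  crisp <- fuzzy_pair_masses(x, y, 0, 0)
  tiny <- fuzzy_pair_masses(x, y, 1e-9, 0)
  expect_equal(tiny, crisp, tolerance = 1e-6)
})

test_that("gamma ignores strictly increasing recodings of the stage ranks", {
  set.seed(4)
  x <- rnorm(15)
  y <- sample(rep(1:5, each = 3))
  g1 <- gamma_statistic(x, y)$gamma
  g2 <- gamma_statistic(x, 10 * y)$gamma
  g3 <- gamma_statistic(x, y^3)$gamma
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(g1, g3, tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one convention", {
  p <- gamma_params(n_permutations = 200)
  # symmetric x over a two-level y: observed gamma 0, every |gamma_b| >= 0
  res <- permutation_pvalue(c(1, 2, 2, 1), c(1, 1, 2, 2), p, seed = 3)
  expect_equal(res$gamma, 0)
  expect_equal(res$p, 1)
  # perfectly monotone gene: no permutation beats it except re-findings
  res2 <- permutation_pvalue(1:12, rep(1:4, each = 3), p, seed = 3)
  expect_gte(res2$p, 1 / 201)
  expect_lt(res2$p, 0.05)
  # undefined gamma propagates
  expect_true(is.na(permutation_pvalue(rep(1, 6), rep(1:3, 2), p)$p))
})

test_that("monotone genes reach small p across seeds", {
  p <- gamma_params(n_permutations = 1000)
  y <- rep(1:4, each = 3)
  hits <- vapply(1:40, function(s) {
    permutation_pvalue(1:12 + stats::rnorm(12, 0, 1e-3), y, p, seed = s)$p
  }, numeric(1))
  expect_gte(mean(hits < 0.01), 0.99)
})

test_that("BH adjustment matches hand computation and supports platform m", {
  expect_equal(fdr_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(fdr_adjust(c(0.001, 0.5), m_total = 2), c(0.002, 0.5))
  # untested features inflate m only
  expect_equal(fdr_adjust(c(0.001, 0.5), m_total = 4), c(0.004, 1))
  expect_error(fdr_adjust(c(0.1, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(fdr_adjust(0.5, m_total = 0.5), "m_total")

  set.seed(91)
  for (rep in 1:25) {
    p <- runif(sample(3:40, 1))
    m <- length(p) + sample(0:50, 1)
    q <- fdr_adjust(p, m)
    expect_equal(q, oracle_bh(p, m), tolerance = 1e-12)
    expect_false(is.unsorted(q[order(p)]))    # q monotone in p
  }
})

test_that("screening selects injected monotone genes and honors thresholds", {
  fx <- make_fixture(n_noise = 30, n_strong = 3, seed = 21)
  sc <- screen_genes(fx$expr, fx$design,
                     gamma_params(n_permutations = 500, seed = 5))
  expect_s3_class(sc, "gamma_screen")
  expect_identical(sc$gene_id, fx$expr$gene_id)
  trend <- grepl("^trend", sc$gene_id)
  expect_true(all(sc$selected[trend]))
  expect_true(all(sc$direction[trend] == "up"))
  expect_true(all(sc$gamma[sc$selected & sc$direction == "up"] > 0.5))

  # an impossible gamma threshold empties the selection
  sc2 <- screen_genes(fx$expr, fx$design,
                      gamma_params(n_permutations = 100, gamma_threshold = 1.1,
                                   seed = 5))
  expect_equal(sum(sc2$selected), 0)

  g <- glance(sc)
  expect_equal(g$n_selected, sum(sc$selected))
  expect_equal(g$n_genes, 33)
})

test_that("screening is deterministic given the seed and flags constants", {
  fx <- make_fixture(n_noise = 8, n_strong = 1, K = 3, reps = 3, seed = 2)
  df <- tibble::as_tibble(fx$expr)
  df[df$gene_id == "noise01", -1] <- 5   # constant gene
  expr <- as_expression(df)
  p <- gamma_params(n_permutations = 300, seed = 11)
  s1 <- screen_genes(expr, fx$design, p)
  s2 <- screen_genes(expr, fx$design, p)
  expect_identical(s1$p_perm, s2$p_perm)
  row <- s1[s1$gene_id == "noise01", ]
  expect_true(is.na(row$gamma) && !row$selected && row$direction == "undefined")
})
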