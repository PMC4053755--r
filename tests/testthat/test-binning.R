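test_that("bin_index implements the half-open power-of-two intervals", {
  g <- bin_grid()
  expect_equal(bin_index(-0.3, g), -1L)          # [-0.5, -0.25)
  expect_equal(bin_index(-1.0, g), 0L)           # left edge included
  expect_equal(bin_index(-0.004, g), -7L)        # [-0.0078125, -0.00390625)
  expect_equal(bin_index(-0.5, g), -1L)          # right edge open for bin 0
  expect_true(is.na(bin_index(-2^-8, g)))        # outer right edge excluded
  expect_true(is.na(bin_index(-1.5, g)))
  expect_true(is.na(bin_index(0, g)))
  expect_true(is.na(bin_index(0.3, g)))          # beneficial off by default
  expect_equal(bin_index(0.3, bin_grid(beneficial = TRUE)), -1L)
})

test_that("the default grid spans relative growth effects 0.5 to 0.997", {
  e <- bin_edges(bin_grid())
  expect_equal(e[1], -1)                # -2^0
  expect_equal(e[length(e)], -2^-8)     # -0.0039
  expect_equal(round(2^e[1], 3), 0.5)
  expect_equal(round(2^e[length(e)], 3), 0.997)
})

test_that("per-bin moments: closed forms on degenerate bins", {
  a <- 0.3
  p <- make_pairs(G01 = rep(-0.3, 4), G10 = rep(-0.3, 4),
                  E = c(a, -a, a, -a))
  bs <- compute_bin_stats(p, B = 50, seed = 1, min_count = 2)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$mean_E, 0)
  expect_equal(bs$var_E, var(c(a, -a, a, -a)))   # unbiased: 4a^2/3
  same <- make_pairs(G01 = rep(-0.3, 6), G10 = rep(-0.3, 6), E = rep(0.1, 6))
  bs2 <- compute_bin_stats(same, B = 50, seed = 1, min_count = 2)
  expect_equal(bs2$var_E, 0)
  expect_equal(bs2$ci25, 0)
  expect_equal(bs2$ci75, 0)
})

test_that("bin counts plus out-of-range plus lethal add up to the input", {
  set.seed(5)
  n <- 2000
  p <- make_pairs(G01 = runif(n, -1.6, 0.1), G10 = runif(n, -1.6, 0.1),
                  E = rnorm(n, 0, 0.1))
  p$E[1:17] <- -Inf
  bs <- compute_bin_stats(p, B = 0, seed = NULL, min_count = 10)
  expect_equal(sum(bs$count) + attr(bs, "out_of_range") + attr(bs, "lethal"),
               n)
  expect_equal(attr(bs, "lethal"), 17)
})

test_that("binned variance estimates a known variance within 5%", {
  set.seed(11)
  n <- 10000
  v <- 0.02
  p <- make_pairs(G01 = rep(-0.4, n), G10 = rep(-0.4, n),
                  E = rnorm(n, 0, sqrt(v)))
  bs <- compute_bin_stats(p, B = 200, seed = 2)
  expect_lt(abs(bs$var_E - v) / v, 0.05)
  expect_lt(bs$ci25, bs$var_E)
  expect_gt(bs$ci75, bs$var_E)
})

test_that("bootstrap quantiles match an independently coded oracle exactly", {
  set.seed(3)
  p <- make_pairs(G01 = c(rep(-0.4, 60), rep(-0.1, 40)),
                  G10 = c(rep(-0.4, 60), rep(-0.1, 40)),
                  E = rnorm(100, 0, 0.2))
  B <- 137
  seed <- 99
  bs <- compute_bin_stats(p, B = B, seed = seed, min_count = 10)

  # oracle: re-implements the documented resampling contract from scratch
  # (bins in sorted key order, one stream, block-wise index draws)
  n01 <- ceiling(log2(-p$G01)); n10 <- ceiling(log2(-p$G10))
  key <- sprintf("%s|%+03d|%+03d", "deleterious",
                 pmin(n01, n10), pmax(n01, n10))
  set.seed(seed)
  oracle <- lapply(sort(unique(key)), function(k) {
    E <- p$E[key == k]
    s <- as.numeric(p$sign_class[key == k] != "none")
    n <- length(E)
    bsize <- max(1L, floor(2e6 / n))
    vb <- numeric(0); sb <- numeric(0); done <- 0L
    while (done < B) {
      b <- min(bsize, B - done)
      idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
      vb <- c(vb, apply(idx, 2, function(i) var(E[i])))
      sb <- c(sb, apply(idx, 2, function(i) mean(s[i])))
      done <- done + b
    }
    list(q = quantile(vb, c(0.025, 0.25, 0.75, 0.975), names = FALSE),
         sem = sd(sb))
  })
  for (i in seq_along(oracle)) {
    expect_equal(unlist(bs[i, c("ci025", "ci25", "ci75", "ci975")]),
                 setNames(oracle[[i]]$q, c("ci025", "ci25", "ci75", "ci975")))
    expect_equal(bs$sem_sign[i], oracle[[i]]$sem)
  }
})

test_that("bootstrap output is reproducible bit-for-bit under a fixed seed", {
  set.seed(8)
  p <- make_pairs(G01 = runif(500, -1, -0.01), G10 = runif(500, -1, -0.01),
                  E = rnorm(500, 0, 0.1))
  a <- compute_bin_stats(p, B = 100, seed = 42)
  b <- compute_bin_stats(p, B = 100, seed = 42)
  expect_identical(a, b)
  # and invariant under pair-order permutation for the point estimates
  perm <- sample(nrow(p))
  c2 <- compute_bin_stats(p[perm, ], B = 0, seed = NULL)
  a0 <- compute_bin_stats(p, B = 0, seed = NULL)
  expect_equal(a0$var_E, c2$var_E)
  expect_equal(a0$count, c2$count)
})

test_that("diagonal selection applies the 20% rule symmetrically", {
  p <- make_pairs(G01 = c(-0.50, -0.50), G10 = c(-0.45, -0.30), E = c(0, 0))
  d <- select_diagonal(p)
  expect_equal(nrow(d), 1)
  expect_equal(d$G, -0.475)
  swapped <- make_pairs(G01 = c(-0.45, -0.30), G10 = c(-0.50, -0.50),
                        E = c(0, 0))
  expect_equal(select_diagonal(swapped)$G, d$G)
})

test_that("sign-epistasis probability counts classes and matches theory", {
  p <- make_pairs(G01 = rep(-0.3, 4), G10 = rep(-0.3, 4), E = rep(0, 4),
                  sign_class = c("reciprocal_sign", "none", "none", "none"))
  d <- select_diagonal(p)
  s <- sign_epistasis_probability(d, B = 50, seed = 1)
  expect_equal(s$S, 0.25)
  p0 <- make_pairs(G01 = rep(-0.3, 5), G10 = rep(-0.3, 5), E = rep(0, 5),
                   sign_class = rep("none", 5))
  s0 <- sign_epistasis_probability(select_diagonal(p0), B = 50, seed = 1)
  expect_equal(s0$S, 0)
  expect_equal(s0$sem, 0)

  # Monte-Carlo: equal-effect pairs with Gaussian E flip both conditional
  # effects together, so S(any) = P(E > |G|) = 1 - pnorm(|G| / sigma)
  set.seed(21)
  G <- -0.2; sig <- 0.15; n <- 40000
  pm <- make_pairs(G01 = rep(G, n), G10 = rep(G, n), E = rnorm(n, 0, sig))
  sm <- sign_epistasis_probability(select_diagonal(pm), B = 100, seed = 2)
  expect_equal(sm$S, 1 - pnorm(abs(G) / sig), tolerance = 0.05)
})
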