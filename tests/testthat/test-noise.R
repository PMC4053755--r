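test_that("mock construction honours the null and the seeding contract", {
  rec <- make_records(c("a", "b"), c("x", "y"), g01 = c(0.9, 0.7),
                      g10 = c(0.8, 0.6), g11 = c(0.5, 0.3),
                      sd01 = 0, sd10 = 0, sd11 = 0)
  ds <- make_dataset(rec)
  cfg <- mock_config(seed = 5)
  m <- build_mock_dataset(ds, cfg, 1)
  # zero uncertainty: mock doubles equal the product exactly, E identically 0
  expect_equal(m$records$g11, rec$g01 * rec$g10)
  expect_equal(pair_stats(m)$E, c(0, 0), tolerance = 1e-12)

  rec2 <- make_records(letters[1:5], LETTERS[1:5], g01 = 0.9, g10 = 0.8,
                       g11 = 0.72, sd01 = 0.02, sd10 = 0.02, sd11 = 0.02)
  ds2 <- make_dataset(rec2)
  m1 <- build_mock_dataset(ds2, cfg, 1)
  m1b <- build_mock_dataset(ds2, cfg, 1)
  m2 <- build_mock_dataset(ds2, cfg, 2)
  expect_identical(m1$records, m1b$records)      # same (seed, index)
  expect_false(isTRUE(all.equal(m1$records$g11, m2$records$g11)))
})

test_that("df <= 2 is rejected: the variance-matching scale needs df > 2", {
  expect_error(mock_config(df = 2), "df > 2")
})

test_that("the t shift's standard deviation matches the reported sd", {
  # many identical records in one mock give many independent double shifts
  n <- 20000
  rec <- make_records(sprintf("q%05d", 1:n), sprintf("a%05d", 1:n),
                      g01 = 1, g10 = 1, g11 = 1,
                      sd01 = 0, sd10 = 0, sd11 = 0.05, n_reps = 1L)
  ds <- make_dataset(rec)
  m <- build_mock_dataset(ds, mock_config(df = 5, scale_mode = "sd", seed = 9), 1)
  shift <- m$records$g11 - 1
  expect_equal(sd(shift), 0.05, tolerance = 0.03)
  # sem mode divides by sqrt(n_reps)
  rec$n_reps <- 4L
  ds4 <- make_dataset(rec)
  m4 <- build_mock_dataset(ds4, mock_config(df = 5, scale_mode = "sem", seed = 9), 1)
  expect_equal(sd(m4$records$g11 - 1), 0.025, tolerance = 0.03)
})

test_that("a single gene's noisy value is shared across its pairs in a mock", {
  rec <- make_records(rep("hub", 4), paste0("p", 1:4), g01 = 0.8,
                      g10 = c(0.9, 0.8, 0.7, 0.6),
                      g11 = c(0.7, 0.6, 0.55, 0.5),
                      sd01 = 0.05, sd10 = 0.01, sd11 = 0.01)
  m <- build_mock_dataset(make_dataset(rec), mock_config(seed = 2), 1)
  expect_equal(length(unique(m$records$g01)), 1)
})

test_that("doubling uncertainties quadruples the noise-generated variance", {
  gen <- generate_null_dataset(small_config(seed = 13))
  ds <- deduplicate_pairs(apply_filters(gen$dataset))
  ds2 <- ds
  ds2$records$sd01 <- 2 * ds2$records$sd01
  ds2$records$sd10 <- 2 * ds2$records$sd10
  ds2$records$sd11 <- 2 * ds2$records$sd11
  g <- bin_grid()
  n1 <- noise_variance_by_bin(ds, mock_config(n_mocks = 3, seed = 4), g)
  n2 <- noise_variance_by_bin(ds2, mock_config(n_mocks = 3, seed = 4), g)
  merged <- merge(n1, n2, by = c("side", "n01", "n10"))
  big <- merged[order(-merged$n01 - merged$n10), ][1:6, ]  # largest effects:
  ratio <- big$var_noise.y / big$var_noise.x               # noise-dominated
  expect_true(all(ratio > 2.5 & ratio < 6))
})

test_that("decomposition arithmetic, flooring and alignment errors", {
  obs <- data.frame(side = "deleterious", n01 = c(-1L, -2L), n10 = c(-1L, -1L),
                    count = c(100L, 100L), var_E = c(0.010, 0.003),
                    ci025 = c(0.008, 0.002))
  noise <- data.frame(side = "deleterious", n01 = c(-1L, -2L),
                      n10 = c(-1L, -1L), var_noise = c(0.004, 0.004))
  d <- decompose_variance(obs, noise)
  expect_equal(d$var_bio, c(0.006, 0))       # floored at zero
  expect_equal(d$ratio, c(2.5, 0.75))
  expect_equal(d$sigma_bio, sqrt(c(0.006, 0)))
  expect_true(all(d$var_bio <= d$var_E))
  misaligned <- noise[1, , drop = FALSE]
  expect_error(decompose_variance(obs, misaligned, strict = TRUE),
               "alignment")
})

test_that("a pure-null run attributes essentially all variance to noise", {
  gen <- generate_null_dataset(small_config(seed = 31, n_pairs = 40000,
                                            n_genes = 800))
  ds <- deduplicate_pairs(apply_filters(gen$dataset))
  ps <- pair_stats(ds)
  bins <- compute_bin_stats(ps, B = 300, seed = 32)
  nz <- noise_variance_by_bin(ds, mock_config(seed = 33), bin_grid())
  dec <- decompose_variance(bins, nz, strict = FALSE)
  dec <- dec[dec$count >= 100, ]
  expect_true(all(is.finite(dec$ratio)))
  # the observed/noise ratio hovers around 1 in every well-populated bin
  expect_true(all(dec$ratio > 0.5 & dec$ratio < 1.6))
  # ground truth: every latent interaction is exactly zero
  expect_true(all(gen$truth$pairs$E_true == 0))
})

test_that("the decomposition recovers the generator's biological variance", {
  gen <- generate_dataset(small_config(seed = 41, n_pairs = 120000,
                                       n_genes = 1500))
  ds <- deduplicate_pairs(apply_filters(gen$dataset))
  ps <- pair_stats(ds)
  bins <- compute_bin_stats(ps, B = 300, seed = 42)
  nz <- noise_variance_by_bin(ds, mock_config(seed = 43), bin_grid())
  dec <- decompose_variance(bins, nz, strict = FALSE)
  # in well-populated strong-effect bins, var_bio matches the generative
  # surface evaluated at the bin's member pairs
  strong <- dec[dec$count >= 400 & dec$mean_absG01 >= 0.05, ]
  expect_gt(nrow(strong), 3)
  expected <- 0.079 * strong$mean_harmonic
  # per-bin variance estimates are heavy-tailed (the E mixture has excess
  # kurtosis ~10), so individual bins scatter widely; the count-weighted
  # aggregate is the meaningful recovery check
  expect_true(all(abs(strong$var_bio - expected) / expected < 0.6))
  expect_lt(abs(sum(strong$count * strong$var_bio) /
                  sum(strong$count * expected) - 1), 0.2)
})

test_that("Gaussian and t mocks of equal sd give compatible noise variances", {
  gen <- generate_null_dataset(small_config(seed = 51))
  ds <- deduplicate_pairs(apply_filters(gen$dataset))
  g <- bin_grid()
  nt <- noise_variance_by_bin(ds, mock_config(n_mocks = 4, df = 5, seed = 6), g)
  ng <- noise_variance_by_bin(ds, mock_config(n_mocks = 4, df = 5000, seed = 6), g)
  m <- merge(nt, ng, by = c("side", "n01", "n10"))
  m <- m[m$var_noise.x > 0, ]
  # distribution-robustness: variance matching makes the noise estimate
  # insensitive to the shape of the perturbation distribution
  expect_lt(abs(median(m$var_noise.y / m$var_noise.x) - 1), 0.2)
})
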