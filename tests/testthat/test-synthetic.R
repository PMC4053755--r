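test_that("the null generator without noise is exactly multiplicative", {
  cfg <- small_config(seed = 2, n_pairs = 500, n_genes = 100, c_true = 0,
                      tail_weight = 0, lethal_pair_fraction = 0,
                      effect_dist = list(neutral = 0.5, neutral_width = 0.01,
                                         deleterious = 0.5,
                                         deleterious_range = c(0.004, 1),
                                         beneficial = 0, beneficial_max = 0.03,
                                         lethal = 0),
                      noise = list(sd = 0, n_reps = 4, df = 5))
  gen <- generate_dataset(cfg)
  r <- gen$dataset$records
  expect_equal(r$g11, r$g01 * r$g10, tolerance = 1e-12)
  expect_true(all(gen$truth$pairs$E_true == 0))
  ps <- pair_stats(deduplicate_pairs(apply_filters(gen$dataset)))
  expect_equal(max(abs(ps$E)), 0, tolerance = 1e-12)
})

test_that("identical configurations reproduce identical datasets", {
  a <- generate_dataset(small_config(seed = 9, n_pairs = 2000, n_genes = 200))
  b <- generate_dataset(small_config(seed = 9, n_pairs = 2000, n_genes = 200))
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth$pairs$E_true, b$truth$pairs$E_true)
  c <- generate_dataset(small_config(seed = 10, n_pairs = 2000, n_genes = 200))
  expect_false(identical(a$dataset$records$g11, c$dataset$records$g11))
  # and the written file is byte-identical
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_raw_table(a$dataset, p1); write_raw_table(b$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pairs are distinct unordered gene pairs", {
  gen <- generate_dataset(small_config(seed = 4, n_pairs = 5000, n_genes = 150))
  r <- gen$dataset$records
  expect_true(all(r$query_id != r$array_id))
  key <- paste(pmin(r$query_id, r$array_id), pmax(r$query_id, r$array_id))
  expect_equal(anyDuplicated(key), 0)
})

test_that("latent E is Gaussian within bins when the tail is off", {
  skip_if_not_installed("nortest")
  cfg <- small_config(seed = 6, n_pairs = 40000, n_genes = 800,
                      tail_weight = 0)
  gen <- generate_dataset(cfg)
  tr <- gen$truth$pairs
  sel <- abs(tr$G01_true + 0.3) < 0.15 & abs(tr$G10_true + 0.3) < 0.15 &
    is.finite(tr$E_true)
  z <- tr$E_true[sel] / sqrt(tr$var_E_true[sel])
  expect_gt(length(z), 100)
  expect_gt(nortest::ad.test(z)$p.value, 0.01)
})

test_that("the heavy tail produces negative skew in the latent E", {
  cfg <- small_config(seed = 6, n_pairs = 40000, n_genes = 800,
                      tail_weight = 0.2)
  gen <- generate_dataset(cfg)
  tr <- gen$truth$pairs
  sel <- tr$G01_true < -0.05 & tr$G10_true < -0.05 & is.finite(tr$E_true) &
    tr$var_E_true > 0
  z <- tr$E_true[sel] / sqrt(tr$var_E_true[sel])
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(skew, -0.5)
})

test_that("latent per-bin variance matches the configured surface", {
  gen <- generate_dataset(small_config(seed = 8, n_pairs = 80000,
                                       n_genes = 1500))
  tr <- gen$truth$pairs
  fin <- is.finite(tr$E_true)
  n01 <- bin_index(tr$G01_true, bin_grid())
  n10 <- bin_index(tr$G10_true, bin_grid())
  ok <- fin & !is.na(n01) & !is.na(n10)
  key <- paste(pmin(n01, n10), pmax(n01, n10))[ok]
  emp <- tapply(tr$E_true[ok], key, var)
  expected <- tapply(tr$var_E_true[ok], key, mean)
  counts <- tapply(tr$E_true[ok], key, length)
  big <- counts >= 400
  expect_gt(sum(big), 5)
  rel <- emp[big] / expected[big] - 1
  expect_lt(max(abs(rel)), 0.5)
  expect_lt(abs(mean(rel)), 0.12)
})

test_that("beneficial-by-beneficial pairs carry no interaction by default", {
  cfg <- small_config(seed = 12, n_pairs = 30000, n_genes = 400,
                      effect_dist = list(neutral = 0.4, neutral_width = 0.01,
                                         deleterious = 0.3,
                                         deleterious_range = c(0.004, 1),
                                         beneficial = 0.3,
                                         beneficial_max = 0.03, lethal = 0))
  gen <- generate_dataset(cfg)
  tr <- gen$truth$pairs
  sing <- gen$truth$singles
  cls <- setNames(sing$class, sing$gene_id)
  bb <- cls[tr$query_id] == "beneficial" & cls[tr$array_id] == "beneficial"
  expect_gt(sum(bb), 500)
  expect_equal(unname(tr$var_E_true[bb]), rep(0, sum(bb)))
  expect_true(all(tr$E_true[bb & is.finite(tr$E_true)] == 0))
})

test_that("lethal pairs are emitted at the configured rate and flagged", {
  gen <- generate_dataset(small_config(seed = 14, n_pairs = 30000,
                                       n_genes = 600,
                                       lethal_pair_fraction = 0.02))
  r <- gen$dataset$records
  frac <- mean(r$g11 == 0)
  expect_gt(frac, 0.02)          # direct lethals plus lethal singles
  expect_lt(frac, 0.08)
  expect_true(all(gen$truth$pairs$E_true[r$g11 == 0] == -Inf))
  ds <- apply_filters(gen$dataset)
  expect_equal(unname(ds$filter_log["lethal"]), sum(r$g11 == 0))
})

test_that("reported uncertainties behave like replicate sample sds", {
  cfg <- small_config(seed = 16, n_pairs = 20000, n_genes = 3000)
  gen <- generate_dataset(cfg)
  s <- gen$truth$singles
  viable <- s$class %in% c("neutral", "deleterious")
  # mean reported sd across genes estimates the replicate-level sd (small-n
  # sample sds are biased slightly low, hence the loose tolerance)
  expect_equal(mean(s$sd_meas[viable]), 0.017, tolerance = 0.15)
  # and the measured values scatter around truth with sd ~ sd/sqrt(n_reps)
  err <- s$g_meas[viable] - s$g_true[viable]
  expect_equal(sd(err), 0.017 / 2, tolerance = 0.1)
})
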