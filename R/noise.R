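#' Configuration for no-epistasis mock datasets
#'
#' Mock datasets quantify how much epistasis variance measurement noise
#' alone generates. Each mock keeps the reported single-mutant growth
#' rates, sets every double to the product of its singles (the
#' multiplicative null), and then shifts every growth rate by an
#' independent draw from a Student's t distribution scaled so that the
#' shift's *standard deviation* (not its scale parameter) equals the
#' record's reported uncertainty — required for the variance-additivity
#' argument behind the decomposition to hold exactly.
#'
#' @param n_mocks number of mock datasets (default 9).
#' @param df Student's t degrees of freedom; must exceed 2 so the
#'   variance-matching scale exists.
#' @param scale_mode how the reported sd maps to the shift's spread:
#'   `"sem"` (default) treats the reported sd as a replicate sample sd and
#'   uses `sd / sqrt(n_reps)` for the reported mean value; `"sd"` uses the
#'   reported sd directly.
#' @param seed base seed; mock `i` is seeded with `seed + 7919 * i`.
#' @return A list of class `"mock_config"`.
#' @export
mock_config <- function(n_mocks = 9, df = 5, scale_mode = c("sem", "sd"),
                        seed = 1) {
  if (df <= 2) stop("mock noise requires df > 2 (finite variance)")
  stopifnot(n_mocks >= 1)
  structure(list(n_mocks = as.integer(n_mocks), df = df,
                 scale_mode = match.arg(scale_mode), seed = seed),
            class = "mock_config")
}

# t draw rescaled so its standard deviation equals sd
scaled_t_shift <- function(n, sd, df) rt(n, df) * sd * sqrt((df - 2) / df)

mock_scale <- function(sd, n_reps, scale_mode) {
  if (scale_mode == "sem") {
    nr <- ifelse(is.na(n_reps) | n_reps < 1, 1, n_reps)
    sd / sqrt(nr)
  } else sd
}

#' Build one randomized no-epistasis mock dataset
#'
#' Singles keep their reported growth rates, doubles are set to the
#' product of the reported singles, and every value is then shifted by a
#' scaled Student's t draw (see [mock_config()]). Each single's noisy
#' value is shared across all pairs that reference it in the same role,
#' mirroring how one measured single-mutant fitness enters many pairs.
#' Records without reported uncertainties are excluded and counted in the
#' `excluded_no_sd` attribute. Shifted growth rates that become
#' non-positive are removed by the standard filters. Fully deterministic
#' given `(cfg$seed, mock_index)`.
#'
#' @param ds a filtered, deduplicated `sga_dataset`.
#' @param cfg a [mock_config()].
#' @param mock_index index of the mock (1-based).
#' @return An `sga_dataset` with provenance `"mock"`.
#' @export
build_mock_dataset <- function(ds, cfg, mock_index = 1) {
  r <- ds$records
  has_sd <- is.finite(r$sd01) & is.finite(r$sd10) & is.finite(r$sd11)
  excluded <- sum(!has_sd)
  r <- r[has_sd, , drop = FALSE]
  set.seed(cfg$seed + 7919 * mock_index)

  # one shift per (gene, role): shared across all pairs referencing it
  shift_role <- function(id, g, sdv, nr) {
    first <- !duplicated(id)
    sh <- scaled_t_shift(sum(first),
                         mock_scale(sdv[first], nr[first], cfg$scale_mode),
                         cfg$df)
    (g[first] + sh)[match(id, id[first])]
  }
  g01m <- shift_role(r$query_id, r$g01, r$sd01, r$n_reps)
  g10m <- shift_role(r$array_id, r$g10, r$sd10, r$n_reps)
  g11null <- r$g01 * r$g10
  g11m <- g11null +
    scaled_t_shift(nrow(r), mock_scale(r$sd11, r$n_reps, cfg$scale_mode),
                   cfg$df)
  mock <- r
  mock$g01 <- g01m; mock$g10 <- g10m; mock$g11 <- g11m
  out <- apply_filters(new_sga_dataset(mock, provenance = "mock"))
  attr(out, "excluded_no_sd") <- excluded
  out
}

# per-bin mean of var(E) across a list of mock pair tables
mock_noise_table <- function(mock_pairs, grid) {
  per_mock <- lapply(seq_along(mock_pairs), function(i) {
    bs <- compute_bin_stats(mock_pairs[[i]], grid, B = 0, seed = NULL)
    bs$mock <- i
    bs
  })
  all <- do.call(rbind, per_mock)
  key <- interaction(all$side, all$n01, all$n10, drop = TRUE)
  agg <- aggregate(list(var_noise = all$var_E),
                   by = list(key = key), FUN = mean, na.rm = TRUE)
  spread <- aggregate(list(var_noise_sd = all$var_E),
                      by = list(key = key),
                      FUN = function(x) if (length(x) > 1) sd(x) else NA_real_)
  nm <- aggregate(list(n_mocks_used = all$var_E),
                  by = list(key = key), FUN = length)
  first <- all[!duplicated(key), c("side", "n01", "n10")]
  first$key <- key[!duplicated(key)]
  out <- Reduce(function(a, b) merge(a, b, by = "key"),
                list(first, agg, spread, nm))
  out$key <- NULL
  out
}

#' Noise-generated epistasis variance per bin
#'
#' Runs the full epistasis and binning pipeline on `cfg$n_mocks` mock
#' datasets and returns the across-mock mean of the per-bin variance of
#' `E` — the variance measurement noise alone would generate — together
#' with the across-mock spread for diagnostics.
#'
#' @param ds a filtered, deduplicated `sga_dataset` with uncertainties.
#' @param cfg a [mock_config()].
#' @param grid the same [bin_grid()] used for the real analysis.
#' @return Data frame keyed by `(side, n01, n10)` with `var_noise`,
#'   `var_noise_sd` and `n_mocks_used`.
#' @export
noise_variance_by_bin <- function(ds, cfg = mock_config(),
                                  grid = bin_grid()) {
  mocks <- lapply(seq_len(cfg$n_mocks), function(i)
    pair_stats(build_mock_dataset(ds, cfg, i), include_lethal = FALSE))
  mock_noise_table(mocks, grid)
}

#' Decompose observed epistasis variance into noise and biology
#'
#' Because variances of independent contributions add, the biological part
#' of the per-bin epistasis variance is estimated as
#' `var_bio = max(var_obs - var_noise, 0)`; its square root `sigma_bio` is
#' the characteristic strength of genuine epistatic interactions. The
#' ratio `var_obs / var_noise` is reported per bin, and a bin is flagged
#' `zero_consistent` when its noise variance lies inside the central 95%
#' bootstrap band of the observed variance, i.e. the biological variance
#' is statistically indistinguishable from zero.
#'
#' @param obs per-bin observed statistics from [compute_bin_stats()]
#'   (run with `B > 0` so the bootstrap quantiles are available).
#' @param noise per-bin noise variances from [noise_variance_by_bin()].
#' @param strict if `TRUE` (default), bins present in one input but not
#'   the other raise an alignment error listing the offending bins; if
#'   `FALSE`, the intersection is used.
#' @return `obs` augmented with `var_noise`, `var_bio`, `sigma_bio`,
#'   `ratio` and `zero_consistent`.
#' @export
decompose_variance <- function(obs, noise, strict = TRUE) {
  ko <- sprintf("%s|%+03d|%+03d", obs$side, obs$n01, obs$n10)
  kn <- sprintf("%s|%+03d|%+03d", noise$side, noise$n01, noise$n10)
  only_obs <- setdiff(ko, kn)
  only_noise <- setdiff(kn, ko)
  if (strict && (length(only_obs) || length(only_noise)))
    stop("bin alignment error; bins missing from noise: [",
         paste(only_obs, collapse = ", "), "], missing from observed: [",
         paste(only_noise, collapse = ", "), "]")
  m <- match(ko, kn)
  out <- obs
  out$var_noise <- noise$var_noise[m]
  out$var_bio <- pmax(out$var_E - out$var_noise, 0)
  out$sigma_bio <- sqrt(out$var_bio)
  out$ratio <- out$var_E / out$var_noise
  out$zero_consistent <- !is.na(out$ci025) & !is.na(out$var_noise) &
    out$ci025 <= out$var_noise
  out[!is.na(m), , drop = FALSE]
}
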