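#' Epistasis variance scaling surfaces
#'
#' The one-parameter surfaces describing how the variance of epistasis
#' depends on the two (deleterious) log growth effects:
#' \describe{
#'   \item{harmonic}{`var = 2c |G01 G10| / (|G01| + |G10|)` — half the
#'     harmonic mean of the two effect magnitudes, scaled by `c`. Along
#'     the diagonal it reduces to `var(G, G) = c |G|`.}
#'   \item{sqrt_product}{`var = c sqrt(|G01 G10|)` — the geometric-mean
#'     alternative; identical on the diagonal, slightly less accurate off
#'     it.}
#' }
#' Both vanish as either effect goes to zero and are symmetric in their
#' arguments.
#'
#' @param G01,G10 log growth effects (signs are ignored).
#' @param c scaling coefficient (log2-scale variance per unit `|G|`).
#' @param model `"harmonic"` (default) or `"sqrt_product"`.
#' @return The surface variance evaluated at each pair of effects.
#' @export
#' @examples
#' surface_variance(log2(0.95), log2(0.95), c = 0.079)  # c * 0.074
surface_variance <- function(G01, G10, c, model = "harmonic") {
  a <- abs(G01); b <- abs(G10)
  switch(match.arg(model, c("harmonic", "sqrt_product")),
         harmonic = c * harmonic_shape(a, b),
         sqrt_product = c * sqrtprod_shape(a, b))
}

fit_shape_column <- function(bins, model) {
  col <- c(harmonic = "mean_harmonic", sqrt_product = "mean_sqrtprod")[model]
  if (col %in% names(bins)) return(bins[[col]])
  if (all(c("mean_absG01", "mean_absG10") %in% names(bins)))
    return(surface_variance(bins$mean_absG01, bins$mean_absG10, 1, model))
  stop("bin table carries neither per-bin shape means nor effect coordinates")
}

#' Fit a one-parameter scaling surface to per-bin variances
#'
#' Weighted least-squares fit of a variance scaling surface to a bin
#' table. For the `"harmonic"` and `"sqrt_product"` models the surface is
#' linear in the coefficient, so the fit is closed-form:
#' `c = sum(w f v) / sum(w f^2)` with `f` the per-bin mean surface shape,
#' `v` the per-bin variance and `w` the weights. The
#' `"michaelis_menten_slice"` model instead fits, for each fixed first
#' effect (each bin exponent), a saturation law `var = v |G10| / (K +
#' |G10|)` across the other effect; on an exact harmonic surface this
#' recovers `v = 2c |G01|` and `K = |G01|`, and the per-slice implied
#' coefficient `v / (2K)` is averaged into `c`.
#'
#' Beneficial-side bins are always excluded from the fit (interactions
#' between beneficial mutations are vanishingly small and are reported
#' separately); lethal pairs never enter the bin table at all.
#'
#' @param bins a bin table from [compute_bin_stats()] or
#'   [decompose_variance()].
#' @param model one of `"harmonic"`, `"sqrt_product"`,
#'   `"michaelis_menten_slice"`.
#' @param weighting `"count"` (default) or `"equal"`.
#' @param value fit the noise-subtracted `"bio"` variance (`var_bio`,
#'   default when present) or the `"raw"` observed variance (`var_E`).
#' @return An object of class `"scaling_fit"`: list with `model`, `c`,
#'   `weighting`, `value`, per-bin `fitted` table with residuals,
#'   `slices` (Michaelis-Menten model only) and a `degenerate` flag.
#' @export
fit_surface <- function(bins, model = c("harmonic", "sqrt_product",
                                        "michaelis_menten_slice"),
                        weighting = c("count", "equal"),
                        value = c("bio", "raw")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  value <- match.arg(value)
  if (value == "bio" && !"var_bio" %in% names(bins)) value <- "raw"
  vcol <- if (value == "bio") "var_bio" else "var_E"
  if (!vcol %in% names(bins)) stop("bin table lacks a '", vcol, "' column")
  if ("side" %in% names(bins)) bins <- bins[bins$side != "beneficial", , drop = FALSE]
  bins <- bins[is.finite(bins[[vcol]]), , drop = FALSE]
  if (nrow(bins) < 2) stop("need at least 2 populated deleterious bins")
  w <- if (weighting == "count") bins$count else rep(1, nrow(bins))
  v <- bins[[vcol]]

  slices <- NULL
  if (model == "michaelis_menten_slice") {
    slices <- fit_mm_slices(bins, vcol, w)
    ok <- is.finite(slices$v) & is.finite(slices$K) & slices$K > 0
    c_hat <- if (any(ok)) {
      stats::weighted.mean(slices$v[ok] / (2 * slices$K[ok]), slices$weight[ok])
    } else NA_real_
    shape <- fit_shape_column(bins, "harmonic")
  } else {
    shape <- fit_shape_column(bins, model)
    denom <- sum(w * shape^2)
    c_hat <- if (denom > 0) sum(w * shape * v) / denom else 0
  }
  degenerate <- all(v == 0)
  if (degenerate) c_hat <- 0
  fitted <- bins
  fitted$fitted_var <- c_hat * shape
  fitted$residual <- fitted$fitted_var - v
  structure(list(model = model, c = max(c_hat, 0), weighting = weighting,
                 value = value, fitted = fitted, slices = slices,
                 degenerate = degenerate),
            class = "scaling_fit")
}

# per-slice Michaelis-Menten fits: slice = fixed first-effect exponent
fit_mm_slices <- function(bins, vcol, w) {
  slice_rows <- function(n) bins$n01 == n | bins$n10 == n
  slices <- sort(unique(c(bins$n01, bins$n10)))
  out <- lapply(slices, function(n) {
    rows <- bins[slice_rows(n), , drop = FALSE]
    # x: magnitude of the varying effect; the fixed effect is bin n
    fixed_is_01 <- rows$n01 == n
    x <- ifelse(fixed_is_01, rows$mean_absG10, rows$mean_absG01)
    Gfix <- mean(ifelse(fixed_is_01, rows$mean_absG01, rows$mean_absG10))
    y <- rows[[vcol]]
    wt <- w[slice_rows(n)]
    if (nrow(rows) < 3 || all(y == 0))
      return(data.frame(slice = n, G01 = Gfix, v = NA_real_, K = NA_real_,
                        weight = sum(wt)))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ v * x / (K + x),
                        start = list(v = max(y), K = stats::median(x)),
                        lower = c(v = 0, K = 1e-8), weights = wt),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(slice = n, G01 = Gfix, v = NA_real_, K = NA_real_,
                        weight = sum(wt)))
    cf <- coef(fit)
    data.frame(slice = n, G01 = Gfix, v = cf[["v"]], K = cf[["K"]],
               weight = sum(wt))
  })
  do.call(rbind, out)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> model:", x$model, " c =", signif(x$c, 4),
      " (", x$weighting, "weights,", x$value, "variance )\n")
  if (x$degenerate) cat("  [degenerate fit: all variances zero]\n")
  invisible(x)
}

#' Characteristic epistasis strength
#'
#' The expected strength of epistasis between two knockouts is the square
#' root of the fitted variance surface: `sigma(G01, G10) =
#' sqrt(var(G01, G10))`. On the diagonal both default surfaces give
#' `sigma(G, G) = sqrt(c |G|)`, so doubling both effects increases the
#' interaction strength only by a factor of `sqrt(2)`.
#'
#' @param G01,G10 log growth effects.
#' @param fit a `scaling_fit`, or a bare coefficient `c` (then `model`
#'   applies).
#' @param model surface model used when `fit` is a bare coefficient.
#' @return `sigma`, in log2-fold units.
#' @export
#' @examples
#' predict_sigma(log_growth(0.95), log_growth(0.95), 0.079)  # 0.076
predict_sigma <- function(G01, G10, fit, model = "harmonic") {
  if (inherits(fit, "scaling_fit")) {
    model <- if (fit$model == "michaelis_menten_slice") "harmonic" else fit$model
    fit <- fit$c
  }
  sqrt(surface_variance(G01, G10, fit, model))
}

#' One-standard-deviation interval for the double mutant's growth rate
#'
#' Under the additive null the double mutant's log growth is
#' `G01 + G10`; epistasis of characteristic strength `sigma` spreads the
#' observable relative growth rate over
#' `[2^(G01 + G10 - sigma), 2^(G01 + G10 + sigma)]`.
#'
#' @param G01,G10 log growth effects of the single mutants.
#' @param sigma characteristic epistasis strength (>= 0).
#' @return Named numeric vector (or 2-column matrix for vector input)
#'   with `lower` and `upper` relative growth rates.
#' @export
#' @examples
#' predict_interval(log_growth(0.95), log_growth(0.95), 0.076)  # 0.86 .. 0.95
predict_interval <- function(G01, G10, sigma) {
  stopifnot(all(sigma >= 0))
  lo <- 2^(G01 + G10 - sigma)
  hi <- 2^(G01 + G10 + sigma)
  if (length(lo) == 1) c(lower = lo, upper = hi)
  else cbind(lower = lo, upper = hi)
}

#' Log-log scaling exponent of the diagonal variance
#'
#' Weighted linear fit of `log(var)` against `log(|G|)` across diagonal
#' bins, with a bin-resampling bootstrap confidence interval. An exponent
#' near 1 diagnoses the empirical law `var(G, G) = c |G|`; an exponent of
#' 2 or more diagnoses Fisher-model-like scaling.
#'
#' @param diag_table data frame with columns `mean_absG` (or `G`), a
#'   variance column (`var_bio` if present, else `var_E` or `var`), and
#'   `count`.
#' @param B bootstrap resamples (over bins).
#' @param seed bootstrap seed.
#' @param level confidence level of the percentile interval.
#' @return List with `exponent`, `ci` (length 2), `level`, `n_bins` and
#'   the fitted `table`.
#' @export
scaling_exponent <- function(diag_table, B = 1000, seed = 1, level = 0.95) {
  vcol <- intersect(c("var_bio", "var_E", "var"), names(diag_table))[1]
  if (is.na(vcol)) stop("no variance column found")
  gcol <- intersect(c("mean_absG", "G"), names(diag_table))[1]
  tb <- diag_table[is.finite(diag_table[[vcol]]) & diag_table[[vcol]] > 0 &
                     is.finite(diag_table[[gcol]]), , drop = FALSE]
  if (nrow(tb) < 3) stop("insufficient data: need >= 3 diagonal bins with positive variance")
  x <- log(abs(tb[[gcol]])); y <- log(tb[[vcol]])
  w <- if ("count" %in% names(tb)) tb$count else rep(1, nrow(tb))
  slope <- function(xi, yi, wi) {
    if (length(unique(xi)) < 2) return(NA_real_)
    coef(lm(yi ~ xi, weights = wi))[[2]]
  }
  est <- slope(x, y, w)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(B), function(b) {
    i <- sample.int(length(x), replace = TRUE)
    slope(x[i], y[i], w[i])
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  alpha <- (1 - level) / 2
  list(exponent = est,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       level = level, n_bins = nrow(tb), table = tb)
}
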