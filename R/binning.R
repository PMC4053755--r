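#' Exponential bin grid over log growth effects
#'
#' Deleterious log growth effects are binned into exponentially growing
#' intervals: bin `n` covers `[-2^n, -2^(n-1))`, left (more negative) edge
#' included. The default exponents `-7..0` span log growth `-1` to
#' `-2^-8 = -0.0039`, i.e. relative growth rates 0.5 to 0.997, so that
#' a roughly constant number of pairs falls in each bin. When
#' `beneficial = TRUE` a mirrored magnitude grid over positive effects is
#' enabled for the (separately reported) beneficial analysis.
#'
#' @param exponents integer bin exponents (default `-7:0`).
#' @param symmetric pool bin `(i, j)` with `(j, i)`: the interaction
#'   variance is a symmetric function of its two arguments.
#' @param beneficial also bin pairs of beneficial effects on a mirrored
#'   positive grid.
#' @return An object of class `"bin_grid"`.
#' @export
bin_grid <- function(exponents = -7:0, symmetric = TRUE, beneficial = FALSE) {
  stopifnot(length(exponents) >= 1, exponents == as.integer(exponents))
  structure(list(exponents = sort(as.integer(exponents)),
                 symmetric = isTRUE(symmetric),
                 beneficial = isTRUE(beneficial)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  e <- x$exponents
  cat("<bin_grid> exponents", min(e), "..", max(e),
      "| log growth", -2^max(e), "..", -2^(min(e) - 1),
      if (x$beneficial) "(+ mirrored beneficial grid)", "\n")
  invisible(x)
}

#' Edges of a bin grid
#'
#' @param grid a [bin_grid()].
#' @return Numeric vector of bin edges on the log growth axis, most
#'   negative first.
#' @export
bin_edges <- function(grid) -2^seq(max(grid$exponents), min(grid$exponents) - 1)

#' Map log growth values to bin exponents
#'
#' Returns, for each finite `G`, the exponent `n` with
#' `G` in `[-2^n, -2^(n-1))`; values outside the grid's range (including
#' `G = 0` and, unless the grid enables it, beneficial `G > 0`) map to
#' `NA`, the out-of-range marker. On the mirrored beneficial grid the
#' intervals are `(2^(n-1), 2^n]`.
#'
#' @param G log growth value(s).
#' @param grid a [bin_grid()].
#' @return Integer exponents, `NA` where out of range.
#' @export
#' @examples
#' bin_index(c(-0.3, -1, -0.004), bin_grid())   # -1, 0, -7
bin_index <- function(G, grid = bin_grid()) {
  n <- rep(NA_integer_, length(G))
  neg <- is.finite(G) & G < 0
  n[neg] <- as.integer(ceiling(log2(-G[neg])))
  if (grid$beneficial) {
    pos <- is.finite(G) & G > 0
    n[pos] <- as.integer(ceiling(log2(G[pos])))
  }
  n[!n %in% grid$exponents] <- NA_integer_
  n
}

# Bootstrap moments for one group of E values (and a 0/1 sign flag).
# Resamples are drawn from the current RNG stream as sample.int(n, n * b)
# in blocks of b = max(1, floor(2e6 / n)) columns until B columns are
# drawn; this block structure is part of the reproducibility contract.
boot_moments <- function(E, s, B, probs = c(0.025, 0.25, 0.75, 0.975)) {
  n <- length(E)
  if (B < 1 || n < 2) {
    return(list(var_q = rep(NA_real_, length(probs)), sem_sign = NA_real_))
  }
  bsize <- max(1L, floor(2e6 / n))
  vboot <- numeric(0)
  sboot <- numeric(0)
  done <- 0L
  while (done < B) {
    b <- min(bsize, B - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    Em <- matrix(E[idx], nrow = n)
    m1 <- colMeans(Em)
    v <- (colMeans(Em^2) - m1^2) * n / (n - 1)
    vboot <- c(vboot, v)
    sboot <- c(sboot, colMeans(matrix(s[idx], nrow = n)))
    done <- done + b
  }
  list(var_q = unname(quantile(vboot, probs, names = FALSE)),
       sem_sign = sd(sboot))
}

# Shared per-group moment table: groups processed in sorted key order under
# a single RNG stream seeded once with `seed`.
bin_moment_table <- function(key, E, signflag, B, seed) {
  ord_keys <- sort(unique(key))
  idx_by <- split(seq_along(key), factor(key, levels = ord_keys))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(ord_keys, function(k) {
    i <- idx_by[[k]]
    Ei <- E[i]; si <- signflag[i]
    bm <- boot_moments(Ei, si, B)
    data.frame(key = k, count = length(i), mean_E = mean(Ei),
               var_E = if (length(i) >= 2) var(Ei) else NA_real_,
               ci025 = bm$var_q[1], ci25 = bm$var_q[2],
               ci75 = bm$var_q[3], ci975 = bm$var_q[4],
               sign_fraction = mean(si), sem_sign = bm$sem_sign,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

harmonic_shape <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
sqrtprod_shape <- function(a, b) sqrt(a * b)

#' Per-bin moments of epistasis with bootstrap intervals
#'
#' Bins pairs by the exponents of their two log growth effects, pooling
#' `(i, j)` with `(j, i)` when the grid is symmetric, and computes per bin
#' the pair count, mean and unbiased variance of `E`, bootstrap quantiles
#' of the variance (25/75% reported as the confidence band, 2.5/97.5%
#' retained for null checks), the fraction of sign-epistatic pairs with
#' its bootstrap standard error, and the per-bin means of the candidate
#' scaling-surface shapes evaluated pair by pair (exponential bins are
#' wide, so evaluating a surface at bin centres would be biased).
#'
#' Lethal pairs (`E = -Inf`) and pairs with non-finite effects are
#' excluded and counted in the attributes `lethal`, `out_of_range` and
#' `total`. Bootstrap output is bit-reproducible for a given `seed`: bins
#' are processed in sorted `(side, n01, n10)` order under one RNG stream,
#' with the resampling block structure described in the package internals.
#'
#' @param pairs a data frame from [pair_stats()] (needs `G01`, `G10`, `E`
#'   and optionally `sign_class`).
#' @param grid a [bin_grid()].
#' @param B number of bootstrap resamples (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap stream.
#' @param min_count bins with fewer pairs are flagged `low_confidence`.
#' @param sign_variant count `"any"` sign epistasis (single or reciprocal,
#'   default) or `"reciprocal"` only.
#' @return Data frame with one row per populated bin: `side`, `n01`,
#'   `n10` (`n01 <= n10`, so `n01` labels the weaker of the two effects),
#'   `count`, `mean_absG01`/`mean_absG10` (mean effect magnitudes on the
#'   `n01` and `n10` sides respectively), `mean_harmonic`,
#'   `mean_sqrtprod`, `mean_E`, `var_E`, `ci025`, `ci25`, `ci75`, `ci975`,
#'   `sign_fraction`, `sem_sign`, `low_confidence`.
#' @export
compute_bin_stats <- function(pairs, grid = bin_grid(), B = 1000, seed = 1,
                              min_count = 50,
                              sign_variant = c("any", "reciprocal")) {
  sign_variant <- match.arg(sign_variant)
  n01 <- bin_index(pairs$G01, grid)
  n10 <- bin_index(pairs$G10, grid)
  lethal <- is.infinite(pairs$E) & pairs$E < 0
  usable <- is.finite(pairs$E)
  same_side <- !is.na(n01) & !is.na(n10) &
    (sign(pairs$G01) == sign(pairs$G10))
  sel <- usable & same_side
  n_oor <- sum(usable & !same_side)

  side <- ifelse(pairs$G01[sel] > 0, "beneficial", "deleterious")
  nlo <- pmin(n01[sel], n10[sel])
  nhi <- pmax(n01[sel], n10[sel])
  if (!grid$symmetric) { nlo <- n01[sel]; nhi <- n10[sel] }
  key <- sprintf("%s|%+03d|%+03d", side, nlo, nhi)

  sflag <- if ("sign_class" %in% names(pairs)) {
    if (sign_variant == "any") pairs$sign_class[sel] != "none"
    else pairs$sign_class[sel] == "reciprocal_sign"
  } else rep(FALSE, sum(sel))
  sflag[is.na(sflag)] <- FALSE

  tab <- bin_moment_table(key, pairs$E[sel], sflag, B, seed)
  aG <- pmax(abs(pairs$G01[sel]), abs(pairs$G10[sel]))
  bG <- pmin(abs(pairs$G01[sel]), abs(pairs$G10[sel]))
  kf <- factor(key, levels = tab$key)
  # n01 is the more negative exponent, i.e. the weaker effect, so the
  # magnitude columns pair as (n01, bG) and (n10, aG)
  tab$mean_absG01 <- as.vector(tapply(bG, kf, mean))
  tab$mean_absG10 <- as.vector(tapply(aG, kf, mean))
  tab$mean_harmonic <- as.vector(tapply(harmonic_shape(aG, bG), kf, mean))
  tab$mean_sqrtprod <- as.vector(tapply(sqrtprod_shape(aG, bG), kf, mean))
  parts <- do.call(rbind, strsplit(tab$key, "|", fixed = TRUE))
  out <- data.frame(side = parts[, 1],
                    n01 = as.integer(parts[, 2]), n10 = as.integer(parts[, 3]),
                    tab[setdiff(names(tab), "key")],
                    low_confidence = tab$count < min_count,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(pairs)
  attr(out, "lethal") <- sum(lethal)
  attr(out, "out_of_range") <- sum(!lethal & !sel)
  out
}

#' Select pairs with similar single-mutant effects
#'
#' Retains pairs whose two log growth effects agree within a relative
#' tolerance, `|G01 - G10| <= tolerance * max(|G01|, |G10|)`, and assigns
#' the diagonal coordinate `G = (G01 + G10) / 2`. Symmetric in the two
#' effects.
#'
#' @param pairs a data frame with finite `G01`, `G10` columns.
#' @param tolerance relative tolerance (default 0.2, i.e. "within 20%").
#' @return The selected rows with an added `G` column.
#' @export
select_diagonal <- function(pairs, tolerance = 0.2) {
  stopifnot(tolerance > 0)
  ok <- is.finite(pairs$G01) & is.finite(pairs$G10) &
    abs(pairs$G01 - pairs$G10) <=
      tolerance * pmax(abs(pairs$G01), abs(pairs$G10))
  out <- pairs[ok, , drop = FALSE]
  out$G <- (out$G01 + out$G10) / 2
  out
}

diagonal_key <- function(G, grid, bins_per_octave) {
  m <- ceiling(bins_per_octave * log2(abs(G))) / bins_per_octave
  valid <- is.finite(G) & G < 0 &
    m <= max(grid$exponents) & m > min(grid$exponents) - 1
  m[!valid] <- NA_real_
  m
}

#' Diagonal-slice variance of epistasis
#'
#' One-dimensional exponential binning of diagonal pairs (from
#' [select_diagonal()]) by their mean effect `G`, with per-bin variance of
#' `E` and bootstrap quantiles. `bins_per_octave > 1` subdivides each
#' factor-of-two interval geometrically (finer bins than the 2-D grid).
#'
#' @param diag output of [select_diagonal()] (needs `G`, `E`).
#' @param grid a [bin_grid()] fixing the covered range.
#' @param bins_per_octave subdivisions per factor-of-two bin.
#' @param B,seed bootstrap resamples and seed (see [compute_bin_stats()]).
#' @return Data frame with `n` (fractional bin exponent), `count`,
#'   `mean_absG`, `mean_E`, `var_E` and bootstrap quantile columns.
#' @export
diagonal_stats <- function(diag, grid = bin_grid(), bins_per_octave = 1,
                           B = 1000, seed = 1) {
  m <- diagonal_key(diag$G, grid, bins_per_octave)
  sel <- !is.na(m) & is.finite(diag$E)
  key <- sprintf("%+09.4f", m[sel])
  sflag <- if ("sign_class" %in% names(diag)) diag$sign_class[sel] != "none"
           else rep(FALSE, sum(sel))
  sflag[is.na(sflag)] <- FALSE
  tab <- bin_moment_table(key, diag$E[sel], sflag, B, seed)
  kf <- factor(key, levels = tab$key)
  tab$mean_absG <- as.vector(tapply(abs(diag$G[sel]), kf, mean))
  data.frame(n = as.numeric(tab$key),
             tab[setdiff(names(tab), "key")],
             stringsAsFactors = FALSE)
}

#' Probability of sign epistasis along the diagonal
#'
#' For pairs of mutations with similar effects, estimates `S(G, G)`: the
#' per-bin fraction of pairs classified as sign-epistatic, with a
#' bootstrap standard error of that fraction. If the characteristic
#' interaction strength grows like `sqrt(|G|)` (the empirical scaling),
#' `S` falls with `|G|`; if it grows super-linearly (Fisher geometric
#' model), `S` rises.
#'
#' @param diag output of [select_diagonal()] carrying `sign_class`.
#' @param grid,bins_per_octave,B,seed as in [diagonal_stats()].
#' @param variant count `"any"` sign epistasis (default) or
#'   `"reciprocal"` only.
#' @return Data frame with `n`, `count`, `mean_absG`, `S`, `sem`.
#' @export
sign_epistasis_probability <- function(diag, grid = bin_grid(),
                                       bins_per_octave = 1, B = 500,
                                       seed = 1,
                                       variant = c("any", "reciprocal")) {
  variant <- match.arg(variant)
  m <- diagonal_key(diag$G, grid, bins_per_octave)
  sel <- !is.na(m) & !is.na(diag$sign_class)
  key <- sprintf("%+09.4f", m[sel])
  sflag <- if (variant == "any") diag$sign_class[sel] != "none"
           else diag$sign_class[sel] == "reciprocal_sign"
  tab <- bin_moment_table(key, as.numeric(sflag), sflag, B, seed)
  kf <- factor(key, levels = tab$key)
  data.frame(n = as.numeric(tab$key), count = tab$count,
             mean_absG = as.vector(tapply(abs(diag$G[sel]), kf, mean)),
             S = tab$sign_fraction, sem = tab$sem_sign,
             stringsAsFactors = FALSE)
}
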