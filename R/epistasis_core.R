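#' Log growth rate
#'
#' The log growth of a mutant is `log2(g / g00)`: the base-2 logarithm of
#' its growth rate relative to the reference genotype (wild type by
#' convention, `g00 = 1`). Non-positive growth rates yield the lethal
#' sentinel `-Inf`, which downstream moment computations always exclude.
#'
#' @param g relative growth rate(s).
#' @param g00 reference growth rate (> 0).
#' @return `log2(g / g00)`; `-Inf` where `g <= 0`.
#' @export
#' @examples
#' log_growth(0.95)   # -0.074
#' log_growth(0.60)   # -0.737
log_growth <- function(g, g00 = 1) {
  stopifnot(is.numeric(g00), length(g00) == 1, g00 > 0)
  out <- rep(-Inf, length(g))
  pos <- !is.na(g) & g > 0
  out[pos] <- log2(g[pos] / g00)
  out[is.na(g)] <- NA_real_
  out
}

#' Geometric epistasis
#'
#' Deviation of the double mutant's log growth from the additive
#' expectation: `E = G11 - G01 - G10` (with `G00 = 0`). `E = +1` means the
#' double mutant grows twice as fast as the multiplicative null model
#' predicts, `E = -1` half as fast. `|E|` does not depend on which corner
#' of the genotype square is called wild type, which makes it an unbiased
#' measure of the local curvature of the fitness landscape.
#'
#' @param G01,G10,G11 log growth rates of the two single mutants and the
#'   double mutant.
#' @return The epistasis value(s) `E`.
#' @export
geometric_epistasis <- function(G01, G10, G11) G11 - G01 - G10

#' Traditional epistasis and its lower bound
#'
#' The traditional measure is the difference between measured and
#' predicted growth rates, `e = g11 - g01 * g10` (wild type = 1). Because
#' growth rates are non-negative, `e` can never fall below
#' `-g01 * g10` (attained by a synthetic lethal, `g11 = 0`), so
#' interactions between very deleterious mutations are compressed towards
#' zero regardless of their biological strength.
#'
#' @param g01,g10,g11 relative growth rates (non-negative).
#' @return `traditional_epistasis()`: the value(s) `e`;
#'   `traditional_lower_bound()`: the minimum achievable `e`.
#' @export
#' @examples
#' traditional_epistasis(0.1, 0.1, 0)   # -0.01: a lethal that looks weak
#' traditional_lower_bound(0.95, 0.95)  # -0.9025
traditional_epistasis <- function(g01, g10, g11) g11 - g01 * g10

#' @rdname traditional_epistasis
#' @export
traditional_lower_bound <- function(g01, g10) -g01 * g10

#' Classify sign epistasis
#'
#' A mutation shows sign epistasis when its effect in the other mutant's
#' background has the strictly opposite sign to its solo effect: for
#' mutation A the conditional effect is `G11 - G10` against solo `G01`,
#' and symmetrically for B. `single_sign` means exactly one of the two
#' mutations flips sign, `reciprocal_sign` both (for two deleterious
#' singles this is the fitness-valley case `G11 > max(G01, G10)`). Exact
#' zero effects never count as a flip: ties classify as `none`.
#'
#' @param G01,G10,G11 finite log growth rates (`G00 = 0`).
#' @return Character vector with values `"none"`, `"single_sign"`,
#'   `"reciprocal_sign"`.
#' @export
classify_sign_epistasis <- function(G01, G10, G11) {
  condA <- G11 - G10
  condB <- G11 - G01
  flipA <- sign(condA) * sign(G01) < 0
  flipB <- sign(condB) * sign(G10) < 0
  out <- rep("none", length(G11))
  out[xor(flipA, flipB)] <- "single_sign"
  out[flipA & flipB] <- "reciprocal_sign"
  out[!is.finite(condA) | !is.finite(condB)] <- NA_character_
  out
}

#' Per-pair epistasis statistics
#'
#' Computes, for every record of a dataset, the log growth rates, the
#' geometric and traditional epistasis measures, the sign-epistasis class
#' and the lethal flag. Synthetic-lethal doubles (`g11 = 0`) carry the
#' sentinel `E = -Inf` and a finite `e`; records whose single-mutant
#' growth rates are non-positive get `E = NA`. All moment computations
#' downstream exclude non-finite `E`.
#'
#' @param ds an `sga_dataset` (filtered; see [apply_filters()]).
#' @param include_lethal if `TRUE` (default), lethal records held in
#'   `ds$lethals` are appended with their sentinel values, so that
#'   lethal-aware analyses (counting, rankings under `e`) see them.
#' @return A data frame of pair statistics; one row per pair.
#' @export
pair_stats <- function(ds, include_lethal = TRUE) {
  r <- ds$records
  if (include_lethal && !is.null(ds$lethals) && nrow(ds$lethals) > 0)
    r <- rbind(r, ds$lethals)
  G01 <- log_growth(r$g01)
  G10 <- log_growth(r$g10)
  G11 <- log_growth(r$g11)
  lethal <- !is.na(r$g11) & r$g11 == 0
  E <- geometric_epistasis(G01, G10, G11)
  E[lethal] <- -Inf
  E[!is.finite(G01) | !is.finite(G10)] <- NA_real_
  e <- traditional_epistasis(r$g01, r$g10, r$g11)
  sign_class <- rep(NA_character_, nrow(r))
  fin <- is.finite(G01) & is.finite(G10) & is.finite(G11)
  sign_class[fin] <- classify_sign_epistasis(G01[fin], G10[fin], G11[fin])
  cbind(r,
        data.frame(G01 = G01, G10 = G10, G11 = G11, E = E, e = e,
                   sign_class = sign_class, lethal = lethal,
                   stringsAsFactors = FALSE))
}
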