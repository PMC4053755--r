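#' Fisher geometric model configuration
#'
#' In Fisher's geometric model an organism is a point in an
#' `n_dim`-dimensional phenotype space, fitness decays with distance from
#' an optimum as `w(z) = exp(-fitness_decay * ||z||^2)`, and mutations are
#' additive phenotype displacements. Epistasis in log fitness arises
#' purely from the curvature of `w`: for two displacements `d1`, `d2`,
#' `E = -2 * fitness_decay * (d1 . d2) / ln 2` exactly, whatever the wild
#' type's position.
#'
#' Displacements are isotropic Gaussians whose per-mutation scale is drawn
#' log-uniformly over `scale_decades` decades below `mut_scale`; the broad
#' scale mixture is what populates effect bins spanning more than two
#' orders of magnitude in `|G|`. The wild type sits at distance `d0` from
#' the optimum.
#'
#' @param n_dim phenotype dimension.
#' @param mut_scale largest per-coordinate displacement s.d.
#' @param scale_decades decades of log-uniform spread of mutation scales.
#' @param fitness_decay decay constant of the Gaussian fitness function.
#' @param d0 wild-type distance from the optimum (0 = at the optimum).
#' @param n_pairs number of simulated mutation pairs.
#' @param effect_window relative tolerance when conditioning on a target
#'   single-mutant effect (rejection sampling).
#' @param seed RNG seed.
#' @return A list of class `"fgm_config"`.
#' @export
fgm_config <- function(n_dim = 8, mut_scale = 0.3, scale_decades = 2.2,
                       fitness_decay = 1, d0 = 0.2, n_pairs = 2e5,
                       effect_window = 0.05, seed = 1) {
  stopifnot(n_dim >= 1, mut_scale > 0, fitness_decay > 0, d0 >= 0,
            n_pairs >= 1)
  structure(list(n_dim = as.integer(n_dim), mut_scale = mut_scale,
                 scale_decades = scale_decades,
                 fitness_decay = fitness_decay, d0 = d0,
                 n_pairs = as.integer(n_pairs),
                 effect_window = effect_window, seed = seed),
            class = "fgm_config")
}

# log2 fitness drop of a displacement matrix relative to the wild type at
# (d0, 0, ..., 0); optimum at the origin
fgm_log_growth <- function(dm, d0, lam) {
  q <- (dm[, 1] + d0)^2 - d0^2
  if (ncol(dm) > 1) q <- q + rowSums(dm[, -1, drop = FALSE]^2)
  -lam * q / log(2)
}

fgm_draw <- function(n, cfg) {
  s <- cfg$mut_scale * 10^(-runif(n, 0, cfg$scale_decades))
  matrix(rnorm(n * cfg$n_dim), n) * s
}

#' Simulate pairwise epistasis under Fisher's geometric model
#'
#' Draws pairs of mutations, combines them additively in phenotype space,
#' and records the log growth effects of the singles and the double. The
#' result has the same `(G01, G10, G11, E)` layout as [pair_stats()]
#' output, so the whole downstream binning/diagonal machinery runs
#' unchanged on it.
#'
#' For testing, explicit displacement matrices can be supplied via
#' `displacements = list(d1, d2)`; `target_effects = c(t1, t2)` instead
#' rejection-samples mutations whose single effects match the targets
#' within `cfg$effect_window` relative tolerance.
#'
#' @param cfg an [fgm_config()].
#' @param displacements optional list of two `n x n_dim` matrices.
#' @param target_effects optional pair of target log growth effects.
#' @return Data frame with `G01`, `G10`, `G11`, `E`, `sign_class`.
#' @export
simulate_fgm_pairs <- function(cfg = fgm_config(), displacements = NULL,
                               target_effects = NULL) {
  lam <- cfg$fitness_decay
  if (is.null(displacements)) {
    set.seed(cfg$seed)
    if (is.null(target_effects)) {
      d1 <- fgm_draw(cfg$n_pairs, cfg)
      d2 <- fgm_draw(cfg$n_pairs, cfg)
    } else {
      d1 <- fgm_condition(cfg, target_effects[1])
      d2 <- fgm_condition(cfg, target_effects[2])
    }
  } else {
    d1 <- displacements[[1]]; d2 <- displacements[[2]]
  }
  G01 <- fgm_log_growth(d1, cfg$d0, lam)
  G10 <- fgm_log_growth(d2, cfg$d0, lam)
  G11 <- fgm_log_growth(d1 + d2, cfg$d0, lam)
  data.frame(G01 = G01, G10 = G10, G11 = G11,
             E = G11 - G01 - G10,
             sign_class = classify_sign_epistasis(G01, G10, G11),
             stringsAsFactors = FALSE)
}

# rejection-sample n_pairs mutations with effect within the relative window
fgm_condition <- function(cfg, target, max_rounds = 200) {
  keep <- matrix(numeric(0), 0, cfg$n_dim)
  tol <- abs(cfg$effect_window * target)
  for (r in seq_len(max_rounds)) {
    cand <- fgm_draw(cfg$n_pairs * 5L, cfg)
    G <- fgm_log_growth(cand, cfg$d0, cfg$fitness_decay)
    keep <- rbind(keep, cand[abs(G - target) <= tol, , drop = FALSE])
    if (nrow(keep) >= cfg$n_pairs) return(keep[seq_len(cfg$n_pairs), , drop = FALSE])
  }
  stop("rejection sampling failed to reach the target effect ", target)
}

#' Variance scaling of Fisher-model epistasis along the diagonal
#'
#' Conditions the simulated pairs on near-equal single effects (via
#' [select_diagonal()]), bins them on the 1-D exponential grid, and
#' estimates the log-log scaling exponent of `var(E | G, G)`. Under the
#' geometric model the variance grows at least as fast as `G^2`, in
#' contrast to the linear empirical law.
#'
#' @param pairs output of [simulate_fgm_pairs()].
#' @param grid a [bin_grid()].
#' @param tolerance diagonal tolerance (see [select_diagonal()]).
#' @param min_count drop bins with fewer pairs before fitting.
#' @param B,seed,level passed to [scaling_exponent()].
#' @return The [scaling_exponent()] result, with the diagonal bin table
#'   attached as `table`.
#' @export
fgm_variance_scaling <- function(pairs, grid = bin_grid(), tolerance = 0.2,
                                 min_count = 50, B = 1000, seed = 1,
                                 level = 0.95) {
  diag <- select_diagonal(pairs, tolerance)
  tab <- diagonal_stats(diag, grid, B = 0, seed = NULL)
  tab <- tab[tab$count >= min_count, , drop = FALSE]
  scaling_exponent(tab, B = B, seed = seed, level = level)
}
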