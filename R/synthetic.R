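#' Configuration of the synthetic SGA-like generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' single-mutant relative fitnesses drawn from a mixture (mass near 1, a
#' log-uniform deleterious tail spanning the full bin range, a small
#' beneficial fraction, a small lethal fraction); pairwise epistasis `E`
#' drawn from a zero-mean Gaussian core plus a heavy negative-exponential
#' tail, with variance given by a scaling surface; double-mutant fitness
#' `g11 = g01 * g10 * 2^E`; and replicate-level Student's t measurement
#' noise, with each gene's reported single fitness (replicate mean) and
#' uncertainty (replicate sample sd) shared across all pairs that contain
#' it.
#'
#' @param n_genes number of single mutants.
#' @param n_pairs number of distinct unordered gene pairs.
#' @param effect_dist single-mutant effect mixture: fractions `neutral`
#'   (log growth uniform in `± neutral_width`), `deleterious` (|G|
#'   log-uniform over `deleterious_range`), `beneficial` (G uniform in
#'   `(0, beneficial_max]`) and `lethal` (g = 0); fractions must sum to 1.
#' @param c_true coefficient of the epistasis variance surface.
#' @param surface_model `"harmonic"` or `"sqrt_product"`.
#' @param tail_weight weight of the heavy negative-exponential tail of the
#'   `E` mixture (0 = pure Gaussian).
#' @param mean_E location of the `E` mixture (default 0).
#' @param beneficial_epistasis if `FALSE` (default), pairs of
#'   beneficial-class mutations carry `E = 0`.
#' @param lethal_pair_fraction fraction of pairs made synthetic lethal
#'   (`g11 = 0`) irrespective of their singles.
#' @param noise list with replicate-level s.d. `sd`, replicate count
#'   `n_reps` and Student's t degrees of freedom `df`.
#' @param max_abs_E latent `E` values beyond this magnitude are clipped
#'   (and counted in the ground truth).
#' @param seed RNG seed; every random element flows from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 2000, n_pairs = 2e5,
                             effect_dist = list(neutral = 0.53,
                                                neutral_width = 0.01,
                                                deleterious = 0.45,
                                                deleterious_range = c(0.004, 1),
                                                beneficial = 0.01,
                                                beneficial_max = 0.03,
                                                lethal = 0.01),
                             c_true = 0.079,
                             surface_model = c("harmonic", "sqrt_product"),
                             tail_weight = 0.2, mean_E = 0,
                             beneficial_epistasis = FALSE,
                             lethal_pair_fraction = 0.01,
                             noise = list(sd = 0.017, n_reps = 4, df = 5),
                             max_abs_E = 20, seed = 1) {
  surface_model <- match.arg(surface_model)
  fr <- unlist(effect_dist[c("neutral", "deleterious", "beneficial", "lethal")])
  stopifnot(all(fr >= 0), abs(sum(fr) - 1) < 1e-8,
            c_true >= 0, tail_weight >= 0, tail_weight <= 1,
            noise$n_reps >= 1, n_genes >= 2, n_pairs >= 1)
  structure(list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
                 effect_dist = effect_dist, c_true = c_true,
                 surface_model = surface_model, tail_weight = tail_weight,
                 mean_E = mean_E,
                 beneficial_epistasis = isTRUE(beneficial_epistasis),
                 lethal_pair_fraction = lethal_pair_fraction,
                 noise = noise, max_abs_E = max_abs_E, seed = seed),
            class = "synthetic_config")
}

# Zero-mean mixture with a heavy left tail: with probability (1 - w) a
# Gaussian N(a, s^2), with probability w a shifted negative exponential
# a - Exp(mean 2s); a = 2ws centres the mixture, and s is set from the
# target variance v via var = 2.24 v-units when w = 0.2 (general closed
# form below). Skewness is negative for any w > 0.
epistasis_mixture <- function(v, w, mean_E = 0) {
  n <- length(v)
  # unit-s mixture variance: (1-w)(1 + a0^2) + w(4 + (a0-2)^2), a0 = 2w
  a0 <- 2 * w
  unit_var <- (1 - w) * (1 + a0^2) + w * (4 + (a0 - 2)^2)
  s <- sqrt(v / unit_var)
  a <- a0 * s
  z <- rnorm(n, a, s)
  tail <- runif(n) < w
  z[tail] <- a[tail] - rexp(sum(tail)) * 2 * s[tail]
  z + mean_E
}

measure_replicates <- function(g_true, noise) {
  n <- length(g_true)
  reps <- matrix(g_true + scaled_t_shift(n * noise$n_reps, noise$sd, noise$df),
                 n, noise$n_reps)
  list(mean = rowMeans(reps),
       sd = apply(reps, 1, sd))
}

#' Generate a synthetic SGA-like dataset with known ground truth
#'
#' Draws single-mutant fitnesses, latent pairwise epistasis values with
#' variance given by the configured scaling surface, double-mutant
#' fitnesses under the multiplicative null times `2^E`, and noisy
#' replicate measurements; returns both the measured dataset (in the same
#' form [read_raw_table()] produces) and the full generative ground
#' truth. Identical configurations reproduce identical output.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `"synthetic_sga"` with elements `dataset` (an
#'   `sga_dataset`) and `truth` (list: `config`, `singles` data frame with
#'   true and measured values per gene, `pairs` data frame with the latent
#'   `E_true` per pair, and `n_clipped`).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  ed <- cfg$effect_dist
  cls <- sample(c("neutral", "deleterious", "beneficial", "lethal"),
                cfg$n_genes, replace = TRUE,
                prob = c(ed$neutral, ed$deleterious, ed$beneficial, ed$lethal))
  G <- numeric(cfg$n_genes)
  G[cls == "neutral"] <- runif(sum(cls == "neutral"),
                               -ed$neutral_width, ed$neutral_width)
  dr <- log2(ed$deleterious_range)
  G[cls == "deleterious"] <- -2^runif(sum(cls == "deleterious"), dr[1], dr[2])
  G[cls == "beneficial"] <- runif(sum(cls == "beneficial"),
                                  0, ed$beneficial_max)
  G[cls == "lethal"] <- -Inf
  g_true <- 2^G
  meas <- measure_replicates(g_true, cfg$noise)
  meas$mean[cls == "lethal"] <- 0
  meas$sd[cls == "lethal"] <- 0

  # distinct unordered pairs, topping up until enough are collected
  max_pairs <- cfg$n_genes * (cfg$n_genes - 1) / 2
  if (cfg$n_pairs > max_pairs)
    stop("n_pairs exceeds the number of distinct gene pairs")
  i <- integer(0); j <- integer(0)
  for (round in 1:60) {
    n_draw <- ceiling((cfg$n_pairs - length(i)) * 1.5) + 16L
    i <- c(i, sample.int(cfg$n_genes, n_draw, replace = TRUE))
    j <- c(j, sample.int(cfg$n_genes, n_draw, replace = TRUE))
    ok <- i != j & !duplicated(paste(pmin(i, j), pmax(i, j)))
    i <- i[ok]; j <- j[ok]
    if (length(i) >= cfg$n_pairs) break
  }
  if (length(i) < cfg$n_pairs)
    stop("could not draw enough distinct pairs; increase n_genes")
  i <- i[seq_len(cfg$n_pairs)]
  j <- j[seq_len(cfg$n_pairs)]

  vE <- surface_variance(G[i], G[j], cfg$c_true, cfg$surface_model)
  if (!cfg$beneficial_epistasis)
    vE[cls[i] == "beneficial" & cls[j] == "beneficial"] <- 0
  vE[cls[i] == "lethal" | cls[j] == "lethal"] <- 0
  E <- epistasis_mixture(vE, cfg$tail_weight, cfg$mean_E)
  n_clipped <- sum(abs(E) > cfg$max_abs_E)
  E <- pmin(pmax(E, -cfg$max_abs_E), cfg$max_abs_E)
  lethal_pair <- runif(cfg$n_pairs) < cfg$lethal_pair_fraction |
    cls[i] == "lethal" | cls[j] == "lethal"
  g11_true <- g_true[i] * g_true[j] * 2^E
  g11_true[lethal_pair] <- 0
  E[lethal_pair] <- -Inf
  m11 <- measure_replicates(g11_true, cfg$noise)
  m11$mean[lethal_pair] <- 0
  m11$sd[lethal_pair] <- 0

  gene_id <- sprintf("g%05d", seq_len(cfg$n_genes))
  rec <- data.frame(query_id = gene_id[i], array_id = gene_id[j],
                    g01 = meas$mean[i], g10 = meas$mean[j], g11 = m11$mean,
                    sd01 = meas$sd[i], sd10 = meas$sd[j], sd11 = m11$sd,
                    n_reps = rep(as.integer(cfg$noise$n_reps), cfg$n_pairs),
                    stringsAsFactors = FALSE)
  ds <- new_sga_dataset(rec, provenance = "synthetic",
                        filter_log = c(nonnumeric_single = 0L,
                                       nonnumeric_double = 0L,
                                       lethal = 0L, corrupt_double = 0L))
  truth <- list(config = cfg,
                singles = data.frame(gene_id = gene_id, class = cls,
                                     g_true = g_true, G_true = G,
                                     g_meas = meas$mean, sd_meas = meas$sd,
                                     stringsAsFactors = FALSE),
                pairs = data.frame(query_id = gene_id[i],
                                   array_id = gene_id[j],
                                   G01_true = G[i], G10_true = G[j],
                                   E_true = E, var_E_true = vE,
                                   g11_true = g11_true,
                                   lethal = lethal_pair,
                                   stringsAsFactors = FALSE),
                n_clipped = n_clipped)
  structure(list(dataset = ds, truth = truth), class = "synthetic_sga")
}

#' Generate a no-epistasis null dataset
#'
#' The measurement-noise oracle: same generator with `c_true = 0`, no
#' heavy tail, and no lethals, but the noise model untouched, so every
#' latent interaction is exactly zero and any epistasis found downstream
#' is noise-generated by construction.
#'
#' @param cfg a [synthetic_config()]; its epistasis and lethal settings
#'   are overridden.
#' @return A `"synthetic_sga"` list, as [generate_dataset()].
#' @export
generate_null_dataset <- function(cfg = synthetic_config()) {
  cfg$c_true <- 0
  cfg$tail_weight <- 0
  cfg$lethal_pair_fraction <- 0
  ed <- cfg$effect_dist
  ed$neutral <- ed$neutral + ed$lethal
  ed$lethal <- 0
  cfg$effect_dist <- ed
  generate_dataset(cfg)
}

#' @export
print.synthetic_sga <- function(x, ...) {
  cat("<synthetic_sga> ", nrow(x$dataset$records), " pairs, ",
      x$truth$config$n_genes, " genes, c_true = ",
      x$truth$config$c_true, " (", x$truth$config$surface_model, ")\n",
      sep = "")
  invisible(x)
}
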