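#' Pipeline configuration
#'
#' A single configuration object drives the whole analysis. Exactly one of
#' `input` (path to a raw table) or `simulate` (a [synthetic_config()], or
#' a list of arguments for one) must be given. `read_pipeline_config()`
#' loads the same structure from a YAML file; entries under `simulate:`,
#' `noise:` and `fit:` map to the corresponding constructor arguments.
#'
#' @param input path to a raw tab-separated table, or `NULL`.
#' @param simulate a [synthetic_config()] (or argument list), or `NULL`.
#' @param dialect an [sga_dialect()] for reading `input`.
#' @param grid a [bin_grid()].
#' @param B bootstrap resamples for the binned statistics.
#' @param noise a [mock_config()] for the noise decomposition.
#' @param fit list with `model` and `weighting` for [fit_surface()].
#' @param fit_min_effect bins whose weaker-side mean effect magnitude is
#'   below this floor are excluded from the surface fit, for the same
#'   reason as `exponent_min_effect`: effects below the measurement
#'   resolution (~2-3% on the growth rate) are noise-dominated, and the
#'   near-neutral pairs smeared into those bins dilute their variance.
#' @param diagonal_tolerance relative tolerance of the diagonal slice.
#' @param diagonal_bins_per_octave subdivisions per factor-of-two bin on
#'   the diagonal slice (finer than the 2-D grid).
#' @param exponent_min_effect diagonal bins with mean effect magnitude
#'   below this floor are excluded from the scaling-exponent fit: such
#'   small effects sit below the measurement resolution and their
#'   noise-subtracted variance is dilution-biased.
#' @param sign_variant sign-epistasis counting variant (see
#'   [compute_bin_stats()]).
#' @param top_k size of the most-interacting ranking.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed master seed; stage seeds are derived from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            dialect = sga_dialect(), grid = bin_grid(),
                            B = 1000, noise = mock_config(),
                            fit = list(model = "harmonic",
                                       weighting = "count"),
                            fit_min_effect = 0.03,
                            diagonal_tolerance = 0.2,
                            diagonal_bins_per_octave = 2,
                            exponent_min_effect = 0.03,
                            sign_variant = "any",
                            top_k = 10000, out_dir = NULL, seed = 1) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given")
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config"))
    simulate <- do.call(synthetic_config, as.list(simulate))
  stopifnot(top_k >= 1)
  structure(list(input = input, simulate = simulate, dialect = dialect,
                 grid = grid, B = B, noise = noise, fit = fit,
                 fit_min_effect = fit_min_effect,
                 diagonal_tolerance = diagonal_tolerance,
                 diagonal_bins_per_octave = diagonal_bins_per_octave,
                 exponent_min_effect = exponent_min_effect,
                 sign_variant = sign_variant,
                 top_k = as.integer(top_k), out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "B", "diagonal_tolerance", "sign_variant",
              "top_k", "out_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$simulate)) args$simulate <- y$simulate
  if (!is.null(y$noise)) args$noise <- do.call(mock_config, y$noise)
  if (!is.null(y$fit)) args$fit <- y$fit
  if (!is.null(y$grid)) args$grid <- do.call(bin_grid, y$grid)
  do.call(pipeline_config, args)
}

#' Run the full epistasis-scaling pipeline
#'
#' Executes, in order: read (or simulate) \eqn{\rightarrow} filter
#' \eqn{\rightarrow} deduplicate \eqn{\rightarrow} per-pair statistics
#' \eqn{\rightarrow} 2-D binning \eqn{\rightarrow} mock-based noise
#' decomposition \eqn{\rightarrow} scaling-surface fit
#' \eqn{\rightarrow} diagonal variance, scaling exponent and
#' sign-epistasis probability \eqn{\rightarrow} interaction ranking under
#' both epistasis definitions. Deterministic given the configuration
#' seed. If `out_dir` is set, tidy TSV tables and a JSON fit report and
#' run log are written there.
#'
#' @param cfg a [pipeline_config()].
#' @return A list ("report bundle") with elements `dataset`, `pairs`,
#'   `bins`, `decomposition`, `fit`, `diagonal`, `exponent`, `sign`,
#'   `ranking` (lists `E` and `e`), `fraction`, `filter_log`, `truth`
#'   (simulated runs only) and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (!is.null(cfg$input)) {
    ds <- read_raw_table(cfg$input, cfg$dialect)
  } else {
    sim <- cfg$simulate
    sim$seed <- cfg$seed
    gen <- generate_dataset(sim)
    ds <- gen$dataset
    truth <- gen$truth
  }
  ds <- deduplicate_pairs(apply_filters(ds))
  ps <- pair_stats(ds)

  bins <- compute_bin_stats(ps, cfg$grid, B = cfg$B, seed = cfg$seed + 1,
                            sign_variant = cfg$sign_variant)
  mock_cfg <- cfg$noise
  mock_cfg$seed <- cfg$seed + 2
  mocks <- lapply(seq_len(mock_cfg$n_mocks), function(i)
    pair_stats(build_mock_dataset(ds, mock_cfg, i), include_lethal = FALSE))
  noise <- mock_noise_table(mocks, cfg$grid)
  dec <- decompose_variance(bins, noise, strict = FALSE)
  fit_bins <- dec[dec$mean_absG01 >= cfg$fit_min_effect, , drop = FALSE]
  fit <- fit_surface(fit_bins, model = cfg$fit$model,
                     weighting = cfg$fit$weighting)

  diag <- select_diagonal(ps, cfg$diagonal_tolerance)
  bpo <- cfg$diagonal_bins_per_octave
  dstats <- diagonal_stats(diag, cfg$grid, bins_per_octave = bpo,
                           B = cfg$B, seed = cfg$seed + 3)
  mock_diag <- vapply(mocks, function(mp) {
    md <- diagonal_stats(select_diagonal(mp, cfg$diagonal_tolerance),
                         cfg$grid, bins_per_octave = bpo, B = 0, seed = NULL)
    md$var_E[match(dstats$n, md$n)]
  }, numeric(nrow(dstats)))
  dstats$var_noise <- rowMeans(as.matrix(mock_diag), na.rm = TRUE)
  dstats$var_bio <- pmax(dstats$var_E - dstats$var_noise, 0)
  # effects below the measurement resolution floor are excluded from the
  # log-log fit (their variance is noise-dominated and dilution-biased)
  exp_tab <- dstats[dstats$mean_absG >= cfg$exponent_min_effect, , drop = FALSE]
  exponent <- tryCatch(
    scaling_exponent(exp_tab, B = cfg$B, seed = cfg$seed + 4),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "try-error"))
  sign_tab <- sign_epistasis_probability(diag, cfg$grid, B = min(cfg$B, 500),
                                         seed = cfg$seed + 5,
                                         variant = cfg$sign_variant)

  rank_E <- rank_interactions(ps, "E", cfg$top_k)
  rank_e <- rank_interactions(ps, "e", cfg$top_k)
  frac <- interacting_fraction(ps, rank_E, cfg$grid)

  bundle <- list(dataset = ds, pairs = ps, bins = bins,
                 decomposition = dec, fit = fit, diagonal = dstats,
                 exponent = exponent, sign = sign_tab,
                 ranking = list(E = rank_E, e = rank_e), fraction = frac,
                 filter_log = ds$filter_log, truth = truth, config = cfg)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  tsv(bundle$bins, "bins.tsv")
  tsv(bundle$decomposition, "decomposition.tsv")
  tsv(bundle$diagonal, "diagonal.tsv")
  tsv(bundle$sign, "sign_epistasis.tsv")
  tsv(bundle$ranking$E, "ranked_geometric.tsv")
  tsv(bundle$ranking$e, "ranked_traditional.tsv")
  fit_rep <- list(model = bundle$fit$model, c = bundle$fit$c,
                  weighting = bundle$fit$weighting,
                  value = bundle$fit$value,
                  exponent = if (!inherits(bundle$exponent, "try-error"))
                    bundle$exponent[c("exponent", "ci", "level", "n_bins")]
                  else NULL,
                  residual_rms = sqrt(mean(bundle$fit$fitted$residual^2)))
  jsonlite::write_json(fit_rep, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- list(package_version = as.character(packageVersion("episcale")),
              r_version = R.version.string,
              seed = bundle$config$seed,
              n_records = nrow(bundle$dataset$records),
              filter_log = as.list(bundle$filter_log))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Rank pairs by interaction strength
#'
#' Sorts pairs by the absolute value of the chosen epistasis measure,
#' descending. Lethal pairs (`E = -Inf`) are excluded when ranking by the
#' geometric measure `E` but participate when ranking by the traditional
#' measure `e`, which is finite for them — a documented asymmetry of the
#' two definitions. Ties are broken by the other measure's magnitude,
#' then lexicographically by gene ids, so the ranking is deterministic.
#'
#' @param pairs a [pair_stats()] data frame.
#' @param measure `"E"` (geometric) or `"e"` (traditional).
#' @param top_k number of pairs to return (capped at availability, with a
#'   warning).
#' @return The `top_k` strongest interactions with both measures attached
#'   and a `rank` column.
#' @export
rank_interactions <- function(pairs, measure = c("E", "e"), top_k = 10000) {
  measure <- match.arg(measure)
  other <- if (measure == "E") "e" else "E"
  keep <- if (measure == "E") is.finite(pairs$E) else is.finite(pairs$e)
  p <- pairs[keep, , drop = FALSE]
  if (top_k > nrow(p)) {
    warning("top_k = ", top_k, " exceeds the ", nrow(p),
            " available pairs; returning all")
    top_k <- nrow(p)
  }
  tie <- abs(p[[other]])
  tie[!is.finite(tie)] <- Inf   # lethal |E| dominates tie-breaks under e
  ord <- order(-abs(p[[measure]]), -tie, p$query_id, p$array_id)
  out <- p[ord[seq_len(top_k)], c("query_id", "array_id", "G01", "G10",
                                  "G11", "E", "e", "lethal")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction of a gene's tested partners that interact
#'
#' For each gene, the fraction of its tested partners whose pair appears
#' in the top-k most-interacting set, aggregated over genes binned by
#' their own growth-rate effect. Under the geometric definition this
#' fraction rises steadily with the magnitude of the gene's effect; the
#' traditional definition suppresses it for strongly deleterious genes.
#'
#' @param pairs a [pair_stats()] data frame (defines tested partners).
#' @param ranked a top-k table from [rank_interactions()].
#' @param grid a [bin_grid()] for the gene-effect axis.
#' @return Data frame with `n` (effect bin), `n_genes`, `mean_absG`,
#'   `fraction` (mean per-gene interacting fraction). Genes without
#'   tested partners are excluded and counted in the `no_partners`
#'   attribute.
#' @export
interacting_fraction <- function(pairs, ranked, grid = bin_grid()) {
  pk <- paste(pmin(pairs$query_id, pairs$array_id),
              pmax(pairs$query_id, pairs$array_id), sep = "\r")
  rk <- paste(pmin(ranked$query_id, ranked$array_id),
              pmax(ranked$query_id, ranked$array_id), sep = "\r")
  hit <- pk %in% rk
  gene <- c(pairs$query_id, pairs$array_id)
  eff <- c(pairs$G01, pairs$G10)
  hit2 <- c(hit, hit)
  tested <- tapply(hit2, gene, length)
  frac <- tapply(hit2, gene, mean)
  gene_G <- tapply(eff, gene, median)
  n <- bin_index(gene_G, grid)
  ok <- !is.na(n) & tested > 0
  nf <- factor(n[ok], levels = sort(unique(n[ok])))
  out <- data.frame(
    n = sort(unique(n[ok])),
    n_genes = as.vector(table(nf)),
    mean_absG = as.vector(tapply(abs(gene_G[ok]), nf, mean)),
    fraction = as.vector(tapply(frac[ok], nf, mean)))
  attr(out, "no_partners") <- sum(tested == 0)
  out
}
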