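#' Column dialect for raw double-mutant fitness tables
#'
#' A dialect maps the fields of a fitness record to columns of a
#' tab-separated file, either by header name (character) or by 0-based
#' column position (integer). `sga_dialect()` is the layout written by
#' [write_raw_table()]; `costanzo_dialect()` is a best-effort mapping for
#' the headerless raw SGA release of Costanzo et al. (2010), in which the
#' single- and double-mutant fitness columns are positional.
#'
#' @param header logical; does the file carry a header line?
#' @param n_reps either a column reference or a fixed integer replicate
#'   count applied to every record.
#' @param ... named column references overriding the defaults. Required
#'   fields: `query_id`, `array_id`, `g01`, `g10`, `g11`. Optional:
#'   `sd01`, `sd10`, `sd11` (set to `NA` to mark them absent).
#' @return A list of class `"sga_dialect"`.
#' @export
#' @examples
#' sga_dialect()
#' costanzo_dialect()
sga_dialect <- function(header = TRUE, n_reps = "n_reps", ...) {
  d <- list(
    columns = list(query_id = "query_id", array_id = "array_id",
                   g01 = "g01", sd01 = "sd01", g10 = "g10", sd10 = "sd10",
                   g11 = "g11", sd11 = "sd11"),
    header = header, n_reps = n_reps)
  override <- list(...)
  for (nm in names(override)) d$columns[[nm]] <- override[[nm]]
  structure(d, class = "sga_dialect")
}

#' @rdname sga_dialect
#' @export
costanzo_dialect <- function() {
  # raw SGA layout: query ORF, query name, array ORF, array name, score, sd,
  # p, query SMF, query SMF sd, array SMF, array SMF sd, DM fitness, DM sd
  sga_dialect(header = FALSE, n_reps = 4L,
              query_id = 0L, array_id = 2L,
              g01 = 7L, sd01 = 8L, g10 = 9L, sd10 = 10L,
              g11 = 11L, sd11 = 12L)
}

new_sga_dataset <- function(records, provenance = NA_character_,
                            filter_log = integer(0), lethals = NULL) {
  structure(list(records = records, provenance = provenance,
                 filter_log = filter_log,
                 lethals = lethals),
            class = "sga_dataset")
}

#' @export
print.sga_dataset <- function(x, ...) {
  cat("<sga_dataset> ", nrow(x$records), " records",
      if (!is.null(x$lethals)) sprintf(" (+%d lethal)", nrow(x$lethals)),
      "\n  provenance: ", x$provenance, "\n", sep = "")
  if (length(x$filter_log))
    cat("  filter_log:", paste(names(x$filter_log), x$filter_log,
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

resolve_column <- function(ref, field, tab, header) {
  if (length(ref) != 1 || is.na(ref)) return(NULL)
  if (is.character(ref)) {
    if (!ref %in% names(tab))
      stop("dialect field '", field, "' refers to missing column '", ref, "'")
    return(tab[[ref]])
  }
  idx <- as.integer(ref) + 1L   # 0-based positions
  if (idx < 1L || idx > ncol(tab))
    stop("dialect field '", field, "' refers to missing column index ", ref)
  tab[[idx]]
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a raw SGA-style double-mutant fitness table
#'
#' Parses a tab-separated table (gzip handled transparently) into a dataset
#' of per-pair fitness records. Unparseable numeric fields become `NA`,
#' never zero; row order is preserved; no filtering happens here (see
#' [apply_filters()]). Negative reported uncertainties are treated as
#' missing.
#'
#' @param path file path (optionally `.gz`).
#' @param dialect an [sga_dialect()] mapping fields to columns.
#' @return An object of class `"sga_dataset"`: a list with `records`
#'   (data frame with columns `query_id`, `array_id`, `g01`, `g10`, `g11`,
#'   `sd01`, `sd10`, `sd11`, `n_reps`), `provenance`, and `filter_log`.
#' @export
read_raw_table <- function(path, dialect = sga_dialect()) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  tab <- read.table(path, sep = "\t", header = isTRUE(dialect$header),
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    check.names = FALSE, colClasses = "character")
  cols <- dialect$columns
  get_num <- function(field) {
    v <- resolve_column(cols[[field]], field, tab, dialect$header)
    if (is.null(v)) rep(NA_real_, nrow(tab)) else num_or_na(v)
  }
  sd_clean <- function(x) ifelse(!is.na(x) & x < 0, NA_real_, x)
  n_reps <- if (is.numeric(dialect$n_reps)) {
    rep(as.integer(dialect$n_reps), nrow(tab))
  } else {
    v <- tryCatch(resolve_column(dialect$n_reps, "n_reps", tab, dialect$header),
                  error = function(e) NULL)
    if (is.null(v)) rep(NA_integer_, nrow(tab)) else as.integer(num_or_na(v))
  }
  rec <- data.frame(
    query_id = as.character(resolve_column(cols$query_id, "query_id", tab, dialect$header)),
    array_id = as.character(resolve_column(cols$array_id, "array_id", tab, dialect$header)),
    g01 = get_num("g01"), g10 = get_num("g10"), g11 = get_num("g11"),
    sd01 = sd_clean(get_num("sd01")), sd10 = sd_clean(get_num("sd10")),
    sd11 = sd_clean(get_num("sd11")),
    n_reps = n_reps, stringsAsFactors = FALSE)
  new_sga_dataset(rec, provenance = path,
                  filter_log = c(nonnumeric_single = 0L, nonnumeric_double = 0L,
                                 lethal = 0L, corrupt_double = 0L))
}

#' Filter a dataset to analysable double-mutant records
#'
#' Retains records whose double-mutant growth rate is a positive finite
#' number and whose single-mutant growth rates are both finite numbers.
#' Synthetic-lethal doubles (`g11 == 0` with numeric singles) are counted
#' under the `lethal` key and moved to the `lethals` component of the
#' returned dataset, so they remain available for the separate
#' lethal-interaction count and for rankings under the traditional
#' epistasis measure. Strictly negative doubles are treated as corrupt.
#' Filtering is idempotent.
#'
#' @param ds an `sga_dataset`.
#' @return The filtered `sga_dataset`, with `filter_log` counts per rule.
#' @export
apply_filters <- function(ds) {
  r <- ds$records
  single_ok <- is.finite(r$g01) & is.finite(r$g10)
  lethal <- single_ok & !is.na(r$g11) & r$g11 == 0
  corrupt <- single_ok & is.finite(r$g11) & r$g11 < 0
  keep <- single_ok & is.finite(r$g11) & r$g11 > 0
  bad_double <- single_ok & !keep & !lethal & !corrupt
  log_new <- c(nonnumeric_single = sum(!single_ok),
               nonnumeric_double = sum(bad_double),
               lethal = sum(lethal),
               corrupt_double = sum(corrupt))
  prev <- ds$filter_log
  for (k in names(log_new)) {
    log_new[k] <- log_new[k] + if (k %in% names(prev)) prev[[k]] else 0L
  }
  extra <- prev[setdiff(names(prev), names(log_new))]
  lethals <- rbind(ds$lethals, r[lethal, , drop = FALSE])
  new_sga_dataset(r[keep, , drop = FALSE], provenance = ds$provenance,
                  filter_log = c(log_new, extra),
                  lethals = lethals)
}

#' Keep one record per unordered gene pair
#'
#' Some genes appear both as query and as array, so the same unordered pair
#' \{a, b\} can occur twice. The default policy keeps the record with the
#' smaller mean reported uncertainty (mean of the available sd fields);
#' ties are broken by the lexicographically smaller query id, then array
#' id, so the result does not depend on input row order.
#'
#' @param ds an `sga_dataset` (normally already filtered).
#' @param policy only `"min_sd"` is implemented.
#' @return The deduplicated `sga_dataset`; removals are counted under
#'   `duplicate_pair` in `filter_log`.
#' @export
deduplicate_pairs <- function(ds, policy = "min_sd") {
  policy <- match.arg(policy, "min_sd")
  r <- ds$records
  if (nrow(r) == 0) return(ds)
  key <- paste(pmin(r$query_id, r$array_id), pmax(r$query_id, r$array_id),
               sep = "\r")
  mean_sd <- rowMeans(cbind(r$sd01, r$sd10, r$sd11), na.rm = TRUE)
  mean_sd[is.nan(mean_sd)] <- Inf  # records with no uncertainty lose ties
  ord <- order(key, mean_sd, r$query_id, r$array_id)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  dropped <- nrow(r) - length(keep)
  fl <- ds$filter_log
  fl["duplicate_pair"] <- dropped +
    if ("duplicate_pair" %in% names(fl)) fl[["duplicate_pair"]] else 0L
  new_sga_dataset(r[keep, , drop = FALSE], provenance = ds$provenance,
                  filter_log = fl, lethals = ds$lethals)
}

#' Write a dataset back to the tab-separated dialect
#'
#' Inverse of [read_raw_table()] for the default dialect: the numeric
#' payload round-trips up to formatting precision. A `.gz` suffix produces
#' gzip output.
#'
#' @param ds an `sga_dataset`.
#' @param path output path.
#' @param dialect an [sga_dialect()]; only header-name dialects are
#'   supported for writing.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(ds, path, dialect = sga_dialect()) {
  cols <- dialect$columns
  r <- ds$records
  out <- data.frame(row.names = seq_len(nrow(r)))
  for (field in names(cols)) {
    ref <- cols[[field]]
    if (length(ref) != 1 || is.na(ref) || !is.character(ref)) next
    out[[ref]] <- r[[field]]
  }
  if (!is.numeric(dialect$n_reps)) out[[dialect$n_reps]] <- r$n_reps
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = isTRUE(dialect$header))
  invisible(path)
}
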