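# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

make_records <- function(query_id, array_id, g01, g10, g11,
                         sd01 = 0.01, sd10 = 0.01, sd11 = 0.01,
                         n_reps = 4L) {
  data.frame(query_id = query_id, array_id = array_id,
             g01 = g01, g10 = g10, g11 = g11,
             sd01 = sd01, sd10 = sd10, sd11 = sd11,
             n_reps = as.integer(n_reps), stringsAsFactors = FALSE)
}

make_dataset <- function(records, provenance = "test") {
  episcale:::new_sga_dataset(records, provenance = provenance,
                             filter_log = c(nonnumeric_single = 0L,
                                            nonnumeric_double = 0L,
                                            lethal = 0L, corrupt_double = 0L))
}

# pair table with explicit log-growth coordinates and epistasis values
make_pairs <- function(G01, G10, E, sign_class = NULL) {
  G11 <- G01 + G10 + E
  if (is.null(sign_class)) sign_class <- classify_sign_epistasis(G01, G10, G11)
  data.frame(G01 = G01, G10 = G10, G11 = G11, E = E,
             sign_class = sign_class, stringsAsFactors = FALSE)
}

write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small-scale synthetic study used by several module tests
small_config <- function(seed = 7, n_genes = 500, n_pairs = 30000, ...) {
  synthetic_config(n_genes = n_genes, n_pairs = n_pairs, seed = seed, ...)
}
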