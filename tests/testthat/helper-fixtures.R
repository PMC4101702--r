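# Small fixtures built in code at test time.

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# 3-gene x 4-sample expression TSV
tiny_expression_file <- function() {
  write_tsv_lines(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "g1\t0.1\t0.2\t0.3\t0.4",
    "g2\t1.0\t-1.0\t1.0\t-1.0",
    "g3\t0.0\t0.5\t-0.5\t0.0"))
}

tiny_gmt_file <- function() {
  write_tsv_lines(c(
    "p1\tfirst pathway\tg1\tg2\tg1",
    "p2\tsecond pathway\tg2\tg3"))
}

tiny_scores_file <- function() {
  write_tsv_lines(c(
    "a\tb\t2.0",
    "b\ta\t3.0",
    "a\tc\t1.5",
    "b\tc\t4.0",
    "c\td\t0.5"))
}

# small factorial dataset for pipeline-level tests
small_dataset <- function(seed = 1, noise_s = 0.01,
                          gene_counts = c(20, 60),
                          profile_types = c(1, 5, 6),
                          inner_correlations = c(0, 0.5, 0.8),
                          n_samples = 36) {
  simulate_dataset(simulation_design(
    gene_counts = gene_counts, profile_types = profile_types,
    inner_correlations = inner_correlations, n_samples = n_samples,
    noise_s = noise_s, seed = seed))
}

# profile_set wrapper around explicit loadings, for driver tests
fake_profile_set <- function(loadings_list) {
  structure(list(plm = NULL, loadings = loadings_list),
            class = "profile_set")
}
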