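#' Simulated expression profiles (SEPs)
#'
#' Seven canonical temporal mean-expression patterns used as planted
#' pathway signals in the factorial simulation: linear rise, convex
#' exponential decay, early Gaussian peak, late Gaussian trough, one-cycle
#' sine, two-cycle sine, and a late step-up.  Each is standardized to zero
#' mean and unit variance, and the seven shapes are mutually
#' distinguishable (max pairwise |correlation| < 0.95 at 36 samples).
#'
#' @param sep_id Integer in 1..7 selecting the shape.
#' @param n_samples Number of samples (time points).
#' @return Numeric vector of length `n_samples`, mean 0, variance 1.
#' @examples
#' s <- sep_profile(5, 36)
#' c(mean(s), var(s))
#' @export
sep_profile <- function(sep_id, n_samples) {
  if (length(sep_id) != 1L || is.na(sep_id) || sep_id %% 1 != 0 ||
      sep_id < 1 || sep_id > 7)
    stop("sep_id must be an integer in 1..7")
  stopifnot(n_samples >= 2)
  t <- seq(0, 1, length.out = n_samples)
  raw <- switch(as.integer(sep_id),
    t,                              # 1: linear rise
    exp(-4 * t),                    # 2: convex decay
    exp(-((t - 0.3) / 0.12)^2),     # 3: early peak
    -exp(-((t - 0.7) / 0.12)^2),    # 4: late trough
    sin(2 * pi * t),                # 5: one cycle
    sin(4 * pi * t),                # 6: two cycles
    as.numeric(t > 2 / 3))          # 7: late step-up
  as.numeric(scale(raw))
}

#' Define a factorial simulation design
#'
#' Full factorial grid over pathway size, SEP type and inner-correlation
#' fraction (the fraction of a pathway's genes that follow its planted
#' SEP); each grid cell yields exactly one pathway of disjoint genes.  The
#' defaults reproduce the benchmark design: 5 sizes x 7 SEPs x 7 fractions
#' = 245 pathways, 24,990 genes, 36 samples, noise variance `s`.
#'
#' @param gene_counts Pathway sizes.
#' @param profile_types SEP identifiers (subset of 1..7).
#' @param inner_correlations Fractions in \[0, 1\].
#' @param n_samples Number of samples.
#' @param noise_s Noise variance per gene per sample (the covariance of the
#'   multivariate-normal noise is `s` times the identity across samples).
#' @param seed Integer seed for [simulate_dataset()].
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(gene_counts = c(10, 60, 100, 140, 200),
                              profile_types = 1:7,
                              inner_correlations = c(0, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8),
                              n_samples = 36,
                              noise_s = 0.01,
                              seed = 1L) {
  stopifnot(all(gene_counts >= 1), all(profile_types %in% 1:7),
            all(inner_correlations >= 0), all(inner_correlations <= 1),
            n_samples >= 2, noise_s >= 0)
  grid <- expand.grid(size = gene_counts, sep = profile_types,
                      rho = inner_correlations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(gene_counts = gene_counts, profile_types = profile_types,
                 inner_correlations = inner_correlations,
                 n_samples = n_samples, noise_s = noise_s,
                 seed = as.integer(seed), grid = grid),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation_design:", nrow(x$grid), "pathways (",
      length(x$gene_counts), "sizes x", length(x$profile_types), "SEPs x",
      length(x$inner_correlations), "inner-correlation levels ),",
      sum(x$grid$size), "genes,", x$n_samples, "samples, s =", x$noise_s, "\n")
  invisible(x)
}

# round-half-up, unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Generate a simulated expression dataset
#'
#' For each grid cell (size g, SEP k, inner correlation rho),
#' `round_half_up(rho * g)` genes get the SEP as mean vector and the rest
#' get mean zero; every gene then receives independent Gaussian noise with
#' variance `s` in every sample.  Pathways are disjoint gene blocks; gene
#' and pathway identifiers are deterministic functions of the grid cell,
#' and the whole matrix is reproducible from the design seed.
#'
#' @param design A `simulation_design`.
#' @return A list of class `simulated_dataset` with elements `matrix`
#'   (genes x samples), `annotation` (named list of gene sets), and `truth`
#'   (data.frame: pathway, sep, rho, size, n_signal).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  grid <- design$grid
  M <- design$n_samples
  sd_noise <- sqrt(design$noise_s)
  seps <- lapply(design$profile_types, sep_profile, n_samples = M)
  names(seps) <- as.character(design$profile_types)

  pw_ids <- sprintf("pw_g%d_sep%d_rho%02d",
                    grid$size, grid$sep, round_half_up(grid$rho * 100))
  n_total <- sum(grid$size)
  mat <- matrix(0, n_total, M)
  annotation <- vector("list", nrow(grid))
  names(annotation) <- pw_ids
  gene_ids <- character(n_total)
  n_signal <- integer(nrow(grid))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)

  offset <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid$size[[i]]
    k <- as.character(grid$sep[[i]])
    ns <- as.integer(round_half_up(grid$rho[[i]] * g))
    n_signal[[i]] <- ns
    rows <- offset + seq_len(g)
    ids <- sprintf("%s_gene%03d", pw_ids[[i]], seq_len(g))
    gene_ids[rows] <- ids
    annotation[[i]] <- ids
    mu <- matrix(0, g, M)
    if (ns > 0L) mu[seq_len(ns), ] <- rep(seps[[k]], each = ns)
    mat[rows, ] <- mu + matrix(stats::rnorm(g * M, sd = sd_noise), g, M)
    offset <- offset + g
  }
  dimnames(mat) <- list(gene_ids, sprintf("sample%02d", seq_len(M)))
  truth <- data.frame(pathway = pw_ids, sep = grid$sep, rho = grid$rho,
                      size = grid$size, n_signal = n_signal,
                      stringsAsFactors = FALSE)
  structure(list(matrix = mat, annotation = annotation, truth = truth,
                 design = design),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples,", length(x$annotation), "pathways\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression TSV, the GMT annotation and a truth TSV with the
#' planted SEP, inner correlation and size per pathway.
#'
#' @param dataset A `simulated_dataset`.
#' @param prefix Output path prefix; files `<prefix>_expr.tsv`,
#'   `<prefix>_pathways.gmt` and `<prefix>_truth.tsv` are produced.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulated <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  paths <- paste0(prefix, c("_expr.tsv", "_pathways.gmt", "_truth.tsv"))
  write_expression(dataset$matrix, paths[[1L]])
  write_gmt(dataset$annotation, paths[[2L]])
  utils::write.table(dataset$truth, paths[[3L]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a truth table written by [write_simulated()]
#' @param path Path to the truth TSV.
#' @return data.frame with columns pathway, sep, rho, size, n_signal.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# save/restore the global RNG state so simulate_dataset() does not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
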