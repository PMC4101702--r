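test_that("gamma cutoff matches the closed-form quantile on gamma samples", {
  set.seed(42)
  v <- rgamma(10000, shape = 2, rate = 1)
  true_q95 <- qgamma(0.95, shape = 2, rate = 1)   # 4.7439
  for (method in c("mle", "moments")) {
    cut <- gamma_cutoff(v, alpha = 0.05, method = method)
    expect_lt(abs(cut - true_q95) / true_q95, 0.05)
  }
  # alpha = 0.5 returns the fitted median
  fit <- fit_gamma(v)
  expect_equal(gamma_cutoff(v, 0.5),
               qgamma(0.5, fit[["shape"]], fit[["rate"]]))
  # smaller alpha, larger cutoff
  cuts <- vapply(c(0.05, 0.01, 0.001), gamma_cutoff, 0, variances = v)
  expect_true(all(diff(cuts) > 0))
})

test_that("gamma MLE agrees with an independent likelihood fit", {
  set.seed(7)
  x <- rgamma(5000, shape = 3.2, rate = 0.7)
  ours <- fit_gamma(x, "mle")
  ref <- MASS::fitdistr(x, "gamma")$estimate
  expect_equal(unname(ours["shape"]), unname(ref["shape"]), tolerance = 1e-3)
  expect_equal(unname(ours["rate"]), unname(ref["rate"]), tolerance = 1e-3)
})

test_that("degenerate variance vectors are rejected", {
  x <- matrix(1, 10, 5)
  expect_error(variance_cutoff(x, 0.05), "degenerate")
  expect_error(fit_gamma(rep(0, 10)), "degenerate")
})

test_that("PCA identities hold for pathway submatrices", {
  set.seed(1)
  sub <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  # eigenvalue conservation: total PCA variance = total gene variance
  ev <- panar:::pca_eigenvalues(sub)
  expect_equal(sum(ev), sum(apply(sub, 1, var)), tolerance = 1e-8)
  # full-rank reconstruction T P^t = centered submatrix
  sc <- sub - rowMeans(sub)
  sv <- svd(t(sc))
  expect_equal(sv$u %*% diag(sv$d) %*% t(sv$v), unname(t(sc)),
               tolerance = 1e-8)
})

test_that("bootstrap selection keeps strong planted components and drops noise", {
  ds <- small_dataset(seed = 6, noise_s = 0.001,
                      gene_counts = 100, profile_types = c(5, 6),
                      inner_correlations = c(0, 1))
  params <- compression_params(alpha = 0.05, n_boot = 50, seed = 6)
  sub_sig <- pathway_submatrix(ds$matrix, ds$annotation$pw_g100_sep5_rho100)
  sel <- select_components(sub_sig, ds$matrix, params)
  expect_gte(sel$h, 1L)
  expect_equal(sel$frequencies[[1]], 1.0)   # component 1 in every repetition

  # pure-noise pathways are rejected in most seeds
  h0 <- vapply(1:20, function(seed) {
    ds <- small_dataset(seed = seed, gene_counts = c(10, 100),
                        profile_types = 5, inner_correlations = c(0, 0.8))
    params <- compression_params(alpha = 0.05, n_boot = 30, seed = seed)
    sub <- pathway_submatrix(ds$matrix, ds$annotation$pw_g10_sep5_rho00)
    select_components(sub, ds$matrix, params)$h
  }, 0L)
  expect_gte(mean(h0 == 0L), 0.9)

  # R = 1 degenerates to single-shot selection
  sel1 <- select_components(sub_sig, ds$matrix,
                            compression_params(alpha = 0.05, n_boot = 1,
                                               q_threshold = 0.95, seed = 1))
  expect_true(all(sel1$frequencies %in% c(0, 1)))
})

test_that("build_plm output satisfies its structural invariants", {
  ds <- small_dataset(seed = 2)
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 30, seed = 2)))
  M <- ncol(ds$matrix)
  expect_equal(ncol(ps$plm), M)
  # scores have zero mean; loadings unit norm; per-pathway scores orthogonal
  expect_true(all(abs(rowMeans(ps$plm)) < 1e-10))
  norms <- vapply(ps$loadings, function(l) sqrt(sum(l^2)), 0)
  expect_equal(unname(norms), rep(1, length(norms)), tolerance = 1e-8)
  for (pw in unique(ps$profiles$pathway)) {
    rows <- ps$plm[ps$profiles$pathway == pw, , drop = FALSE]
    if (nrow(rows) > 1) {
      g <- tcrossprod(rows)
      expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
    }
  }
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(vapply(ps$loadings, function(l) l[which.max(abs(l))] > 0,
                         NA)))
  # deterministic under pathway reordering (same seed)
  perm <- rev(seq_along(ds$annotation))
  ps2 <- suppressMessages(build_plm(ds$matrix, ds$annotation[perm],
           compression_params(alpha = 0.05, n_boot = 30, seed = 2)))
  common <- intersect(rownames(ps$plm), rownames(ps2$plm))
  expect_setequal(rownames(ps$plm), rownames(ps2$plm))
  expect_equal(ps2$plm[rownames(ps$plm), ], ps$plm, tolerance = 1e-12)
})

test_that("decreasing alpha never increases the number of retained components", {
  ds <- small_dataset(seed = 8)
  h_by_alpha <- sapply(c(0.05, 0.01, 0.001), function(a) {
    ps <- try(suppressMessages(build_plm(ds$matrix, ds$annotation,
               compression_params(alpha = a, n_boot = 30, seed = 8))),
              silent = TRUE)
    if (inherits(ps, "try-error")) rep(0L, length(ds$annotation))
    else ps$selection$h
  })
  expect_true(all(h_by_alpha[, 2] <= h_by_alpha[, 1]))
  expect_true(all(h_by_alpha[, 3] <= h_by_alpha[, 2]))
})

test_that("planted rank-1 pathways are recovered with near-perfect profiles", {
  ds <- small_dataset(seed = 5, gene_counts = 60, profile_types = c(1, 5, 6),
                      inner_correlations = c(0.5, 1), noise_s = 0.01)
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 30, seed = 5)))
  for (k in c(1, 5, 6)) {
    id <- sprintf("pw_g60_sep%d_rho100#1", k)
    expect_gt(abs(cor(ps$plm[id, ], sep_profile(k, 36))), 0.99)
  }
})

test_that("uncorrelated heterogeneous data yields an explicit empty-PLM error", {
  # no covariance structure: 200 genes with spread-out variances, pathways
  # of 2 genes each; no 2-gene eigenvalue reaches the genome-wide 99.9%
  # variance quantile
  set.seed(3)
  x <- matrix(rnorm(200 * 20, sd = sqrt(rgamma(200, 2, 2))), 200, 20,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
  ann <- split(paste0("g", 1:20), rep(1:10, each = 2))
  names(ann) <- paste0("p", 1:10)
  expect_error(suppressMessages(build_plm(x, ann,
                 compression_params(alpha = 0.001, n_boot = 20, seed = 3))),
               "empty PLM")
})

test_that("the PLM round-trips through TSV", {
  ds <- small_dataset(seed = 2)
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 20, seed = 2)))
  p <- tempfile(fileext = ".tsv")
  write_plm(ps, p)
  m <- read_plm(p)
  expect_equal(rownames(m), rownames(ps$plm))
  expect_equal(m, ps$plm, tolerance = 1e-12)
})
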