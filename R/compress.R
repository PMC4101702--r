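#' Parameters for pathway compression
#'
#' @param alpha Significance level in (0,1) for the bootstrap eigenvalue
#'   cutoff: components must exceed the (1 - alpha) quantile of the fitted
#'   genome-wide gene-variance gamma distribution.  Smaller alpha is more
#'   stringent.
#' @param n_boot Number of bootstrap repetitions R.
#' @param q_threshold Frequency threshold Q in (0,1]: a component index is
#'   retained when it is selected in more than `Q` of the repetitions.
#' @param seed Integer seed for the bootstrap column resampling.
#' @param gamma_method `"mle"` (maximum likelihood, default) or
#'   `"moments"` for the gamma fit.
#' @return An object of class `compression_params`.
#' @export
compression_params <- function(alpha = 0.05, n_boot = 100L, q_threshold = 0.95,
                               seed = 1L, gamma_method = c("mle", "moments")) {
  stopifnot(alpha > 0, alpha < 1, n_boot >= 1,
            q_threshold > 0, q_threshold <= 1)
  structure(list(alpha = alpha, n_boot = as.integer(n_boot),
                 q_threshold = q_threshold, seed = as.integer(seed),
                 gamma_method = match.arg(gamma_method)),
            class = "compression_params")
}

#' @export
print.compression_params <- function(x, ...) {
  cat(sprintf("compression_params: alpha=%g, R=%d, Q=%g, seed=%d, gamma=%s\n",
              x$alpha, x$n_boot, x$q_threshold, x$seed, x$gamma_method))
  invisible(x)
}

# fast row variances
row_vars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

#' Fit a gamma distribution to a sample
#'
#' Two-parameter gamma fit.  `"mle"` solves the profile-likelihood shape
#' equation `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` by Newton
#' iteration (the rate MLE is then shape/mean); `"moments"` matches mean
#' and variance.
#'
#' @param x Positive numeric sample.
#' @param method `"mle"` or `"moments"`.
#' @return Named numeric `c(shape=, rate=)`.
#' @export
fit_gamma <- function(x, method = c("mle", "moments")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  x <- x[x > 0]
  if (length(x) < 2L || stats::var(x) == 0)
    stop("degenerate gamma fit: need >= 2 distinct positive values")
  m <- mean(x)
  if (method == "moments") {
    v <- stats::var(x)
    return(c(shape = m^2 / v, rate = m / v))
  }
  s <- log(m) - mean(log(x))
  # Minka's closed-form start, then Newton on f(k) = log k - digamma(k) - s
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, rate = k / m)
}

#' Gamma-quantile cutoff from a vector of gene variances
#'
#' Fits a gamma distribution to per-gene variances and returns its
#' `1 - alpha` quantile, the eigenvalue significance cutoff.
#'
#' @param variances Positive numeric vector of per-gene variances.
#' @param alpha Significance level.
#' @param method Gamma fitting method, see [fit_gamma()].
#' @return Nonnegative scalar cutoff.
#' @export
gamma_cutoff <- function(variances, alpha, method = c("mle", "moments")) {
  fit <- fit_gamma(variances, method)
  stats::qgamma(1 - alpha, shape = fit[["shape"]], rate = fit[["rate"]])
}

#' Bootstrap variance cutoff from an expression matrix
#'
#' Resamples the matrix columns with replacement (or uses the column
#' indices supplied in `cols`), computes per-gene variances of the
#' resampled matrix, and returns the fitted-gamma `1 - alpha` quantile.
#'
#' @param x Expression matrix (genes x samples).
#' @param alpha Significance level.
#' @param cols Optional integer vector of column indices; by default `M`
#'   columns are drawn with replacement using the current RNG state.
#' @param method Gamma fitting method.
#' @return Nonnegative scalar cutoff.
#' @export
variance_cutoff <- function(x, alpha, cols = NULL, method = c("mle", "moments")) {
  stopifnot(ncol(x) >= 2)
  if (is.null(cols)) cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
  v <- row_vars(x[, cols, drop = FALSE])
  if (all(v == 0)) stop("degenerate gamma fit: all-constant matrix")
  gamma_cutoff(v, alpha, method)
}

# eigenvalues of the PCA of a pathway submatrix (genes x samples), i.e. of
# the column-mean-centered transposed matrix; uses the smaller Gram matrix
pca_eigenvalues <- function(sub) {
  sc <- sub - rowMeans(sub)
  n <- nrow(sc); m <- ncol(sc)
  gram <- if (n <= m) tcrossprod(sc) else crossprod(sc)
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  ev / (m - 1)
}

# shared bootstrap engine: one column resample per repetition drives both
# the genome-wide variance cutoff and every pathway submatrix PCA
boot_component_counts <- function(x, submats, params) {
  M <- ncol(x)
  R <- params$n_boot
  kmat <- matrix(0L, R, length(submats))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  for (r in seq_len(R)) {
    cols <- sample.int(M, M, replace = TRUE)
    cutoff <- variance_cutoff(x, params$alpha, cols = cols,
                              method = params$gamma_method)
    for (f in seq_along(submats)) {
      sub <- submats[[f]]
      if (nrow(sub) < 2L) next
      ev <- pca_eigenvalues(sub[, cols, drop = FALSE])
      kmat[r, f] <- sum(ev > cutoff)
    }
  }
  kmat
}

# h_f from a column of bootstrap component counts: the largest index i such
# that at least i components were selected in > Q of the repetitions.
# Selected index sets are prefixes (eigenvalues are sorted), so the retained
# set is contiguous 1..h_f.
h_from_counts <- function(k_r, q_threshold) {
  if (max(k_r) == 0L) return(list(h = 0L, freq = numeric(0)))
  freq <- vapply(seq_len(max(k_r)), function(i) mean(k_r >= i), 0)
  h <- which(freq > q_threshold)
  list(h = if (length(h)) max(h) else 0L, freq = freq)
}

#' Bootstrap component selection for one pathway
#'
#' Runs the bootstrap selection for a single pathway submatrix against the
#' full expression matrix: in each repetition the same resampled column
#' index vector drives the genome-wide variance cutoff and the submatrix
#' PCA, and the number of eigenvalues above the cutoff is recorded.
#'
#' @param sub Pathway submatrix (genes x samples), columns aligned with
#'   `x`.
#' @param x Full expression matrix.
#' @param params A [compression_params()] object.
#' @return List with `h` (number of retained components, 0 allowed) and
#'   `frequencies` (selection frequency of component index i, i.e. the
#'   fraction of repetitions retaining at least i components).
#' @export
select_components <- function(sub, x, params) {
  stopifnot(ncol(sub) == ncol(x))
  kmat <- boot_component_counts(x, list(sub), params)
  res <- h_from_counts(kmat[, 1L], params$q_threshold)
  list(h = res$h, frequencies = res$freq)
}

#' Compress pathways into a pathway level matrix (PLM)
#'
#' Phase 1 of the pathway network analysis.  For every pathway, the
#' bootstrap procedure of [select_components()] determines how many
#' principal components of its expression submatrix are significant at
#' level `alpha`; pathways retaining at least one component contribute
#' their component scores, computed from the original (un-resampled)
#' centered submatrix, as rows of the PLM.  Loadings are unit-norm; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param x Expression matrix (genes x samples).
#' @param annotation Named list of pathway gene sets.
#' @param params A [compression_params()] object.
#' @return An object of class `profile_set`: list with `plm` (profiles x
#'   samples matrix, row names `pathway#component`), `profiles`
#'   (data.frame: profile, pathway, component, eigenvalue), `loadings`
#'   (named list of per-gene loading vectors), `selection` (data.frame:
#'   pathway, n_genes, h), `frequencies` (list of per-pathway selection
#'   frequencies) and `params`.
#' @export
build_plm <- function(x, annotation, params = compression_params()) {
  annotation <- match_annotation(annotation, x)
  if (length(annotation) == 0L) stop("no pathway has measured genes")
  submats <- lapply(annotation, function(g) pathway_submatrix(x, g))
  kmat <- boot_component_counts(x, submats, params)
  sel <- lapply(seq_along(submats),
                function(f) h_from_counts(kmat[, f], params$q_threshold))
  h <- vapply(sel, `[[`, 0L, "h")
  selection <- data.frame(pathway = names(annotation),
                          n_genes = vapply(submats, nrow, 0L),
                          h = h, stringsAsFactors = FALSE)
  if (all(h == 0L))
    stop("empty PLM: no pathway retained a significant component; ",
         "consider a larger alpha")

  prof_rows <- list(); prof_meta <- list(); loadings <- list()
  for (f in which(h > 0L)) {
    sub <- submats[[f]]
    sc <- sub - rowMeans(sub)            # genes centered across samples
    sv <- svd(t(sc), nu = h[[f]], nv = h[[f]])
    for (k in seq_len(h[[f]])) {
      load_k <- sv$v[, k]
      score_k <- sv$u[, k] * sv$d[[k]]
      imax <- which.max(abs(load_k))
      if (load_k[[imax]] < 0) {          # fixed sign convention
        load_k <- -load_k
        score_k <- -score_k
      }
      id <- paste0(names(annotation)[[f]], "#", k)
      prof_rows[[id]] <- score_k
      loadings[[id]] <- stats::setNames(load_k, rownames(sub))
      prof_meta[[id]] <- data.frame(profile = id,
                                    pathway = names(annotation)[[f]],
                                    component = k,
                                    eigenvalue = sv$d[[k]]^2 / (ncol(x) - 1),
                                    stringsAsFactors = FALSE)
    }
  }
  plm <- do.call(rbind, prof_rows)
  colnames(plm) <- colnames(x)
  structure(list(plm = plm,
                 profiles = do.call(rbind, c(prof_meta,
                                             list(make.row.names = FALSE))),
                 loadings = loadings,
                 selection = selection,
                 frequencies = lapply(sel, `[[`, "freq"),
                 params = params),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set:", nrow(x$plm), "pathway profiles (",
      sum(x$selection$h > 0), "of", nrow(x$selection),
      "pathways ) x", ncol(x$plm), "samples\n")
  invisible(x)
}

#' Write / read the pathway level matrix as TSV
#'
#' Row names follow the `pathway#component` convention so that the
#' pathway of each profile can be recovered on reload.
#'
#' @param profile_set A `profile_set` (or bare PLM matrix for writing).
#' @param path Output path.
#' @export
write_plm <- function(profile_set, path) {
  plm <- if (inherits(profile_set, "profile_set")) profile_set$plm else profile_set
  df <- data.frame(profile = rownames(plm), plm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plm
#' @return `read_plm` returns a numeric matrix, profiles x samples.
#' @export
read_plm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write per-profile loadings as a long TSV (profile, gene, loading)
#' @param profile_set A `profile_set`.
#' @param path Output path.
#' @export
write_loadings <- function(profile_set, path) {
  stopifnot(inherits(profile_set, "profile_set"))
  rows <- lapply(names(profile_set$loadings), function(id) {
    l <- profile_set$loadings[[id]]
    data.frame(profile = id, gene = names(l), loading = unname(l),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# pathway of each profile id under the "pathway#component" convention
profile_pathway <- function(ids) sub("#[0-9]+$", "", ids)
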