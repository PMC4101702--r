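#' Pathway-pair association strength (ASp)
#'
#' Sum of the gene-pair association scores over all unordered gene pairs
#' \{g, h\} with g in pathway i, h in pathway j and g != h.  A pair of
#' genes shared by both pathways is counted once; a gene paired with
#' itself never contributes (the score table has no self-scores).  Absent
#' pairs contribute 0.
#'
#' @param annotation Named list of pathway gene sets.
#' @param scores A `score_table`.
#' @param i,j Pathway identifiers.
#' @return Nonnegative scalar.
#' @export
pathway_pair_score <- function(annotation, scores, i, j) {
  gi <- annotation[[i]]; gj <- annotation[[j]]
  if (is.null(gi) || is.null(gj)) stop("pathway not in annotation: ",
                                       if (is.null(gi)) i else j)
  pairs_score(gi, gj, scores)
}

# ASp over explicit gene sets: unique unordered cross pairs, g != h
pairs_score <- function(gi, gj, scores) {
  grid <- expand.grid(a = gi, b = gj, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  if (nrow(grid) == 0L) return(0)
  key <- pair_key(grid$a, grid$b)
  keep <- !duplicated(key)
  sum(lookup_score(scores, grid$a[keep], grid$b[keep]))
}

#' Universal set of pathway-pair association strengths
#'
#' ASp for every unordered pathway pair of the annotation, keeping pairs
#' with ASp > 0 (the reference distribution for percentile enrichment).
#'
#' @param annotation Named list of pathway gene sets.
#' @param scores A `score_table`.
#' @return data.frame: pathway_i, pathway_j, asp (asp > 0 rows only).
#' @export
universal_pairs <- function(annotation, scores) {
  ids <- names(annotation)
  out <- list()
  n <- length(ids)
  for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
    s <- pathway_pair_score(annotation, scores, ids[[a]], ids[[b]])
    if (s > 0)
      out[[length(out) + 1L]] <- data.frame(pathway_i = ids[[a]],
                                            pathway_j = ids[[b]], asp = s,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(pathway_i = character(0), pathway_j = character(0),
                  asp = numeric(0), stringsAsFactors = FALSE)
}

#' Percentile breakdown of ASp distributions
#'
#' Empirical quantiles (linear interpolation, `stats::quantile` type 7)
#' of the universal-set and network ASp values at the requested
#' percentiles.
#'
#' @param universal Numeric vector of universal-set ASp values.
#' @param network Numeric vector of network-edge ASp values.
#' @param percentiles Percentile levels (percent).
#' @return data.frame: percentile, universal, network.
#' @export
percentile_table <- function(universal, network,
                             percentiles = c(10, 20, 25, 30, 40, 50,
                                             60, 70, 75, 80, 90, 100)) {
  if (length(universal) == 0L || length(network) == 0L)
    stop("empty ASp set")
  data.frame(percentile = percentiles,
             universal = unname(stats::quantile(universal, percentiles / 100)),
             network = unname(stats::quantile(network, percentiles / 100)))
}

#' Cardinality-matched random null for one pathway pair
#'
#' Samples `n_random` random pathway pairs from the gene universe
#' preserving the edge's cardinality pattern (the sizes of the two
#' pathways and the number of genes they share), computes their ASp, and
#' returns the empirical percentile of the observed edge ASp within the
#' null (mid-rank convention: ties count one half, so exchangeable scores
#' give 0.5).
#'
#' @param annotation Named list of pathway gene sets.
#' @param scores A `score_table`.
#' @param i,j Pathway identifiers of the edge.
#' @param n_random Number of random pairs.
#' @param seed Integer seed.
#' @param universe Gene universe to sample from; defaults to the genes of
#'   the score table.
#' @return List: `observed` ASp, `percentile` in \[0,1\], `null` (the
#'   `n_random` ASp values).
#' @export
cardinality_null <- function(annotation, scores, i, j, n_random = 100L,
                             seed = 1L, universe = NULL) {
  gi <- annotation[[i]]; gj <- annotation[[j]]
  if (is.null(gi) || is.null(gj)) stop("pathway not in annotation")
  if (is.null(universe)) universe <- scores$genes
  n_i <- length(gi); n_j <- length(gj)
  n_shared <- length(intersect(gi, gj))
  if (length(universe) < n_i + n_j - n_shared)
    stop("gene universe too small for the cardinality pattern (",
         n_i, ", ", n_j, ", ", n_shared, ")")
  observed <- pairs_score(gi, gj, scores)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_random), function(r) {
    g <- sample(universe, n_i + n_j - n_shared)
    ri <- g[seq_len(n_i)]
    rj <- c(g[seq_len(n_shared)], g[n_i + seq_len(n_j - n_shared)])
    pairs_score(ri, rj, scores)
  }, 0)
  pct <- (sum(null < observed) + 0.5 * sum(null == observed)) / n_random
  list(observed = observed, percentile = pct, null = null)
}

#' Validate a pathway network against a gene-pair score table
#'
#' Computes the per-edge pathway-pair association strength (ASp), the
#' network mean (ASn), the percentile breakdown of network vs universal
#' ASp distributions, optionally the per-edge cardinality-matched random
#' null, a two-sample Welch t-test of network edge ASp against the
#' pooled null ASp, and a pathway-size-vs-ASp correlation diagnostic.
#'
#' @param network An igraph network from [build_network()].
#' @param annotation Named list of pathway gene sets.
#' @param scores A `score_table`.
#' @param n_random Random pairs per edge for the null (0 disables it).
#' @param seed Integer seed for the null sampling.
#' @return List of class `validation_report`: `edges` (data.frame with
#'   asp and null percentile), `asn`, `percentiles`, `size_correlation`
#'   (Pearson r of ASp with each side's pathway size), `null_asn`,
#'   `t_test` (htest or NULL).
#' @export
validate_network <- function(network, annotation, scores,
                             n_random = 100L, seed = 1L) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (nrow(el) == 0L) stop("empty network")
  pw_i <- profile_pathway(el$from)
  pw_j <- profile_pathway(el$to)
  # distinct pathway pairs (several profile pairs may join the same pathways)
  edges <- unique(data.frame(pathway_i = pmin(pw_i, pw_j),
                             pathway_j = pmax(pw_i, pw_j),
                             stringsAsFactors = FALSE))
  edges$asp <- mapply(function(a, b) pathway_pair_score(annotation, scores, a, b),
                      edges$pathway_i, edges$pathway_j)
  asn <- mean(edges$asp)
  univ <- universal_pairs(annotation, scores)
  pct <- percentile_table(univ$asp, edges$asp)
  null_values <- NULL
  if (n_random > 0L) {
    nulls <- mapply(function(a, b, s) {
      cardinality_null(annotation, scores, a, b, n_random = n_random, seed = s)
    }, edges$pathway_i, edges$pathway_j,
       seed + seq_len(nrow(edges)), SIMPLIFY = FALSE)
    edges$null_percentile <- vapply(nulls, `[[`, 0, "percentile")
    null_values <- unlist(lapply(nulls, `[[`, "null"))
  }
  sizes_i <- lengths(annotation)[edges$pathway_i]
  sizes_j <- lengths(annotation)[edges$pathway_j]
  size_cor <- c(left = suppressWarnings(stats::cor(edges$asp, sizes_i)),
                right = suppressWarnings(stats::cor(edges$asp, sizes_j)))
  tt <- if (!is.null(null_values) && nrow(edges) >= 2L &&
            stats::sd(c(edges$asp, null_values)) > 0)
    stats::t.test(edges$asp, null_values) else NULL
  structure(list(edges = edges, asn = asn, percentiles = pct,
                 size_correlation = size_cor,
                 null_asn = if (is.null(null_values)) NA_real_
                            else mean(null_values),
                 t_test = tt),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", nrow(x$edges), "pathway pairs, ASn =",
      format(x$asn, digits = 6), "\n")
  if (!is.na(x$null_asn))
    cat("  cardinality-matched null ASn =", format(x$null_asn, digits = 6), "\n")
  invisible(x)
}

#' Write a validation report's edge table as TSV
#' @param report A `validation_report`.
#' @param path Output path.
#' @export
write_validation <- function(report, path) {
  utils::write.table(report$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
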