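#' Density-valley cutoff on a nonnegative statistic (minAS)
#'
#' Estimates the density of the values with a Gaussian kernel (Silverman's
#' rule-of-thumb bandwidth, 512-point grid on \[0, 1.05 * max\]) and
#' returns the abscissa of the first local minimum encountered scanning
#' from 0 upward, provided it lies after the first mode.  The statistic is
#' assumed to be at least bimodal when a meaningful cutoff exists: a large
#' near-zero component of negligible values and one or more components of
#' important ones; the valley between them separates the two regimes.
#'
#' @param values Nonnegative numeric vector, length >= 5.
#' @return Scalar cutoff, or `NA_real_` when the density is unimodal on
#'   the grid.
#' @export
minas_cutoff <- function(values) {
  if (length(values) < 5L) stop("need at least 5 values for a density cutoff")
  stopifnot(all(values >= 0))
  if (max(values) == 0) return(NA_real_)
  d <- stats::density(values, bw = "nrd0", n = 512,
                      from = 0, to = max(values) * 1.05)
  y <- d$y
  # floor FFT round-off so zero-density plateaus are exact
  y[y < 1e-10 * max(y)] <- 0
  n <- length(y)
  # a density already falling at x = 0 has its first mode at the boundary
  first_mode <- if (y[1L] > y[2L]) 1L else NA_integer_
  i <- 2L
  while (i <= n) {
    # leftmost point of a (possibly flat) local extremum
    if (y[i - 1L] < y[i]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j == n || y[j + 1L] < y[j]) {      # local maximum at i
        if (is.na(first_mode)) first_mode <- i
      }
      i <- j + 1L
    } else if (y[i - 1L] > y[i]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] > y[j] && !is.na(first_mode))
        return(d$x[[i]])                     # first valley after the mode
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_real_                                   # unimodal on the grid
}

#' Driving genes of a pathway profile
#'
#' Applies [minas_cutoff()] to the absolute loadings of a profile; genes
#' with |loading| above the cutoff are the profile's driving genes, the
#' dominant contributors to the signature.  When the loading density is
#' unimodal (no valley), the single gene with the largest |loading| is
#' reported and the profile is flagged `no_bimodality`.
#'
#' @param profile_set A `profile_set` from [build_plm()].
#' @param profile Profile identifier (`pathway#component`).
#' @return List of class `driving_gene_report`: `profile`, `cutoff`
#'   (`NA` under the fallback), `flag` (`"ok"` or `"no_bimodality"`), and
#'   `driving_genes` (data.frame gene/loading, by decreasing |loading|).
#' @export
driving_genes <- function(profile_set, profile) {
  stopifnot(inherits(profile_set, "profile_set"))
  l <- profile_set$loadings[[profile]]
  if (is.null(l)) stop("unknown profile: ", profile)
  al <- abs(l)
  cutoff <- if (length(al) >= 5L) minas_cutoff(al) else NA_real_
  if (is.na(cutoff)) {
    genes <- names(al)[which.max(al)]
    flag <- "no_bimodality"
  } else {
    genes <- names(al)[al > cutoff]
    flag <- "ok"
  }
  ord <- order(al[genes], decreasing = TRUE)
  structure(list(profile = profile, cutoff = cutoff, flag = flag,
                 driving_genes = data.frame(gene = genes[ord],
                                            loading = unname(l[genes][ord]),
                                            stringsAsFactors = FALSE)),
            class = "driving_gene_report")
}

#' @export
print.driving_gene_report <- function(x, ...) {
  cat(sprintf("driving genes of %s: %d gene(s), cutoff %s%s\n",
              x$profile, nrow(x$driving_genes),
              if (is.na(x$cutoff)) "NA" else format(x$cutoff, digits = 4),
              if (x$flag == "ok") "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Driving genes for every profile of a profile set
#'
#' @param profile_set A `profile_set`.
#' @return Named list of `driving_gene_report`s, one per profile.
#' @export
all_driving_genes <- function(profile_set) {
  ids <- names(profile_set$loadings)
  stats::setNames(lapply(ids, driving_genes, profile_set = profile_set), ids)
}

#' Write driving-gene reports as a long TSV
#' @param reports List of `driving_gene_report`s (see [all_driving_genes()]).
#' @param path Output path.
#' @export
write_drivers <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    data.frame(profile = r$profile, gene = r$driving_genes$gene,
               loading = r$driving_genes$loading,
               cutoff = r$cutoff, flag = r$flag, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
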