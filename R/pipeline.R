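#' Run the full pathway-network pipeline
#'
#' Convenience wrapper chaining pathway compression ([build_plm()]), rule
#' inference ([infer_rules()]), driving-gene identification
#' ([all_driving_genes()]) and network assembly ([build_network()]).
#'
#' @param x Expression matrix (genes x samples).
#' @param annotation Named list of pathway gene sets.
#' @param params A [compression_params()] object.
#' @param accuracy_min Rule accuracy threshold.
#' @param drivers Also compute driving genes per profile.
#' @param dedupe Collapse mutual same-class rules into undirected edges.
#' @return List of class `pana_result`: `profile_set`, `rules`,
#'   `drivers` (or NULL), `network`.
#' @examples
#' \donttest{
#' design <- simulation_design(gene_counts = c(30, 60),
#'                             profile_types = c(1, 5),
#'                             inner_correlations = c(0, 0.8),
#'                             n_samples = 20, seed = 7)
#' ds <- simulate_dataset(design)
#' res <- pana(ds$matrix, ds$annotation,
#'             compression_params(alpha = 0.05, n_boot = 20, seed = 7))
#' res$rules
#' }
#' @export
pana <- function(x, annotation, params = compression_params(),
                 accuracy_min = 0.9, drivers = TRUE, dedupe = FALSE) {
  ps <- build_plm(x, annotation, params)
  rules <- infer_rules(ps, accuracy_min)
  dg <- if (drivers) all_driving_genes(ps) else NULL
  net <- build_network(rules, ps, drivers = dg, dedupe = dedupe)
  structure(list(profile_set = ps, rules = rules, drivers = dg,
                 network = net, accuracy_min = accuracy_min),
            class = "pana_result")
}

#' @export
print.pana_result <- function(x, ...) {
  cat("pana_result:", nrow(x$profile_set$plm), "profiles,",
      nrow(x$rules), "rules (accuracy >=", x$accuracy_min, "),",
      igraph::ecount(x$network), "network edges\n")
  invisible(x)
}
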