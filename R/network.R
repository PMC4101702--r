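#' Assemble accuracy-filtered rules into a pathway network
#'
#' Builds an igraph graph whose nodes are pathway profiles and whose edges
#' are association rules.  Edge attributes carry class, accuracy,
#' correlation and a display color (direct = blue, opposite = red); node
#' attributes carry the pathway, component index and (optionally) the
#' driving genes.  With `dedupe = TRUE`, mutual rules (l -> j and j -> l
#' of the same class) collapse into one undirected edge keeping the
#' maximum accuracy.
#'
#' @param rules A `rule_set` (already accuracy-filtered).
#' @param profile_set The `profile_set` the rules were inferred from.
#' @param drivers Optional list of `driving_gene_report`s (see
#'   [all_driving_genes()]).
#' @param dedupe Collapse mutual same-class rules into undirected edges.
#' @return An igraph object with a `params` graph attribute recording the
#'   compression/rule parameters (provenance).
#' @export
build_network <- function(rules, profile_set, drivers = NULL, dedupe = FALSE) {
  ids <- rownames(profile_set$plm)
  unknown <- setdiff(unique(c(rules$source, rules$target)), ids)
  if (length(unknown))
    stop("rule references unknown profile(s): ", paste(unknown, collapse = ", "))
  if (nrow(rules) > 0 && any(rules$source == rules$target))
    stop("self-edges are not allowed")

  if (dedupe && nrow(rules) > 0) {
    key <- paste(pmin(rules$source, rules$target),
                 pmax(rules$source, rules$target), rules$class, sep = "\r")
    ord <- order(key, -rules$accuracy)
    rules <- rules[ord, , drop = FALSE]
    rules <- rules[!duplicated(key[ord]), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    rules[, c("source", "target", "class", "threshold", "sensitivity",
              "specificity", "accuracy", "correlation")],
    directed = !dedupe,
    vertices = data.frame(name = ids,
                          pathway = profile_pathway(ids),
                          component = as.integer(sub("^.*#", "", ids)),
                          stringsAsFactors = FALSE))
  igraph::E(g)$color <- ifelse(igraph::E(g)$class == "direct", "blue", "red")
  if (!is.null(drivers)) {
    dg <- vapply(ids, function(id) {
      r <- drivers[[id]]
      if (is.null(r)) "" else paste(r$driving_genes$gene, collapse = ",")
    }, "")
    igraph::V(g)$driving_genes <- unname(dg)
  }
  p <- profile_set$params
  g <- igraph::set_graph_attr(g, "params",
    sprintf("alpha=%g;n_boot=%d;q=%g;seed=%d;gamma=%s",
            p$alpha, p$n_boot, p$q_threshold, p$seed, p$gamma_method))
  g
}

#' Fraction of network links joining pathways with the same planted SEP
#'
#' For simulated data: looks up the planted SEP identifier of each edge's
#' two pathways in the simulation truth table and returns the fraction of
#' edges whose pathways share it.
#'
#' @param network An igraph network from [build_network()].
#' @param truth Truth data.frame (`simulated_dataset$truth` or
#'   [read_truth()]), columns `pathway` and `sep`.
#' @param class Optional `"direct"` or `"opposite"` to restrict the edge
#'   set.
#' @return Scalar in \[0, 1\]; `NaN` when the (restricted) edge set is
#'   empty.
#' @export
same_sep_fraction <- function(network, truth, class = NULL) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (!is.null(class)) el <- el[el$class == class, , drop = FALSE]
  sep <- stats::setNames(truth$sep, truth$pathway)
  pw_from <- profile_pathway(el$from)
  pw_to <- profile_pathway(el$to)
  missing <- setdiff(unique(c(pw_from, pw_to)), names(sep))
  if (length(missing))
    stop("pathway(s) missing from truth: ", paste(missing, collapse = ", "))
  if (nrow(el) == 0L) return(NaN)
  mean(sep[pw_from] == sep[pw_to])
}

#' Export a pathway network
#'
#' `write_graphml` keeps all node/edge attributes; `write_sif` writes the
#' minimal `source  class  target` interaction format.
#'
#' @param network An igraph network.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname write_graphml
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  writeLines(paste(el$from, el$class, el$to, sep = "\t"), path)
  invisible(path)
}
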