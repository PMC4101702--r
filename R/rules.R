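#' Partition entropy of a binary target under a binary source partition
#'
#' The source states split the samples into the low (-1) and high (+1)
#' partitions; within each, the base-2 Shannon entropy of the target
#' states is computed and the two entropies are averaged with weights
#' proportional to partition size.  0 means the target is constant within
#' each partition (a perfect discretization threshold); 1 means the
#' partitions carry no information about the target.  An empty partition
#' contributes 0 with weight 0.
#'
#' @param states_l Source state vector, values in \{-1, +1\}.
#' @param states_j Target state vector, same length.
#' @return Scalar in \[0, 1\].
#' @export
partition_entropy <- function(states_l, states_j) {
  stopifnot(length(states_l) == length(states_j), length(states_l) >= 2)
  n <- length(states_l)
  pe <- 0
  for (v in c(-1, 1)) {
    idx <- states_l == v
    nv <- sum(idx)
    if (nv == 0L) next
    p <- sum(states_j[idx] == 1) / nv
    pe <- pe + (nv / n) * binary_entropy(p)
  }
  pe
}

binary_entropy <- function(p) {
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

#' Entropy-minimizing discretization threshold for one profile
#'
#' Scans every observed score value of `x_l` as candidate threshold `t_c`
#' (samples with value <= t_c go to the low partition, value > t_c to the
#' high partition) and returns the candidate minimizing the partition
#' entropy of the already-discretized target states.  Ties are broken by
#' the smallest threshold.  Candidates leaving the high partition empty
#' (the row maximum) are not usable thresholds and are skipped.
#'
#' @param x_l Continuous score vector of the profile to discretize.
#' @param states_j Target state vector in \{-1, +1\}.
#' @return List with `threshold`, `states` (the induced \{-1,+1\} vector)
#'   and `entropy`; or `NULL` when `x_l` is constant (no valid threshold).
#' @export
entropy_threshold <- function(x_l, states_j) {
  stopifnot(length(x_l) == length(states_j))
  n <- length(x_l)
  ord <- order(x_l)
  xs <- x_l[ord]
  tj <- states_j[ord] == 1
  # candidate thresholds: unique values except the maximum (which would
  # leave S_1 empty); the cut after the last tied occurrence of each value
  last <- which(xs[-n] != xs[-1L])     # split positions between distinct values
  if (length(last) == 0L) return(NULL) # constant row
  cand <- xs[last]
  cum_pos <- cumsum(tj)
  tot_pos <- cum_pos[[n]]
  n1 <- last                            # |S_-1| per candidate
  p1 <- cum_pos[last] / n1
  n2 <- n - n1
  p2 <- (tot_pos - cum_pos[last]) / n2
  pe <- (n1 / n) * vapply(p1, binary_entropy, 0) +
        (n2 / n) * vapply(p2, binary_entropy, 0)
  i <- which.min(pe)                    # first minimum = smallest threshold
  t_lj <- cand[[i]]
  list(threshold = t_lj,
       states = ifelse(x_l > t_lj, 1, -1),
       entropy = pe[[i]])
}

#' Discretize a PLM against one target profile
#'
#' The target row is discretized at its mean score (value > mean gives
#' state +1); every other row is discretized at its entropy-minimizing
#' threshold relative to the discretized target (see
#' [entropy_threshold()]).  Constant rows have no valid threshold and are
#' excluded (with a message).
#'
#' @param plm Numeric matrix, profiles x samples (e.g. `profile_set$plm`).
#' @param target Row name or index of the target profile.
#' @return List of class `discretized_plm` with `target`, `states`
#'   (matrix in \{-1,+1\}, one row per retained profile, target included)
#'   and `thresholds` (named vector; the target entry is its mean).
#' @export
discretize_plm <- function(plm, target) {
  if (inherits(plm, "profile_set")) plm <- plm$plm
  if (is.character(target)) target <- match(target, rownames(plm))
  stopifnot(!is.na(target), nrow(plm) >= 2)
  x_j <- plm[target, ]
  t_j <- mean(x_j)
  states_j <- ifelse(x_j > t_j, 1, -1)
  ids <- rownames(plm)
  states <- matrix(0, 0, ncol(plm))
  thresholds <- numeric(0)
  keep <- character(0)
  dropped <- character(0)
  for (l in seq_len(nrow(plm))) {
    if (l == target) {
      states <- rbind(states, states_j)
      thresholds <- c(thresholds, t_j)
      keep <- c(keep, ids[[l]])
      next
    }
    res <- entropy_threshold(plm[l, ], states_j)
    if (is.null(res)) { dropped <- c(dropped, ids[[l]]); next }
    states <- rbind(states, res$states)
    thresholds <- c(thresholds, res$threshold)
    keep <- c(keep, ids[[l]])
  }
  if (length(dropped))
    message("constant profile row(s) excluded from discretization: ",
            paste(dropped, collapse = ", "))
  rownames(states) <- keep
  names(thresholds) <- keep
  structure(list(target = ids[[target]], states = states,
                 thresholds = thresholds),
            class = "discretized_plm")
}

# rule accuracy from source/target state vectors for one class.
# "positive" = target state +1; a direct rule predicts the target state
# equal to the source state, an opposite rule predicts its negation.
rule_metrics <- function(states_l, states_j, class = c("direct", "opposite")) {
  class <- match.arg(class)
  pred <- if (class == "direct") states_l else -states_l
  tp <- sum(pred == 1 & states_j == 1)
  fn <- sum(pred == -1 & states_j == 1)
  tn <- sum(pred == -1 & states_j == -1)
  fp <- sum(pred == 1 & states_j == -1)
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  c(sensitivity = se, specificity = sp, accuracy = se * sp)
}

#' Infer direct/opposite association rules between pathway profiles
#'
#' Phase 2 of the pathway network analysis.  For every ordered profile
#' pair (l, j) with l != j and belonging to different pathways, the PLM is
#' discretized against target j, the 2x2 contingency of source and target
#' states is evaluated under both rule classes (direct: states co-vary;
#' opposite: states anti-vary), and the class with higher accuracy is
#' kept.  Accuracy is the product of sensitivity and specificity of
#' predicting the target state from the source state; rules with accuracy
#' below `accuracy_min` are discarded.
#'
#' @param profile_set A `profile_set` from [build_plm()], or a bare PLM
#'   matrix with `pathway#component` row names.
#' @param accuracy_min Accuracy threshold in (0, 1].
#' @return data.frame of class `rule_set`: source, target, class,
#'   threshold, sensitivity, specificity, accuracy, correlation (Pearson r
#'   of the two continuous profiles).
#' @export
infer_rules <- function(profile_set, accuracy_min = 0.9) {
  plm <- if (inherits(profile_set, "profile_set")) profile_set$plm else profile_set
  stopifnot(nrow(plm) >= 2, accuracy_min > 0, accuracy_min <= 1)
  ids <- rownames(plm)
  pw <- profile_pathway(ids)
  out <- vector("list", nrow(plm))
  for (j in seq_len(nrow(plm))) {
    x_j <- plm[j, ]
    t_j <- mean(x_j)
    states_j <- ifelse(x_j > t_j, 1, -1)
    if (length(unique(states_j)) < 2L) next   # degenerate target
    for (l in seq_len(nrow(plm))) {
      if (l == j || pw[[l]] == pw[[j]]) next
      res <- entropy_threshold(plm[l, ], states_j)
      if (is.null(res)) next
      md <- rule_metrics(res$states, states_j, "direct")
      mo <- rule_metrics(res$states, states_j, "opposite")
      if (md[["accuracy"]] >= mo[["accuracy"]]) {
        m <- md; cls <- "direct"
      } else {
        m <- mo; cls <- "opposite"
      }
      if (m[["accuracy"]] >= accuracy_min) {
        out[[j]] <- c(out[[j]], list(data.frame(
          source = ids[[l]], target = ids[[j]], class = cls,
          threshold = res$threshold,
          sensitivity = m[["sensitivity"]],
          specificity = m[["specificity"]],
          accuracy = m[["accuracy"]],
          correlation = stats::cor(plm[l, ], x_j),
          stringsAsFactors = FALSE)))
      }
    }
  }
  out <- unlist(out, recursive = FALSE)
  rules <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
           else data.frame(source = character(0), target = character(0),
                           class = character(0), threshold = numeric(0),
                           sensitivity = numeric(0), specificity = numeric(0),
                           accuracy = numeric(0), correlation = numeric(0),
                           stringsAsFactors = FALSE)
  class(rules) <- c("rule_set", "data.frame")
  rules
}

#' Write / read an association rule table as TSV
#' @param rules A `rule_set` data.frame.
#' @param path Output path.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(rules) <- c("rule_set", "data.frame")
  rules
}
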