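# independent naive re-implementation of the threshold scan, used as oracle
brute_force_threshold <- function(x_l, states_j) {
  cand <- sort(unique(x_l))
  cand <- cand[cand < max(x_l)]   # a threshold must leave both states present
  if (length(cand) == 0) return(NULL)
  pe <- vapply(cand, function(t) {
    partition_entropy(ifelse(x_l > t, 1, -1), states_j)
  }, 0)
  i <- which(pe == min(pe))[1]    # tie -> smallest threshold
  list(threshold = cand[[i]], entropy = pe[[i]])
}

test_that("partition entropy matches hand-computed values", {
  expect_equal(partition_entropy(c(1, 1, -1, -1), c(1, 1, -1, -1)), 0)
  expect_equal(partition_entropy(c(1, 1, -1, -1), c(1, -1, 1, -1)), 1)
  # (3/4) * H(2/3) + (1/4) * 0
  h23 <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(partition_entropy(c(1, 1, 1, -1), c(1, 1, -1, -1)),
               0.75 * h23, tolerance = 1e-12)
  expect_equal(0.75 * h23, 0.6887, tolerance = 1e-4)
})

test_that("entropy-minimizing thresholds align identical and negated rows", {
  x <- c(0.3, -1.2, 0.8, -0.4, 1.5, -0.9)
  sj <- ifelse(x > mean(x), 1, -1)
  res <- entropy_threshold(x, sj)
  expect_equal(res$entropy, 0)
  expect_equal(res$states, sj)
  res_neg <- entropy_threshold(-x, sj)
  expect_equal(res_neg$entropy, 0)
  expect_equal(res_neg$states, -sj)
  expect_null(entropy_threshold(rep(1, 6), sj))  # constant row
})

test_that("threshold selection agrees with exhaustive enumeration", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(4:8, 1)
    x_l <- round(rnorm(m), 2)          # rounded to force occasional ties
    states_j <- sample(c(-1, 1), m, replace = TRUE)
    if (length(unique(states_j)) < 2) next
    res <- entropy_threshold(x_l, states_j)
    ref <- brute_force_threshold(x_l, states_j)
    if (is.null(ref)) { expect_null(res); next }
    expect_equal(res$threshold, ref$threshold)
    expect_equal(res$entropy, ref$entropy, tolerance = 1e-12)
  }
})

test_that("rule accuracy is the product of sensitivity and specificity", {
  # contingency TP=10, FN=2, TN=9, FP=3 on 24 samples
  states_l <- c(rep(1, 10), rep(-1, 2), rep(-1, 9), rep(1, 3))
  states_j <- c(rep(1, 12), rep(-1, 12))
  m <- panar:::rule_metrics(states_l, states_j, "direct")
  expect_equal(m[["sensitivity"]], 10 / 12)
  expect_equal(m[["specificity"]], 9 / 12)
  expect_equal(m[["accuracy"]], 0.625)
})

test_that("identical and negated profiles give perfect rules of each class", {
  t <- seq(0, 1, length.out = 12)
  plm <- rbind("a#1" = sin(2 * pi * t), "b#1" = sin(2 * pi * t),
               "c#1" = -sin(2 * pi * t))
  rules <- infer_rules(plm, accuracy_min = 0.9)
  ab <- rules[rules$source == "a#1" & rules$target == "b#1", ]
  expect_equal(ab$class, "direct")
  expect_equal(ab$accuracy, 1.0)
  expect_equal(ab$sensitivity, 1.0)
  expect_equal(ab$specificity, 1.0)
  ac <- rules[rules$source == "a#1" & rules$target == "c#1", ]
  expect_equal(ac$class, "opposite")
  expect_equal(ac$accuracy, 1.0)
  expect_lt(ac$correlation, 0)
})

test_that("profiles of the same pathway never form rules", {
  set.seed(3)
  plm <- rbind("a#1" = rnorm(10), "a#2" = rnorm(10), "b#1" = rnorm(10))
  rules <- infer_rules(plm, accuracy_min = 1e-6)
  pairs <- paste(panar:::profile_pathway(rules$source),
                 panar:::profile_pathway(rules$target))
  expect_false(any(pairs == "a a"))
  expect_true(all(rules$source != rules$target))
})

test_that("raising the accuracy threshold never adds rules", {
  ds <- small_dataset(seed = 4)
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 30, seed = 4)))
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95, 1.0),
                   function(a) nrow(infer_rules(ps, a)), 0L)
  expect_true(all(diff(counts) <= 0))
  # and the accuracy-1 rules are exactly the perfectly (anti-)matching ones
  r1 <- infer_rules(ps, 1.0)
  expect_true(all(r1$accuracy == 1))
})

test_that("rule class agrees with the sign of the profile correlation", {
  ds <- small_dataset(seed = 12, noise_s = 0.01)
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 30, seed = 12)))
  rules <- infer_rules(ps, accuracy_min = 0.9)
  expect_gt(nrow(rules), 0)
  concordant <- (rules$class == "direct") == (rules$correlation > 0)
  expect_gte(mean(concordant), 0.99)
})

test_that("discretized PLMs satisfy their structural contract", {
  ds <- small_dataset(seed = 4, gene_counts = 30,
                      profile_types = c(1, 6), inner_correlations = c(0.8, 1))
  ps <- suppressMessages(build_plm(ds$matrix, ds$annotation,
          compression_params(alpha = 0.05, n_boot = 20, seed = 4)))
  d <- discretize_plm(ps, rownames(ps$plm)[1])
  expect_true(all(d$states %in% c(-1, 1)))
  # every retained row has both states
  expect_true(all(apply(d$states, 1, function(s) length(unique(s)) == 2)))
  # the target row is thresholded at its mean
  xj <- ps$plm[d$target, ]
  expect_equal(unname(d$states[d$target, ]),
               unname(ifelse(xj > mean(xj), 1, -1)))
  expect_equal(d$thresholds[[d$target]], mean(xj))
  # rules round-trip through TSV
  rules <- infer_rules(ps, 0.5)
  p <- tempfile(fileext = ".tsv")
  write_rules(rules, p)
  expect_equal(read_rules(p)$accuracy, rules$accuracy, tolerance = 1e-12)
})
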