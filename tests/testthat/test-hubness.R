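# helper: wrap a raw matrix as a tihs_centrality tibble
cm_from_matrix <- function(x) {
  colnames(x) <- c("degree", "betweenness", "eigenvector", "mcc", "epc")
  cm <- dplyr::bind_cols(tibble::tibble(gene = sprintf("G%02d", seq_len(nrow(x)))),
                         tibble::as_tibble(x))
  class(cm) <- c("tihs_centrality", class(cm))
  cm
}

test_that("zscore_shift standardizes with population sd and shifts to min 0.001", {
  x <- cbind(c(0, 2), c(5, 5), c(1, 3), c(0, 4), c(0.2, 0.8))
  nm <- zscore_shift(cm_from_matrix(x))
  # column [0,2]: population sd 1 -> Z = (-1, 1), Z' = (0.001, 2.001)
  expect_equal(unname(nm$z[, 1]), c(-1, 1))
  expect_equal(unname(nm$z_shifted[, 1]), c(0.001, 2.001))
  # degenerate column -> Z = 0, Z' = 0.001
  expect_equal(unname(nm$z[, 2]), c(0, 0))
  expect_equal(unname(nm$z_shifted[, 2]), c(0.001, 0.001))
  # every column has minimum exactly 0.001 and positive entries
  expect_equal(unname(apply(nm$z_shifted, 2, min)), rep(0.001, 5))
  expect_true(all(nm$z_shifted > 0))
  # non-degenerate Z columns have mean 0 and population sd 1
  set.seed(31)
  nm2 <- zscore_shift(cm_from_matrix(matrix(stats::runif(50), 10, 5)))
  expect_equal(unname(colMeans(nm2$z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(nm2$z^2))), rep(1, 5), tolerance = 1e-12)
  # a single-node matrix has no definable variance
  expect_error(zscore_shift(cm_from_matrix(matrix(1:5, 1, 5))), "2 nodes")
})

test_that("std_share weights are the sigma shares of min-max rescaled columns", {
  # columns engineered so rescaled sigmas are proportional to (2,1,1,1,0):
  # shape1 rescales to half 0s / half 1s (population sd 0.5); shape2 rescales
  # to 0, six 0.5s, 1 (population sd 0.25)
  shape1 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  shape2 <- c(0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1)
  x <- cbind(shape1 * 10 + 3, shape2, shape2 * 100, shape2 - 2, rep(7, 8))
  cm <- cm_from_matrix(x)
  w <- derive_weights(zscore_shift(cm), cm, mode = "std_share")
  expect_equal(w$weight, c(0.4, 0.2, 0.2, 0.2, 0), tolerance = 1e-12)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
})

test_that("five identical i.i.d. columns give near-equal weights in both modes", {
  set.seed(8)
  col <- stats::rnorm(40)
  x <- matrix(rep(col, 5), ncol = 5)
  cm <- cm_from_matrix(x)
  nm <- zscore_shift(cm)
  w1 <- derive_weights(nm, cm, mode = "std_share")
  expect_equal(w1$weight, rep(0.2, 5), tolerance = 1e-12)
  # rank-1 correlation: PC1 loadings are equal in magnitude
  w2 <- derive_weights(nm, cm, mode = "pca_loading")
  expect_equal(w2$weight, rep(0.2, 5), tolerance = 1e-9)
})

test_that("compute_tihs is the weighted dot product, sorted with deterministic ties", {
  set.seed(3)
  x <- matrix(stats::rexp(100), 20, 5)
  cm <- cm_from_matrix(x)
  nm <- zscore_shift(cm)
  w <- derive_weights(nm, cm, mode = "std_share")
  hub <- compute_tihs(nm, w)
  # independent dot-product oracle
  oracle <- as.numeric(nm$z_shifted %*% w$weight)
  names(oracle) <- nm$genes
  expect_equal(hub$tihs, unname(oracle[hub$gene]), tolerance = 1e-12)
  expect_true(all(diff(hub$tihs) <= 0))
  expect_true(all(hub$tihs > 0))

  # all-equal shifted scores: TIHS = 0.001 everywhere
  xc <- matrix(rep(c(1, 1, 1), 5), 3, 5)
  nmc <- zscore_shift(cm_from_matrix(xc))
  hubc <- compute_tihs(nmc, w)
  expect_equal(hubc$tihs, rep(0.001, 3))
  # ties broken by gene name ascending
  expect_equal(hubc$gene, sort(hubc$gene))

  # weights concentrated on one metric reproduce that metric's ordering
  wdeg <- w
  wdeg$weight <- c(1, 0, 0, 0, 0)
  hubd <- compute_tihs(nm, wdeg)
  expect_equal(hubd$gene[order(-hubd$tihs)],
               cm$gene[order(-cm$degree, cm$gene)])

  # metric mismatch errors
  wbad <- w
  wbad$metric[1] <- "closeness"
  expect_error(compute_tihs(nm, wbad), "mismatch")
})

test_that("average_weights is the renormalized per-metric mean", {
  m <- tihs:::tihs_metrics()
  w1 <- tihs:::new_weights(c(0.4, 0.2, 0.2, 0.1, 0.1), m, mode = "std_share")
  w2 <- tihs:::new_weights(c(0.2, 0.4, 0.2, 0.1, 0.1), m, mode = "std_share")
  avg <- average_weights(list(w1, w2))
  expect_equal(avg$weight, c(0.3, 0.3, 0.2, 0.1, 0.1), tolerance = 1e-12)
  expect_equal(average_weights(list(w1))$weight, w1$weight)
  set.seed(2)
  ws <- lapply(1:4, function(i) {
    v <- stats::runif(5)
    tihs:::new_weights(v / sum(v), m, mode = "std_share")
  })
  expect_equal(sum(average_weights(ws)$weight), 1, tolerance = 1e-14)
  w3 <- tihs:::new_weights(rep(0.2, 5), m, mode = "pca_loading")
  expect_warning(average_weights(list(w1, w3)), "mixed")
})

test_that("cosine_stability reproduces hand-computed cosines and flags instability", {
  m <- tihs:::tihs_metrics()
  mk <- function(v) tihs:::new_weights(v / sum(v), m, mode = "std_share")
  u <- mk(c(1, 0, 0, 0, 0))
  rep_ <- cosine_stability(list(self = u, orth = mk(c(0, 1, 0, 0, 0)),
                                diag = mk(c(1, 1, 0, 0, 0))), u)
  expect_equal(rep_$cosine[rep_$source == "self"], 1)
  expect_equal(rep_$cosine[rep_$source == "orth"], 0)
  expect_equal(rep_$cosine[rep_$source == "diag"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(rep_$stable, c(TRUE, FALSE, FALSE))
})

test_that("TIHS is invariant to positive affine transforms of raw centrality columns", {
  set.seed(17)
  x <- matrix(stats::rexp(150), 30, 5)
  cm <- cm_from_matrix(x)
  nm <- zscore_shift(cm)
  for (mode in c("std_share", "pca_loading")) {
    w <- derive_weights(nm, cm, mode = mode)
    ref <- compute_tihs(nm, w)
    for (rep in 1:3) {
      a <- stats::runif(5, 0.1, 20)
      b <- stats::runif(5, -5, 5)
      x2 <- sweep(sweep(x, 2, a, `*`), 2, b, `+`)
      cm2 <- cm_from_matrix(x2)
      nm2 <- zscore_shift(cm2)
      w2 <- derive_weights(nm2, cm2, mode = mode)
      hub2 <- compute_tihs(nm2, w2)
      expect_equal(w2$weight, w$weight, tolerance = 1e-9)
      expect_equal(hub2$tihs, ref$tihs, tolerance = 1e-9)
      expect_equal(hub2$gene, ref$gene)
    }
  }
})
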