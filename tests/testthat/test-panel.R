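test_that("z-scoring centres and scales each marker over the given subjects", {
  x <- nb_fixture(n_mirnas = 20, seed = 41)
  norm <- cpm_matrix(x)
  subj <- colnames(norm$values)
  z <- zscore_markers(norm, rownames(norm$values)[1:5], subj)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-10)
  # two subjects, sample sd: z = -1/sqrt(2), +1/sqrt(2)
  m <- matrix(c(3, 7), 1, 2, dimnames = list("m", c("a", "b")))
  z2 <- zscore_markers(m, "m", c("a", "b"))
  expect_equal(unname(z2[1, ]), c(-1, 1) / sqrt(2))
  # affine transforms leave z unchanged
  z3 <- zscore_markers(m * 10 + 3, "m", c("a", "b"))
  expect_equal(z3, z2)
  # zero sd errors, naming the miRNA
  mc <- rbind(flat = c(1, 1), ok = c(5, 6))
  colnames(mc) <- c("a", "b")
  expect_error(zscore_markers(mc, c("flat", "ok"), c("a", "b")), "flat")
})

test_that("AUC matches hand-counted concordant pairs and handles separation", {
  lab <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(c(1, 2, 3, 4), lab)$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), lab)$auc, 0.75)
  expect_equal(roc_auc(c(4, 3, 2, 1), lab)$auc, 0)
  # ties count one half
  expect_equal(roc_auc(c(1, 2, 2, 3), lab)$auc, 0.875)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "non-empty")
})

test_that("mean AUC over all label placements is one half", {
  # exhaustive enumeration: scores fixed, all C(4,2) positive placements
  scores <- c(0.3, 1.2, 0.7, 2.0)
  placements <- combn(4, 2)
  aucs <- apply(placements, 2, function(pos) {
    lab <- seq_len(4) %in% pos
    roc_auc(scores, lab)$auc
  })
  expect_equal(mean(aucs), 0.5)
})

test_that("rank-based AUC equals the trapezoidal ROC area on random fixtures", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(c(0, 1, 2), 1))  # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("label flip maps AUC to its complement and preserves p", {
  set.seed(9)
  scores <- rnorm(20)
  labels <- rep(c(TRUE, FALSE), 10)
  a <- roc_auc(scores, labels)
  b <- roc_auc(scores, !labels)
  expect_equal(a$auc + b$auc, 1)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("Mann-Whitney p agrees with the base-R normal approximation", {
  set.seed(10)
  scores <- c(rnorm(12), rnorm(10, 1))
  labels <- rep(c(FALSE, TRUE), c(12, 10))
  r <- roc_auc(scores, labels)
  w <- wilcox.test(scores[labels], scores[!labels], exact = FALSE,
                   correct = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("marker ranking orients, sorts, and breaks ties by p then ID", {
  z <- rbind(good = c(0, 1, 2, 3, 10, 11, 12, 13),
             weak = c(5, 0, 3, 1, 4, 2, 6, 7),
             inverse = c(9, 8, 7, 6, 1, 2, 0, 3))
  colnames(z) <- paste0("s", 1:8)
  labels <- rep(c(FALSE, TRUE), each = 4)
  rk <- rank_markers(z, labels)
  expect_equal(rk$mirna_id[1:2], c("good", "inverse"))
  expect_equal(rk$orientation[rk$mirna_id == "inverse"], -1)
  expect_gte(min(rk$auc), 0.5)
})

test_that("panel growth stops when an added marker does not improve AUC", {
  # two copies of a strong marker plus one pure-noise marker
  strong <- c(0.1, 0.4, 0.2, 0.3, 1.8, 1.6, 1.9, 1.7)
  noise <- c(1, -1, 1, -1, 1, -1, 1, -1)
  z <- rbind(m1 = strong, m2 = strong, m3 = noise)
  colnames(z) <- paste0("s", 1:8)
  labels <- rep(c(FALSE, TRUE), each = 4)
  zs <- t(apply(z, 1, function(v) (v - mean(v)) / sd(v)))
  pan <- build_panel(zs, labels)
  expect_lte(length(pan$selected_panel), 2)
  expect_false("m3" %in% pan$selected_panel)
  # trajectory AUCs correspond to successive prefixes of the ranking
  expect_equal(pan$trajectory$panel_size, seq_len(nrow(pan$trajectory)))
  # stop-rule guarantee: panel AUC >= best single marker
  expect_gte(pan$panel_auc, max(pan$ranked_markers$auc))
})

test_that("single-marker panels degenerate gracefully", {
  z <- matrix(c(-1.2, -0.3, 0.4, 1.1), 1, 4,
              dimnames = list("only", paste0("s", 1:4)))
  pan <- build_panel(z, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(pan$selected_panel, "only")
  expect_gte(nrow(pan$trajectory), 1)
})

test_that("pooled t-test matches the textbook formula and base R", {
  x <- c(1.1, 2.3, 0.7, 1.9); y <- c(3.2, 4.1, 2.8, 3.6, 3.9)
  scores <- c(x, y); labels <- rep(c("A", "B"), c(4, 5))
  res <- panel_group_test(scores, labels)
  sp2 <- (3 * var(x) + 4 * var(y)) / 7
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 5))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 7)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  res0 <- panel_group_test(c(1, 2, 1, 2), c("A", "A", "B", "B"))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(panel_group_test(c(1, 1, 1, 1), c("A", "A", "B", "B")),
               "pooled variance")
})

test_that("K2 normality statistic reproduces frozen reference values", {
  # reference values computed with an independent implementation of the
  # D'Agostino (skew) and Anscombe-Glynn (kurtosis) transforms
  x1 <- c(10.691168, 11.643236, 10.660874, 7.393686, 11.810712, 10.892749,
          8.926094, 11.162236, 10.729145, 10.588265, 10.056844, 11.093426,
          8.527092, 9.67418, 9.035761, 11.197692, 10.079444, 9.415086,
          8.436183, 9.485616)
  r1 <- dagostino_k2(x1)
  expect_equal(r1$k2, 1.3687308590956069, tolerance = 1e-9)
  expect_equal(r1$p, 0.5044102118546672, tolerance = 1e-9)
  expect_equal(r1$z_skew, -1.1624883794513725, tolerance = 1e-9)
  expect_equal(r1$z_kurt, -0.13172557358436038, tolerance = 1e-9)
  x2 <- c(1.008175, 0.759114, 3.64758, 2.736622, 0.06646, 0.151221,
          0.839648, 0.655609, 1.238181, 1.242744, 8.313151, 0.328894,
          0.685501, 7.711954, 1.909236)
  r2 <- dagostino_k2(x2)
  expect_equal(r2$k2, 11.698355014102496, tolerance = 1e-9)
  expect_equal(r2$p, 0.002882268829224196, tolerance = 1e-9)
  # perfectly symmetric data has exactly zero skew statistic
  expect_equal(dagostino_k2(as.numeric(1:12))$z_skew, 0)
  expect_error(dagostino_k2(rnorm(5)), "n >= 8")
})

test_that("covariate correlation gates the method on normality", {
  set.seed(12)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30, sd = 1e-6)
  res <- correlate_panel_covariate(y, x)
  expect_equal(res$method, "pearson")
  expect_equal(res$r, 1, tolerance = 1e-6)
  # heavy-tailed monotone data fails the K2 gate -> spearman
  xl <- exp(rnorm(40, sd = 2))
  yl <- xl^2
  res2 <- correlate_panel_covariate(yl, xl)
  expect_equal(res2$method, "spearman")
  expect_equal(res2$r, 1)
  expect_error(correlate_panel_covariate(rnorm(5), rnorm(5)), "n >= 8")
})

test_that("independent covariates rarely produce spurious correlation", {
  set.seed(13)
  hits <- 0
  for (i in 1:20) {
    res <- correlate_panel_covariate(rnorm(18), rnorm(18))
    hits <- hits + (res$p < 0.05)
  }
  expect_lte(hits, 2)
})
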