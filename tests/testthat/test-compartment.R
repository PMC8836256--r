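make_pairs <- function(serum, csf, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(nrow(serum)))
  rownames(serum) <- rownames(csf) <- ids
  colnames(serum) <- paste0("S", seq_len(ncol(serum)))
  colnames(csf) <- paste0("C", seq_len(ncol(csf)))
  map <- data.frame(serum_id = colnames(serum), csf_id = colnames(csf))
  pair_compartments(serum, csf, map)
}

test_that("compartment pairing computes hand-checked means and exclusions", {
  serum <- rbind(c(2, 4), c(10, 30), c(5, 5))
  csf <- rbind(c(1, 3), c(20, 40), c(4, 6))
  pr <- make_pairs(serum, csf)
  expect_equal(pr$serum_mean, c(3, 20, 5))
  expect_equal(pr$csf_mean, c(2, 30, 5))
  # a miRNA missing from one compartment is excluded but counted
  s2 <- serum; rownames(s2) <- c("m001", "m002", "extra")
  colnames(s2) <- c("S1", "S2")
  c2 <- csf; rownames(c2) <- c("m001", "m002", "m003")
  colnames(c2) <- c("C1", "C2")
  map <- data.frame(serum_id = c("S1", "S2"), csf_id = c("C1", "C2"))
  pr2 <- pair_compartments(s2, c2, map)
  expect_equal(nrow(pr2), 2)
  expect_equal(unname(attr(pr2, "excluded")["serum_only"]), 1)
  # identical matrices land on the identity line
  pr3 <- make_pairs(serum, serum)
  expect_equal(pr3$log10_serum, pr3$log10_csf)
  bad_map <- data.frame(serum_id = c("S1", "S1"), csf_id = c("C1", "C2"))
  expect_error(pair_compartments(s2, c2, bad_map), "bijection")
})

test_that("two-means split recovers a bimodal log-difference structure", {
  set.seed(5)
  n_sim <- 500; n_hi <- 40
  serum <- matrix(10^runif((n_sim + n_hi) * 4, 1, 4), ncol = 4)
  ratio <- c(10^rnorm(n_sim, 0, 0.2), 10^(-2 + rnorm(n_hi, 0, 0.2)))
  csf <- serum * ratio
  pr <- split_populations(make_pairs(serum, csf))
  truth <- rep(c("similar", "high_serum"), c(n_sim, n_hi))
  expect_gte(mean(pr$population == truth), 0.98)
  sizes <- attr(pr, "sizes")
  expect_equal(sum(sizes), nrow(pr))
  # the threshold separates the two clusters
  d <- pr$log10_serum - pr$log10_csf
  thr <- attr(pr, "threshold")
  expect_true(all(d[pr$population == "high_serum"] > thr))
  expect_true(all(d[pr$population == "similar"] < thr))
})

test_that("split is invariant to ID relabeling and global log shifts", {
  set.seed(6)
  serum <- matrix(10^runif(200, 1, 4), ncol = 2)
  ratio <- c(rep(1, 80), rep(0.01, 20)) * 10^rnorm(100, 0, 0.1)
  csf <- serum * ratio
  p1 <- split_populations(make_pairs(serum, csf))
  p2 <- split_populations(make_pairs(serum, csf,
                                     ids = sprintf("zz%03d", 100:1)))
  expect_equal(unname(attr(p1, "sizes")), unname(attr(p2, "sizes")))
  expect_equal(p1$population, p2$population)
  # multiplying both compartments by a constant shifts both log means
  p3 <- split_populations(make_pairs(serum * 100, csf * 100))
  expect_equal(p3$population, p1$population)
})

test_that("degenerate log-differences yield a single population with warning", {
  serum <- matrix(10^runif(40, 1, 3), ncol = 2)
  expect_warning(pr <- split_populations(make_pairs(serum, serum)),
                 "single population")
  expect_true(all(pr$population == "similar"))
  expect_error(split_populations(make_pairs(serum[1:4, ], serum[1:4, ])),
               ">= 10")
})

test_that("population correlation is rank-invariant and null-calibrated", {
  set.seed(7)
  # single-subject compartments so the per-miRNA means ARE the values:
  # a monotone transform of the means then gives exactly rho = 1
  serum <- matrix(10^runif(200, 1, 4), ncol = 1)
  csf <- serum^1.3
  pr <- make_pairs(serum, csf)
  pr$population <- "similar"
  r <- correlate_population(pr, "similar")
  expect_equal(r$r, 1)
  # independent compartments: small correlation
  csf2 <- matrix(10^runif(200, 1, 4), ncol = 1)
  pr2 <- make_pairs(serum, csf2)
  pr2$population <- "similar"
  expect_lt(abs(correlate_population(pr2, "similar")$r), 0.2)
  expect_error(correlate_population(pr2, "high_serum"), "< 5")
})

test_that("per-miRNA correlation recovers coupling and reports missing IDs", {
  set.seed(8)
  n <- 16
  latent <- rnorm(n)
  serum <- rbind(coupled = 100 * 2^(latent + rnorm(n, sd = 0.1)),
                 uncoupled = 100 * 2^rnorm(n))
  csf <- rbind(coupled = 50 * 2^(latent + rnorm(n, sd = 0.1)),
               uncoupled = 50 * 2^rnorm(n))
  colnames(serum) <- paste0("S", 1:n); colnames(csf) <- paste0("C", 1:n)
  map <- data.frame(serum_id = colnames(serum), csf_id = colnames(csf))
  res <- suppressWarnings(
    per_mirna_correlation(serum, csf, c("coupled", "uncoupled", "ghost"), map))
  expect_gt(res$r[res$mirna_id == "coupled"], 0.8)
  expect_true(is.na(res$r[res$mirna_id == "ghost"]))
  # a column equal to its serum counterpart correlates perfectly
  res2 <- per_mirna_correlation(serum, serum[, , drop = FALSE],
                                "coupled",
                                data.frame(serum_id = colnames(serum),
                                           csf_id = colnames(serum)))
  expect_equal(res2$r, 1, tolerance = 1e-12)
})
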