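fake_de <- function(ids, lfc, p) {
  data.frame(mirna_id = ids, log2fc = lfc, raw_p = p,
             adj_p = pmin(p * 2, 1), dispersion = 0.2,
             stringsAsFactors = FALSE)
}

test_that("BH adjustment matches the textbook step-up on hand-computed cases", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.42), 0.42)                 # single p unchanged
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))       # all ones stay ones
  # hand-computed mixed case: p_(i) * n / i with running minimum from top
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(adjust_bh(p), c(0.02, 0.0533333333333333, 0.0533333333333333, 0.8),
               tolerance = 1e-12)
  expect_error(adjust_bh(c(0.1, 0)), "0, 1")
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
})

test_that("BH is permutation-equivariant", {
  set.seed(4)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("DE calling thresholds are boundary-inclusive on the fold change", {
  det <- fake_de(c("x", "y", "z"), c(1.0, 0.99, 3), c(0.005, 0.005, 0.02))
  s <- call_de(det)
  expect_equal(s$up, "x")           # p<0.01 & lfc >= 1 -> up
  expect_length(s$down, 0)          # lfc 0.99 misses; p 0.02 misses
})

test_that("dispersion estimation recovers the generating value", {
  x <- nb_fixture(n_mirnas = 800, n_a = 8, n_b = 8, phi = 0.2,
                  depth = 2e5, seed = 19)
  d <- estimate_dispersion(x)
  expect_gt(d$common, 0.15)
  expect_lt(d$common, 0.25)
  # Poisson data: common estimate collapses toward zero
  xp <- nb_fixture(n_mirnas = 800, n_a = 8, n_b = 8, phi = 1e-8,
                   depth = 2e5, seed = 20)
  expect_lt(estimate_dispersion(xp)$common, 0.05)
})

test_that("dispersion estimation survives boundary inputs", {
  m <- matrix(c(1e6, 1.1e6, 0.9e6, 1.05e6), 1, 4,
              dimnames = list("big", paste0("s", 1:4)))
  x <- toy_counts(m, c("A", "A", "B", "B"))
  d <- estimate_dispersion(x)
  expect_true(is.finite(d$common) && d$common >= 0)
  expect_error(estimate_dispersion(toy_counts(m, c("A", "A", "A", "B"))),
               ">= 2 samples")
})

test_that("a planted 8-fold effect is detected by both engines with correct sign", {
  set.seed(23)
  x <- nb_fixture(n_mirnas = 300, n_a = 8, n_b = 8, phi = 0.1,
                  depth = 1e5, seed = 23)
  target <- "miR-0005"
  stopifnot(mean(x$counts[target, ]) > 50)
  x$counts[target, x$meta$group == "A"] <-
    rnbinom(8, size = 10, mu = 8 * mean(x$counts[target, ]))
  for (eng in c("ql", "exact")) {
    det <- de_test(x, "A", "B", engine = eng)
    row <- det[det$mirna_id == target, ]
    expect_lt(row$raw_p, 0.01)
    expect_gt(row$log2fc, 1)
  }
})

test_that("contrast antisymmetry: swapping groups negates lfc, keeps p", {
  x <- nb_fixture(n_mirnas = 150, n_a = 5, n_b = 7, seed = 29)
  for (eng in c("ql", "exact")) {
    ab <- de_test(x, "A", "B", engine = eng)
    ba <- de_test(x, "B", "A", engine = eng)
    expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-10)
    tol <- if (eng == "exact") 1e-12 else 1e-8
    expect_equal(ab$raw_p, ba$raw_p, tolerance = tol)
  }
})

test_that("all-zero miRNAs are skipped with p = 1 and lfc = 0", {
  x <- nb_fixture(n_mirnas = 50, seed = 31)
  x$counts[3, ] <- 0
  det <- suppressWarnings(de_test(x, "A", "B"))
  expect_equal(det$raw_p[3], 1)
  expect_equal(det$log2fc[3], 0)
  expect_error(de_test(x, "A", "A"), "differ")
  expect_error(de_test(x, "A", "nope"), "unknown group")
})

test_that("exact and QL engines agree in ranking on two-group data", {
  x <- nb_fixture(n_mirnas = 400, n_a = 8, n_b = 8, phi = 0.15,
                  depth = 5e4, seed = 37)
  pq <- de_test(x, "A", "B", engine = "ql")$raw_p
  pe <- de_test(x, "A", "B", engine = "exact")$raw_p
  expect_gte(cor(rank(pq), rank(pe)), 0.95)
})

test_that("stage-specific sets follow the double-dissociation definition", {
  ids <- c("m1", "m2", "m3")
  de <- list(
    CIS_vs_HealthCtl = fake_de(ids, c(-2, -2, 1.5), c(0.001, 0.001, 0.001)),
    RRMS_vs_HealthCtl = fake_de(ids, c(0, 1.8, 2.1), c(0.5, 0.001, 0.001)),
    CIS_vs_RRMS = fake_de(ids, c(-1.6, 0.2, -1.9), c(0.002, 0.9, 0.004)))
  s <- stage_specific_sets(de)
  # m1 down in CIS vs both comparators -> CIS-specific
  expect_equal(s$cis_specific_down, "m1")
  # m3 up in RRMS vs HealthCtl and up vs CIS (down in CIS_vs_RRMS)
  expect_equal(s$rrms_specific_up, "m3")

  # the flipped orientation gives identical sets
  de2 <- de
  de2$RRMS_vs_CIS <- fake_de(ids, -de$CIS_vs_RRMS$log2fc, de$CIS_vs_RRMS$raw_p)
  de2$CIS_vs_RRMS <- NULL
  s2 <- stage_specific_sets(de2)
  expect_equal(s2$cis_specific_down, s$cis_specific_down)
  expect_equal(s2$rrms_specific_up, s$rrms_specific_up)

  # empty DE tables give empty sets
  de0 <- lapply(de, function(d) { d$raw_p[] <- 1; d })
  s0 <- stage_specific_sets(de0)
  expect_length(s0$cis_specific_down, 0)
  expect_length(s0$rrms_specific_up, 0)
  expect_length(s0$venn_partition, 0)

  expect_error(stage_specific_sets(de[1:2]), "missing contrast")
})

test_that("venn partition assigns each miRNA to its direction-resolved region", {
  ids <- c("m1", "m2")
  de <- list(
    CIS_vs_HealthCtl = fake_de(ids, c(2, -2), c(0.001, 0.001)),
    RRMS_vs_HealthCtl = fake_de(ids, c(2, 0), c(0.001, 0.9)),
    VI_vs_HealthCtl = fake_de(ids, c(2, 0), c(0.001, 0.9)),
    CIS_vs_RRMS = fake_de(ids, c(0, 0), c(0.9, 0.9)))
  s <- stage_specific_sets(de)
  expect_equal(s$venn_partition[["CIS+RRMS+VI:up"]], "m1")
  expect_equal(s$venn_partition[["CIS:down"]], "m2")
})
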