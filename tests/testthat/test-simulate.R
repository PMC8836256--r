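test_that("identical seeds give bit-identical simulations", {
  a <- simulate_counts(sim_params(n_mirnas = 300, seed = 9))
  b <- simulate_counts(sim_params(n_mirnas = 300, seed = 9))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$cis_down_ids, b$truth$cis_down_ids)
  c_ <- simulate_counts(sim_params(n_mirnas = 300, seed = 10))
  expect_false(identical(a$counts$counts, c_$counts$counts))
})

test_that("null configuration plants no effects", {
  p <- sim_params(n_mirnas = 400, planted_log2fc = 0, seed = 2)
  sim <- simulate_counts(p)
  expect_true(all(sim$truth$log2fc == 0))
})

test_that("planted sets are disjoint and present in the matrix", {
  sim <- simulate_counts(sim_params(seed = 3))
  tr <- sim$truth
  expect_length(intersect(tr$cis_down_ids, tr$rrms_up_ids), 0)
  all_planted <- c(tr$cis_down_ids, tr$rrms_up_ids, tr$shared_up_ids,
                   tr$shared_down_ids, tr$vi_up_ids, tr$vi_down_ids)
  expect_false(anyDuplicated(all_planted) > 0)
  expect_true(all(all_planted %in% rownames(sim$counts$counts)))
})

test_that("per-sample detected miRNAs fall in the observed band", {
  sim <- simulate_counts(sim_params(seed = 21))
  det <- detected_per_sample(sim$counts)
  expect_gte(mean(det >= 731 & det <= 2407), 0.95)
})

test_that("empirical log2FC of planted miRNAs is near the planted value", {
  sim <- simulate_counts(sim_params(seed = 6))
  x <- sim$counts
  cpm <- t(t(x$counts) / colSums(x$counts)) * 1e6
  g <- x$meta$group
  emp_lfc <- function(ids, grp) {
    log2(rowMeans(cpm[ids, g == grp, drop = FALSE]) /
           rowMeans(cpm[ids, g == "HealthCtl", drop = FALSE]))
  }
  expect_true(all(abs(emp_lfc(sim$truth$rrms_up_ids, "RRMS") - 2) < 0.5))
  expect_true(all(abs(emp_lfc(sim$truth$cis_down_ids, "CIS") + 2) < 0.5))
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_params(dispersion = 0), "dispersion")
  expect_error(sim_params(group_sizes = c(A = 1, B = 5)), "> 1 subject")
  expect_error(sim_params(baseline_logmean_range = c(-2, -5)), "increasing")
})

test_that("outlier injection changes only the designated subjects", {
  sim <- simulate_counts(sim_params(n_mirnas = 400, seed = 8))
  inj <- inject_outlier_subjects(sim$counts, 3, 0.9, seed = 77)
  victims <- inj$truth$outlier_subject_ids
  expect_length(victims, 3)
  intact <- setdiff(colnames(sim$counts$counts), victims)
  expect_identical(inj$counts$counts[, intact], sim$counts$counts[, intact])
  expect_false(identical(inj$counts$counts[, victims],
                         sim$counts$counts[, victims]))
  # n_outliers = 0 is the identity
  id0 <- inject_outlier_subjects(sim$counts, 0, 1, seed = 1)
  expect_identical(id0$counts$counts, sim$counts$counts)
  expect_error(inject_outlier_subjects(sim$counts, 3, 1.5), "severity")
})

test_that("severity-1 victims lose profile correlation, intact subjects keep it", {
  sim <- simulate_counts(sim_params(seed = 15))
  inj <- inject_outlier_subjects(sim$counts, 2, 1, groups = "HospCtl",
                                 seed = 42)
  rho <- suppressWarnings(subject_homogeneity(inj$counts))
  victims <- inj$truth$outlier_subject_ids
  hosp <- inj$counts$meta$sample_id[inj$counts$meta$group == "HospCtl"]
  expect_true(all(rho[victims] < 0.5))
  expect_true(all(rho[setdiff(hosp, victims)] >= 0.75))
  other <- setdiff(names(rho), hosp)
  expect_true(all(rho[other] >= 0.9))
})

test_that("matched CSF simulation honours its exact identities", {
  sim <- simulate_counts(sim_params(n_mirnas = 300, seed = 5))
  rrms <- subset_samples(sim$counts,
                         sim$counts$meta$sample_id[sim$counts$meta$group == "RRMS"])
  sv <- rrms$counts + 0.5
  # offset 0, noise 0: CSF mean profile equals serum mean profile exactly
  id <- simulate_matched_csf(sv, offset_log10 = 0, noise_sd = 0, seed = 1)
  expect_equal(rowMeans(id$csf), rowMeans(sv), tolerance = 1e-12)
  # offset 2, noise 0: high-serum miRNAs sit exactly 2 decades below
  off <- simulate_matched_csf(sv, offset_log10 = 2, noise_sd = 0, seed = 2)
  d <- log10(rowMeans(sv)) - log10(rowMeans(off$csf))
  hi <- off$truth$population == "high_serum"
  expect_equal(unname(d[hi]), rep(2, sum(hi)), tolerance = 1e-9)
  expect_equal(unname(d[!hi]), rep(0, sum(!hi)), tolerance = 1e-9)
  # serum input is never modified (conservation)
  expect_identical(sv, rrms$counts + 0.5)
  expect_error(simulate_matched_csf(sv, high_serum_fraction = 1.2),
               "high_serum_fraction")
})

test_that("qPCR simulation: noise-free triplicates and rank anticorrelation", {
  x <- nb_fixture(n_mirnas = 30, n_a = 8, n_b = 8, seed = 11)
  qp <- simulate_qpcr(x, c("miR-0001", "miR-0002"), replicate_sd = 0,
                      outlier_rate = 0, seed = 3)
  sp <- split(qp$plate$cq, paste(qp$plate$sample, qp$plate$assay))
  tri <- sp[vapply(sp, length, 1L) == 3]
  expect_true(all(vapply(tri, function(v) diff(range(v)) == 0, TRUE)))
  # slope 1, noise off: Delta Cq perfectly rank-anticorrelated with counts
  dcq <- delta_cq(qp$plate)
  cpm <- t(t(x$counts) / colSums(x$counts)) * 1e6
  for (a in c("miR-0001", "miR-0002")) {
    sub <- dcq[dcq$target == a, ]
    rho <- cor(sub$delta_cq, cpm[a, sub$sample], method = "spearman")
    expect_equal(rho, -1)
  }
  expect_error(simulate_qpcr(x, character(0)), "non-empty")
})

test_that("qPCR displaced-replicate rate matches the requested probability", {
  x <- nb_fixture(n_mirnas = 20, n_a = 20, n_b = 20, seed = 12)
  qp <- simulate_qpcr(x, rownames(x$counts)[1:5], outlier_rate = 0.1,
                      seed = 31)
  n_rep <- 40 * 5 * 3
  n_out <- nrow(qp$truth)
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.1)
  expect_gte(n_out, ci[1])
  expect_lte(n_out, ci[2])
})
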