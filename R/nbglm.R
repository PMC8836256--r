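# Vectorized negative-binomial GLM machinery shared by the dispersion
# estimator and the differential-expression tests.  All fits use a log
# link with the effective library size as offset, so the fitted
# coefficient is a log relative abundance; the NB variance is
# mu + phi * mu^2.

# Fit one mean parameter per miRNA for a block of samples.
# Y: G x n counts, N: length-n effective library sizes, phi: scalar or
# length-G.  Returns log-abundance b (exp(b) * N_j = mu_ij); -Inf for
# all-zero rows.  Newton-Raphson on the score, vectorized over rows.
.nb_fit_block <- function(Y, N, phi, max_iter = 50L, tol = 1e-10) {
  G <- nrow(Y)
  phi <- rep_len(phi, G)
  rs <- rowSums(Y)
  b <- ifelse(rs > 0, log(rs / sum(N)), -Inf)
  active <- which(rs > 0)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    mu <- exp(b[active]) %o% N
    denom <- 1 + phi[active] * mu
    S <- rowSums((Y[active, , drop = FALSE] - mu) / denom)
    I <- rowSums(mu / denom)
    step <- S / pmax(I, 1e-12)
    step <- pmax(pmin(step, 3), -3)
    b[active] <- b[active] + step
    active <- active[abs(step) > tol]
  }
  b
}

# Row log-likelihoods given fitted log-abundances.
.nb_loglik_rows <- function(Y, b, N, phi) {
  G <- nrow(Y)
  phi <- rep_len(phi, G)
  mu <- exp(b) %o% N
  mu[mu == 0] <- 1e-300
  ll <- matrix(stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE),
               nrow = G)
  rowSums(ll)
}

# Row residual deviances: 2 * (saturated - fitted log-likelihood).
.nb_dev_rows <- function(Y, b, N, phi) {
  G <- nrow(Y)
  phi <- rep_len(phi, G)
  mu <- exp(b) %o% N
  mu[mu == 0] <- 1e-300
  mu_sat <- pmax(Y, 1e-300)
  ll_sat <- matrix(stats::dnbinom(Y, size = 1 / phi, mu = mu_sat, log = TRUE),
                   nrow = G)
  ll_fit <- matrix(stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE),
                   nrow = G)
  pmax(2 * rowSums(ll_sat - ll_fit), 0)
}

# Cox-Reid adjusted profile log-likelihood per row for a grouped design:
# sum over groups of (loglik - 0.5 * log Fisher information).
.nb_apl_rows <- function(Y, group_idx, N, phi) {
  G <- nrow(Y)
  apl <- numeric(G)
  for (idx in group_idx) {
    Yg <- Y[, idx, drop = FALSE]
    Ng <- N[idx]
    b <- .nb_fit_block(Yg, Ng, phi)
    apl <- apl + .nb_loglik_rows(Yg, b, Ng, phi)
    mu <- exp(b) %o% Ng
    info <- rowSums(mu / (1 + phi * mu))
    pos <- info > 0
    apl[pos] <- apl[pos] - 0.5 * log(info[pos])
  }
  apl
}

# Quadratic interpolation of the maximum over a log-spaced grid.
.grid_peak <- function(logx, y) {
  k <- which.max(y)
  if (k == 1 || k == length(y)) return(exp(logx[k]))
  x3 <- logx[(k - 1):(k + 1)]
  y3 <- y[(k - 1):(k + 1)]
  d1 <- (y3[3] - y3[1]) / (x3[3] - x3[1])
  d2 <- (y3[3] - 2 * y3[2] + y3[1]) / ((x3[2] - x3[1])^2)
  if (d2 >= 0) return(exp(x3[2]))
  exp(x3[2] - d1 / d2 / 2)
}

#' Estimate negative-binomial dispersion
#'
#' Common dispersion by maximizing the Cox-Reid adjusted profile
#' likelihood (summed over miRNAs) on a log-spaced grid with quadratic
#' refinement; per-miRNA dispersions by weighted-likelihood shrinkage
#' toward the common profile (each miRNA's adjusted profile likelihood
#' plus `prior_n` times the average profile, maximized on the grid).
#' All-zero miRNAs are excluded from estimation (with a warning) and
#' receive the common value.
#'
#' @param counts an [ev_counts] object or count matrix.
#' @param groups per-sample group labels (defaults to metadata groups).
#' @param eff_lib effective library sizes (library size x TMM factor);
#'   plain library sizes when `NULL`.
#' @param grid dispersion grid searched (log-spaced).
#' @param prior_n prior weight, in units of miRNA-equivalents, pulling
#'   per-miRNA estimates toward the common value.
#' @return list with `common` (scalar), `tagwise` (named vector aligned
#'   to rows) and `grid`.
#' @export
estimate_dispersion <- function(counts, groups = NULL, eff_lib = NULL,
                                grid = 10^seq(-4, 0.8, length.out = 19),
                                prior_n = 10) {
  m <- if (inherits(counts, "ev_counts")) counts$counts else as.matrix(counts)
  if (is.null(groups)) {
    if (!inherits(counts, "ev_counts"))
      stopf("groups required when counts is a bare matrix")
    groups <- counts$meta$group
  }
  if (length(groups) != ncol(m)) stopf("groups must align with samples")
  if (any(table(groups) < 2)) stopf("every group needs >= 2 samples")
  if (is.null(eff_lib)) eff_lib <- colSums(m)
  nz <- rowSums(m) > 0
  if (!all(nz)) warnf("%d all-zero miRNAs excluded from dispersion estimation",
                      sum(!nz))
  Y <- m[nz, , drop = FALSE]
  group_idx <- split(seq_len(ncol(m)), groups)
  apl <- vapply(grid, function(phi) .nb_apl_rows(Y, group_idx, eff_lib, phi),
                numeric(nrow(Y)))
  if (nrow(Y) == 1L) apl <- matrix(apl, nrow = 1)
  total <- colSums(apl)
  common <- .grid_peak(log(grid), total)
  shrunk_score <- apl + matrix(rep(total / nrow(Y) * prior_n, each = nrow(Y)),
                               nrow = nrow(Y))
  tag_nz <- grid[max.col(shrunk_score, ties.method = "first")]
  tagwise <- setNames(rep(common, nrow(m)), rownames(m))
  tagwise[nz] <- tag_nz
  list(common = common, tagwise = tagwise, grid = grid)
}

# Exact conditional two-group NB test on library-equalized counts.
# sA, sB: group sums of pseudo-counts; nA, nB: group sizes; phi: per-row
# dispersion.  Returns two-sided p by the double-tail rule: the summed
# probability of outcomes no more likely than the observed split.
.exact_nb_p <- function(sA, sB, nA, nB, phi) {
  G <- length(sA)
  p <- rep(1, G)
  for (i in seq_len(G)) {
    t_i <- sA[i] + sB[i]
    if (t_i == 0) next
    mu <- t_i / (nA + nB)          # common per-sample mean
    size_a <- nA / phi[i]
    size_b <- nB / phi[i]
    a0 <- t_i * nA / (nA + nB)
    va <- nA * mu * (1 + phi[i] * mu)
    vb <- nB * mu * (1 + phi[i] * mu)
    vc <- va * vb / (va + vb)
    hw <- 25 * sqrt(vc) + 50
    lo <- max(0, floor(min(sA[i], a0 - hw)))
    hi <- min(t_i, ceiling(max(sA[i], a0 + hw)))
    a <- lo:hi
    f <- stats::dnbinom(a, size = size_a, mu = nA * mu) *
      stats::dnbinom(t_i - a, size = size_b, mu = nB * mu)
    tot <- sum(f)
    if (tot <= 0) next
    f_obs <- f[sA[i] - lo + 1]
    p[i] <- min(1, sum(f[f <= f_obs * (1 + 1e-10)]) / tot)
  }
  p
}
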