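# small simulated cohort of unrelated animals for LMM tests
sim_cohort <- function(n, m, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.5)
  G <- sapply(maf, function(p) rbinom(n, 2, p))
  rownames(G) <- sprintf("A%04d", seq_len(n))
  colnames(G) <- sprintf("s%04d", seq_len(m))
  map <- data.frame(chrom = 1L, snp_id = colnames(G),
                    pos_bp = seq_len(m) * 1e4, stringsAsFactors = FALSE)
  genotype_table(map, G)
}

test_that("phenotype construction averages meioses and counts weights", {
  regions <- data.frame(
    meiosis_id = c(rep("O1:P", 24), rep("O2:P", 26), rep("O3:M", 20)),
    parent_id = c(rep("S1", 50), rep("D1", 20)),
    parent_sex = c(rep("M", 50), rep("F", 20)),
    chrom = 1L, left_idx = 1L, right_idx = 2L,
    left_pos = 100, right_pos = 200, n_intervals = 1L)
  calls <- manual_calls(regions)
  meta <- attr(calls, "meioses")
  meta$parent_sex <- c("M", "M", "F")
  attr(calls, "meioses") <- meta
  ph <- build_phenotypes(calls, kind = "rate")
  s1 <- ph[ph$animal_id == "S1", ]
  expect_equal(s1$y, 25)
  expect_equal(s1$w, 2)
  expect_equal(ph$y[ph$animal_id == "D1"], 20)
})

test_that("subtelomeric phenotypes count only the terminal 15 percent", {
  lens <- c(`1` = 1e6)
  mk <- function(mid_rel) {
    data.frame(meiosis_id = "O1:P", parent_id = "S1", parent_sex = "M",
               chrom = 1L, left_idx = 1L, right_idx = 2L,
               left_pos = mid_rel * 1e6 - 50, right_pos = mid_rel * 1e6 + 50,
               n_intervals = 1L)
  }
  ph90 <- build_phenotypes(manual_calls(mk(0.90)), kind = "subtelomeric",
                           chrom_lengths = lens)
  ph80 <- build_phenotypes(manual_calls(mk(0.80)), kind = "subtelomeric",
                           chrom_lengths = lens)
  expect_equal(ph90$y, 1)
  expect_equal(ph80$y, 0)
})

test_that("chip-corrected counts feed the rate phenotype", {
  regions <- data.frame(
    meiosis_id = c(rep("O1:P", 10), rep("O2:P", 20)),
    parent_id = "S1", parent_sex = "M", chrom = 1L,
    left_idx = 1L, right_idx = 2L, left_pos = 100, right_pos = 200,
    n_intervals = 1L)
  calls <- manual_calls(regions)
  counts <- data.frame(meiosis_id = c("O1:P", "O2:P"), parent_id = "S1",
                       sex = "M", category = c("3K", "50K"), count = c(10, 20))
  cc <- chip_correct(counts, "50K")
  ph <- build_phenotypes(calls, kind = "rate", corrections = cc)
  expect_equal(ph$y, 20)  # the 3K meiosis is scaled up to the reference mean
})

test_that("SNP filtering drops low MAF, duplicates and high-LD pairs", {
  set.seed(301)
  gt <- sim_cohort(300, 5)
  G <- gt$geno
  G[, 2] <- G[, 1]                          # exact duplicate (r = 1)
  G[, 4] <- G[, 3]
  flip <- sample(300, 4)                    # near-duplicate, r ~ 0.99
  G[flip, 4] <- pmin(2, G[flip, 4] + 1L)
  G[, 5] <- rbinom(300, 2, 0.0005)          # tiny MAF
  gt$geno <- G
  kept <- filter_snps(gt, maf_min = 0.001, r_max = 0.95)
  expect_setequal(kept, c("s0001", "s0003"))
  dropped <- attr(kept, "dropped")
  expect_equal(sort(dropped$reason), c("ld", "ld", "maf"))
})

test_that("the GRM has VanRaden structure", {
  gt <- sim_cohort(120, 400, seed = 31)
  A <- grm(gt)
  expect_true(isSymmetric(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # unrelated founders: near-zero mean relationship off-diagonal
  off <- A[upper.tri(A)]
  expect_lt(abs(mean(off)), 0.02)
  # clones: off-diagonal equals the diagonal
  G2 <- gt$geno[c(1, 1, 2:40), ]
  rownames(G2) <- sprintf("B%02d", seq_len(nrow(G2)))
  A2 <- grm(G2)
  expect_equal(A2[1, 2], A2[1, 1] - 1e-8, tolerance = 1e-10)
  # monomorphic SNPs are an error
  gt$geno[, 1] <- 0L
  expect_error(grm(gt), "monomorphic")
})

test_that("REML recovers iid variance partitions and boundaries", {
  set.seed(311)
  n <- 400
  ids <- sprintf("A%04d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  # pure noise, A = I, w = 1: V = (sigma_a2 + sigma_e2) I, so only the sum is
  # identified and it must match the sample variance
  y <- rnorm(n, 10, 2)
  ph <- data.frame(animal_id = ids, y = y, w = 1)
  fit <- fit_null(ph, A)
  expect_equal(fit$sigma_a2 + fit$sigma_e2, var(y), tolerance = 0.05)

  # data generated with no genetic variance and weighted residuals: the
  # genetic component hits the boundary
  w <- sample(1:10, n, replace = TRUE)
  y <- rnorm(n, 10, sqrt(4 / w))
  fitb <- fit_null(data.frame(animal_id = ids, y = y, w = w), A)
  expect_lt(fitb$sigma_a2, 0.2 * fitb$sigma_e2)
  expect_equal(fitb$sigma_e2, 4, tolerance = 0.6)

  # doubling all weights doubles the fitted residual variance (R = diag(1/w)
  # shrinks by half, so sigma_e2 must double to fit the same data)
  ph1 <- data.frame(animal_id = ids, y = y, w = w)
  ph2 <- data.frame(animal_id = ids, y = y, w = 2 * w)
  f1 <- fit_null(ph1, A)
  f2 <- fit_null(ph2, A)
  expect_equal(f2$sigma_e2 / f1$sigma_e2, 2, tolerance = 0.05)
})

test_that("REML recovers a planted heritable component", {
  set.seed(321)
  gt <- sim_cohort(500, 600, seed = 32)
  A <- grm(gt)
  L <- t(chol(A + diag(1e-6, 500)))
  a <- L %*% rnorm(500) * sqrt(2)
  w <- sample(1:8, 500, replace = TRUE)
  y <- 5 + a + rnorm(500, 0, sqrt(1 / w))
  ph <- data.frame(animal_id = rownames(A), y = as.numeric(y), w = w)
  fit <- fit_null(ph, A)
  expect_gt(fit$sigma_a2, 0.8)
  expect_lt(abs(fit$sigma_e2 - 1), 0.5)
})

test_that("with equal weights and A = I the scan is exactly ordinary regression", {
  set.seed(331)
  n <- 200
  gt <- sim_cohort(n, 50, seed = 33)
  ids <- rownames(gt$geno)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  y <- rnorm(n) + 0.4 * gt$geno[, 7]
  ph <- data.frame(animal_id = ids, y = y, w = 1)
  fit <- fit_null(ph, A)
  sc <- lmm_scan(fit, gt)
  for (j in c(1, 7, 20)) {
    ols <- summary(lm(y ~ gt$geno[, j]))$coefficients
    expect_equal(sc$beta[j], ols[2, 1], tolerance = 1e-8)
    expect_equal(sc$se[j], ols[2, 2], tolerance = 1e-8)
    expect_equal(sc$p[j], ols[2, 4], tolerance = 1e-8)
  }
})

test_that("a planted QTL is recovered and conditioning removes it", {
  set.seed(341)
  n <- 500
  gt <- sim_cohort(n, 80, seed = 34)
  ids <- rownames(gt$geno)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  beta_true <- 0.5
  qtl <- "s0040"
  y <- 2 + beta_true * gt$geno[, qtl] + rnorm(n)
  ph <- data.frame(animal_id = ids, y = y, w = 1)
  fit <- fit_null(ph, A)
  sc <- lmm_scan(fit, gt)
  row <- sc[sc$snp_id == qtl, ]
  expect_lt(abs(row$beta - beta_true), 2 * row$se)
  expect_lt(row$p, 1e-10)
  # conditional analysis on the causal SNP: nothing else is associated
  sc2 <- lmm_scan(fit, gt, condition_snps = qtl)
  expect_gt(min(sc2$p, na.rm = TRUE), 1e-4)
  # joint analysis returns the same effect for the causal SNP
  j <- lmm_joint(fit, gt, c(qtl, "s0010"))
  expect_lt(abs(j$beta[1] - beta_true), 2 * j$se[1])
})

test_that("weighted records equal expanded unit records for fixed effects", {
  set.seed(351)
  n <- 60
  x <- rnorm(n)
  w <- sample(1:5, n, replace = TRUE)
  ybar <- 1 + 2 * x + rnorm(n, 0, sqrt(1 / w))
  # weighted fit on animal means
  fw <- lm(ybar ~ x, weights = w)
  # equivalent expanded data: w unit records per animal averaging ybar
  xe <- rep(x, w)
  ye <- unlist(mapply(function(m, k) m + (seq_len(k) - mean(seq_len(k))) * 0.3,
                      ybar, w))
  fe <- lm(ye ~ xe)
  expect_equal(unname(coef(fw)), unname(coef(fe)), tolerance = 1e-10)
})

test_that("type-I error is calibrated at alpha = 1e-3 on a null scan", {
  set.seed(361)
  n <- 400
  gt <- sim_cohort(n, 800, seed = 36)
  ids <- rownames(gt$geno)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  w <- sample(1:6, n, replace = TRUE)
  y <- rnorm(n, 0, sqrt(1 / w))
  ph <- data.frame(animal_id = ids, y = y, w = w)
  fit <- fit_null(ph, A)
  sc <- lmm_scan(fit, gt)
  hits <- sum(sc$p < 1e-3)
  expect_lte(hits, qbinom(0.999, 800, 1e-3))
})
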