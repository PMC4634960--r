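# A small SNP map with I+1 SNPs (I intervals) on one chromosome.
grid_map <- function(I, spacing = 1000) {
  data.frame(chrom = 1L, snp_id = paste0("s", seq_len(I + 1)),
             pos_bp = seq_len(I + 1) * spacing)
}

# Build a meiosis_calls object from within-chromosome interval ranges
# (left interval .. right interval), one region per row.
range_calls <- function(l_int, r_int, map) {
  regions <- data.frame(
    meiosis_id = sprintf("O%03d:P", seq_along(l_int)),
    parent_id = sprintf("S%03d", seq_along(l_int)), parent_sex = "M",
    chrom = 1L, left_idx = l_int, right_idx = r_int + 1L,
    left_pos = map$pos_bp[l_int], right_pos = map$pos_bp[r_int + 1L],
    n_intervals = r_int - l_int + 1L)
  manual_calls(regions)
}

test_that("single-interval regions give closed-form rates", {
  map <- grid_map(4)
  calls <- range_calls(c(2L, 2L, 3L), c(2L, 2L, 3L), map)
  fit <- em_fit(calls, n_meioses = 10, map)
  expect_equal(fit$rate, c(0, 2 / 10, 1 / 10, 0))
  expect_true(attr(fit, "converged"))

  # n = 4, two crossovers both exactly in interval 3
  calls2 <- range_calls(c(3L, 3L), c(3L, 3L), map)
  fit2 <- em_fit(calls2, 4, map)
  expect_equal(fit2$rate, c(0, 0, 0.5, 0))
})

test_that("overlapping regions resolve to the hand-derived fixed point", {
  # regions {2,3} and {2} with n = 2: all mass concentrates in interval 2
  map <- grid_map(4)
  calls <- range_calls(c(2L, 2L), c(3L, 2L), map)
  fit <- em_fit(calls, 2, map)
  expect_equal(fit$rate[2], 1.0, tolerance = 1e-6)
  expect_equal(fit$rate[3], 0.0, tolerance = 1e-6)
  expect_error(em_fit(range_calls(2L, 1L, map), 2, map), "zero intervals")
})

test_that("EM equals the brute-force multinomial MLE on identifiable instances", {
  set.seed(101)
  for (rep in 1:25) {
    I <- sample(2:4, 1)
    map <- grid_map(I)
    # identifiable instances: one singleton region per covered interval plus
    # random wider regions, at most 6 regions total
    l <- seq_len(I)
    r <- seq_len(I)
    extra <- sample(0:(6 - I), 1)
    for (k in seq_len(extra)) {
      a <- sample(seq_len(I), 1); b <- sample(seq_len(I), 1)
      l <- c(l, min(a, b)); r <- c(r, max(a, b))
    }
    n <- length(l) + sample(0:4, 1)
    fit <- em_fit(range_calls(as.integer(l), as.integer(r), map), n, map,
                  tol = 1e-12, max_iter = 10000)
    ora <- oracle_em_mle(l, r, I, n)
    expect_lt(max(abs(fit$rate - ora$p)), 1e-4)
    expect_lt(abs(region_loglik(fit$rate, l, r) - ora$loglik), 1e-4)
  }
})

test_that("EM reaches at least the grid-search likelihood on random instances", {
  set.seed(111)
  for (rep in 1:15) {
    I <- sample(2:4, 1)
    map <- grid_map(I)
    nreg <- sample(1:6, 1)
    a <- sample(seq_len(I), nreg, replace = TRUE)
    b <- sample(seq_len(I), nreg, replace = TRUE)
    l <- pmin(a, b); r <- pmax(a, b)
    n <- nreg + 2
    fit <- em_fit(range_calls(as.integer(l), as.integer(r), map), n, map,
                  tol = 1e-12, max_iter = 10000)
    ora <- oracle_em_mle(l, r, I, n)
    expect_gte(region_loglik(fit$rate, l, r), ora$loglik - 1e-6)
  }
})

test_that("EM conserves mass and increases the likelihood at every iteration", {
  set.seed(121)
  for (rep in 1:50) {
    I <- sample(3:12, 1)
    map <- grid_map(I)
    nreg <- sample(2:20, 1)
    a <- sample(seq_len(I), nreg, replace = TRUE)
    b <- pmin(I, a + sample(0:3, nreg, replace = TRUE))
    n <- nreg + sample(1:10, 1)
    fit <- em_fit(range_calls(as.integer(a), as.integer(b), map), n, map,
                  max_iter = 20000, keep_trace = TRUE)
    tr <- attr(fit, "trace")
    expect_true(all(abs(tr$total_mass - nreg) < 1e-9))
    expect_true(all(diff(tr$loglik) > -1e-10))
    expect_equal(sum(fit$rate) * n, nreg, tolerance = 1e-9)
    expect_true(all(fit$rate >= 0))
  }
})

test_that("chip correction equalizes category means", {
  counts <- data.frame(
    meiosis_id = sprintf("m%02d", 1:6),
    parent_id = sprintf("p%02d", 1:6),
    sex = "M",
    category = rep(c("50K", "low", "mid"), each = 2),
    count = c(20, 31.8, 15, 20.4, 8, 12))
  cc <- chip_correct(counts, reference = "50K")
  f <- cc$factors
  expect_equal(f$factor[f$category == "50K"], 1)
  got <- tapply(cc$counts$count_corrected, cc$counts$category, mean)
  expect_true(all(abs(got - mean(c(20, 31.8))) < 1e-12))
  # the published-scale example: category mean 17.7 vs reference mean 25.9
  counts2 <- data.frame(meiosis_id = c("a", "b"), parent_id = c("x", "y"),
                        sex = "M", category = c("50K", "3K"),
                        count = c(25.9, 17.7))
  f2 <- chip_correct(counts2, "50K")$factors
  expect_equal(f2$factor[f2$category == "3K"], 25.9 / 17.7, tolerance = 1e-12)
  expect_error(chip_correct(counts2[counts2$category != "50K", ], "50K"),
               "reference category is empty")
})

test_that("Haldane adjustment lengthens maps, strictly when any rate > 0", {
  map <- grid_map(4)
  calls <- range_calls(c(2L, 3L), c(2L, 3L), map)
  fit <- em_fit(calls, 4, map)
  hl <- haldane_length(fit)
  expect_gt(hl$total_haldane, hl$total_raw)
  # c = 0.25 -> d = -0.5 log(0.5) ~ 0.3466
  fit2 <- em_fit(range_calls(2L, 2L, map), 4, map)
  d <- haldane_length(fit2)
  expect_equal(d$total_haldane - (-0.5 * log(1 - 2 * 0.25)), 0, tolerance = 1e-12)
  # zero map: equality
  empty <- manual_calls(as.data.frame(range_calls(2L, 2L, map))[0, ])
  h0 <- haldane_length(em_fit(empty, 4, map))
  expect_equal(h0$total_haldane, h0$total_raw)
  # rates at or above 0.5 are rejected by name
  fit3 <- em_fit(range_calls(c(2L, 2L), c(2L, 2L), map), 4, map)
  fit3$rate[2] <- 0.5
  expect_error(haldane_length(fit3), "interval")
})

test_that("map summaries report totals, kb/cM and between-sex correlation", {
  map <- grid_map(4)
  calls <- range_calls(c(1L, 2L, 3L), c(1L, 2L, 3L), map)
  m <- em_fit(calls, 10, map, sex = "M")
  s <- map_summary(m, m)
  expect_equal(s$rate_correlation, 1.0)
  # a 2,516 Mb span carrying 25.5 Morgans corresponds to ~986 kb/cM
  expect_equal(2.516e9 / 1000 / (100 * 25.5), 986.7, tolerance = 1e-3)
  expect_equal(s$genome$male_kb_per_cM,
               sum(map$pos_bp[-1] - map$pos_bp[-5]) / 1000 / (100 * sum(m$rate)))
  f <- em_fit(range_calls(c(1L, 4L), c(1L, 4L), map), 10, map, sex = "F")
  s2 <- map_summary(m, f)
  expect_lt(s2$rate_correlation, 1)
  bad <- f[-1, ]
  expect_error(map_summary(m, bad), "grid")
})

test_that("EM recovers a simulated truth map as meioses accumulate", {
  set.seed(131)
  pos <- sort(sample.int(5e7, 400))
  gmap <- genetic_map(5e7, 1.2)
  truth <- truth_interval_rates(gmap, pos)
  snp_map <- data.frame(chrom = 1L, snp_id = paste0("s", seq_along(pos)),
                        pos_bp = pos)
  rmse <- vapply(c(500, 5000), function(n) {
    sim <- simulate_crossover_regions(pos, gmap, n, info_rate = 0.5, seed = n)
    fit <- em_fit(sim$calls, n, snp_map)
    sqrt(mean((fit$rate - truth)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
  sim <- simulate_crossover_regions(pos, gmap, 5000, info_rate = 0.5, seed = 5)
  fit <- em_fit(sim$calls, 5000, snp_map)
  expect_gt(cor(fit$rate, truth), 0.9)
})
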