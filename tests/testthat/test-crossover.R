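test_that("origin assignment follows informativeness rules", {
  # parent het with known phase, transmitted allele identifies the haplotype
  expect_identical(grandparental_origin(1L, 0L, 1L), 2L)
  expect_identical(grandparental_origin(1L, 1L, 0L), 1L)
  expect_identical(grandparental_origin(0L, 0L, 1L), 1L)
  # parent homozygous or unphased: uninformative
  expect_true(is.na(grandparental_origin(1L, 1L, 1L)))
  expect_true(is.na(grandparental_origin(1L, NA, 0L)))
  expect_true(is.na(grandparental_origin(NA, 0L, 1L)))
})

test_that("origin sequences on error-free simulations match truth segments", {
  cfg <- tiny_config(n_snps = 1000, seed = 51)
  sim <- simulate_pedigree(cfg, 30, keep_haplotypes = TRUE)
  fams <- extract_families(sim$pedigree, rownames(sim$genotypes$geno))
  ph <- phase_families(sim$genotypes, fams)
  origin <- grandparental_origin(ph$paternal$transmitted,
                                 ph$paternal$parent_pat,
                                 ph$paternal$parent_mat)
  pos <- sim$genotypes$map$pos_bp
  tr <- sim$truth$crossovers
  h <- sim$truth$haplotypes
  for (i in seq_len(nrow(fams))) {
    xo <- tr$pos_bp[tr$meiosis_id == paste0(fams$offspring[i], ":P")]
    # true origin parity along the chromosome for this paternal meiosis:
    # the transmitted allele comes from sire hap1 (grandsire) on even
    # segments iff it matches; compare allele-wise instead of parity to stay
    # independent of the simulator's internal starting-haplotype convention
    sire <- fams$sire[i]
    o <- origin[i, ]
    inf <- which(!is.na(o))
    trans <- ph$paternal$transmitted[i, inf]
    from_h1 <- h$h1[sire, inf] == trans
    expect_identical(unname(o[inf] == 1L), unname(from_h1))
    if (length(xo) == 0 && length(inf) > 1) expect_equal(length(unique(o[inf])), 1)
  }
})

test_that("minimum-support calling matches the spec examples", {
  pos <- 1:12 * 100
  o <- function(s) {
    x <- rep(NA_integer_, 12)
    v <- utils::head(as.integer(strsplit(s, "")[[1]]), 12)
    x[seq_along(v)] <- ifelse(v == 0, NA_integer_, v)
    x
  }
  # 4+4 informative: one region between SNP 4 and 5
  r <- call_crossovers(o("11112222"), pos)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$left_idx, r$right_idx, r$n_intervals), c(4, 5, 1))
  # singleton discordance: no calls
  expect_equal(nrow(call_crossovers(o("111121111"), pos)), 0)
  # run of two: no calls at min_support 3, two calls at 2
  expect_equal(nrow(call_crossovers(o("1111221111"), pos)), 0)
  expect_equal(nrow(call_crossovers(o("1111221111"), pos, min_support = 2)), 2)
  expect_error(call_crossovers(o("1111"), pos, min_support = 0), "min_support")
})

test_that("calling agrees with the naive oracle over enumerated origin strings", {
  pos <- seq_len(9) * 1000
  alphabet <- c(1L, 2L, NA)
  # exhaustive over all strings of length 7 (informative/uninformative mix)
  grid <- do.call(expand.grid, rep(list(alphabet), 7))
  for (ms in c(2, 3)) {
    for (i in seq_len(nrow(grid))) {
      ovec <- c(unlist(grid[i, ], use.names = FALSE), NA, NA)
      got <- call_crossovers(ovec, pos, min_support = ms)
      ora <- oracle_call_crossovers(ovec, pos, min_support = ms)
      if (!isTRUE(all.equal(got, ora, check.attributes = FALSE)))
        fail(sprintf("mismatch at %s (ms=%d)",
                     paste(ovec, collapse = ","), ms))
    }
  }
  succeed()
  # random longer strings
  set.seed(61)
  for (rep in 1:300) {
    ovec <- sample(alphabet, 12, replace = TRUE)
    expect_equal(call_crossovers(ovec, pos <- seq_len(12) * 10, min_support = 3),
                 oracle_call_crossovers(ovec, pos, 3), ignore_attr = TRUE)
  }
})

test_that("raising min_support never increases the call count", {
  set.seed(71)
  pos <- seq_len(40) * 500
  for (rep in 1:200) {
    ovec <- sample(c(1L, 2L, NA), 40, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    n3 <- nrow(call_crossovers(ovec, pos, 3))
    n5 <- nrow(call_crossovers(ovec, pos, 5))
    expect_lte(n5, n3)
  }
})

test_that("calls are invariant to relabeling the parent haplotypes", {
  set.seed(81)
  pos <- seq_len(30) * 100
  for (rep in 1:50) {
    ovec <- sample(c(1L, 2L, NA), 30, replace = TRUE)
    swapped <- ifelse(is.na(ovec), NA_integer_, 3L - ovec)
    expect_equal(call_crossovers(ovec, pos), call_crossovers(swapped, pos))
  }
})

test_that("the adjacent-support reading is stricter", {
  pos <- seq_len(9) * 100
  # three informative same-origin SNPs interrupted by uninformative gaps
  ovec <- c(1L, NA, 1L, NA, 1L, 2L, 2L, 2L, NA)
  expect_equal(nrow(call_crossovers(ovec, pos, 3)), 1)
  expect_equal(nrow(call_crossovers(ovec, pos, 3, require_adjacent = TRUE)), 0)
})

test_that("detection power scores overlaps correctly", {
  regions <- data.frame(meiosis_id = "O1:P", parent_id = "S1", parent_sex = "M",
                        chrom = 1L, left_idx = 4L, right_idx = 6L,
                        left_pos = 400, right_pos = 600, n_intervals = 2L)
  calls <- manual_calls(regions)
  truth <- data.frame(meiosis_id = "O1:P", chrom = 1, pos_bp = 450)
  expect_equal(detection_power(calls, truth)$power, 1.0)
  truth5 <- data.frame(meiosis_id = rep("O1:P", 5), chrom = 1,
                       pos_bp = c(100, 200, 700, 800, 900))
  expect_equal(detection_power(calls, truth5)$power, 0.0)
  empty <- manual_calls(regions[0, ],
                        meioses = attr(calls, "meioses"))
  expect_equal(detection_power(empty, truth5)$power, 0.0)
  expect_error(detection_power(calls, truth[0, ]), "no true crossovers")
})

test_that("error-free simulations yield no false positives and bounded calls", {
  cfg <- tiny_config(n_snps = 1500, total_male_morgans = 1.5,
                     total_female_morgans = 1.2, seed = 91)
  sim <- simulate_pedigree(cfg, 60)
  fams <- extract_families(sim$pedigree, rownames(sim$genotypes$geno))
  ph <- phase_families(sim$genotypes, fams)
  calls <- call_crossover_set(ph, sim$genotypes$map, sim$genotypes)
  truth <- sim$truth$crossovers
  key_t <- paste(truth$meiosis_id, truth$chrom)
  # every call overlaps a true crossover of its meiosis
  for (j in seq_len(nrow(calls))) {
    xo <- truth$pos_bp[key_t == paste(calls$meiosis_id[j], calls$chrom[j])]
    expect_true(any(xo >= calls$left_pos[j] & xo <= calls$right_pos[j]),
                info = paste("false positive call row", j))
  }
  # per meiosis, called <= true
  n_call <- table(calls$meiosis_id)
  meta <- attr(calls, "meioses")
  evaluated <- truth[truth$meiosis_id %in% meta$meiosis_id, ]
  n_true <- table(evaluated$meiosis_id)
  for (mid in names(n_call))
    expect_lte(n_call[[mid]], n_true[[mid]])
})
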