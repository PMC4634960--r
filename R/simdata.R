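# Synthetic cattle-pedigree simulator: founder haplotypes, meioses with known
# crossover locations, nested chip masks, genotyping error.  Ground truth is
# recorded before masking/error so downstream stages can be scored against it.

#' Default bovine autosome physical lengths
#'
#' Approximate relative physical lengths of the 29 bovine autosomes, scaled so
#' the genome totals \code{total_bp} (default 2,516 Mb, the span covered by a
#' dense autosomal SNP set in cattle).
#'
#' @param total_bp total genome length in bp.
#' @return integer vector of 29 chromosome lengths in bp.
#' @export
cattle_autosome_lengths <- function(total_bp = 2.516e9) {
  rel <- c(158.3, 136.9, 121.4, 120.6, 121.2, 119.5, 112.6, 113.4, 105.7,
           104.3, 107.3, 91.2, 84.2, 84.6, 85.3, 81.7, 75.2, 66.0, 64.1,
           72.0, 71.6, 61.4, 52.5, 62.7, 42.9, 51.7, 45.4, 46.3, 51.5)
  as.integer(round(rel / sum(rel) * total_bp))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate a
#' multi-generation Holstein pedigree genotyped on nested chips: 29 autosomes
#' spanning 2,516 Mb, ~54,000 chip SNPs with MAF drawn Uniform(0.05, 0.5),
#' sex-specific genetic lengths of 25.5 (male) and 23.2 (female) Morgans
#' allocated proportionally to physical length, crossovers from a Poisson
#' process (no interference), and no genotyping error.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_lengths_bp physical lengths; default scaled bovine autosomes.
#' @param n_snps total SNPs, allocated to chromosomes proportionally to
#'   length (at least 2 per chromosome).
#' @param maf_law chip-SNP minor-allele-frequency law:
#'   \code{list(dist = "uniform", min =, max =)} or
#'   \code{list(dist = "point", value =)}.
#' @param total_male_morgans,total_female_morgans genome genetic lengths.
#' @param male_map_morgans,female_map_morgans optional per-chromosome genetic
#'   lengths overriding the proportional allocation.
#' @param interference_nu gamma-renewal shape for crossover interference;
#'   1 = none (Poisson).
#' @param obligate_crossover force at least one crossover per chromosome.
#' @param genotype_error_rate per-call probability that a dosage is flipped to
#'   a uniformly chosen different valid dosage.
#' @param missing_rate per-call missingness probability.
#' @param chip_panels named sizes of nested SNP panels; the largest panel must
#'   equal \code{n_snps}.
#' @param chip_mix named probabilities (over panel names) used to assign a
#'   chip to offspring, parents and grandsires.
#' @param granddam_genotyped_prob probability that a granddam is genotyped;
#'   the default matches an expected 1.14 genotyped granddams per family, the
#'   rate observed in large dairy pedigrees.
#' @param progeny_per_sire families sharing one sire (AI bull structure).
#' @param dams_per_grandsire full-sib dams per maternal grandparent pair.
#' @param hotspot_frac_bp,hotspot_mass if \code{hotspot_frac_bp > 0}, that
#'   fraction of each chromosome's bp (whole SNP intervals) is designated
#'   hotspot and carries \code{hotspot_mass} of the chromosome's genetic
#'   length; otherwise the genetic map is uniform per bp.
#' @param base_year birth year of the founder generation.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 29,
                       chrom_lengths_bp = NULL,
                       n_snps = 54000,
                       maf_law = list(dist = "uniform", min = 0.05, max = 0.5),
                       total_male_morgans = 25.5,
                       total_female_morgans = 23.2,
                       male_map_morgans = NULL,
                       female_map_morgans = NULL,
                       interference_nu = 1,
                       obligate_crossover = FALSE,
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       chip_panels = NULL,
                       chip_mix = c("50K" = 1),
                       granddam_genotyped_prob = 0.5695,
                       progeny_per_sire = 10,
                       dams_per_grandsire = 10,
                       hotspot_frac_bp = 0,
                       hotspot_mass = 0,
                       base_year = 1990,
                       seed = 1L) {
  if (is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- cattle_autosome_lengths()[seq_len(n_chromosomes)]
    if (n_chromosomes > 29)
      abort("default chromosome lengths cover at most 29 autosomes")
  }
  if (length(chrom_lengths_bp) != n_chromosomes)
    abort("chrom_lengths_bp must have one entry per chromosome")
  if (any(chrom_lengths_bp <= 0)) abort("chromosome lengths must be positive")
  share <- chrom_lengths_bp / sum(chrom_lengths_bp)
  if (is.null(male_map_morgans)) male_map_morgans <- total_male_morgans * share
  if (is.null(female_map_morgans)) female_map_morgans <- total_female_morgans * share
  if (any(male_map_morgans < 0) || any(female_map_morgans < 0))
    abort("genetic lengths must be non-negative")
  if (is.null(chip_panels)) {
    chip_panels <- c(`3K` = 3000, `7K` = 7000, `10K` = 10000, `50K` = n_snps)
    chip_panels <- chip_panels[chip_panels <= n_snps]
    chip_panels["50K"] <- n_snps
  }
  chip_panels <- sort(chip_panels)
  if (max(chip_panels) != n_snps)
    abort("largest chip panel must contain all n_snps SNPs")
  if (!all(names(chip_mix) %in% names(chip_panels)))
    abort("chip_mix names must be a subset of chip_panels names")
  if (interference_nu < 1) abort("interference_nu must be >= 1")
  n_alloc <- allocate_snps(n_snps, chrom_lengths_bp)
  cfg <- list(n_chromosomes = n_chromosomes,
              chrom_lengths_bp = as.numeric(chrom_lengths_bp),
              n_snps = n_snps, snps_per_chrom = n_alloc,
              maf_law = maf_law,
              male_map_morgans = as.numeric(male_map_morgans),
              female_map_morgans = as.numeric(female_map_morgans),
              interference_nu = interference_nu,
              obligate_crossover = obligate_crossover,
              genotype_error_rate = genotype_error_rate,
              missing_rate = missing_rate,
              chip_panels = chip_panels,
              chip_mix = chip_mix / sum(chip_mix),
              granddam_genotyped_prob = granddam_genotyped_prob,
              progeny_per_sire = progeny_per_sire,
              dams_per_grandsire = dams_per_grandsire,
              hotspot_frac_bp = hotspot_frac_bp,
              hotspot_mass = hotspot_mass,
              base_year = base_year,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# proportional SNP allocation with largest-remainder rounding, min 2 per chrom
allocate_snps <- function(n_snps, lengths) {
  lengths <- as.numeric(lengths)
  share <- n_snps * lengths / sum(lengths)
  n <- pmax(2L, floor(share))
  rem <- n_snps - sum(n)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    take <- ord[seq_len(min(rem, length(ord)))]
    n[take] <- n[take] + 1L
    rem <- n_snps - sum(n)
    if (rem > 0) n[seq_len(rem)] <- n[seq_len(rem)] + 1L
  }
  if (sum(n) != n_snps && n_snps >= 2 * length(lengths)) {
    # shave overshoot caused by the min-2 floor from the largest chromosomes
    while (sum(n) > n_snps) {
      i <- which.max(n)
      n[i] <- n[i] - 1L
    }
  }
  as.integer(n)
}

draw_maf <- function(law, n) {
  switch(law$dist,
         uniform = stats::runif(n, law$min, law$max),
         point = rep(law$value, n),
         abort("unknown maf_law dist: ", law$dist))
}

chrom_seed <- function(seed, chrom) {
  as.integer((as.numeric(seed) + 7919 * chrom) %% 2147483647)
}

#' Build a genetic map for one chromosome
#'
#' A genetic map is a piecewise-linear cumulative genetic position (Morgans)
#' over physical position (bp).  With \code{hotspot_frac_bp > 0}, randomly
#' chosen SNP intervals totalling that fraction of the chromosome's bp carry
#' \code{hotspot_mass} of the genetic length; the remainder is uniform per bp.
#'
#' @param chrom_len_bp chromosome length in bp.
#' @param morgans genetic length in Morgans.
#' @param positions SNP positions (needed only for the hotspot design).
#' @param hotspot_frac_bp,hotspot_mass hotspot design, see \code{sim_config}.
#' @return object of class \code{genetic_map}: list with \code{bp}, \code{M}
#'   breakpoints, \code{morgans}, \code{length_bp}, \code{hotspot_intervals}.
#' @export
genetic_map <- function(chrom_len_bp, morgans, positions = NULL,
                        hotspot_frac_bp = 0, hotspot_mass = 0) {
  if (chrom_len_bp <= 0) abort("chromosome length must be positive")
  hot <- NULL
  if (hotspot_frac_bp > 0) {
    if (is.null(positions) || length(positions) < 2)
      abort("hotspot maps need SNP positions")
    iv_start <- positions[-length(positions)]
    iv_end <- positions[-1]
    iv_len <- iv_end - iv_start
    ord <- sample.int(length(iv_len))
    cum <- cumsum(iv_len[ord])
    k <- which(cum >= hotspot_frac_bp * chrom_len_bp)[1]
    if (is.na(k)) k <- length(ord)
    sel <- sort(ord[seq_len(k)])
    hot <- data.frame(start = iv_start[sel], end = iv_end[sel])
    hot_bp <- sum(hot$end - hot$start)
    cold_bp <- chrom_len_bp - hot_bp
    r_hot <- hotspot_mass * morgans / hot_bp
    r_cold <- (1 - hotspot_mass) * morgans / cold_bp
    # breakpoints at hotspot boundaries
    bp <- sort(unique(c(0, hot$start, hot$end, chrom_len_bp)))
    rate <- rep(r_cold, length(bp) - 1)
    mid <- (bp[-1] + bp[-length(bp)]) / 2
    in_hot <- vapply(mid, function(x) any(x > hot$start & x <= hot$end), logical(1))
    rate[in_hot] <- r_hot
    M <- c(0, cumsum(rate * diff(bp)))
    M <- M * (morgans / M[length(M)])
  } else {
    bp <- c(0, chrom_len_bp)
    M <- c(0, morgans)
  }
  structure(list(bp = bp, M = M, morgans = morgans,
                 length_bp = chrom_len_bp, hotspot_intervals = hot),
            class = "genetic_map")
}

# cumulative genetic position (Morgans) at physical positions x
map_cum_morgans <- function(gmap, x) {
  stats::approx(gmap$bp, gmap$M, xout = x, rule = 2, ties = "ordered")$y
}

#' True per-interval crossover rates implied by a genetic map
#'
#' @param gmap a \code{genetic_map}.
#' @param positions SNP positions on the chromosome.
#' @return numeric vector of Morgans per adjacent-SNP interval.
#' @export
truth_interval_rates <- function(gmap, positions) {
  diff(map_cum_morgans(gmap, positions))
}

# Draw crossover positions (bp) for one meiosis on one chromosome.
# nu = 1: Poisson process with intensity 1 per Morgan.  nu > 1: stationary
# gamma-renewal chiasma process (shape nu, rate 2*nu per Morgan) thinned by
# 1/2, the standard counting model for positive interference.
draw_crossovers <- function(gmap, nu = 1, obligate = FALSE) {
  L <- gmap$morgans
  if (L <= 0) return(numeric(0))
  repeat {
    if (nu == 1) {
      g <- sort(stats::runif(stats::rpois(1, L), 0, L))
    } else {
      burn <- 5
      need <- ceiling((burn + L) * 2 * 1.5) + 10
      gaps <- stats::rgamma(need, shape = nu, rate = 2 * nu)
      pts <- cumsum(gaps) - burn
      while (pts[length(pts)] < L) {
        gaps <- stats::rgamma(need, shape = nu, rate = 2 * nu)
        pts <- c(pts, pts[length(pts)] + cumsum(gaps))
      }
      pts <- pts[pts > 0 & pts <= L]
      g <- pts[stats::runif(length(pts)) < 0.5]
    }
    if (!obligate || length(g) > 0) break
  }
  if (length(g) == 0) return(numeric(0))
  # invert the cumulative map to physical coordinates
  sort(stats::approx(gmap$M, gmap$bp, xout = g, ties = "ordered")$y)
}

#' Simulate one meiosis
#'
#' Draws crossover positions along the genetic map and recombines the two
#' parental haplotypes into a gamete.  The starting haplotype is chosen fairly
#' at random and the gamete alternates between the parental haplotypes at each
#' crossover.
#'
#' @param h1,h2 parental haplotypes (0/1 vectors over the chromosome's SNPs).
#' @param positions SNP positions (bp), strictly increasing.
#' @param gmap \code{genetic_map} covering the chromosome.
#' @param interference_nu gamma-renewal shape (1 = no interference).
#' @param obligate_crossover resample until at least one crossover (ignored
#'   when the genetic length is zero).
#' @return list with \code{gamete} (0/1 vector), \code{crossovers_bp} and
#'   \code{start_hap}.
#' @export
simulate_meiosis <- function(h1, h2, positions, gmap, interference_nu = 1,
                             obligate_crossover = FALSE) {
  if (is.null(gmap) || length(gmap$bp) < 2) abort("empty genetic map")
  if (length(h1) != length(positions) || length(h2) != length(positions))
    abort("haplotype/position length mismatch")
  if (interference_nu < 1) abort("interference_nu must be >= 1")
  xo <- draw_crossovers(gmap, interference_nu, obligate_crossover)
  start <- sample(2L, 1L)
  k <- findInterval(positions, xo)
  use_first <- ((k + start) %% 2L) == 1L
  gam <- ifelse(use_first, h1, h2)
  list(gamete = as.integer(gam), crossovers_bp = xo, start_hap = start)
}

#' Simulate founder haplotypes
#'
#' Founders are draws from linkage equilibrium: per-SNP alternate-allele
#' frequencies come from the configured MAF law and sites are independent.
#'
#' @param config a \code{sim_config}.
#' @param n_founders number of founder animals.
#' @return list with \code{snp_map} (chrom, snp_id, pos_bp), \code{maf}, and
#'   haplotype matrices \code{h1}, \code{h2} (founders x SNPs).
#' @export
simulate_founders <- function(config, n_founders) {
  stopifnot(inherits(config, "sim_config"))
  if (n_founders < 1) abort("n_founders must be positive")
  frames <- lapply(seq_len(config$n_chromosomes), function(cc) {
    set.seed(chrom_seed(config$seed, cc))
    fr <- sim_chrom_frame(config, cc)
    h <- draw_founder_haps(fr$maf, 2 * n_founders)
    list(frame = fr, h = h)
  })
  snp_map <- do.call(rbind, lapply(frames, function(x) x$frame$map))
  h <- do.call(cbind, lapply(frames, function(x) x$h))
  odd <- seq(1, 2 * n_founders, by = 2)
  list(snp_map = snp_map,
       maf = unlist(lapply(frames, function(x) x$frame$maf)),
       h1 = h[odd, , drop = FALSE], h2 = h[odd + 1, , drop = FALSE])
}

draw_founder_haps <- function(maf, n_haps) {
  m <- matrix(stats::runif(n_haps * length(maf)), nrow = n_haps)
  storage.mode(m) <- "double"
  out <- matrix(as.integer(m < rep(maf, each = n_haps)), nrow = n_haps)
  out
}

# per-chromosome frame: SNP positions, MAF, nested-panel priority, sex maps.
# Caller is responsible for seeding the RNG (one stream per chromosome).
sim_chrom_frame <- function(config, cc) {
  n_c <- config$snps_per_chrom[cc]
  L <- config$chrom_lengths_bp[cc]
  pos <- sort(sample.int(L, n_c))
  maf <- draw_maf(config$maf_law, n_c)
  priority <- sample.int(n_c)
  gmap_m <- genetic_map(L, config$male_map_morgans[cc], pos,
                        config$hotspot_frac_bp, config$hotspot_mass)
  gmap_f <- genetic_map(L, config$female_map_morgans[cc], pos,
                        config$hotspot_frac_bp, config$hotspot_mass)
  map <- data.frame(chrom = as.integer(cc),
                    snp_id = sprintf("snp%02d_%05d", cc, seq_len(n_c)),
                    pos_bp = pos, stringsAsFactors = FALSE)
  list(map = map, maf = maf, priority = priority,
       gmap_m = gmap_m, gmap_f = gmap_f)
}

#' Simulate a genotyped three-generation pedigree
#'
#' Builds \code{n_families} three-generation families (offspring, sire, dam,
#' two grandsires, granddams per the configured genotyping probability), with
#' sires shared across families and dams sharing maternal grandparents.
#' Haplotypes descend from founder grandparents through simulated meioses, so
#' every animal's genotype is the sum of two recorded transmitted haplotypes.
#' Chip masks, genotyping error and missingness are applied after the truth is
#' recorded.  Deterministic given \code{config$seed}; each chromosome has its
#' own seed stream, so simulating a subset of chromosomes reproduces exactly
#' the corresponding slice of a full-genome run.
#'
#' @param config a \code{sim_config}.
#' @param n_families number of three-generation families.
#' @param chromosomes chromosomes to simulate (default all).
#' @param keep_haplotypes keep true phased haplotypes (memory-hungry; meant
#'   for small validation runs).
#' @return list of class \code{sim_pedigree}: \code{pedigree} (data frame),
#'   \code{genotypes} (a \code{genotype_table}), \code{truth} (list with
#'   \code{crossovers} data frame and optional \code{haplotypes}), and
#'   \code{config}.
#' @export
simulate_pedigree <- function(config, n_families, chromosomes = NULL,
                              keep_haplotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_families < 1) abort("n_families must be >= 1")
  chromosomes <- as.integer(chromosomes %||% seq_len(config$n_chromosomes))

  ## --- pedigree structure (seeded independently of chromosome content) ---
  set.seed(config$seed)
  n_sires <- ceiling(n_families / config$progeny_per_sire)
  sire_of <- rep(seq_len(n_sires), each = config$progeny_per_sire)[seq_len(n_families)]
  n_mgs <- ceiling(n_families / config$dams_per_grandsire)
  mgs_of <- rep(seq_len(n_mgs), each = config$dams_per_grandsire)[seq_len(n_families)]

  id_off <- sprintf("O%05d", seq_len(n_families))
  id_sire <- sprintf("S%04d", seq_len(n_sires))
  id_dam <- sprintf("D%05d", seq_len(n_families))
  id_pgs <- sprintf("GPS%04d", seq_len(n_sires))
  id_pgd <- sprintf("GPD%04d", seq_len(n_sires))
  id_mgs <- sprintf("GMS%04d", seq_len(n_mgs))
  id_mgd <- sprintf("GMD%04d", seq_len(n_mgs))

  pgd_geno <- stats::runif(n_sires) < config$granddam_genotyped_prob
  mgd_geno <- stats::runif(n_mgs) < config$granddam_genotyped_prob
  off_sex <- sample(c("M", "F"), n_families, replace = TRUE)
  off_year <- config$base_year + 8 + sample(0:4, n_families, replace = TRUE)

  ped <- rbind(
    data.frame(id = id_pgs, sire = NA, dam = NA, sex = "M",
               birth_year = config$base_year, genotyped = TRUE),
    data.frame(id = id_pgd, sire = NA, dam = NA, sex = "F",
               birth_year = config$base_year, genotyped = pgd_geno),
    data.frame(id = id_mgs, sire = NA, dam = NA, sex = "M",
               birth_year = config$base_year, genotyped = TRUE),
    data.frame(id = id_mgd, sire = NA, dam = NA, sex = "F",
               birth_year = config$base_year, genotyped = mgd_geno),
    data.frame(id = id_sire, sire = id_pgs, dam = id_pgd, sex = "M",
               birth_year = config$base_year + 4, genotyped = TRUE),
    data.frame(id = id_dam, sire = id_mgs[mgs_of], dam = id_mgd[mgs_of],
               sex = "F", birth_year = config$base_year + 4, genotyped = TRUE),
    data.frame(id = id_off, sire = id_sire[sire_of], dam = id_dam,
               sex = off_sex, birth_year = off_year, genotyped = TRUE)
  )
  ped$chip <- sample(names(config$chip_mix), nrow(ped), replace = TRUE,
                     prob = config$chip_mix)
  rownames(ped) <- ped$id

  founders <- c(id_pgs, id_pgd, id_mgs, id_mgd)
  geno_ids <- ped$id[ped$genotyped]
  all_ids <- ped$id

  ## --- per-chromosome genetics ---
  geno_cols <- vector("list", length(chromosomes))
  map_rows <- vector("list", length(chromosomes))
  truth_rows <- vector("list", length(chromosomes))
  hap_store <- if (keep_haplotypes) vector("list", length(chromosomes)) else NULL
  panel_cols <- vector("list", length(chromosomes))

  for (k in seq_along(chromosomes)) {
    cc <- chromosomes[k]
    set.seed(chrom_seed(config$seed, cc))
    fr <- sim_chrom_frame(config, cc)
    n_c <- nrow(fr$map)
    pos <- fr$map$pos_bp

    H1 <- matrix(NA_integer_, length(all_ids), n_c, dimnames = list(all_ids, NULL))
    H2 <- H1
    fh <- draw_founder_haps(fr$maf, 2 * length(founders))
    odd <- seq(1, nrow(fh), by = 2)
    H1[founders, ] <- fh[odd, , drop = FALSE]
    H2[founders, ] <- fh[odd + 1, , drop = FALSE]

    xo_list <- list()
    do_meiosis <- function(parent, child, sex_of_parent) {
      gmap <- if (sex_of_parent == "M") fr$gmap_m else fr$gmap_f
      m <- simulate_meiosis(H1[parent, ], H2[parent, ], pos, gmap,
                            config$interference_nu, config$obligate_crossover)
      if (length(m$crossovers_bp))
        xo_list[[length(xo_list) + 1]] <<- data.frame(
          meiosis_id = paste0(child, ":", if (sex_of_parent == "M") "P" else "M"),
          child_id = child, parent_id = parent, parent_sex = sex_of_parent,
          chrom = cc, pos_bp = m$crossovers_bp, stringsAsFactors = FALSE)
      m$gamete
    }
    for (i in seq_len(n_sires)) {
      H1[id_sire[i], ] <- do_meiosis(id_pgs[i], id_sire[i], "M")
      H2[id_sire[i], ] <- do_meiosis(id_pgd[i], id_sire[i], "F")
    }
    for (i in seq_len(n_families)) {
      H1[id_dam[i], ] <- do_meiosis(id_mgs[mgs_of[i]], id_dam[i], "M")
      H2[id_dam[i], ] <- do_meiosis(id_mgd[mgs_of[i]], id_dam[i], "F")
    }
    for (i in seq_len(n_families)) {
      H1[id_off[i], ] <- do_meiosis(id_sire[sire_of[i]], id_off[i], "M")
      H2[id_off[i], ] <- do_meiosis(id_dam[i], id_off[i], "F")
    }

    G <- H1[geno_ids, , drop = FALSE] + H2[geno_ids, , drop = FALSE]

    # chip masks: nested panels via per-SNP priority ranks
    frac <- config$chip_panels / config$n_snps
    keep_n <- stats::setNames(pmin(n_c, ceiling(frac * n_c)), names(frac))
    for (chip in names(config$chip_panels)) {
      on_panel <- fr$priority <= keep_n[chip]
      rows <- geno_ids[ped[geno_ids, "chip"] == chip]
      if (length(rows) && any(!on_panel)) G[rows, !on_panel] <- NA_integer_
    }
    # genotype error: flip to a uniformly chosen different dosage
    if (config$genotype_error_rate > 0) {
      obs <- which(!is.na(G))
      hit <- obs[stats::runif(length(obs)) < config$genotype_error_rate]
      if (length(hit))
        G[hit] <- (G[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
    }
    if (config$missing_rate > 0) {
      obs <- which(!is.na(G))
      drop <- obs[stats::runif(length(obs)) < config$missing_rate]
      if (length(drop)) G[drop] <- NA_integer_
    }

    geno_cols[[k]] <- G
    map_rows[[k]] <- fr$map
    truth_rows[[k]] <- if (length(xo_list)) do.call(rbind, xo_list) else NULL
    panel_cols[[k]] <- outer(fr$priority, keep_n, "<=")
    if (keep_haplotypes) hap_store[[k]] <- list(h1 = H1, h2 = H2)
  }

  snp_map <- do.call(rbind, map_rows)
  geno <- do.call(cbind, geno_cols)
  colnames(geno) <- snp_map$snp_id
  chip <- stats::setNames(ped[geno_ids, "chip"], geno_ids)
  gt <- genotype_table(snp_map, geno, chip)
  panels <- do.call(rbind, panel_cols)
  attr(gt, "panels") <- stats::setNames(
    lapply(colnames(panels), function(p) snp_map$snp_id[panels[, p]]),
    colnames(panels))

  truth <- list(crossovers = if (length(truth_rows))
                  do.call(rbind, Filter(Negate(is.null), truth_rows))
                else NULL)
  if (keep_haplotypes) {
    truth$haplotypes <- list(
      h1 = do.call(cbind, lapply(hap_store, `[[`, "h1")),
      h2 = do.call(cbind, lapply(hap_store, `[[`, "h2")))
    colnames(truth$haplotypes$h1) <- snp_map$snp_id
    colnames(truth$haplotypes$h2) <- snp_map$snp_id
  }
  class(truth) <- "truth_set"

  structure(list(pedigree = ped, genotypes = gt, truth = truth,
                 config = config, chromosomes = chromosomes),
            class = "sim_pedigree")
}

#' Simulate observed crossover regions directly
#'
#' Draws meioses on one chromosome from a genetic map and converts the true
#' crossovers into observed crossover regions using a random informative-SNP
#' mask: per meiosis each SNP is informative with probability
#' \code{info_rate}, and an observed region is a parity switch between
#' consecutive informative SNPs (so double crossovers within one uninformative
#' gap cancel, as in real trio data).  Used to validate the EM map builder and
#' hotspot-usage statistics at scales where full family simulation is not
#' needed.
#'
#' @param positions SNP positions on the chromosome.
#' @param gmap a \code{genetic_map}.
#' @param n_meioses number of meioses.
#' @param info_rate per-SNP informative probability (typical trio data yields
#'   roughly a third of SNPs informative).
#' @param chrom chromosome label.
#' @param parent_sex sex label for all meioses.
#' @param meioses_per_animal meioses attributed to each synthetic parent.
#' @param interference_nu,obligate_crossover see \code{simulate_meiosis}.
#' @param seed optional seed.
#' @return list with \code{calls} (a \code{meiosis_calls} object) and
#'   \code{truth} (data frame of true crossover positions).
#' @export
simulate_crossover_regions <- function(positions, gmap, n_meioses,
                                       info_rate = 0.35, chrom = 1,
                                       parent_sex = "M",
                                       meioses_per_animal = 1,
                                       interference_nu = 1,
                                       obligate_crossover = FALSE,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(positions)
  out <- vector("list", n_meioses)
  truth <- vector("list", n_meioses)
  animal <- rep(seq_len(ceiling(n_meioses / meioses_per_animal)),
                each = meioses_per_animal)[seq_len(n_meioses)]
  for (i in seq_len(n_meioses)) {
    mid <- sprintf("SIMME%06d", i)
    xo <- draw_crossovers(gmap, interference_nu, obligate_crossover)
    if (length(xo))
      truth[[i]] <- data.frame(meiosis_id = mid, chrom = chrom, pos_bp = xo,
                               stringsAsFactors = FALSE)
    inf <- which(stats::runif(S) < info_rate)
    if (length(inf) < 2 || !length(xo)) next
    par <- findInterval(positions[inf], xo) %% 2L
    sw <- which(diff(par) != 0)
    if (!length(sw)) next
    li <- inf[sw]
    ri <- inf[sw + 1]
    out[[i]] <- data.frame(meiosis_id = mid, parent_id = sprintf("SIMAN%05d", animal[i]),
                           parent_sex = parent_sex, chrom = chrom,
                           left_idx = li, right_idx = ri,
                           left_pos = positions[li], right_pos = positions[ri],
                           n_intervals = ri - li, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(calls)) calls <- empty_calls()
  meta <- data.frame(meiosis_id = sprintf("SIMME%06d", seq_len(n_meioses)),
                     parent_id = sprintf("SIMAN%05d", animal),
                     parent_sex = parent_sex,
                     n_informative = NA_integer_,
                     chip_category = "50K", stringsAsFactors = FALSE)
  calls <- as_meiosis_calls(calls, meta)
  list(calls = calls,
       truth = do.call(rbind, Filter(Negate(is.null), truth)))
}
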