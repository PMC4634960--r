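# Positional and temporal diagnostics: smoothing-spline profiles of
# recombination rate along the (relative) chromosome, covariate-adjusted time
# trends, and a two-point linkage/LD screen that flags SNPs whose linkage
# pattern is inconsistent with their mapped position.

#' Positional profile of recombination rate
#'
#' Converts interval midpoints to relative chromosome positions (position
#' divided by chromosome length), trims the terminal \code{trim_bp} of each
#' chromosome where detection power is low, and fits a smoothing spline
#' (default 5 degrees of freedom) to the interval rates pooled across
#' chromosomes.
#'
#' @param map a \code{recombination_map}.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param trim_bp length trimmed from each chromosome end; intervals
#'   overlapping the trimmed regions are excluded.
#' @param spline_df spline degrees of freedom.
#' @param per_chromosome also fit one spline per chromosome.
#' @return list with \code{points} (relative position, rate, chrom),
#'   \code{fit} (data frame of relative position and smoothed rate) and
#'   optionally \code{per_chromosome}.
#' @export
position_profile <- function(map, chrom_lengths, trim_bp = 2e6,
                             spline_df = 5, per_chromosome = FALSE) {
  len <- chrom_lengths[as.character(map$chrom)]
  keep <- map$start_pos >= trim_bp & map$end_pos <= len - trim_bp
  pts <- data.frame(chrom = map$chrom[keep],
                    rel_pos = ((map$start_pos + map$end_pos) / 2 / len)[keep],
                    rate = map$rate[keep])
  if (spline_df >= nrow(pts)) abort("spline_df must be smaller than the number of points")
  sp <- stats::smooth.spline(pts$rel_pos, pts$rate, df = spline_df)
  grid <- seq(min(pts$rel_pos), max(pts$rel_pos), length.out = 200)
  out <- list(points = pts,
              fit = data.frame(rel_pos = grid,
                               rate = stats::predict(sp, grid)$y))
  if (per_chromosome) {
    out$per_chromosome <- lapply(split(pts, pts$chrom), function(d) {
      if (nrow(d) <= spline_df) return(NULL)
      s <- stats::smooth.spline(d$rel_pos, d$rate, df = spline_df)
      data.frame(rel_pos = grid, rate = stats::predict(s, grid)$y)
    })
  }
  out
}

#' Stratify meioses by observed crossover count
#'
#' Splits a callset per chromosome into single-crossover and double-crossover
#' meioses (used to contrast positional profiles and reveal interference).
#'
#' @param callset a \code{meiosis_calls} object.
#' @return list of two data frames of (meiosis_id, chrom): \code{single} and
#'   \code{double}.
#' @export
crossover_strata <- function(callset) {
  key <- paste(callset$meiosis_id, callset$chrom)
  n <- table(key)
  pick <- function(k) {
    ks <- names(n)[n == k]
    sel <- !duplicated(key) & key %in% ks
    data.frame(meiosis_id = callset$meiosis_id[sel], chrom = callset$chrom[sel])
  }
  list(single = pick(1), double = pick(2))
}

#' Covariate-adjusted time trend of recombination
#'
#' Adjusts meiosis-level crossover counts for nuisance fixed effects with an
#' ordinary linear model (chip categories, the parent's genomic inbreeding
#' coefficient, informative-SNP counts with polynomial and interaction terms —
#' whatever columns are supplied), then fits a smoothing spline of the
#' adjusted counts on birth year.  Reports the inbreeding coefficient's
#' estimated effect when a column named \code{inbreeding} is among the
#' adjusters.
#'
#' @param counts numeric vector of per-meiosis crossover counts.
#' @param birth_year numeric vector aligned with \code{counts}.
#' @param adjusters optional data frame of covariates (same rows).
#' @param spline_df spline degrees of freedom.
#' @return list with \code{trend} (year, adjusted mean, spline fit),
#'   \code{inbreeding} (beta, se, p or NULL), and the adjustment \code{model}.
#' @export
time_trend <- function(counts, birth_year, adjusters = NULL, spline_df = 5) {
  if (!is.null(adjusters) && ncol(adjusters) > 0) {
    dat <- data.frame(.count = counts, adjusters)
    fit <- stats::lm(.count ~ ., data = dat)
    if (any(is.na(stats::coef(fit)))) {
      warning("rank-deficient adjustment design; aliased columns dropped")
    }
    adj <- stats::residuals(fit) + mean(counts)
    inb <- NULL
    if ("inbreeding" %in% names(adjusters)) {
      sm <- stats::coef(summary(fit))
      row <- grep("^inbreeding$", rownames(sm))
      if (length(row))
        inb <- c(beta = sm[row, 1], se = sm[row, 2], p = sm[row, 4])
    }
  } else {
    fit <- NULL
    adj <- counts
    inb <- NULL
  }
  if (spline_df >= length(unique(birth_year))) {
    # too few distinct years for a spline: fall back to yearly means
    ym <- stats::aggregate(adj, list(year = birth_year), mean)
    trend <- data.frame(year = ym$year, fit = ym$x)
  } else {
    sp <- stats::smooth.spline(birth_year, adj, df = spline_df)
    yrs <- sort(unique(birth_year))
    trend <- data.frame(year = yrs, fit = stats::predict(sp, yrs)$y)
  }
  list(trend = trend, inbreeding = inb, model = fit,
       adjusted = data.frame(birth_year = birth_year, adjusted = adj))
}

#' Two-point linkage screen of a candidate SNP
#'
#' Estimates, from phase-known meioses, the recombination fraction between the
#' candidate and every other SNP on the same chromosome: r-hat is the
#' recombinant fraction (capped at 0.5) and LOD = log10 L(r-hat)/L(0.5) with
#' L(r) = r^R (1-r)^(N-R).  For a correctly placed SNP the LOD peaks at the
#' SNP and decays with distance while r-hat does the opposite.  The SNP is
#' flagged suspicious when the LOD argmax lies farther than
#' \code{max_peak_dist_bp} from its mapped position or the binned LOD profile
#' fails to decay monotonically (within a small tolerance) with distance.
#'
#' @param candidate_snp SNP id.
#' @param origins matrix of grandparental origins (meioses x SNPs, 1/2/NA)
#'   for one parent sex or both stacked.
#' @param snp_map SNP map aligned with the origin columns.
#' @param min_informative pairs with fewer phase-known meioses are skipped.
#' @param max_peak_dist_bp allowed distance between the LOD argmax and the
#'   candidate's mapped position.
#' @param bin_bp width of the distance bins for the decay check.
#' @param decay_tol tolerated non-monotonicity, as a fraction of the peak LOD.
#' @return list of class \code{ld_screen}: per-SNP table (pos, N, R, rhat,
#'   lod), \code{flag} ("normal"/"suspicious") and the reasons.
#' @export
ld_screen <- function(candidate_snp, origins, snp_map, min_informative = 20,
                      max_peak_dist_bp = 1e7, bin_bp = 5e6, decay_tol = 0.05) {
  j <- match(candidate_snp, snp_map$snp_id)
  if (is.na(j)) abort("unknown candidate SNP: ", candidate_snp)
  cc <- snp_map$chrom[j]
  idx <- which(snp_map$chrom == cc)
  if (length(idx) < 11) abort("candidate chromosome has fewer than 10 other SNPs")
  oc <- origins[, j]
  O <- origins[, idx, drop = FALSE]
  known <- !is.na(oc) & !is.na(O)
  N <- colSums(known)
  R <- colSums(known & (O != oc), na.rm = TRUE)
  ok <- N >= min_informative
  rhat <- ifelse(ok, pmin(R / N, 0.5), NA_real_)
  lod <- rep(NA_real_, length(idx))
  for (k in which(ok)) {
    r <- rhat[k]
    l0 <- N[k] * log10(0.5)
    l1 <- if (r <= 0) 0 else if (r >= 0.5) N[k] * log10(0.5) else
      R[k] * log10(r) + (N[k] - R[k]) * log10(1 - r)
    lod[k] <- max(l1 - l0, 0)
  }
  tab <- data.frame(snp_id = snp_map$snp_id[idx], pos = snp_map$pos_bp[idx],
                    N = N, R = R, rhat = rhat, lod = lod)
  tab_ok <- tab[ok, , drop = FALSE]
  reasons <- character(0)
  peak_pos <- tab_ok$pos[which.max(tab_ok$lod)]
  if (abs(peak_pos - snp_map$pos_bp[j]) > max_peak_dist_bp)
    reasons <- c(reasons, sprintf("LOD peak %.1f Mb from mapped position",
                                  abs(peak_pos - snp_map$pos_bp[j]) / 1e6))
  dist <- abs(tab_ok$pos - snp_map$pos_bp[j])
  bins <- floor(dist / bin_bp)
  prof <- tapply(tab_ok$lod, bins, mean)
  prof <- prof[order(as.integer(names(prof)))]
  if (length(prof) >= 2) {
    tol <- decay_tol * max(tab_ok$lod, na.rm = TRUE)
    if (any(diff(prof) > tol))
      reasons <- c(reasons, "binned LOD profile does not decay with distance")
  }
  structure(list(table = tab, candidate = candidate_snp,
                 flag = if (length(reasons)) "suspicious" else "normal",
                 reasons = reasons),
            class = "ld_screen")
}
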