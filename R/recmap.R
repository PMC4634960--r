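# Recombination-map construction.  Each called crossover is localized to a
# run of m adjacent SNP intervals; an EM algorithm distributes the event's
# expected count across those intervals and estimates the per-interval
# crossover probability per meiosis.

#' Adjacent-SNP interval grid of a SNP map
#'
#' @param snp_map data frame with \code{chrom}, \code{pos_bp} (strictly
#'   increasing within chromosome).
#' @return data frame with \code{chrom, start_pos, end_pos} (half-open
#'   intervals \code{(start, end]}), one row per adjacent-SNP pair, plus an
#'   \code{offset} attribute mapping chromosome to global interval offset.
#' @export
map_intervals <- function(snp_map) {
  by_chr <- split(snp_map$pos_bp, snp_map$chrom)
  iv <- do.call(rbind, lapply(names(by_chr), function(cc) {
    p <- by_chr[[cc]]
    data.frame(chrom = as.integer(cc), start_pos = p[-length(p)], end_pos = p[-1])
  }))
  n_iv <- vapply(by_chr, function(p) length(p) - 1L, integer(1))
  offset <- stats::setNames(cumsum(c(0L, n_iv[-length(n_iv)])), names(by_chr))
  attr(iv, "offset") <- offset
  iv
}

#' Fit a recombination map by EM
#'
#' Initialization assigns an expected count of 1/m to each of the m intervals
#' of a crossover region.  The M-step sets each interval's rate to its total
#' expected count divided by the number of meioses; the E-step redistributes
#' each region's single event across its intervals proportionally to the
#' current rates.  Iterated until the largest absolute rate change falls
#' below \code{tol}.  The total fitted mass times n equals the number of
#' crossover regions at every iteration, and the observed-region
#' log-likelihood is non-decreasing.
#'
#' @param callset a \code{meiosis_calls} object (regions with
#'   within-chromosome SNP indices \code{left_idx}, \code{right_idx}).
#' @param n_meioses number of meioses contributing to the map.
#' @param snp_map the SNP map the calls were made on.
#' @param tol convergence tolerance on max absolute rate change.
#' @param max_iter iteration cap; non-convergence warns and returns the last
#'   iterate.
#' @param sex optional sex label stored on the map.
#' @param keep_trace record per-iteration log-likelihood and total mass.
#' @return object of class \code{recombination_map}: data frame
#'   \code{chrom, start_pos, end_pos, rate} with attributes \code{n_meioses},
#'   \code{n_iter}, \code{converged}, \code{loglik}, \code{sex}, and
#'   optionally \code{trace}.
#' @export
em_fit <- function(callset, n_meioses, snp_map, tol = 1e-8, max_iter = 5000,
                   sex = NA_character_, keep_trace = FALSE) {
  if (n_meioses < 1) abort("n_meioses must be >= 1")
  iv <- map_intervals(snp_map)
  offset <- attr(iv, "offset")
  I <- nrow(iv)
  if (nrow(callset)) {
    if (any(callset$right_idx <= callset$left_idx))
      abort("crossover region referencing zero intervals")
    l <- offset[as.character(callset$chrom)] + callset$left_idx
    r <- offset[as.character(callset$chrom)] + callset$right_idx - 1L
  } else {
    l <- r <- integer(0)
  }
  fit <- em_fit_ranges(l, r, I, n_meioses, tol, max_iter, keep_trace)
  map <- cbind(iv, rate = fit$p)
  attr(map, "offset") <- offset
  attr(map, "n_meioses") <- n_meioses
  attr(map, "n_iter") <- fit$n_iter
  attr(map, "converged") <- fit$converged
  attr(map, "loglik") <- fit$loglik
  attr(map, "sex") <- sex
  if (keep_trace) attr(map, "trace") <- fit$trace
  class(map) <- c("recombination_map", "data.frame")
  map
}

# Core EM on integer interval ranges [l, r] (global indices), I intervals.
em_fit_ranges <- function(l, r, I, n, tol = 1e-8, max_iter = 5000,
                          keep_trace = FALSE) {
  # add each value over its index range [from, to] via a difference array
  range_add <- function(values, from, to) {
    d <- numeric(I + 1)
    agg_f <- tapply(values, from, sum)
    agg_t <- tapply(values, to + 1L, sum)
    d[as.integer(names(agg_f))] <- agg_f
    d[as.integer(names(agg_t))] <- d[as.integer(names(agg_t))] - agg_t
    cumsum(d)[1:I]
  }
  if (!length(l)) {
    return(list(p = numeric(I), n_iter = 0L, converged = TRUE,
                loglik = 0, trace = NULL))
  }
  m <- r - l + 1L
  p <- range_add(1 / m, l, r) / n
  trace <- if (keep_trace) list() else NULL
  converged <- FALSE
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    S <- c(0, cumsum(p))
    rs <- S[r + 1L] - S[l]
    zero <- rs <= 0
    ll <- sum(log(rs[!zero]))
    v <- ifelse(zero, 0, 1 / rs)
    newp <- p * range_add(v, l, r) / n
    if (any(zero))
      newp <- newp + range_add(1 / m[zero], l[zero], r[zero]) / n
    delta <- max(abs(newp - p))
    p <- newp
    if (keep_trace)
      trace[[it]] <- data.frame(iter = it, loglik = ll,
                                total_mass = sum(p) * n, max_delta = delta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations (last max delta ",
            signif(delta, 3), ")")
  S <- c(0, cumsum(p))
  rs <- S[r + 1L] - S[l]
  list(p = p, n_iter = it, converged = converged,
       loglik = sum(log(rs[rs > 0])),
       trace = if (keep_trace) do.call(rbind, trace) else NULL)
}

#' Chip-density correction of crossover counts
#'
#' Meioses genotyped on lower-density chips reveal fewer crossovers.  Using
#' the meioses where all animals carry the reference (densest) panel as the
#' standard, every chip category's counts are scaled by
#' (reference mean / category mean) per sex, so that corrected category means
#' coincide with the reference mean.
#'
#' @param counts data frame with columns \code{meiosis_id, parent_id, sex,
#'   category, count} (one row per meiosis).
#' @param reference the reference category label.
#' @return list with \code{counts} (input plus \code{count_corrected}) and
#'   \code{factors} (per sex x category: mean, factor).
#' @export
chip_correct <- function(counts, reference) {
  out <- vector("list", 0)
  counts$count_corrected <- NA_real_
  for (sx in unique(counts$sex)) {
    sel <- counts$sex == sx
    ref <- counts$count[sel & counts$category == reference]
    if (!length(ref)) abort("reference category is empty for sex ", sx)
    ref_mean <- mean(ref)
    for (cat in unique(counts$category[sel])) {
      csel <- sel & counts$category == cat
      cat_mean <- mean(counts$count[csel])
      if (!is.finite(cat_mean) || cat_mean == 0) {
        warning("category ", cat, " (", sx, ") has no usable counts; excluded")
        next
      }
      f <- ref_mean / cat_mean
      counts$count_corrected[csel] <- counts$count[csel] * f
      out[[length(out) + 1]] <- data.frame(sex = sx, category = cat,
                                           mean = cat_mean, factor = f)
    }
  }
  list(counts = counts, factors = do.call(rbind, out))
}

#' Haldane-adjusted genetic length of a map
#'
#' Converts each interval's crossover probability c to a map distance
#' d = -log(1 - 2c) / 2 (Haldane), which is >= c with equality iff c = 0.
#'
#' @param map a \code{recombination_map}.
#' @return list with \code{per_chromosome} (raw and Haldane Morgans) and
#'   genome totals \code{total_raw}, \code{total_haldane}.
#' @export
haldane_length <- function(map) {
  bad <- which(map$rate >= 0.5)
  if (length(bad))
    abort("interval rate >= 0.5 at chrom ", map$chrom[bad[1]], " interval [",
          map$start_pos[bad[1]], ", ", map$end_pos[bad[1]], "]")
  d <- -0.5 * log1p(-2 * map$rate)
  per <- data.frame(
    chrom = as.integer(names(tapply(map$rate, map$chrom, sum))),
    raw_morgans = as.numeric(tapply(map$rate, map$chrom, sum)),
    haldane_morgans = as.numeric(tapply(d, map$chrom, sum)))
  list(per_chromosome = per,
       total_raw = sum(map$rate), total_haldane = sum(d))
}

#' Summarize a pair of sex-specific maps
#'
#' @param map_male,map_female \code{recombination_map}s on the same grid.
#' @return list with \code{per_chromosome} (Morgans and kb/cM per sex),
#'   \code{genome} (totals) and \code{rate_correlation} (Pearson correlation
#'   of interval rates between sexes).
#' @export
map_summary <- function(map_male, map_female) {
  if (!identical(map_male[, c("chrom", "start_pos", "end_pos")],
                 map_female[, c("chrom", "start_pos", "end_pos")]))
    abort("maps are not on the same interval grid")
  span_kb <- tapply(map_male$end_pos - map_male$start_pos, map_male$chrom, sum) / 1000
  m_tot <- tapply(map_male$rate, map_male$chrom, sum)
  f_tot <- tapply(map_female$rate, map_female$chrom, sum)
  per <- data.frame(chrom = as.integer(names(m_tot)),
                    span_kb = as.numeric(span_kb),
                    male_morgans = as.numeric(m_tot),
                    female_morgans = as.numeric(f_tot),
                    male_kb_per_cM = as.numeric(span_kb / (100 * m_tot)),
                    female_kb_per_cM = as.numeric(span_kb / (100 * f_tot)))
  genome <- data.frame(span_kb = sum(per$span_kb),
                       male_morgans = sum(per$male_morgans),
                       female_morgans = sum(per$female_morgans))
  genome$male_kb_per_cM <- genome$span_kb / (100 * genome$male_morgans)
  genome$female_kb_per_cM <- genome$span_kb / (100 * genome$female_morgans)
  list(per_chromosome = per, genome = genome,
       rate_correlation = stats::cor(map_male$rate, map_female$rate))
}

#' Write a sex-specific recombination map as TSV
#'
#' @param map_male,map_female maps on the same grid.
#' @param path output path.
#' @export
write_map <- function(map_male, map_female, path) {
  stopifnot(identical(map_male$start_pos, map_female$start_pos))
  cum_cm <- function(m) unlist(lapply(split(m$rate, m$chrom), cumsum),
                               use.names = FALSE) * 100
  out <- data.frame(chrom = map_male$chrom, start_pos = map_male$start_pos,
                    end_pos = map_male$end_pos,
                    rate_male = map_male$rate, rate_female = map_female$rate,
                    cum_cM_male = cum_cm(map_male),
                    cum_cM_female = cum_cm(map_female))
  write_tsv(out, path)
}
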