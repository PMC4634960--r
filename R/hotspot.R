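# Recombination hotspots: intervals whose rate exceeds the genome-wide mean
# by k standard deviations, between-sex sharing, and per-animal hotspot usage.

#' Call recombination hotspots from a map
#'
#' The threshold is mean(rate) + k_sd * sd(rate) over all autosomal intervals;
#' membership is strict (rate > threshold).
#'
#' @param map a \code{recombination_map}.
#' @param k_sd number of standard deviations above the mean (commonly swept
#'   over 2, 2.5, 3, 5, 10).
#' @return object of class \code{hotspot_set}: the map's interval grid with a
#'   logical \code{is_hotspot} column, plus attributes \code{threshold},
#'   \code{k_sd}, \code{sex}, \code{genome_fraction} (bp fraction covered) and
#'   \code{mass_fraction} (share of total map mass in hotspots).
#' @export
call_hotspots <- function(map, k_sd = 2.5) {
  if (nrow(map) < 2) abort("need at least 2 intervals to call hotspots")
  thr <- mean(map$rate) + k_sd * stats::sd(map$rate)
  hs <- data.frame(chrom = map$chrom, start_pos = map$start_pos,
                   end_pos = map$end_pos, rate = map$rate,
                   is_hotspot = map$rate > thr)
  len <- hs$end_pos - hs$start_pos
  attr(hs, "threshold") <- thr
  attr(hs, "k_sd") <- k_sd
  attr(hs, "sex") <- attr(map, "sex")
  attr(hs, "genome_fraction") <- sum(len[hs$is_hotspot]) / sum(len)
  attr(hs, "mass_fraction") <- if (sum(map$rate) > 0)
    sum(map$rate[hs$is_hotspot]) / sum(map$rate) else 0
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' Call hotspots on distance-standardized rates
#'
#' Divides each interval's rate by its physical length before thresholding.
#' Intervals shorter than \code{min_interval_bp} are excluded from both the
#' threshold computation and the calling (they can never be hotspots here),
#' guarding against spurious hotspots caused by inaccurate physical distances.
#'
#' @param map a \code{recombination_map}.
#' @param min_interval_bp minimum interval length retained.
#' @param k_sd standard-deviation cutoff on the standardized scale (the
#'   standardized rates vary less, so a smaller cutoff is used).
#' @return a \code{hotspot_set}; excluded intervals carry
#'   \code{is_hotspot = FALSE} and are listed in the \code{excluded} attribute.
#' @export
standardized_hotspots <- function(map, min_interval_bp = 500, k_sd = 0.6) {
  len <- map$end_pos - map$start_pos
  excl <- len < min_interval_bp
  if (all(excl)) abort("all intervals shorter than min_interval_bp")
  srate <- map$rate / len
  thr <- mean(srate[!excl]) + k_sd * stats::sd(srate[!excl])
  hs <- data.frame(chrom = map$chrom, start_pos = map$start_pos,
                   end_pos = map$end_pos, rate = map$rate,
                   standardized_rate = srate,
                   is_hotspot = !excl & srate > thr)
  attr(hs, "threshold") <- thr
  attr(hs, "k_sd") <- k_sd
  attr(hs, "sex") <- attr(map, "sex")
  attr(hs, "genome_fraction") <- sum(len[hs$is_hotspot]) / sum(len)
  attr(hs, "excluded") <- which(excl)
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' Hotspots shared between sexes
#'
#' @param set_m,set_f \code{hotspot_set}s on the same interval grid.
#' @return list with \code{shared} (interval data frame), \code{n_shared},
#'   and \code{fraction_male}, \code{fraction_female} (share of each sex's
#'   hotspots that is shared).
#' @export
shared_hotspots <- function(set_m, set_f) {
  if (!identical(set_m[, c("chrom", "start_pos", "end_pos")],
                 set_f[, c("chrom", "start_pos", "end_pos")]))
    abort("hotspot sets are not on the same interval grid")
  both <- set_m$is_hotspot & set_f$is_hotspot
  list(shared = set_m[both, c("chrom", "start_pos", "end_pos")],
       n_shared = sum(both),
       fraction_male = if (sum(set_m$is_hotspot)) sum(both) / sum(set_m$is_hotspot) else NA_real_,
       fraction_female = if (sum(set_f$is_hotspot)) sum(both) / sum(set_f$is_hotspot) else NA_real_)
}

#' Per-animal hotspot usage
#'
#' Each crossover region contributes fractional mass to hotspot intervals in
#' proportion to the fitted map rates within the region (the EM posterior for
#' the event's location); a region spanning only zero-rate intervals falls
#' back to a uniform split.  A meiosis' usage is its summed hotspot mass
#' divided by its crossover count; an animal's usage is the mean over its
#' meioses with at least one crossover, weighted for the downstream LMM by the
#' number of meioses averaged.
#'
#' @param callset a \code{meiosis_calls} object.
#' @param hotspots a \code{hotspot_set} on the map's grid.
#' @param map the fitted \code{recombination_map} used for allocation.
#' @param method \code{"expected"} (fractional mass, default) or
#'   \code{"hard"} (a region counts as hotspot iff more than half of its
#'   rate-weighted mass lies in hotspot intervals).
#' @return data frame of \code{UsageRecord}s: \code{animal_id, sex, usage, w}.
#' @export
hotspot_usage <- function(callset, hotspots, map,
                          method = c("expected", "hard")) {
  method <- match.arg(method)
  if (!nrow(callset)) {
    return(data.frame(animal_id = character(0), sex = character(0),
                      usage = numeric(0), w = integer(0)))
  }
  offset <- attr(map, "offset")
  if (is.null(offset)) offset <- attr(map_intervals(map), "offset")
  rate <- map$rate
  hot <- hotspots$is_hotspot
  S_all <- c(0, cumsum(rate))
  S_hot <- c(0, cumsum(rate * hot))
  l <- offset[as.character(callset$chrom)] + callset$left_idx
  r <- offset[as.character(callset$chrom)] + callset$right_idx - 1L
  tot <- S_all[r + 1L] - S_all[l]
  hmass <- S_hot[r + 1L] - S_hot[l]
  frac <- ifelse(tot > 0, hmass / tot, NA_real_)
  if (anyNA(frac)) {
    # uniform fallback over the region's intervals
    C_hot <- c(0, cumsum(as.numeric(hot)))
    nz <- is.na(frac)
    frac[nz] <- (C_hot[r[nz] + 1L] - C_hot[l[nz]]) / (r[nz] - l[nz] + 1L)
  }
  # guard against floating-point drift in the long cumulative sums
  frac <- pmin(pmax(frac, 0), 1)
  if (method == "hard") frac <- as.numeric(frac > 0.5)
  per_meiosis <- tapply(frac, callset$meiosis_id, mean)
  meta <- attr(callset, "meioses")
  keep <- meta$meiosis_id %in% names(per_meiosis)
  meta <- meta[keep, , drop = FALSE]
  u <- as.numeric(per_meiosis[meta$meiosis_id])
  agg <- stats::aggregate(u, list(animal_id = meta$parent_id,
                                  sex = meta$parent_sex), mean)
  n <- stats::aggregate(u, list(animal_id = meta$parent_id,
                                sex = meta$parent_sex), length)
  data.frame(animal_id = agg$animal_id, sex = agg$sex,
             usage = agg$x, w = n$x, stringsAsFactors = FALSE)
}

#' Write hotspots as BED (0-based half-open) plus a TSV with rates
#'
#' @param hs a \code{hotspot_set}.
#' @param path_bed,path_tsv output paths (either may be NULL to skip).
#' @export
write_hotspots <- function(hs, path_bed = NULL, path_tsv = NULL) {
  sel <- hs[hs$is_hotspot, , drop = FALSE]
  if (!is.null(path_bed)) {
    bed <- data.frame(chrom = sel$chrom, start = sel$start_pos,
                      end = sel$end_pos)
    utils::write.table(bed, path_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(path_tsv)) {
    out <- sel
    out$threshold <- attr(hs, "threshold")
    write_tsv(out, path_tsv)
  }
  invisible(hs)
}
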