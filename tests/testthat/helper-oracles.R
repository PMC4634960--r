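# Independent reference implementations used as oracles.  These are written
# naively (loops, enumeration, grid search) and must stay independent of the
# package's vectorized code paths.

# --- naive crossover caller -------------------------------------------------
# Walks the informative sites, groups them into origin runs, discards runs
# shorter than min_support, and reports a call at every boundary between
# surviving runs of different origin.
oracle_call_crossovers <- function(origin, positions, min_support = 3) {
  inf <- which(!is.na(origin))
  runs <- list()
  for (i in inf) {
    k <- length(runs)
    if (k > 0 && runs[[k]]$origin == origin[i]) {
      runs[[k]]$idx <- c(runs[[k]]$idx, i)
    } else {
      runs[[k + 1]] <- list(origin = origin[i], idx = i)
    }
  }
  runs <- Filter(function(r) length(r$idx) >= min_support, runs)
  out <- NULL
  if (length(runs) >= 2) {
    for (k in seq_len(length(runs) - 1)) {
      a <- runs[[k]]; b <- runs[[k + 1]]
      if (a$origin != b$origin) {
        li <- max(a$idx); ri <- min(b$idx)
        out <- rbind(out, data.frame(left_idx = li, right_idx = ri,
                                     left_pos = positions[li],
                                     right_pos = positions[ri],
                                     n_intervals = ri - li))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(left_idx = integer(0), right_idx = integer(0),
                      left_pos = numeric(0), right_pos = numeric(0),
                      n_intervals = integer(0))
  out
}

# --- brute-force trio phasing rule ------------------------------------------
# Enumerates the transmissions consistent with the three dosages.
oracle_phase_trio <- function(o, s, d) {
  if (is.na(o)) return(list(pat = NA, mat = NA, err = FALSE))
  trans <- function(g) if (is.na(g)) 0:1 else c(if (g <= 1) 0, if (g >= 1) 1)
  sols <- NULL
  for (p in trans(s)) for (m in trans(d)) if (p + m == o)
    sols <- rbind(sols, c(p, m))
  if (is.null(sols)) return(list(pat = NA, mat = NA, err = TRUE))
  if (nrow(sols) == 1 && (o != 1 || (!is.na(s) && !is.na(d))))
    return(list(pat = sols[1, 1], mat = sols[1, 2], err = FALSE))
  list(pat = NA, mat = NA, err = FALSE)
}

# --- brute-force multinomial MLE for the EM ---------------------------------
# Maximizes sum_r log( sum_{i in region r} q_i ) over the simplex by grid
# search with recursive refinement, then rescales by total mass R/n.
simplex_grid <- function(k, m) {
  if (k == 1) return(matrix(m, ncol = 1))
  out <- NULL
  for (j in 0:m) {
    sub <- simplex_grid(k - 1, m - j)
    out <- rbind(out, cbind(j, sub))
  }
  out
}

oracle_em_mle <- function(l, r, I, n, m = 20, rounds = 8) {
  regions <- lapply(seq_along(l), function(k) l[k]:r[k])
  ll <- function(q) {
    s <- vapply(regions, function(ix) sum(q[ix]), numeric(1))
    if (any(s <= 0)) return(-Inf)
    sum(log(s))
  }
  base <- simplex_grid(I, m) / m
  center <- rep(1 / I, I)
  width <- 1
  best <- NULL
  for (rd in seq_len(rounds)) {
    pts <- sweep(sweep(base, 2, rep(1 / I, I)) * width, 2, center, `+`)
    pts[pts < 0] <- 0
    pts <- pts / rowSums(pts)
    vals <- apply(pts, 1, ll)
    best <- pts[which.max(vals), ]
    center <- best
    width <- width / 4
  }
  list(q = best, p = best * length(l) / n, loglik = ll(best))
}

# log-likelihood of a fitted rate vector under the observed regions
region_loglik <- function(p, l, r) {
  tot <- sum(p)
  q <- if (tot > 0) p / tot else p
  s <- vapply(seq_along(l), function(k) sum(q[l[k]:r[k]]), numeric(1))
  if (any(s <= 0)) return(-Inf)
  sum(log(s))
}

# --- misc fixtures ----------------------------------------------------------
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 1, chrom_lengths_bp = 1e8, n_snps = 1500,
                   total_male_morgans = 1.0, total_female_morgans = 0.9,
                   seed = 11)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Build a meiosis_calls object by hand (regions given as within-chromosome
# SNP indices).
manual_calls <- function(regions, meioses = NULL) {
  calls <- regions
  if (is.null(meioses)) {
    ids <- unique(as.character(regions$meiosis_id))
    first <- match(ids, regions$meiosis_id)
    pid <- if ("parent_id" %in% names(regions) && length(ids))
      as.character(regions$parent_id[first]) else sub(":.*", "", ids)
    meioses <- data.frame(meiosis_id = ids,
                          parent_id = pid,
                          parent_sex = rep("M", length(ids)),
                          n_informative = rep(NA_integer_, length(ids)),
                          chip_category = rep("50K", length(ids)),
                          stringsAsFactors = FALSE)
  }
  attr(calls, "meioses") <- meioses
  class(calls) <- c("meiosis_calls", "data.frame")
  calls
}
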