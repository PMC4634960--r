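# Crossover identification: grandparental-origin switches in the offspring's
# transmitted haplotype, with a minimum-support rule (default three
# consecutive informative SNPs on each flank of a switch).

#' Grandparental origin of a transmitted haplotype
#'
#' A site is informative iff the transmitting parent is heterozygous with
#' known phase and the offspring's transmitted allele at the site is assigned;
#' the origin is the parent haplotype carrying that allele (1 = the parent's
#' paternal/grandsire haplotype, 2 = maternal/granddam haplotype).
#'
#' @param transmitted offspring transmitted allele (0/1/NA), vector or matrix.
#' @param parent_pat,parent_mat the parent's labeled haplotype pair.
#' @return integer vector/matrix: 1, 2 or NA (uninformative).
#' @export
grandparental_origin <- function(transmitted, parent_pat, parent_mat) {
  informative <- !is.na(transmitted) & !is.na(parent_pat) & !is.na(parent_mat) &
    parent_pat != parent_mat
  origin <- ifelse(informative & transmitted == parent_pat, 1L,
                   ifelse(informative, 2L, NA_integer_))
  if (!is.null(dim(transmitted))) dim(origin) <- dim(transmitted)
  origin
}

#' Call crossovers from an origin vector
#'
#' Emits a crossover at each origin switch where both flanking origin runs are
#' supported by at least \code{min_support} consecutive informative SNPs.
#' Runs shorter than \code{min_support} are treated as unresolved: they
#' neither create calls nor break the flanking runs (so if the runs on both
#' sides of a skipped run share an origin, no call results).  The called
#' region spans from the last supporting SNP of the left run to the first
#' supporting SNP of the right run, covering the adjacent-SNP intervals
#' between them.
#'
#' @param origin integer vector (1/2/NA) ordered by position.
#' @param positions SNP positions (bp) aligned with \code{origin}.
#' @param min_support minimum consecutive informative SNPs per flank.
#' @param require_adjacent if \code{TRUE}, supporting SNPs must also be
#'   physically adjacent in the map (no uninformative SNPs interleaved); by
#'   default "consecutive" is read as consecutive among informative sites.
#' @return data frame with \code{left_idx, right_idx, left_pos, right_pos,
#'   n_intervals} (one row per crossover region).
#' @export
call_crossovers <- function(origin, positions, min_support = 3,
                            require_adjacent = FALSE) {
  if (min_support < 1) abort("min_support must be >= 1")
  inf <- which(!is.na(origin))
  if (length(inf) < 2) return(empty_regions())
  o <- origin[inf]
  run_id <- cumsum(c(TRUE, o[-1] != o[-length(o)]))
  run_len <- tabulate(run_id)
  if (require_adjacent) {
    # support = longest block of map-adjacent informative SNPs within the run
    blk <- cumsum(c(TRUE, diff(inf) > 1)) + run_id * (max(inf) + 1)
    blk_len <- tapply(rep(1L, length(inf)), blk, sum)
    blk_run <- tapply(run_id, blk, `[`, 1)
    support <- rep(0L, length(run_len))
    agg <- tapply(as.integer(blk_len), as.integer(blk_run), max)
    support[as.integer(names(agg))] <- agg
  } else {
    support <- run_len
  }
  keep <- which(support >= min_support)
  if (length(keep) < 2) return(empty_regions())
  run_start <- c(1, cumsum(run_len)[-length(run_len)] + 1)
  run_end <- cumsum(run_len)
  run_origin <- o[run_start]
  ko <- run_origin[keep]
  switch_at <- which(ko[-1] != ko[-length(ko)])
  if (!length(switch_at)) return(empty_regions())
  left_run <- keep[switch_at]
  right_run <- keep[switch_at + 1]
  li <- inf[run_end[left_run]]
  ri <- inf[run_start[right_run]]
  data.frame(left_idx = li, right_idx = ri,
             left_pos = positions[li], right_pos = positions[ri],
             n_intervals = ri - li)
}

empty_regions <- function() {
  data.frame(left_idx = integer(0), right_idx = integer(0),
             left_pos = numeric(0), right_pos = numeric(0),
             n_intervals = integer(0))
}

empty_calls <- function() {
  cbind(data.frame(meiosis_id = character(0), parent_id = character(0),
                   parent_sex = character(0), chrom = integer(0)),
        empty_regions())
}

as_meiosis_calls <- function(calls, meioses) {
  rownames(calls) <- NULL
  attr(calls, "meioses") <- meioses
  class(calls) <- c("meiosis_calls", "data.frame")
  calls
}

#' Call crossovers for every phased meiosis
#'
#' Runs origin assignment and crossover calling per meiosis per chromosome.
#'
#' @param phased a \code{phased_meioses} object.
#' @param snp_map SNP map data frame (\code{chrom}, \code{snp_id},
#'   \code{pos_bp}) matching the phased matrices' columns.
#' @param gt optional \code{genotype_table} used to annotate each meiosis
#'   with its chip category (offspring x parent x grandsire panel combo).
#' @param min_support,require_adjacent see \code{\link{call_crossovers}}.
#' @return object of class \code{meiosis_calls}: data frame of crossover
#'   regions (meiosis_id, parent_id, parent_sex, chrom, left_idx, right_idx,
#'   left_pos, right_pos, n_intervals; indices are within-chromosome), with a
#'   \code{meioses} attribute listing every analyzed meiosis, its informative
#'   SNP count and chip category.
#' @export
call_crossover_set <- function(phased, snp_map, gt = NULL, min_support = 3,
                               require_adjacent = FALSE) {
  fam <- phased$families
  chroms <- split(seq_len(nrow(snp_map)), snp_map$chrom)
  res <- list()
  meta <- list()
  for (side in c("paternal", "maternal")) {
    ph <- phased[[side]]
    sex <- if (side == "paternal") "M" else "F"
    parent <- if (side == "paternal") fam$sire else fam$dam
    gs <- if (side == "paternal") fam$pgs else fam$mgs
    origin <- grandparental_origin(ph$transmitted, ph$parent_pat, ph$parent_mat)
    mids <- paste0(fam$offspring, ":", if (sex == "M") "P" else "M")
    chip_cat <- if (!is.null(gt))
      paste(gt$chip[fam$offspring], gt$chip[parent], gt$chip[gs], sep = "x")
    else rep(NA_character_, nrow(fam))
    meta[[side]] <- data.frame(meiosis_id = mids, parent_id = parent,
                               parent_sex = sex,
                               n_informative = rowSums(!is.na(origin)),
                               chip_category = chip_cat,
                               stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fam))) {
      ovec <- origin[i, ]
      for (cc in names(chroms)) {
        j <- chroms[[cc]]
        regs <- call_crossovers(ovec[j], snp_map$pos_bp[j], min_support,
                                require_adjacent)
        if (nrow(regs)) {
          res[[length(res) + 1]] <- cbind(
            data.frame(meiosis_id = mids[i], parent_id = parent[i],
                       parent_sex = sex, chrom = as.integer(cc),
                       stringsAsFactors = FALSE),
            regs)
        }
      }
    }
  }
  calls <- if (length(res)) do.call(rbind, res) else empty_calls()
  as_meiosis_calls(calls, do.call(rbind, meta))
}

#' Power of crossover detection against simulated truth
#'
#' A true crossover is a positive when some called region in the same meiosis
#' and chromosome spans its position.  Power is the proportion of positives
#' among all true crossovers of the analyzed meioses.
#'
#' @param callset a \code{meiosis_calls} object.
#' @param truth data frame of true crossovers (\code{meiosis_id}, \code{chrom},
#'   \code{pos_bp}), e.g. \code{sim$truth$crossovers}.
#' @return list with \code{power}, \code{n_true}, \code{n_positive}.
#' @export
detection_power <- function(callset, truth) {
  meioses <- attr(callset, "meioses")$meiosis_id
  truth <- truth[truth$meiosis_id %in% meioses, , drop = FALSE]
  if (!nrow(truth)) abort("no true crossovers for the analyzed meioses")
  tkey <- paste(truth$meiosis_id, truth$chrom)
  ckey <- paste(callset$meiosis_id, callset$chrom)
  regs <- split(callset[, c("left_pos", "right_pos")], ckey)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    r <- regs[[tkey[i]]]
    if (is.null(r)) return(FALSE)
    any(r$left_pos <= truth$pos_bp[i] & truth$pos_bp[i] <= r$right_pos)
  }, logical(1))
  list(power = mean(hits), n_true = nrow(truth), n_positive = sum(hits))
}

#' End-to-end crossover-detection power study
#'
#' Simulates three-generation families chromosome by chromosome, runs family
#' extraction, trio phasing and crossover calling, and scores the called
#' regions against the simulator's true crossover locations.  Only the
#' offspring's paternal and maternal meioses are evaluated (the meioses the
#' family design observes).
#'
#' @param config a \code{sim_config}.
#' @param n_families number of families to simulate.
#' @param min_support,require_adjacent see \code{\link{call_crossovers}}.
#' @param chromosomes chromosomes to include (default all in config).
#' @return list with overall \code{power}, \code{n_true}, \code{n_positive},
#'   \code{n_meioses} and a per-chromosome data frame.
#' @export
crossover_power_study <- function(config, n_families, min_support = 3,
                                  require_adjacent = FALSE,
                                  chromosomes = NULL) {
  chromosomes <- chromosomes %||% seq_len(config$n_chromosomes)
  per <- vector("list", length(chromosomes))
  n_meioses <- NA_integer_
  for (k in seq_along(chromosomes)) {
    cc <- chromosomes[k]
    sim <- simulate_pedigree(config, n_families, chromosomes = cc)
    fams <- extract_families(sim$pedigree,
                             rownames(sim$genotypes$geno))
    phased <- phase_families(sim$genotypes, fams)
    calls <- call_crossover_set(phased, sim$genotypes$map, sim$genotypes,
                                min_support = min_support,
                                require_adjacent = require_adjacent)
    pw <- detection_power(calls, sim$truth$crossovers)
    per[[k]] <- data.frame(chrom = cc, n_true = pw$n_true,
                           n_positive = pw$n_positive, power = pw$power)
    n_meioses <- nrow(attr(calls, "meioses"))
  }
  per <- do.call(rbind, per)
  list(power = sum(per$n_positive) / sum(per$n_true),
       n_true = sum(per$n_true), n_positive = sum(per$n_positive),
       n_meioses = n_meioses, per_chromosome = per)
}
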