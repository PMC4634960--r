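# File formats, validation, and three-generation family extraction.
#
# Coordinates are 1-based bp.  Adjacent-SNP intervals are half-open
# (pos_i, pos_{i+1}]; all interval accounting downstream relies on this.

#' Genotype table
#'
#' Container pairing a SNP map with a dosage matrix.
#'
#' @param map data frame with columns \code{chrom}, \code{snp_id},
#'   \code{pos_bp}; positions must be strictly increasing within chromosome.
#' @param geno integer matrix, animals x SNPs, dosages in \{0, 1, 2, NA\};
#'   rownames are animal ids, colnames match \code{map$snp_id}.
#' @param chip optional named character vector of chip labels per animal.
#' @return object of class \code{genotype_table}.
#' @export
genotype_table <- function(map, geno, chip = NULL) {
  stopifnot(is.data.frame(map), all(c("chrom", "snp_id", "pos_bp") %in% names(map)))
  if (anyDuplicated(map$snp_id)) abort("duplicated SNP ids in map")
  bad <- unlist(lapply(split(map$pos_bp, map$chrom), function(p) any(diff(p) <= 0)))
  if (any(bad)) abort("SNP positions must be strictly increasing within chromosome")
  if (ncol(geno) != nrow(map)) abort("genotype matrix does not match SNP map")
  rng <- range(geno, na.rm = TRUE)
  if (!all(is.na(geno)) && (rng[1] < 0 || rng[2] > 2))
    abort("dosages must lie in {0, 1, 2, NA}")
  if (is.null(colnames(geno))) colnames(geno) <- map$snp_id
  if (!identical(colnames(geno), map$snp_id)) abort("genotype columns must match map snp ids")
  if (is.null(rownames(geno))) abort("genotype matrix needs animal-id rownames")
  if (is.null(chip)) chip <- stats::setNames(rep("50K", nrow(geno)), rownames(geno))
  structure(list(map = map, geno = geno, chip = chip), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a genotype table by chromosome
#' @param gt a \code{genotype_table}.
#' @param chroms chromosomes to keep.
#' @export
subset_chromosomes <- function(gt, chroms) {
  keep <- gt$map$chrom %in% chroms
  genotype_table(gt$map[keep, , drop = FALSE],
                 gt$geno[, keep, drop = FALSE], gt$chip)
}

#' Remove SNPs from a genotype table
#'
#' Drops blacklisted SNPs from the map and matrix consistently.  Unknown ids
#' produce a warning and are skipped.
#'
#' @param gt a \code{genotype_table}.
#' @param blacklist character vector of SNP ids to remove.
#' @export
drop_snps <- function(gt, blacklist) {
  unknown <- setdiff(blacklist, gt$map$snp_id)
  if (length(unknown))
    warning("ignoring ", length(unknown), " unknown SNP id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
  keep <- !(gt$map$snp_id %in% blacklist)
  genotype_table(gt$map[keep, , drop = FALSE],
                 gt$geno[, keep, drop = FALSE], gt$chip)
}

#' Read / write a pedigree table
#'
#' Pedigree TSV columns: \code{id, sire, dam, sex, birth_year, chip,
#' genotyped}.  Missing parents are empty/NA.
#'
#' @param ped pedigree data frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) write_tsv(ped, path)

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv(path)
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[ped$sire %in% c("", "NA", "0")] <- NA
  ped$dam[ped$dam %in% c("", "NA", "0")] <- NA
  rownames(ped) <- ped$id
  ped
}

#' Write / read genotypes
#'
#' Two text dialects: \code{"tsv"} (one file: snp_id, chrom, pos_bp, then one
#' dosage column per animal, \code{NA} for missing) and \code{"plink"}
#' (\code{.ped}/\code{.map} pair with A/B allele coding and \code{0 0} for
#' missing).  A write-then-read round trip is the identity, including missing
#' codes.
#'
#' @param gt a \code{genotype_table}.
#' @param path output path; for \code{"plink"} it is the stem of the
#'   \code{.ped}/\code{.map} pair.
#' @param dialect \code{"tsv"} or \code{"plink"}.
#' @export
write_genotypes <- function(gt, path, dialect = c("tsv", "plink")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- cbind(gt$map[, c("snp_id", "chrom", "pos_bp")],
                 as.data.frame(t(gt$geno)))
    write_tsv(out, path)
  } else {
    map <- data.frame(chrom = gt$map$chrom, snp_id = gt$map$snp_id,
                      cm = 0, pos_bp = gt$map$pos_bp)
    utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    code <- c(`0` = "A A", `1` = "A B", `2` = "B B")
    g <- gt$geno
    alle <- matrix("0 0", nrow(g), ncol(g))
    obs <- !is.na(g)
    alle[obs] <- code[as.character(g[obs])]
    ped <- cbind(FAM = "FAM1", ID = rownames(g), PAT = "0", MAT = "0",
                 SEX = "0", PHE = "-9", alle)
    utils::write.table(ped, paste0(path, ".ped"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    x <- read_tsv(path)
    map <- data.frame(chrom = x$chrom, snp_id = as.character(x$snp_id),
                      pos_bp = x$pos_bp, stringsAsFactors = FALSE)
    geno <- t(as.matrix(x[, setdiff(names(x), c("snp_id", "chrom", "pos_bp")),
                          drop = FALSE]))
    storage.mode(geno) <- "integer"
    colnames(geno) <- map$snp_id
    genotype_table(map, geno)
  } else {
    map <- utils::read.table(paste0(path, ".map"), header = FALSE,
                             stringsAsFactors = FALSE)
    names(map) <- c("chrom", "snp_id", "cm", "pos_bp")
    ped <- utils::read.table(paste0(path, ".ped"), header = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(ped[[2]])
    al <- as.matrix(ped[, -(1:6), drop = FALSE])
    n_snp <- ncol(al) / 2
    if (n_snp != nrow(map)) abort("ped/map SNP count mismatch")
    a1 <- al[, 2 * seq_len(n_snp) - 1, drop = FALSE]
    a2 <- al[, 2 * seq_len(n_snp), drop = FALSE]
    geno <- (a1 == "B") + (a2 == "B")
    geno[a1 == "0" | a2 == "0"] <- NA
    storage.mode(geno) <- "integer"
    rownames(geno) <- ids
    colnames(geno) <- map$snp_id
    genotype_table(map[, c("chrom", "snp_id", "pos_bp")], geno)
  }
}

# Kahn-style acyclicity check on the pedigree graph (parent -> child edges)
check_acyclic <- function(ped) {
  ids <- ped$id
  idx <- match(ids, ids)
  parents <- cbind(match(ped$sire, ids), match(ped$dam, ids))
  indeg <- rowSums(!is.na(parents))
  children <- split(rep(seq_along(ids), 2)[!is.na(c(parents))],
                    c(parents)[!is.na(c(parents))])
  queue <- which(indeg == 0)
  seen <- 0
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1
    for (ch in children[[as.character(v)]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) abort("pedigree contains a cycle")
  invisible(TRUE)
}

#' Extract three-generation families
#'
#' Returns every offspring whose sire, dam and both grandsires are genotyped.
#' Granddam genotyping status is recorded (0/1/2) but not required.  An animal
#' may appear in more than one family (e.g. a bull as sire of many offspring).
#'
#' @param ped pedigree data frame (columns \code{id, sire, dam, sex}).
#' @param genotyped_ids character vector of genotyped animal ids.
#' @return data frame of class \code{trio_families} with columns
#'   \code{offspring, sire, dam, pgs, pgd, mgs, mgd, n_granddams} (ungenotyped
#'   granddams are NA in \code{pgd}/\code{mgd}).
#' @export
extract_families <- function(ped, genotyped_ids) {
  check_acyclic(ped)
  g <- function(x) !is.na(x) & x %in% genotyped_ids
  sire_sex <- ped$sex[match(ped$sire, ped$id)]
  dam_sex <- ped$sex[match(ped$dam, ped$id)]
  if (any(sire_sex == "F", na.rm = TRUE) || any(dam_sex == "M", na.rm = TRUE))
    abort("pedigree sex inconsistency: sires must be male and dams female")

  look <- function(ids, col) ped[[col]][match(ids, ped$id)]
  off <- ped$id
  sire <- ped$sire
  dam <- ped$dam
  pgs <- look(sire, "sire"); pgd <- look(sire, "dam")
  mgs <- look(dam, "sire"); mgd <- look(dam, "dam")
  ok <- g(off) & g(sire) & g(dam) & g(pgs) & g(mgs)
  fam <- data.frame(offspring = off, sire = sire, dam = dam,
                    pgs = pgs, pgd = ifelse(g(pgd), pgd, NA),
                    mgs = mgs, mgd = ifelse(g(mgd), mgd, NA),
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  fam$n_granddams <- (!is.na(fam$pgd)) + (!is.na(fam$mgd))
  rownames(fam) <- NULL
  class(fam) <- c("trio_families", "data.frame")
  fam
}
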