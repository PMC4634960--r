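# Rule-based within-family phasing.  Homozygous genotypes phase trivially;
# heterozygous genotypes phase whenever the two parents are not both
# heterozygous.  No LD and no multi-offspring pooling: each site is phased
# from the trio alone, so paternal and maternal meioses are treated on an
# equal footing.

# Lookup tables over dosage triples (child, father-side, mother-side), with
# code 3 = missing.  For each combination we enumerate the transmissions
# consistent with Mendelian inheritance (a parent with dosage g can transmit
# allele 0 if g <= 1 and allele 1 if g >= 1; a missing parent can transmit
# either): a unique consistent pair phases the site, none flags a Mendelian
# error, several leaves the site unknown.  Heterozygous children additionally
# require both parents observed (conservative handling of missing data).
.trio_tables <- local({
  pat <- mat <- rep(NA_integer_, 64)
  err <- rep(FALSE, 64)
  enc <- function(o, s, d) 1 + o + 4 * s + 16 * d
  for (o in 0:2) for (s in 0:3) for (d in 0:3) {
    ps <- if (s == 3) 0:1 else as.integer(c(if (s <= 1) 0, if (s >= 1) 1))
    pd <- if (d == 3) 0:1 else as.integer(c(if (d <= 1) 0, if (d >= 1) 1))
    cmb <- expand.grid(p = ps, m = pd)
    cmb <- cmb[cmb$p + cmb$m == o, , drop = FALSE]
    i <- enc(o, s, d)
    if (nrow(cmb) == 0) {
      err[i] <- TRUE
    } else if (nrow(cmb) == 1) {
      if (o != 1 || (s != 3 && d != 3)) {
        pat[i] <- cmb$p
        mat[i] <- cmb$m
      }
    }
  }
  list(pat = pat, mat = mat, err = err)
})

.code3 <- function(g) {
  g <- as.integer(g)
  g[is.na(g)] <- 3L
  g
}

#' Phase an offspring against its two parents
#'
#' Assigns the paternal and maternal allele of the offspring at each SNP.
#' Homozygous sites are phased trivially; heterozygous sites are phased
#' whenever the sire and dam are not both heterozygous.  Sites inconsistent
#' with Mendelian inheritance are flagged and left unknown.
#'
#' @param offspring,sire,dam dosage vectors or matrices (0/1/2/NA) of equal
#'   shape, on a common SNP set.
#' @return list with \code{paternal}, \code{maternal} (0/1/NA, same shape as
#'   the input) and \code{mendelian} (logical error flags).
#' @export
phase_offspring <- function(offspring, sire, dam) {
  if (length(offspring) != length(sire) || length(offspring) != length(dam))
    abort("offspring/sire/dam length mismatch")
  o <- .code3(offspring); s <- .code3(sire); d <- .code3(dam)
  idx <- 1L + o + 4L * s + 16L * d
  idx[o == 3L] <- NA_integer_
  pat <- .trio_tables$pat[idx]
  mat <- .trio_tables$mat[idx]
  err <- .trio_tables$err[idx]
  err[is.na(err)] <- FALSE
  shape <- function(x) { attributes(x) <- attributes(offspring)["dim"]; x }
  if (!is.null(dim(offspring))) {
    dim(pat) <- dim(mat) <- dim(err) <- dim(offspring)
  }
  list(paternal = pat, maternal = mat, mendelian = err)
}

#' Phase a parent against its own parents
#'
#' Applies the trio rules with the parent as the child (grandsire as father,
#' granddam as mother) where the granddam's genotype is available.  Where it
#' is not, a homozygous parent still phases trivially and a heterozygous
#' parent is phased only if the grandsire is homozygous: the grandsire's
#' allele is assigned to the parent's paternal haplotype and the remaining
#' allele to the maternal haplotype.
#'
#' @param parent,grandsire dosage vectors or matrices of equal shape.
#' @param granddam dosage data for the granddam, or \code{NULL} when she is
#'   not genotyped; missing entries fall back to the grandsire-only rule.
#' @return list with \code{paternal}, \code{maternal} (the parent's labeled
#'   haplotype pair) and \code{mendelian} flags.
#' @export
phase_parent <- function(parent, grandsire, granddam = NULL) {
  if (length(parent) != length(grandsire))
    abort("parent/grandsire length mismatch")
  if (is.null(granddam)) granddam <- rep(NA_integer_, length(parent))
  if (length(granddam) != length(parent))
    abort("parent/granddam length mismatch")
  p <- .code3(parent); gs <- .code3(grandsire); gd <- .code3(granddam)

  out_p <- rep(NA_integer_, length(p))
  out_m <- rep(NA_integer_, length(p))
  err <- rep(FALSE, length(p))

  tri <- gd != 3L
  if (any(tri)) {
    idx <- 1L + p[tri] + 4L * gs[tri] + 16L * gd[tri]
    idx[p[tri] == 3L] <- NA_integer_
    out_p[tri] <- .trio_tables$pat[idx]
    out_m[tri] <- .trio_tables$mat[idx]
    e <- .trio_tables$err[idx]
    e[is.na(e)] <- FALSE
    err[tri] <- e
  }
  solo <- !tri & p != 3L
  if (any(solo)) {
    pp <- p[solo]; gg <- gs[solo]
    sp <- rep(NA_integer_, sum(solo)); sm <- sp
    se <- (pp == 0L & gg == 2L) | (pp == 2L & gg == 0L)
    hom <- pp != 1L & !se
    sp[hom] <- pp[hom] %/% 2L
    sm[hom] <- sp[hom]
    het <- pp == 1L & gg %in% c(0L, 2L)
    sp[het] <- gg[het] %/% 2L
    sm[het] <- 1L - sp[het]
    out_p[solo] <- sp; out_m[solo] <- sm; err[solo] <- se
  }
  if (!is.null(dim(parent))) dim(out_p) <- dim(out_m) <- dim(err) <- dim(parent)
  list(paternal = out_p, maternal = out_m, mendelian = err)
}

#' Phase all meioses of a family set
#'
#' Vectorized trio phasing over an extracted family table: phases every
#' offspring against its parents and every parent against its own parents,
#' yielding for each family one paternal and one maternal phased meiosis.
#'
#' @param gt a \code{genotype_table} containing all family members.
#' @param families a \code{trio_families} table.
#' @param mendel_flag_rate families whose fraction of Mendelian-inconsistent
#'   sites (across the offspring trio) exceeds this are flagged.
#' @return object of class \code{phased_meioses}: a list with elements
#'   \code{paternal} and \code{maternal}, each containing matrices
#'   (families x SNPs) \code{transmitted}, \code{parent_pat},
#'   \code{parent_mat}; plus \code{families}, \code{mendel_rate} and
#'   \code{flagged}.
#' @export
phase_families <- function(gt, families, mendel_flag_rate = 0.02) {
  if (!nrow(families)) abort("no families to phase")
  G <- gt$geno
  row_of <- function(ids) {
    m <- matrix(NA_integer_, length(ids), ncol(G))
    ok <- !is.na(ids) & ids %in% rownames(G)
    if (any(ok)) m[ok, ] <- G[ids[ok], , drop = FALSE]
    m
  }
  O <- row_of(families$offspring)
  S <- row_of(families$sire)
  D <- row_of(families$dam)
  off <- phase_offspring(O, S, D)
  sire_hap <- phase_parent(S, row_of(families$pgs), row_of(families$pgd))
  dam_hap <- phase_parent(D, row_of(families$mgs), row_of(families$mgd))

  mendel_rate <- rowMeans(off$mendelian)
  structure(list(
    paternal = list(transmitted = off$paternal,
                    parent_pat = sire_hap$paternal,
                    parent_mat = sire_hap$maternal),
    maternal = list(transmitted = off$maternal,
                    parent_pat = dam_hap$paternal,
                    parent_mat = dam_hap$maternal),
    families = families,
    mendel_rate = mendel_rate,
    flagged = mendel_rate > mendel_flag_rate),
    class = "phased_meioses")
}
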