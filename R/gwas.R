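# Association scans of recombination phenotypes with a linear mixed model
# whose residual variances are inversely proportional to the number of
# repeated measurements:
#   y = X g + Z a + e,  a ~ N(0, A sigma_a^2),  e ~ N(0, R sigma_e^2),
# with A a genomic relationship matrix and R = diag(1/w).  Variance
# components are REML-estimated once on the null model and held fixed across
# SNPs; per-SNP tests are generalized least squares with a per-SNP residual
# scale, so with A = I and equal weights the scan reduces exactly to ordinary
# regression.

#' Build animal-level recombination phenotypes
#'
#' Aggregates per-meiosis measurements into one record per animal: the
#' phenotype is the mean over the animal's meioses and the weight w is the
#' number of meioses (used as inverse residual-variance weights in the LMM).
#'
#' @param callset a \code{meiosis_calls} object.
#' @param kind \code{"rate"} (crossover count per meiosis, optionally
#'   chip-corrected), \code{"subtelomeric"} (count of crossovers whose region
#'   midpoint lies in the terminal \code{subtel_frac} of its chromosome), or
#'   \code{"usage"} (delegates to \code{\link{hotspot_usage}}).
#' @param corrections optional result of \code{\link{chip_correct}} applied to
#'   this callset's counts (used for \code{kind = "rate"}).
#' @param chrom_lengths named chromosome lengths in bp (needed for
#'   \code{"subtelomeric"}).
#' @param subtel_frac terminal fraction of the chromosome counted as
#'   subtelomeric (cattle autosomes are acrocentric, so only the telomeric
#'   end qualifies).
#' @param hotspots,map passed to \code{hotspot_usage} for \code{kind="usage"}.
#' @return data frame with \code{animal_id, sex, y, w}.
#' @export
build_phenotypes <- function(callset, kind = c("rate", "usage", "subtelomeric"),
                             corrections = NULL, chrom_lengths = NULL,
                             subtel_frac = 0.15, hotspots = NULL, map = NULL) {
  kind <- match.arg(kind)
  meta <- attr(callset, "meioses")
  if (kind == "usage") {
    u <- hotspot_usage(callset, hotspots, map)
    return(data.frame(animal_id = u$animal_id, sex = u$sex, y = u$usage,
                      w = u$w, stringsAsFactors = FALSE))
  }
  if (kind == "rate") {
    if (!is.null(corrections)) {
      cc <- corrections$counts
      counts <- stats::setNames(cc$count_corrected, cc$meiosis_id)[meta$meiosis_id]
    } else {
      tab <- table(factor(callset$meiosis_id, levels = meta$meiosis_id))
      counts <- as.numeric(tab)
    }
  } else {
    if (is.null(chrom_lengths)) abort("subtelomeric phenotype needs chrom_lengths")
    midpoint <- (callset$left_pos + callset$right_pos) / 2
    rel <- midpoint / chrom_lengths[as.character(callset$chrom)]
    sub <- callset[rel > 1 - subtel_frac, , drop = FALSE]
    tab <- table(factor(sub$meiosis_id, levels = meta$meiosis_id))
    counts <- as.numeric(tab)
  }
  keep <- !is.na(counts)
  df <- data.frame(animal_id = meta$parent_id[keep], sex = meta$parent_sex[keep],
                   count = counts[keep], stringsAsFactors = FALSE)
  if (!nrow(df)) abort("no meioses with usable counts")
  agg <- stats::aggregate(count ~ animal_id + sex, df, mean)
  n <- stats::aggregate(count ~ animal_id + sex, df, length)
  data.frame(animal_id = agg$animal_id, sex = agg$sex, y = agg$count,
             w = n$count, stringsAsFactors = FALSE)
}

#' Filter SNPs for association testing
#'
#' Drops SNPs with minor allele frequency below \code{maf_min}; then, within
#' each chromosome in position order, greedily drops any SNP whose dosage
#' correlation with one of the previous \code{window} kept SNPs exceeds
#' \code{r_max} in absolute value (duplicated columns, r = 1, are always
#' dropped).
#'
#' @param gt a \code{genotype_table}.
#' @param maf_min minimum minor allele frequency.
#' @param r_max maximum absolute pairwise correlation.
#' @param window number of preceding kept SNPs checked.
#' @return character vector of kept SNP ids, with a \code{dropped} attribute
#'   (data frame of id and reason).
#' @export
filter_snps <- function(gt, maf_min = 0.001, r_max = 0.95, window = 50) {
  G <- gt$geno
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  dropped <- list()
  low <- maf < maf_min | is.na(maf)
  if (any(low))
    dropped[[1]] <- data.frame(snp_id = colnames(G)[low], reason = "maf")
  keep_ids <- character(0)
  for (cc in unique(gt$map$chrom)) {
    idx <- which(gt$map$chrom == cc & !low)
    kept <- integer(0)
    for (j in idx) {
      if (length(kept)) {
        prev <- utils::tail(kept, window)
        r <- suppressWarnings(stats::cor(G[, j], G[, prev, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        if (any(abs(r) > r_max, na.rm = TRUE)) {
          dropped[[length(dropped) + 1]] <-
            data.frame(snp_id = colnames(G)[j], reason = "ld")
          next
        }
      }
      kept <- c(kept, j)
    }
    keep_ids <- c(keep_ids, colnames(G)[kept])
  }
  attr(keep_ids, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
  else data.frame(snp_id = character(0), reason = character(0))
  keep_ids
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' A = Z Z' / (2 sum p(1-p)) with Z the dosage matrix centered at twice the
#' observed allele frequencies.  Missing dosages are imputed to the column
#' mean before centering.
#'
#' @param gt a \code{genotype_table} or a dosage matrix (animals x SNPs).
#' @param ridge small value added to the diagonal to keep the matrix
#'   numerically positive semi-definite.
#' @return symmetric PSD matrix with animal ids as dimnames.
#' @export
grm <- function(gt, ridge = 1e-8) {
  G <- if (inherits(gt, "genotype_table")) gt$geno else gt
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  p <- colMeans(G, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    abort("monomorphic SNP(s) in GRM input; filter them first")
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(G, 2, 2 * p)
  A <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  diag(A) <- diag(A) + ridge
  dimnames(A) <- list(rownames(G), rownames(G))
  A
}

#' REML fit of the weighted-residual null model
#'
#' Estimates (sigma_a^2, sigma_e^2) for y = X g + a + e with
#' a ~ N(0, A sigma_a^2), e ~ N(0, diag(1/w) sigma_e^2), by profiling the
#' REML likelihood over the variance ratio lambda = sigma_a^2 / sigma_e^2 on
#' the spectral decomposition of the weight-standardized A.
#'
#' @param phenotypes data frame with \code{animal_id, y, w}.
#' @param A genomic relationship matrix with matching dimnames.
#' @param covariates optional numeric matrix/data frame of fixed covariates
#'   (an intercept is always included), rows aligned with \code{phenotypes}.
#' @return object of class \code{recpipe_lmm} with variance components and the
#'   cached rotation used by \code{\link{lmm_scan}}.
#' @export
fit_null <- function(phenotypes, A, covariates = NULL) {
  ids <- phenotypes$animal_id
  if (is.null(rownames(A)) || !all(ids %in% rownames(A)))
    abort("A must carry dimnames covering all phenotype animals")
  A <- A[ids, ids]
  n <- length(ids)
  y <- phenotypes$y
  w <- phenotypes$w
  if (any(w <= 0)) abort("weights must be positive")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  t <- sqrt(w)
  At <- A * tcrossprod(t)
  eg <- eigen(At, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d))) abort("A is not positive semi-definite")
  d <- pmax(d, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, t * y))
  Xs <- crossprod(U, t * X)

  p <- ncol(X)
  reml <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- lam * d + 1
    Xw <- Xs / sqrt(v)
    yw <- ys / sqrt(v)
    qx <- qr(Xw)
    res <- qr.resid(qx, yw)
    rss <- sum(res^2)
    s2 <- rss / (n - p)
    Rd <- abs(diag(qr.R(qx)))
    -0.5 * ((n - p) * log(s2) + sum(log(v)) + 2 * sum(log(Rd)) + (n - p))
  }
  grid <- seq(log(1e-6), log(1e6), length.out = 41)
  vals <- vapply(grid, reml, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE)
  lam <- exp(opt$maximum)
  # boundary: compare against lambda -> 0
  if (reml(log(1e-12)) >= opt$objective) lam <- 0
  v <- lam * d + 1
  Xw <- Xs / sqrt(v)
  yw <- ys / sqrt(v)
  qx <- qr(Xw)
  s2 <- sum(qr.resid(qx, yw)^2) / (n - p)
  structure(list(sigma_a2 = lam * s2, sigma_e2 = s2, lambda = lam,
                 U = U, d = d, ys = ys, Xs = Xs, ids = ids, t = t, n = n,
                 reml_loglik = reml(log(max(lam, 1e-12)))),
            class = "recpipe_lmm")
}

rotate_snps <- function(fit, gt, snp_ids = NULL) {
  G <- gt$geno[fit$ids, , drop = FALSE]
  if (!is.null(snp_ids)) G <- G[, snp_ids, drop = FALSE]
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  }
  list(G = G, Gs = crossprod(fit$U, fit$t * G))
}

#' Mixed-model association scan
#'
#' Tests each SNP by generalized least squares with the covariance structure
#' V = A sigma_a^2 + diag(1/w) sigma_e^2 held at the null REML estimates
#' (the residual scale is re-estimated per SNP, so the test is an exact
#' t-test under the fixed correlation structure).  Conditional analyses add
#' the listed SNPs as fixed covariates.
#'
#' @param fit a \code{recpipe_lmm} from \code{\link{fit_null}}.
#' @param gt a \code{genotype_table} containing the phenotyped animals.
#' @param snp_ids SNPs to test (default: all in \code{gt}).
#' @param condition_snps SNP ids added as fixed covariates (conditional
#'   analysis); a test SNP collinear with the covariates is skipped with NA.
#' @param threshold significance threshold; default Bonferroni 0.05 / #tests.
#' @return data frame of class \code{scan_result}: \code{snp_id, chrom, pos,
#'   freq, beta, se, p}, with \code{threshold} attribute.
#' @export
lmm_scan <- function(fit, gt, snp_ids = NULL, condition_snps = NULL,
                     threshold = NULL) {
  snp_ids <- snp_ids %||% gt$map$snp_id
  snp_ids <- setdiff(snp_ids, condition_snps)
  rot <- rotate_snps(fit, gt, snp_ids)
  v <- fit$lambda * fit$d + 1
  sw <- 1 / sqrt(v)
  X0 <- fit$Xs
  if (!is.null(condition_snps)) {
    cond <- rotate_snps(fit, gt, condition_snps)
    X0 <- cbind(X0, cond$Gs)
  }
  Xw <- X0 * sw
  yw <- fit$ys * sw
  Gw <- rot$Gs * sw
  qx <- qr(Xw)
  ry <- qr.resid(qx, yw)
  RG <- qr.resid(qx, Gw)
  gg <- colSums(RG^2)
  gy <- colSums(RG * ry)
  df <- fit$n - ncol(X0) - 1
  beta <- gy / gg
  rss <- pmax(sum(ry^2) - beta * gy, 0)
  s2 <- rss / df
  se <- sqrt(s2 / gg)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- gg <= max(gg, 0) * 1e-12 | !is.finite(gg)
  if (any(degenerate)) {
    warning(sum(degenerate), " SNP(s) collinear with covariates; skipped")
    beta[degenerate] <- se[degenerate] <- pval[degenerate] <- NA_real_
  }
  m <- match(snp_ids, gt$map$snp_id)
  out <- data.frame(snp_id = snp_ids, chrom = gt$map$chrom[m],
                    pos = gt$map$pos_bp[m],
                    freq = colMeans(rot$G) / 2,
                    beta = beta, se = se, p = pval,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- threshold %||% (0.05 / sum(!degenerate))
  attr(out, "df") <- df
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Joint fit of several SNPs as fixed effects
#'
#' Fits all listed SNPs simultaneously in one generalized-least-squares model
#' (the usual follow-up after a scan: effects and p-values of the significant
#' SNPs adjusted for one another).
#'
#' @param fit a \code{recpipe_lmm}.
#' @param gt a \code{genotype_table}.
#' @param snp_ids SNPs to fit jointly.
#' @return data frame \code{snp_id, beta, se, p}.
#' @export
lmm_joint <- function(fit, gt, snp_ids) {
  rot <- rotate_snps(fit, gt, snp_ids)
  v <- fit$lambda * fit$d + 1
  sw <- 1 / sqrt(v)
  X <- cbind(fit$Xs, rot$Gs) * sw
  yw <- fit$ys * sw
  qx <- qr(X)
  cf <- qr.coef(qx, yw)
  res <- qr.resid(qx, yw)
  df <- fit$n - qx$rank
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * diag(XtX_inv))
  k <- ncol(fit$Xs)
  idx <- k + seq_along(snp_ids)
  beta <- cf[idx]
  se <- se[idx]
  tstat <- beta / se
  data.frame(snp_id = snp_ids, beta = beta, se = se,
             p = 2 * stats::pt(-abs(tstat), df), row.names = NULL)
}
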