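`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a deterministic, headered TSV
#'
#' All on-disk tables produced by the pipeline go through this writer so that
#' reruns with the same inputs are byte-identical.
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# stop() with the calling function's name stripped of namespace noise
abort <- function(...) stop(..., call. = FALSE)

# Genomic inflation factor of a p-value vector (median chi-square method).
#' Genomic inflation factor
#'
#' Lambda is the median association chi-square divided by the null median;
#' values near 1 indicate a well-calibrated scan.
#'
#' @param p vector of p-values.
#' @return scalar lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}
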