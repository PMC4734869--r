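#' Genotype matrix container
#'
#' Couples an `n x p` matrix of allele-dosage codes (0 = AA, 1 = AB, 2 = BB,
#' `NA` = missing, counting copies of the B allele) with per-marker metadata:
#' identifier, chromosome, base-pair position, allele labels and a GenCall-type
#' quality score in `[0, 1]`.
#'
#' @param codes Numeric or integer matrix, animals in rows, markers in columns.
#'   Row names are animal ids and column names marker ids (supplied names win).
#' @param markers `data.frame` with columns `id`, `chrom`, `pos` (bp) and
#'   optionally `cm`, `allele_a`, `allele_b`, `gencall`. Defaults are filled
#'   in for the optional columns.
#' @param samples Character vector of animal ids (defaults to row names).
#' @return An object of class `geno_matrix`: a list with elements `codes`,
#'   `markers` and `samples`.
#' @export
geno_matrix <- function(codes, markers, samples = rownames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(samples)) samples <- paste0("id", seq_len(nrow(codes)))
  if (length(samples) != nrow(codes))
    stop_arg("`samples` must have one entry per row of `codes`")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(markers)))
    stop_arg("`markers` needs columns id, chrom, pos")
  if (nrow(markers) != ncol(codes))
    stop_arg("`markers` must have one row per column of `codes`")
  if (is.null(markers$allele_a)) markers$allele_a <- "A"
  if (is.null(markers$allele_b)) markers$allele_b <- "B"
  if (is.null(markers$gencall)) markers$gencall <- 1.0
  markers$chrom <- as.character(markers$chrom)
  if (any(markers$pos < 0)) stop_arg("marker positions must be non-negative")
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop_arg("genotype codes must be 0, 1, 2 or NA")
  rownames(codes) <- samples
  colnames(codes) <- markers$id
  structure(list(codes = codes, markers = markers,
                 samples = as.character(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cr <- mean(!is.na(x$codes))
  cat(sprintf("geno_matrix: %d animals x %d markers (%d chromosome%s), call rate %.3f\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$markers$chrom)),
              if (length(unique(x$markers$chrom)) == 1L) "" else "s", cr))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Animal indices or ids (default: all).
#' @param j Marker indices or ids (default: all).
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the requested animals and markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$markers$id)
  geno_matrix(x$codes[i, j, drop = FALSE], x$markers[j, , drop = FALSE],
              x$samples[i])
}

as_geno_codes <- function(x) {
  if (inherits(x, "geno_matrix")) x$codes else as.matrix(x)
}

#' Mean-impute missing genotype codes
#'
#' Fills each missing entry with the column mean of the observed codes — the
#' standard preparation for whole-genome regression and genomic relationship
#' matrices, which require a complete matrix. Imputed codes are fractional.
#'
#' @param genotypes A [geno_matrix()] or plain dosage matrix.
#' @return Object of the same kind with no missing entries.
#' @export
impute_genotypes <- function(genotypes) {
  codes <- as_geno_codes(genotypes)
  miss <- which(is.na(codes), arr.ind = TRUE)
  if (nrow(miss)) {
    mu <- colMeans(codes, na.rm = TRUE)
    if (anyNA(mu)) stop_arg("cannot impute a column with no observed genotypes")
    codes[miss] <- mu[miss[, 2L]]
  }
  if (inherits(genotypes, "geno_matrix")) {
    genotypes$codes <- codes
    genotypes
  } else codes
}
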