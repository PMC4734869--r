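# VanRaden genomic relationships, stratification PCA, and train-validation
# relationship statistics.

#' VanRaden genomic relationship matrix (method 1)
#'
#' \deqn{G = \frac{M M'}{2 \sum_j p_j (1 - p_j)}, \quad M = W - 2P,}
#' where `W` holds the 0/1/2 B-allele dosages and `p_j` is the observed
#' B-allele frequency in the panel (the single-denominator estimator, not
#' marker-specific scaling). Centering frequencies come from the full panel
#' supplied, so with training and validation animals together a single `G`
#' describes the whole population.
#'
#' @param genotypes A [geno_matrix()] or complete dosage matrix; missing
#'   genotypes must be imputed first and every marker must be polymorphic.
#' @return Symmetric `n x n` matrix of class `grm` with animal-id dimnames
#'   and the centering frequencies in the `"freq"` attribute.
#' @export
vanraden_g <- function(genotypes) {
  W <- as_geno_codes(genotypes)
  if (anyNA(W))
    stop_arg("missing genotypes: impute (see `impute_genotypes`) before G")
  p <- colMeans(W) / 2
  if (any(p <= 0 | p >= 1))
    stop_arg("monomorphic markers present; run quality control before G")
  M <- sweep(W, 2L, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  attr(G, "freq") <- p
  class(G) <- c("grm", class(G))
  G
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("grm: %d x %d, mean diagonal %.3f, mean off-diagonal %.4f\n",
              n, n, mean(diag(x)), mean(x[upper.tri(x)])))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Leading eigenpairs of `G`, used to check for population stratification
#' before genomic prediction: clustered projections indicate subpopulations.
#'
#' @param G A [vanraden_g()] matrix (any symmetric matrix accepted).
#' @param k Number of leading components (<= n).
#' @return List with `values` (top-k eigenvalues, descending), `vectors`
#'   (orthonormal columns), `projections` (vectors scaled by sqrt eigenvalue)
#'   and `prop_var` (share of the trace).
#' @export
pca_g <- function(G, k = 2) {
  k <- check_count(k, "k")
  if (k > nrow(G)) stop_arg("`k` exceeds the matrix dimension")
  eg <- eigen(unclass(G), symmetric = TRUE)
  vals <- eg$values[seq_len(k)]
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(vecs) <- rownames(G)
  proj <- sweep(vecs, 2L, sqrt(pmax(vals, 0)), "*")
  list(values = vals, vectors = vecs, projections = proj,
       prop_var = vals / sum(pmax(eg$values, 0)))
}

#' Training-validation relationship statistics
#'
#' For each validation animal of each fold: the maximum off-diagonal genomic
#' relationship to the training set (`maxr`) and the means of the five
#' (`mean5`) and ten (`mean10`) highest such relationships. Statistics are
#' averaged over animals within fold, then across folds.
#'
#' @param G A [vanraden_g()] matrix.
#' @param folds A [make_folds()] assignment (named integer vector), or a list
#'   with elements `train`/`val` per fold.
#' @return Object of class `relationship_stats`: `per_fold` data.frame and
#'   `overall` named vector.
#' @export
relationship_stats <- function(G, folds) {
  ids <- rownames(G)
  fold_sets <- if (is.list(folds) && !is.null(folds[[1L]]$val)) folds
    else lapply(sort(unique(folds)), function(f)
      list(val = names(folds)[folds == f], train = names(folds)[folds != f]))
  per <- lapply(seq_along(fold_sets), function(fi) {
    fs <- fold_sets[[fi]]
    tr <- match(fs$train, ids); va <- match(fs$val, ids)
    if (anyNA(tr) || anyNA(va))
      stop_arg("fold ids missing from the relationship matrix")
    if (length(intersect(fs$train, fs$val)))
      stop_arg("training and validation sets overlap")
    if (length(tr) < 10L)
      warning("training set smaller than 10; top-k statistics truncated")
    stats <- vapply(va, function(v) {
      rel <- sort(G[v, tr], decreasing = TRUE)
      c(max = rel[1L],
        mean5 = mean(rel[seq_len(min(5L, length(rel)))]),
        mean10 = mean(rel[seq_len(min(10L, length(rel)))]))
    }, numeric(3))
    data.frame(fold = fi, n_val = length(va), maxr = mean(stats[1L, ]),
               mean5 = mean(stats[2L, ]), mean10 = mean(stats[3L, ]))
  })
  per <- do.call(rbind, per)
  overall <- c(maxr = mean(per$maxr), mean5 = mean(per$mean5),
               mean10 = mean(per$mean10))
  structure(list(per_fold = per, overall = overall),
            class = "relationship_stats")
}

#' @export
print.relationship_stats <- function(x, ...) {
  cat(sprintf("relationship_stats over %d folds: maxr = %.3f, mean5 = %.3f, mean10 = %.3f\n",
              nrow(x$per_fold), x$overall["maxr"], x$overall["mean5"],
              x$overall["mean10"]))
  invisible(x)
}
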