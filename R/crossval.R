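# k-fold cross-validation of direct genomic values: correlation, accuracy,
# regression slope, MSE, and train-validation relationship summaries.

#' Random k-fold assignment
#'
#' Uniformly random partition with fold sizes differing by at most one;
#' deterministic for a given seed.
#'
#' @param animal_ids Character vector of animal ids.
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed.
#' @return Named integer vector of fold labels in `1..k`, class
#'   `fold_assignment`, with `k` and `seed` attributes.
#' @export
make_folds <- function(animal_ids, k = 5, seed = NULL) {
  k <- check_count(k, "k", min = 2L)
  n <- length(animal_ids)
  if (k > n) stop_arg("`k` exceeds the number of animals")
  if (anyDuplicated(animal_ids)) stop_arg("duplicated animal ids")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  structure(setNames(folds, animal_ids), k = k, seed = seed,
            class = "fold_assignment")
}

#' Evaluate one validation fold
#'
#' Computes the field's standard comparison criteria between pseudo-phenotype
#' and direct genomic value: Pearson correlation `r`; prediction accuracy
#' (`r / sqrt(h2)` for the adjusted-phenotype response, which approximates
#' the correlation with the true breeding value, or `r` itself for the EBV
#' response); the least-squares slope `b` of pseudo-phenotype on DGV
#' (inflation/deflation of predictions, 1 is ideal); and
#' `MSE = mean((pseudo - DGV)^2)`.
#'
#' @param pseudo Pseudo-phenotype vector of the validation animals.
#' @param dgv Direct genomic values, aligned with `pseudo`.
#' @param h2 Trait heritability used in the accuracy denominator.
#' @param response_type `"Ystar"` or `"EBV"`.
#' @return Named numeric vector: `r`, `accuracy`, `slope`, `mse`.
#' @export
evaluate_fold <- function(pseudo, dgv, h2, response_type = c("Ystar", "EBV")) {
  response_type <- match.arg(response_type)
  if (length(pseudo) != length(dgv) || length(pseudo) < 3L)
    stop_arg("`pseudo` and `dgv` must be aligned vectors of length >= 3")
  h2 <- check_proportion(h2, "h2", open = TRUE)
  if (var(dgv) == 0) {
    warning("zero variance in DGV; correlation and slope undefined")
    return(c(r = NA_real_, accuracy = NA_real_, slope = NA_real_,
             mse = mean((pseudo - dgv)^2)))
  }
  r <- cor(pseudo, dgv)
  acc <- if (response_type == "Ystar") r / sqrt(h2) else r
  b <- cov(pseudo, dgv) / var(dgv)
  c(r = r, accuracy = acc, slope = b, mse = mean((pseudo - dgv)^2))
}

#' k-fold cross-validation of a whole-genome regression model
#'
#' Fits the chosen model on k-1 folds with the response-appropriate record
#' weights, predicts DGV for the held-out fold, and evaluates the fold with
#' [evaluate_fold()]. Pseudo-phenotypes come from a single step-1 fit on all
#' data (the multiple-step design: they are fixed across folds). Fold metrics
#' are aggregated as unweighted mean and sample SD across folds, and genomic
#' relationship summaries (maxr/mean5/mean10) are reported per fold when a
#' relationship matrix is available.
#'
#' @param W Complete (imputed) genotype matrix with animal-id row names.
#' @param pseudo A [pseudo_phenotypes()] data.frame, or any data.frame with
#'   columns `animal`, the response, and its weight.
#' @param response_type `"Ystar"` (response `ystar`, weight `ystar_weight`)
#'   or `"EBV"` (response `ebv`, weight `ebv_weight`).
#' @param model "BRR", "BayesC" or "BL".
#' @param h2 Heritability for the accuracy denominator (the step-1 posterior
#'   mean of the full data).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment; fold f's chain uses `seed + f`.
#' @param chain List with `n_iter`, `burn_in`, `thin` for the per-fold fits.
#' @param G Optional [vanraden_g()] matrix (computed from `W` when
#'   `compute_relationships = TRUE` and omitted).
#' @param compute_relationships Report maxr/mean5/mean10 per fold.
#' @param weights Optional explicit weight vector overriding the table's.
#' @param ... Further arguments to [wgr()].
#' @return Object of class `cv_metrics`: `per_fold` data.frame (fold, n_val,
#'   r, accuracy, slope, mse, and relationship columns), `aggregate` (mean
#'   and SD rows), `model`, `response_type`, `h2`, `folds`, and per-fold
#'   `dgv` predictions.
#' @export
run_cv <- function(W, pseudo, response_type = c("Ystar", "EBV"),
                   model = "BRR", h2, k = 5, seed = NULL,
                   chain = list(n_iter = 20000, burn_in = 4000, thin = 10),
                   G = NULL, compute_relationships = TRUE, weights = NULL,
                   ...) {
  response_type <- match.arg(response_type)
  W <- as_geno_codes(W)
  if (is.null(rownames(W))) stop_arg("`W` needs animal-id row names")
  stopifnot(is.data.frame(pseudo), "animal" %in% names(pseudo))
  resp_col <- if (response_type == "Ystar") "ystar" else "ebv"
  wt_col <- if (response_type == "Ystar") "ystar_weight" else "ebv_weight"
  if (!resp_col %in% names(pseudo))
    stop_arg("`pseudo` lacks column '", resp_col, "'")
  idx <- match(rownames(W), pseudo$animal)
  if (anyNA(idx))
    stop_arg("animals in `W` missing from the pseudo-phenotype table")
  y <- pseudo[[resp_col]][idx]
  wt <- if (!is.null(weights)) weights
        else if (wt_col %in% names(pseudo)) pseudo[[wt_col]][idx]
        else rep(1, length(y))
  wt <- pmax(wt, 1e-6) # animals with zero accuracy keep a vanishing weight
  folds <- make_folds(rownames(W), k = k, seed = seed)
  if (compute_relationships && is.null(G)) G <- vanraden_g(W)
  per <- vector("list", k)
  dgv_all <- setNames(numeric(nrow(W)), rownames(W))
  for (f in seq_len(k)) {
    val <- which(folds == f)
    trn <- which(folds != f)
    fit <- wgr(y[trn], W[trn, , drop = FALSE], model = model,
               weights = wt[trn], n_iter = chain$n_iter,
               burn_in = chain$burn_in, thin = chain$thin,
               seed = if (is.null(seed)) NULL else seed + f, ...)
    dgv <- predict(fit, W[val, , drop = FALSE])
    dgv_all[val] <- dgv
    met <- evaluate_fold(y[val], dgv, h2, response_type)
    row <- data.frame(fold = f, n_val = length(val), t(met))
    per[[f]] <- row
  }
  per <- do.call(rbind, per)
  if (!is.null(G)) {
    rs <- relationship_stats(G, folds)
    per <- cbind(per, rs$per_fold[, c("maxr", "mean5", "mean10")])
  }
  metric_cols <- setdiff(names(per), c("fold", "n_val"))
  aggregate <- data.frame(
    stat = c("mean", "sd"),
    rbind(vapply(per[metric_cols], mean, 0),
          vapply(per[metric_cols], sd, 0)))
  names(aggregate)[-1L] <- metric_cols
  structure(list(per_fold = per, aggregate = aggregate, model = model,
                 response_type = response_type, h2 = h2, folds = folds,
                 dgv = dgv_all, seed = seed),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  m <- x$aggregate[x$aggregate$stat == "mean", ]
  s <- x$aggregate[x$aggregate$stat == "sd", ]
  cat(sprintf("%d-fold CV, %s on %s (h2 = %.3f)\n", nrow(x$per_fold),
              x$model, x$response_type, x$h2))
  cat(sprintf("  r = %.3f +/- %.3f, accuracy = %.3f +/- %.3f\n",
              m$r, s$r, m$accuracy, s$accuracy))
  cat(sprintf("  slope = %.3f +/- %.3f, MSE = %.4g\n", m$slope, s$slope,
              m$mse))
  if ("maxr" %in% names(m))
    cat(sprintf("  maxr = %.3f, mean5 = %.3f, mean10 = %.3f\n",
                m$maxr, m$mean5, m$mean10))
  invisible(x)
}

#' Tidy per-fold results table
#'
#' @param x A `cv_metrics` object.
#' @return `data.frame` with one row per fold plus aggregated rows, carrying
#'   model and response-type columns (the tidy results layout written by
#'   [cmd_cv()]).
#' @export
cv_results_table <- function(x) {
  stopifnot(inherits(x, "cv_metrics"))
  per <- x$per_fold
  per$fold <- as.character(per$fold)
  agg <- x$aggregate
  names(agg)[1L] <- "fold"
  agg$n_val <- NA
  agg <- agg[, names(per)]
  out <- rbind(per, agg)
  cbind(model = x$model, response_type = x$response_type, out)
}
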