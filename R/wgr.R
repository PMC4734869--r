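# Step 2: whole-genome regression by Gibbs sampling — Bayesian ridge
# regression, BayesC and the Bayesian Lasso, with weighted records and DGV
# prediction.

#' Default hyperparameters for whole-genome regression
#'
#' Scales the priors so that a proportion `R2` of the phenotypic variance is
#' attributed a priori to the linear predictor and `1 - R2` to the residual:
#' \deqn{S_e = var(y)(1 - R^2)(df_e + 2), \qquad
#'   S_\beta = \frac{var(y) R^2 (df_\beta + 2)}{MSx},}
#' with \eqn{MSx = \sum_j var(w_{\cdot j})} the summed marker variances (so
#' the prior modes of the scaled inverse-chi-squared variances match the
#' split). For the Bayesian Lasso the gamma prior on \eqn{\lambda^2} gets
#' rate-scale \eqn{s = (r - 1) R^2 / (2 (1 - R^2) MSx)}: its mode is then the
#' \eqn{\lambda^2} whose double-exponential marker variance
#' \eqn{2\sigma^2_e/\lambda^2} allocates `R2` of `var(y)` to the markers.
#'
#' @param y Response vector (non-constant).
#' @param W Genotype dosage matrix (animals x markers, no missing values).
#' @param R2 Prior proportion of variance for the linear predictor.
#' @param model One of "BRR", "BayesC", "BL" (affects nothing here beyond
#'   bookkeeping; all scales are returned).
#' @param df_beta,df_e Degrees of freedom of the scaled inverse-chi-squared
#'   priors on the marker-effect and residual variances.
#' @param pi0,p0 BayesC prior: `pi ~ beta` parameterised by mean `pi0` and
#'   concentration `p0` (shapes `p0*pi0`, `p0*(1 - pi0)`).
#' @param lasso_rate Shape `r` of the gamma prior on lambda-squared.
#' @return A list of class `wgr_hyper` with all strictly positive scales.
#' @export
default_hyperparameters <- function(y, W, R2 = 0.5, model = "BRR",
                                    df_beta = 5, df_e = 5, pi0 = 0.5,
                                    p0 = 10, lasso_rate = 1.1) {
  R2 <- check_proportion(R2, "R2", open = TRUE)
  vy <- var(y)
  if (!is.finite(vy) || vy == 0) stop_arg("`y` must be non-constant")
  if (is.null(dim(W)) || ncol(W) < 1L) stop_arg("`W` must be a matrix")
  msx <- sum(apply(W, 2L, var))
  if (msx <= 0) stop_arg("all markers are monomorphic")
  structure(list(
    df_beta = df_beta,
    S_beta = vy * R2 * (df_beta + 2) / msx,
    df_e = df_e,
    S_e = vy * (1 - R2) * (df_e + 2),
    R2 = R2, pi0 = pi0, p0 = p0,
    lasso_rate = lasso_rate,
    lasso_scale = (lasso_rate - 1) * R2 / (2 * (1 - R2) * msx),
    msx = msx), class = "wgr_hyper")
}

#' Bayesian whole-genome regression
#'
#' Gibbs sampler for the marker model
#' \deqn{y = 1\mu + Wg + e, \qquad e_i \sim N(0, \sigma^2_e / w_i^2),}
#' with per-record weights `w` (1 = unweighted) and one of three priors on
#' the marker effects:
#' * **BRR** — independent \eqn{N(0, \sigma^2_\beta)} with a scaled
#'   inverse-chi-squared prior on the common variance;
#' * **BayesC** — spike-and-slab mixture: a point mass at zero with
#'   probability \eqn{1 - \pi} and a \eqn{N(0, \sigma^2_\beta)} slab, with
#'   \eqn{\pi \sim beta(p_0\pi_0,\ p_0(1 - \pi_0))};
#' * **BL** — Bayesian Lasso: double-exponential effects via the
#'   scale-mixture-of-normals representation (per-marker variances
#'   \eqn{\tau^2_j \sigma^2_e} with inverse-Gaussian full conditionals and
#'   \eqn{\lambda^2 \sim gamma(r, s)}).
#'
#' Effects are updated one at a time in fixed marker order (set
#' `random_order = TRUE` to shuffle each sweep); the intercept and all
#' variance parameters have conjugate full conditionals. Weights enter as
#' residual precision multipliers (`var(e_i) = sigma_e2 / w_i^2`),
#' implemented by scaling each record by its weight.
#'
#' @param y Response (pseudo-phenotype) vector.
#' @param W Genotype dosage matrix, rows matching `y`; no missing values.
#' @param model "BRR", "BayesC" or "BL".
#' @param weights Positive per-record weights (default 1).
#' @param hyper A [default_hyperparameters()] list (built from `y`, `W` if
#'   omitted).
#' @param n_iter,burn_in,thin Chain settings (desk-scale defaults
#'   20000/4000/10).
#' @param seed Integer seed; identical seeds reproduce identical chains.
#' @param R2 Prior R-squared passed to [default_hyperparameters()] when
#'   `hyper` is omitted.
#' @param pi_fixed Optionally fix the BayesC inclusion probability (e.g. 1
#'   recovers BRR).
#' @param fixed_variances Optional list with `sigma_e2` and/or `sigma_b2` to
#'   hold a variance fixed (used by conjugate oracle checks).
#' @param keep_effects_chain Store the retained samples of every marker
#'   effect (only sensible for small p).
#' @param random_order Shuffle the marker update order each sweep.
#' @param verbose Print progress.
#' @return Object of class `wgr`: `mu`, `coefficients` (posterior-mean marker
#'   effects), `inclusion_prob` (BayesC), `chains` (data.frame of retained
#'   variance/hyperparameter samples), `fitted`, `residuals`, `model`,
#'   `hyper`.
#' @seealso [predict.wgr()] for direct genomic values.
#' @export
wgr <- function(y, W, model = c("BRR", "BayesC", "BL"), weights = NULL,
                hyper = NULL, n_iter = 20000, burn_in = 4000, thin = 10,
                seed = NULL, R2 = 0.5, pi_fixed = NULL,
                fixed_variances = NULL, keep_effects_chain = FALSE,
                random_order = FALSE, verbose = FALSE) {
  model <- match.arg(model)
  W <- as_geno_codes(W)
  if (!is.numeric(y) || length(y) != nrow(W))
    stop_arg("`y` must be numeric with one entry per row of `W`")
  if (anyNA(y) || anyNA(W) || !all(is.finite(y)))
    stop_arg("missing or non-finite values in `y`/`W`; impute genotypes upstream")
  n_iter <- check_count(n_iter, "n_iter")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  thin <- check_count(thin, "thin")
  if (burn_in >= n_iter) stop_arg("`burn_in` must be smaller than `n_iter`")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(weights) != length(y) || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop_arg("`weights` must be positive and finite, one per record")
  if (is.null(hyper)) hyper <- default_hyperparameters(y, W, R2 = R2)
  stopifnot(inherits(hyper, "wgr_hyper"))
  model_code <- match(model, c("BRR", "BayesC", "BL")) - 1L
  pi_fix <- if (is.null(pi_fixed)) -1 else check_proportion(pi_fixed, "pi_fixed")
  fe <- if (!is.null(fixed_variances$sigma_e2)) fixed_variances$sigma_e2 else -1
  fb <- if (!is.null(fixed_variances$sigma_b2)) fixed_variances$sigma_b2 else -1
  res <- with_seed(seed,
    wgr_gibbs_cpp(as.numeric(y), W, as.numeric(weights), model_code,
                  hyper$df_beta, hyper$S_beta, hyper$df_e, hyper$S_e,
                  hyper$pi0, hyper$p0, hyper$lasso_rate, hyper$lasso_scale,
                  n_iter, burn_in, thin, pi_fix, fe, fb,
                  isTRUE(keep_effects_chain), isTRUE(random_order),
                  isTRUE(verbose)))
  g <- setNames(res$g_mean, colnames(W))
  chains <- data.frame(mu = res$mu_chain, sigma_b2 = res$sigma_b2_chain,
                       sigma_e2 = res$sigma_e2_chain)
  if (model == "BayesC") chains$pi <- res$pi_chain
  if (model == "BL") chains$lambda2 <- res$lambda2_chain
  fitted <- res$mu_mean + drop(W %*% g)
  out <- list(mu = res$mu_mean, coefficients = g,
              inclusion_prob = if (model == "BayesC")
                setNames(res$inclusion_prob, colnames(W)) else NULL,
              chains = chains,
              effects_chain = if (keep_effects_chain) res$g_chain else NULL,
              fitted = fitted, residuals = y - fitted,
              model = model, hyper = hyper, weights = weights,
              n = nrow(W), p = ncol(W), markers = colnames(W),
              n_iter = n_iter, burn_in = burn_in, thin = thin,
              call = match.call())
  class(out) <- "wgr"
  out
}

#' @rdname wgr
#' @param ... Arguments forwarded to [wgr()].
#' @export
fit_brr <- function(y, W, ...) wgr(y, W, model = "BRR", ...)

#' @rdname wgr
#' @export
fit_bayesc <- function(y, W, ...) wgr(y, W, model = "BayesC", ...)

#' @rdname wgr
#' @export
fit_bl <- function(y, W, ...) wgr(y, W, model = "BL", ...)

#' @export
print.wgr <- function(x, ...) {
  cat(sprintf("%s fit: %d records, %d markers, %d retained samples\n",
              x$model, x$n, x$p, nrow(x$chains)))
  cat(sprintf("  mu = %.4g, sigma_b2 = %.4g, sigma_e2 = %.4g\n",
              x$mu, mean(x$chains$sigma_b2), mean(x$chains$sigma_e2)))
  if (x$model == "BayesC")
    cat(sprintf("  posterior mean pi = %.3f\n", mean(x$chains$pi)))
  if (x$model == "BL")
    cat(sprintf("  posterior mean lambda2 = %.4g\n", mean(x$chains$lambda2)))
  invisible(x)
}

#' @export
summary.wgr <- function(object, ...) {
  g <- coef(object)
  top <- head(order(abs(g), decreasing = TRUE), 10L)
  out <- list(model = object$model, n = object$n, p = object$p,
              top_markers = data.frame(
                marker = names(g)[top], effect = unname(g[top]),
                inclusion_prob = if (!is.null(object$inclusion_prob))
                  unname(object$inclusion_prob[top]) else NA),
              varcomp = vapply(object$chains, mean, 0))
  class(out) <- "summary.wgr"
  out
}

#' @export
print.summary.wgr <- function(x, ...) {
  cat(sprintf("%s: %d records x %d markers\n", x$model, x$n, x$p))
  cat("Posterior means:\n")
  print(round(x$varcomp, 5))
  cat("Largest marker effects:\n")
  print(x$top_markers, row.names = FALSE)
  invisible(x)
}

#' @export
coef.wgr <- function(object, ...) object$coefficients

#' @export
fitted.wgr <- function(object, ...) object$fitted

#' @export
residuals.wgr <- function(object, ...) object$residuals

#' Direct genomic values from a whole-genome regression fit
#'
#' \eqn{DGV_i = \sum_j w_{ij}\,\hat g_j}: the genotype dosages of the new
#' animals times the posterior-mean marker effects. The intercept is excluded
#' by default.
#'
#' @param object A [wgr()] fit.
#' @param W_new Genotype matrix of the animals to predict; the marker set
#'   (and order, checked by name when available) must match the training
#'   matrix.
#' @param include_intercept Add the posterior-mean intercept.
#' @param ... Unused.
#' @return Named numeric vector of DGV.
#' @export
predict.wgr <- function(object, W_new, include_intercept = FALSE, ...) {
  W_new <- as_geno_codes(W_new)
  if (ncol(W_new) != object$p)
    stop_arg("marker count of `W_new` does not match the training matrix")
  if (!is.null(colnames(W_new)) && !is.null(object$markers) &&
      !identical(colnames(W_new), object$markers))
    stop_arg("marker names of `W_new` do not match the training matrix")
  dgv <- drop(W_new %*% object$coefficients)
  if (include_intercept) dgv <- dgv + object$mu
  setNames(dgv, rownames(W_new))
}
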