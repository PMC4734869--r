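# Step 1: pedigree animal model by Gibbs sampling — variance components, EBV,
# PEV-based accuracies, adjusted phenotypes Y*, and record weights.

#' Contemporary-group outlier filter
#'
#' Removes records lying more than `k` standard deviations from their
#' contemporary-group mean (mean and SD computed within the group, candidate
#' included), then drops groups left with fewer than `min_cg` records.
#'
#' @param phenotypes `data.frame` with columns `value` and `cg` (and anything
#'   else, carried through).
#' @param k SD multiple defining the outlier interval.
#' @param min_cg Minimum records per retained contemporary group.
#' @return The filtered `data.frame`; removed rows are recorded in the
#'   `"removed"` attribute.
#' @export
filter_outliers_cg <- function(phenotypes, k = 3.5, min_cg = 3) {
  stopifnot(all(c("value", "cg") %in% names(phenotypes)))
  cg <- as.character(phenotypes$cg)
  mu <- tapply(phenotypes$value, cg, mean)
  sdv <- tapply(phenotypes$value, cg, sd)
  z <- abs(phenotypes$value - mu[cg]) / sdv[cg]
  out <- !is.na(z) & z > k
  keep <- phenotypes[!out, , drop = FALSE]
  sizes <- table(as.character(keep$cg))
  small <- names(sizes)[sizes < min_cg]
  removed <- rbind(phenotypes[out, , drop = FALSE],
                   keep[as.character(keep$cg) %in% small, , drop = FALSE])
  keep <- keep[!(as.character(keep$cg) %in% small), , drop = FALSE]
  if (!nrow(keep)) warning("outlier filter removed every record")
  attr(keep, "removed") <- removed
  keep
}

# Topologically order a pedigree (parents before offspring); unknown = "0".
order_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  names(ped)[1:3] <- c("id", "sire", "dam")
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$id)) stop_arg("duplicated animal ids in pedigree")
  miss <- setdiff(c(ped$sire, ped$dam), c("0", ped$id))
  if (length(miss)) {
    # parents without their own row become founders
    ped <- rbind(data.frame(id = miss, sire = "0", dam = "0",
                            stringsAsFactors = FALSE),
                 ped[, c("id", "sire", "dam")])
  }
  placed <- character(0)
  remaining <- ped
  out <- NULL
  while (nrow(remaining)) {
    ready <- (remaining$sire == "0" | remaining$sire %in% placed) &
             (remaining$dam == "0" | remaining$dam %in% placed)
    if (!any(ready)) stop_arg("pedigree contains a cycle")
    out <- rbind(out, remaining[ready, , drop = FALSE])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular method: \eqn{a_{ii} = 1 + F_i} with \eqn{F_i} the inbreeding
#' coefficient (half the relationship between the parents), and
#' \eqn{a_{ij} = (a_{j,s_i} + a_{j,d_i})/2}. Unknown parents are treated as
#' unrelated, non-inbred founders.
#'
#' @param pedigree `data.frame` with columns id, sire, dam ("0" unknown).
#' @return Symmetric positive semi-definite matrix with animal-id dimnames,
#'   in topological order.
#' @export
build_a_matrix <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s) A[j, s] else 0) + (if (d) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s && d) 0.5 * A[s, d] else 0
  }
  A
}

# Memoised kinship/inbreeding on an ordered pedigree. Returns per-animal F.
pedigree_inbreeding <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  Fcoef <- rep(NA_real_, n)
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, "_", j)
    val <- memo[[key]]
    if (!is.null(val)) return(val)
    val <- if (i == j) 0.5 * (1 + inbreeding(i))
           else 0.5 * (kin(si[i], j) + kin(di[i], j))
    memo[[key]] <- val
    val
  }
  inbreeding <- function(i) {
    if (!is.na(Fcoef[i])) return(Fcoef[i])
    f <- if (si[i] && di[i]) kin(si[i], di[i]) else 0
    Fcoef[i] <<- f
    f
  }
  vapply(seq_len(n), inbreeding, numeric(1))
}

# Sparse inverse of the numerator relationship matrix (Henderson's rules with
# inbreeding), returned as CSR arrays for the C++ sampler.
a_inverse_csr <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  Fc <- pedigree_inbreeding(ped)
  Fs <- ifelse(si > 0L, Fc[si], 0)
  Fd <- ifelse(di > 0L, Fc[di], 0)
  # Mendelian sampling variance
  m <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(si > 0L | di > 0L, 0.75 - 0.25 * ifelse(si > 0L, Fs, Fd), 1))
  alpha <- 1 / m
  ii <- jj <- xx <- vector("list", n)
  for (k in seq_len(n)) {
    trio_i <- c(k, si[k], di[k])
    trio_w <- c(1, -0.5, -0.5)
    keep <- trio_i > 0L
    ti <- trio_i[keep]; tw <- trio_w[keep]
    cmb <- expand.grid(a = seq_along(ti), b = seq_along(ti))
    ii[[k]] <- ti[cmb$a]
    jj[[k]] <- ti[cmb$b]
    xx[[k]] <- alpha[k] * tw[cmb$a] * tw[cmb$b]
  }
  trip <- data.frame(i = unlist(ii), j = unlist(jj), x = unlist(xx))
  agg <- rowsum(trip$x, paste0(trip$i, "_", trip$j))
  key <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
  i <- as.integer(key[, 1L]); j <- as.integer(key[, 2L]); x <- as.numeric(agg)
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; x <- x[ord]
  ptr <- c(0L, cumsum(tabulate(i, nbins = n)))
  list(ptr = ptr, idx = j - 1L, val = x, n = n)
}

#' Fit a pedigree animal model by Gibbs sampling
#'
#' Samples from the posterior of the single-trait animal model
#' \deqn{y = X\beta + Za + e, \quad a \sim N(0, A\sigma^2_a), \quad
#'   e \sim N(0, I\sigma^2_e),}
#' where `A` is the pedigree numerator relationship matrix, with flat priors
#' on the fixed effects and, by default, flat (bounded-below) priors on both
#' variance components — the scaled inverse-chi-squared family with `df = -2`
#' and scale 0, whose posterior mode matches REML. Informative
#' inverse-chi-squared priors are available through `priors`. Fixed effects
#' and additive values are updated one at a time from their normal full
#' conditionals, using the sparse inverse of `A` built directly from the
#' pedigree; variances are drawn from their conjugate full conditionals,
#' followed by an interweaving (ASIS) rescaling move that re-draws
#' `sigma_a` in the ancillary parameterisation to keep the heritability
#' chain mixing well.
#'
#' EBV are posterior means of `a`; prediction error variances (PEV) are the
#' variances of the retained posterior samples of `a`, which feed the
#' accuracy formula \eqn{acc = \sqrt{1 - PEV/\sigma^2_g}}.
#'
#' @param formula Fixed-effect formula, e.g. `value ~ cg + age`; the response
#'   is the trait. Contemporary group enters as a factor.
#' @param data `data.frame` of phenotype records, one per animal.
#' @param pedigree Pedigree `data.frame` (id, sire, dam; "0" unknown)
#'   containing every phenotyped animal.
#' @param animal Name of the column of `data` holding animal ids.
#' @param n_iter,burn_in,thin Chain settings. Defaults (20000/4000/10) are a
#'   desk-scale reduction of the heavy chains used in production genetic
#'   evaluations; raise them for final analyses.
#' @param seed Integer seed (chains are reproducible given the seed).
#' @param priors List with `df` (both components; default -2, a flat prior
#'   on each variance) and optionally `s_a`, `s_e` (inverse-chi-squared scale
#'   sums; default 0). For a weakly informative prior with mode `m`, use
#'   `df = v`, `s_a = m * (v + 2)`.
#' @param fixed_variances Optional list with `sigma_a2` and/or `sigma_e2` to
#'   hold a variance component fixed (conjugate oracle checks).
#' @param verbose Print progress.
#' @return Object of class `animal_model`: posterior-mean fixed effects
#'   (`coefficients`), `ebv` and `pev` for every pedigree animal, posterior
#'   means `sigma_a2`, `sigma_e2`, `h2`, retained variance-component `chains`,
#'   and the model frame pieces needed by [adjusted_phenotype()] and
#'   [ystar_weights()].
#' @export
animal_model <- function(formula, data, pedigree, animal = "animal",
                         n_iter = 20000, burn_in = 4000, thin = 10,
                         seed = NULL, priors = list(df = -2, s_a = 0, s_e = 0),
                         fixed_variances = NULL, verbose = FALSE) {
  n_iter <- check_count(n_iter, "n_iter")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  thin <- check_count(thin, "thin")
  if (burn_in >= n_iter) stop_arg("`burn_in` must be smaller than `n_iter`")
  if (!animal %in% names(data)) stop_arg("`data` lacks column '", animal, "'")
  ids <- as.character(data[[animal]])
  if (anyDuplicated(ids)) stop_arg("one record per animal is required")
  ped <- order_pedigree(pedigree)
  if (!all(ids %in% ped$id))
    stop_arg("phenotyped animals missing from the pedigree")
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    warning("dropping aliased fixed-effect columns: ",
            paste(drop, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  Ainv <- a_inverse_csr(ped)
  rec_animal <- match(ids, ped$id) - 1L
  df_prior <- if (is.null(priors$df)) -2 else priors$df
  s_a <- if (is.null(priors$s_a)) 0 else priors$s_a
  s_e <- if (is.null(priors$s_e)) 0 else priors$s_e
  fa <- if (!is.null(fixed_variances$sigma_a2)) fixed_variances$sigma_a2 else -1
  fe <- if (!is.null(fixed_variances$sigma_e2)) fixed_variances$sigma_e2 else -1
  fit <- with_seed(seed,
    animal_gibbs_cpp(y, X, rec_animal, Ainv$ptr, Ainv$idx, Ainv$val,
                     as.integer(Ainv$n), df_prior, s_a, df_prior, s_e,
                     n_iter, burn_in, thin, fa, fe, isTRUE(verbose)))
  chains <- data.frame(sigma_a2 = fit$sigma_a2_chain,
                       sigma_e2 = fit$sigma_e2_chain)
  chains$h2 <- chains$sigma_a2 / (chains$sigma_a2 + chains$sigma_e2)
  conv_z <- split_chain_z(chains$h2)
  if (is.finite(conv_z) && abs(conv_z) > 5)
    warning(sprintf(
      "possible non-convergence: split-chain z = %.1f for h2; consider a longer chain",
      conv_z))
  structure(list(
    call = match.call(), formula = formula,
    coefficients = setNames(fit$beta_mean, colnames(X)),
    ebv = setNames(fit$a_mean, ped$id),
    pev = setNames(fit$a_var, ped$id),
    sigma_a2 = mean(chains$sigma_a2), sigma_e2 = mean(chains$sigma_e2),
    h2 = mean(chains$h2), chains = chains,
    animals = ids, pedigree_ids = ped$id, X = X, y = y,
    n_iter = n_iter, burn_in = burn_in, thin = thin,
    convergence_z = conv_z), class = "animal_model")
}

# Split-chain mean-difference z statistic (loose convergence heuristic).
split_chain_z <- function(x) {
  m <- length(x) %/% 2L
  if (m < 5L) return(NA_real_)
  a <- x[seq_len(m)]; b <- x[(m + 1L):length(x)]
  (mean(a) - mean(b)) / sqrt(var(a) / m + var(b) / (length(x) - m))
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Pedigree animal model (Gibbs)\n")
  cat(sprintf("  records: %d, pedigree animals: %d\n",
              length(x$y), length(x$ebv)))
  cat(sprintf("  sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  ch <- object$chains
  vc <- data.frame(
    mean = vapply(ch, mean, 0), sd = vapply(ch, sd, 0),
    q2.5 = vapply(ch, quantile, 0, probs = 0.025),
    q97.5 = vapply(ch, quantile, 0, probs = 0.975))
  out <- list(varcomp = vc, coefficients = object$coefficients,
              n_records = length(object$y),
              accuracy = mean(ebv_weights(object)),
              convergence_z = object$convergence_z)
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Posterior summaries of variance components:\n")
  print(round(x$varcomp, 4))
  cat(sprintf("\nMean EBV accuracy of phenotyped animals: %.3f\n", x$accuracy))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$coefficients

#' @export
fitted.animal_model <- function(object, ...) {
  drop(object$X %*% object$coefficients) +
    object$ebv[object$animals]
}

#' @export
residuals.animal_model <- function(object, ...) object$y - fitted(object)

#' Trace plot of the heritability chain
#'
#' @param x An [animal_model()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.animal_model <- function(x, ...) {
  graphics::plot(x$chains$h2, type = "l", xlab = "retained sample",
                 ylab = expression(h^2), ...)
  graphics::abline(h = x$h2, col = 2)
  invisible(x)
}

#' Accuracy of an estimated breeding value
#'
#' \eqn{acc = \sqrt{\max(0, 1 - PEV/\sigma^2_g)}}; clamped at zero when the
#' prediction error variance exceeds the genetic variance.
#'
#' @param pev Prediction error variance(s), >= 0.
#' @param sigma_g2 Additive genetic variance, > 0.
#' @return Accuracies in `[0, 1]`, vectorised over `pev`.
#' @export
ebv_accuracy <- function(pev, sigma_g2) {
  if (length(sigma_g2) != 1L || !is.finite(sigma_g2) || sigma_g2 <= 0)
    stop_arg("`sigma_g2` must be a single positive variance")
  if (any(pev < 0)) stop_arg("`pev` must be non-negative")
  sqrt(pmax(0, 1 - pev / sigma_g2))
}

#' Phenotypes adjusted for fixed effects (Y*)
#'
#' \eqn{Y^*_i = y_i - x_i'\hat\beta}: contemporary-group and covariate
#' contributions are subtracted, additive value and residual are retained.
#' `Y* + fitted fixed effects` reconstructs `y` exactly.
#'
#' @param fit An [animal_model()] fit.
#' @return Named numeric vector of adjusted phenotypes for the phenotyped
#'   animals.
#' @export
adjusted_phenotype <- function(fit) {
  stopifnot(inherits(fit, "animal_model"))
  setNames(fit$y - drop(fit$X %*% fit$coefficients), fit$animals)
}

#' Record weights for the adjusted-phenotype response
#'
#' The weight of record `i` is the square root of the `i`th diagonal of the
#' covariance matrix of the adjusted residuals,
#' \eqn{\Sigma = (I - H)\,cov(y)\,(I - H)'}, with hat matrix
#' \eqn{H = X(X'V^{-1}X)^{-1}X'V^{-1}}, \eqn{V = ZGZ' + R} and `G`, `R` the
#' diagonal matrices of additive and residual variances (so `V` is diagonal
#' and `cov(y)` is taken as `V`). With diagonal `V` the diagonal of
#' \eqn{\Sigma} reduces to \eqn{V_{ii} - x_i'(X'V^{-1}X)^{-1}x_i}.
#'
#' @param x An [animal_model()] fit, or a fixed-effect incidence matrix.
#' @param ... Passed on to methods.
#' @return Strictly positive weight vector, one per record.
#' @export
ystar_weights <- function(x, ...) UseMethod("ystar_weights")

#' @rdname ystar_weights
#' @param g_var,r_var Per-record additive and residual variances (recycled).
#' @export
ystar_weights.matrix <- function(x, g_var, r_var, ...) {
  n <- nrow(x)
  v <- rep_len(g_var, n) + rep_len(r_var, n)
  if (any(v <= 0)) stop_arg("variances must be positive")
  if (qr(x)$rank < ncol(x))
    stop_arg("fixed-effect matrix is rank deficient (estimability error)")
  xtvx <- crossprod(x / v, x)
  q <- rowSums((x %*% solve(xtvx)) * x)
  w <- sqrt(pmax(v - q, 0))
  if (any(w <= 0))
    stop_arg("non-positive adjusted-residual variance; model is saturated")
  setNames(w, rownames(x))
}

#' @rdname ystar_weights
#' @export
ystar_weights.animal_model <- function(x, ...) {
  setNames(ystar_weights.matrix(x$X, x$sigma_a2, x$sigma_e2), x$animals)
}

#' EBV-response record weights
#'
#' When EBV is the pseudo-phenotype, the step-1 accuracies are the weights.
#'
#' @param fit An [animal_model()] fit.
#' @return Named accuracy vector for the phenotyped animals.
#' @export
ebv_weights <- function(fit) {
  stopifnot(inherits(fit, "animal_model"))
  setNames(ebv_accuracy(unname(fit$pev[fit$animals]), fit$sigma_a2),
           fit$animals)
}

#' Pseudo-phenotype table from a step-1 fit
#'
#' Bundles the two response variables used for whole-genome regression —
#' the adjusted phenotype Y* and the EBV — with their weights (hat-matrix
#' SD weights for Y*, accuracies for EBV).
#'
#' @param fit An [animal_model()] fit.
#' @return `data.frame`: animal, ystar, ebv, accuracy, ystar_weight,
#'   ebv_weight.
#' @export
pseudo_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "animal_model"))
  acc <- ebv_weights(fit)
  data.frame(animal = fit$animals,
             ystar = unname(adjusted_phenotype(fit)),
             ebv = unname(fit$ebv[fit$animals]),
             accuracy = unname(acc),
             ystar_weight = unname(ystar_weights(fit)),
             ebv_weight = unname(acc),
             stringsAsFactors = FALSE)
}
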