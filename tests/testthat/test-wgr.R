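# Whole-genome regression samplers: hyperparameter scaling, conjugate
# oracles, model-specific behaviour and DGV prediction.

test_that("default hyperparameters implement the R2 variance split", {
  set.seed(8)
  W <- matrix(rbinom(200 * 50, 2, 0.4), 200, 50)
  y <- rnorm(200, sd = 2)
  hy <- default_hyperparameters(y, W, R2 = 0.5)
  msx <- sum(apply(W, 2, var))
  expect_equal(hy$S_beta, var(y) * 0.5 * (5 + 2) / msx)
  expect_equal(hy$S_e, var(y) * 0.5 * (5 + 2))
  expect_equal(hy$lasso_scale, (1.1 - 1) * 0.5 / (2 * 0.5 * msx))
  # worked numbers: var(y) = 1, MSx = 100, R2 = 0.5, df = 5 => S_beta = 0.035
  expect_equal(1 * 0.5 * (5 + 2) / 100, 0.035)
  expect_equal(1 * 0.5 * (5 + 2), 3.5) # S_e under the same convention
  # residual prior vanishes as R2 -> 1
  hy2 <- default_hyperparameters(y, W, R2 = 1 - 1e-9)
  expect_lt(hy2$S_e, 1e-7)
  expect_error(default_hyperparameters(rep(1, 200), W), "non-constant")
})

test_that("BRR with fixed variances matches the closed-form ridge solution", {
  set.seed(9)
  n <- 60; p <- 10
  W <- scale(matrix(rbinom(n * p, 2, 0.4), n, p), center = TRUE, scale = FALSE)
  y <- drop(W %*% rnorm(p, 0, 0.3)) + rnorm(n)
  y <- y - mean(y)
  se2 <- 1; sb2 <- 0.09
  fit <- wgr(y, W, model = "BRR", n_iter = 8000, burn_in = 1500, thin = 2,
             seed = 11, fixed_variances = list(sigma_e2 = se2, sigma_b2 = sb2),
             keep_effects_chain = TRUE)
  ridge <- drop(solve(crossprod(W) + diag(p) * se2 / sb2, crossprod(W, y)))
  expect_gt(cor(coef(fit), ridge), 0.999)
  mcse <- apply(fit$effects_chain, 2, sd) / sqrt(nrow(fit$effects_chain) / 3)
  expect_true(all(abs(coef(fit) - ridge) < 3 * mcse))
})

test_that("the p = 1 conjugate posterior is reproduced within Monte Carlo error", {
  set.seed(15)
  n <- 80
  x <- rbinom(n, 2, 0.5)
  x <- x - mean(x)
  y <- 0.4 * x + rnorm(n)
  y <- y - mean(y)
  se2 <- 1; sb2 <- 0.25
  fit <- wgr(y, matrix(x), model = "BRR", n_iter = 22000, burn_in = 2000,
             thin = 2, seed = 3,
             fixed_variances = list(sigma_e2 = se2, sigma_b2 = sb2),
             keep_effects_chain = TRUE)
  q <- sum(x^2) / se2 + 1 / sb2
  post_mean <- sum(x * y) / se2 / q
  post_var <- 1 / q
  ch <- fit$effects_chain[, 1]
  ess <- length(ch) / 3 # conservative for a near-independent chain
  expect_lt(abs(mean(ch) - post_mean), 3 * sqrt(post_var / ess))
  expect_lt(abs(var(ch) - post_var), 3 * post_var * sqrt(2 / ess))
})

test_that("chains are reproducible and null responses yield null effects", {
  set.seed(21)
  W <- matrix(rbinom(80 * 30, 2, 0.3), 80, 30)
  y <- rnorm(80)
  f1 <- wgr(y, W, model = "BL", n_iter = 2000, burn_in = 500, seed = 5)
  f2 <- wgr(y, W, model = "BL", n_iter = 2000, burn_in = 500, seed = 5)
  expect_identical(f1$chains, f2$chains)
  expect_identical(coef(f1), coef(f2))
  # null response: posterior-mean effects vanish up to Monte Carlo noise
  for (m in c("BRR", "BL")) {
    f0 <- wgr(rep(0, 80), W, model = m, n_iter = 2000, burn_in = 500,
              seed = 1, hyper = default_hyperparameters(rnorm(80), W),
              fixed_variances = list(sigma_e2 = 1))
    expect_lt(max(abs(coef(f0))), 0.05)
    expect_lt(max(abs(coef(f0))) / sd(y), 0.05)
  }
})

test_that("record weights act as residual precision: duplication equals sqrt(2)", {
  set.seed(33)
  n <- 40; p <- 8
  W <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- drop(scale(W, scale = FALSE) %*% rnorm(p, 0, 0.4)) + rnorm(n)
  fv <- list(sigma_e2 = 1, sigma_b2 = 0.2)
  dup <- c(seq_len(n), 1:10)
  f_dup <- wgr(y[dup], W[dup, ], model = "BRR", n_iter = 12000,
               burn_in = 2000, thin = 2, seed = 7, fixed_variances = fv)
  wts <- rep(1, n); wts[1:10] <- sqrt(2)
  f_wt <- wgr(y, W, model = "BRR", weights = wts, n_iter = 12000,
              burn_in = 2000, thin = 2, seed = 7, fixed_variances = fv)
  # oracle: both equal the ridge solution on the duplicated data
  Xd <- cbind(1, W[dup, ])
  pen <- diag(c(0, rep(1 / 0.2, p)))
  sol <- solve(crossprod(Xd) + pen, crossprod(Xd, y[dup]))[-1]
  expect_gt(cor(coef(f_dup), coef(f_wt)), 0.999)
  expect_lt(max(abs(coef(f_wt) - sol)), 0.05)
  expect_lt(max(abs(coef(f_dup) - sol)), 0.05)
})

test_that("BayesC degenerates to BRR at pi = 1 and finds planted QTL", {
  set.seed(44)
  W <- matrix(rbinom(150 * 60, 2, 0.35), 150, 60)
  y <- drop(scale(W, scale = FALSE) %*% rnorm(60, 0, 0.2)) + rnorm(150)
  fb <- wgr(y, W, model = "BRR", n_iter = 3000, burn_in = 500, seed = 2)
  fc <- wgr(y, W, model = "BayesC", n_iter = 3000, burn_in = 500, seed = 2,
            pi_fixed = 1)
  expect_gt(cor(coef(fb), coef(fc)), 0.99)
  # large-effect QTL rank at the top of the inclusion probabilities
  set.seed(45)
  n <- 600; p <- 300
  Wq <- matrix(rbinom(n * p, 2, 0.4), n, p,
               dimnames = list(NULL, sprintf("m%03d", 1:p)))
  qtl <- c(20, 80, 140, 200, 260)
  yq <- drop(scale(Wq[, qtl], scale = FALSE) %*% rep(0.8, 5)) + rnorm(n)
  fq <- wgr(yq, Wq, model = "BayesC", n_iter = 4000, burn_in = 1000, seed = 3)
  top10 <- order(fq$inclusion_prob, decreasing = TRUE)[1:10]
  expect_true(all(qtl %in% top10))
  # no signal: effects vanish; in the small-slab limit the Bayes factor for
  # inclusion is 1, so pi falls back to its prior mean 0.5
  f0 <- wgr(rep(0, 150), W, model = "BayesC", n_iter = 4000, burn_in = 1000,
            seed = 4, hyper = default_hyperparameters(rnorm(150), W),
            fixed_variances = list(sigma_e2 = 1, sigma_b2 = 5e-4))
  expect_lt(max(abs(coef(f0))), 0.05)
  expect_equal(mean(f0$chains$pi), 0.5, tolerance = 0.1)
})

test_that("the Bayesian Lasso shrinks harder than ridge under a stiff penalty", {
  set.seed(55)
  W <- matrix(rbinom(120 * 40, 2, 0.4), 120, 40)
  y <- drop(scale(W, scale = FALSE) %*% rnorm(40, 0, 0.3)) + rnorm(120)
  fb <- wgr(y, W, model = "BRR", n_iter = 3000, burn_in = 600, seed = 6)
  hy <- default_hyperparameters(y, W)
  hy$lasso_rate <- 1e6   # prior concentrates lambda2 at a huge penalty
  hy$lasso_scale <- 1
  fl <- wgr(y, W, model = "BL", n_iter = 3000, burn_in = 600, seed = 6,
            hyper = hy)
  expect_lt(max(abs(coef(fl))), max(abs(coef(fb))))
  # shrinkage ordering on a null trait at matched prior variance
  set.seed(56)
  yn <- rnorm(120)
  fb0 <- wgr(yn, W, model = "BRR", n_iter = 3000, burn_in = 600, seed = 8)
  fl0 <- wgr(yn, W, model = "BL", n_iter = 3000, burn_in = 600, seed = 8)
  expect_lt(sum(coef(fl0)^2), sum(coef(fb0)^2))
})

test_that("DGV prediction is the dosage-effect inner product", {
  fit <- structure(list(mu = 0.7, coefficients = c(0.5, -0.2, 0.3), p = 3,
                        markers = NULL),
                   class = "wgr")
  expect_equal(unname(predict(fit, matrix(c(1, 2, 0), 1))), 0.1)
  expect_equal(unname(predict(fit, matrix(c(1, 2, 0), 1),
                              include_intercept = TRUE)), 0.8)
  fit0 <- fit; fit0$coefficients <- rep(0, 3)
  expect_equal(unname(predict(fit0, matrix(rbinom(30, 2, .5), 10))),
               rep(0, 10))
  # linearity in the genotype row
  w <- c(2, 1, 1); w1 <- c(1, 0, 1); w2 <- c(1, 1, 0)
  expect_equal(predict(fit, matrix(w, 1)),
               predict(fit, matrix(w1, 1)) + predict(fit, matrix(w2, 1)))
  expect_error(predict(fit, matrix(0, 1, 5)), "marker count")
})

test_that("the three marker priors give near-identical DGV on a polygenic trait", {
  st <- med_step1()
  W <- st$W
  y <- st$pseudo$ystar[match(rownames(W), st$pseudo$animal)]
  wts <- st$pseudo$ystar_weight[match(rownames(W), st$pseudo$animal)]
  set.seed(61)
  val <- sample(nrow(W), 120)
  trn <- setdiff(seq_len(nrow(W)), val)
  dgv <- sapply(c("BRR", "BayesC", "BL"), function(m) {
    f <- wgr(y[trn], W[trn, ], model = m, weights = wts[trn],
             n_iter = 2500, burn_in = 600, thin = 5, seed = 9)
    predict(f, W[val, ])
  })
  cc <- cor(dgv)
  expect_true(all(cc[upper.tri(cc)] > 0.95))
})
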