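# Step-1 animal model: outlier filter, relationship matrices, Gibbs sampler
# against the mixed-model-equation oracle, accuracies, Y* and weights.

test_that("contemporary-group outlier filter applies the 3.5 SD rule", {
  # 19 zeros and one 100: mean 5, SD sqrt(500) ~ 22.36, z ~ 4.25 > 3.5
  ph <- data.frame(animal = sprintf("a%02d", 1:20),
                   value = c(rep(0, 19), 100), cg = "CG1")
  kept <- filter_outliers_cg(ph)
  expect_identical(nrow(kept), 19L)
  expect_identical(attr(kept, "removed")$animal, "a20")
  # all within bounds: unchanged
  ph2 <- data.frame(value = rnorm(30), cg = rep(c("A", "B"), 15))
  expect_identical(nrow(filter_outliers_cg(ph2)), 30L)
  # a two-record group falls to the minimum-size rule
  ph3 <- data.frame(value = c(rnorm(10), 1, 2),
                    cg = c(rep("A", 10), "B", "B"))
  kept3 <- filter_outliers_cg(ph3)
  expect_identical(unique(as.character(kept3$cg)), "A")
})

test_that("the numerator relationship matrix matches textbook values", {
  ped <- data.frame(id = c("S", "D", "O"), sire = c("0", "0", "S"),
                    dam = c("0", "0", "D"))
  A <- build_a_matrix(ped)
  expect_equal(A["S", "O"], 0.5)
  expect_equal(A["O", "O"], 1)
  # half sibs: shared sire, unrelated dams
  ped2 <- data.frame(id = c("S", "D1", "D2", "O1", "O2"),
                     sire = c("0", "0", "0", "S", "S"),
                     dam = c("0", "0", "0", "D1", "D2"))
  expect_equal(build_a_matrix(ped2)["O1", "O2"], 0.25)
  # sire mated to his own daughter: inbred offspring, diagonal 1.25
  ped3 <- data.frame(id = c("S", "D0", "D", "C"),
                     sire = c("0", "0", "S", "S"),
                     dam = c("0", "0", "D0", "D"))
  expect_equal(build_a_matrix(ped3)["C", "C"], 1.25)
  expect_error(build_a_matrix(data.frame(id = c("a", "b"),
                                         sire = c("b", "a"),
                                         dam = c("0", "0"))), "cycle")
  # sparse inverse agrees with the dense inverse, inbreeding included
  ped4 <- simulate_pedigree(6, 20, 30, seed = 3)
  ped4 <- rbind(ped4, data.frame(id = "X", sire = "S0001", dam = "O0001"))
  ord <- genopred:::order_pedigree(ped4)
  csr <- genopred:::a_inverse_csr(ord)
  Ainv <- matrix(0, csr$n, csr$n)
  for (i in seq_len(csr$n)) {
    kk <- seq(csr$ptr[i] + 1, csr$ptr[i + 1])
    Ainv[i, csr$idx[kk] + 1] <- csr$val[kk]
  }
  A4 <- build_a_matrix(ped4)
  expect_lt(max(abs(A4 %*% Ainv - diag(csr$n))), 1e-10)
})

test_that("Gibbs posterior means match the mixed-model equations at fixed variances", {
  set.seed(3)
  ped <- simulate_pedigree(20, 90, 90, seed = 2)
  ord <- genopred:::order_pedigree(ped)
  sa2 <- 0.3; se2 <- 0.7
  idx <- setNames(seq_len(nrow(ord)), ord$id)
  a <- numeric(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    s <- ord$sire[i]; d <- ord$dam[i]
    a[i] <- if (s == "0") rnorm(1, 0, sqrt(sa2))
            else 0.5 * (a[idx[[s]]] + a[idx[[d]]]) + rnorm(1, 0, sqrt(sa2 / 2))
  }
  off <- ord$id[ord$sire != "0"]
  cg <- sample(rep(1:6, length.out = length(off)))
  y <- 1 + 0.2 * cg + a[idx[off]] + rnorm(length(off), 0, sqrt(se2))
  dat <- data.frame(animal = off, value = y, cg = factor(cg))
  fit <- animal_model(value ~ cg, dat, ped, n_iter = 40000, burn_in = 8000,
                      thin = 5, seed = 4,
                      fixed_variances = list(sigma_a2 = sa2, sigma_e2 = se2))
  X <- fit$X
  A <- build_a_matrix(ped)[fit$pedigree_ids, fit$pedigree_ids]
  q <- nrow(A)
  Z <- matrix(0, length(y), q)
  Z[cbind(seq_along(y), match(off, fit$pedigree_ids))] <- 1
  LHS <- rbind(cbind(crossprod(X) / se2, crossprod(X, Z) / se2),
               cbind(crossprod(Z, X) / se2,
                     crossprod(Z) / se2 + solve(A) / sa2))
  sol <- solve(LHS, c(crossprod(X, y) / se2, crossprod(Z, y) / se2))
  a_mme <- sol[-seq_len(ncol(X))]
  expect_gt(cor(fit$ebv, a_mme), 0.999)
  # PEV against the inverse-coefficient-matrix diagonal
  pev_mme <- diag(solve(LHS))[-seq_len(ncol(X))]
  expect_equal(unname(fit$pev), pev_mme, tolerance = 0.08)
  # an animal with a record keeps PEV below sigma_a2
  expect_true(all(fit$pev[off] < sa2))
})

test_that("EBV accuracy formula and its edge cases", {
  expect_equal(ebv_accuracy(0, 2), 1)
  expect_equal(ebv_accuracy(2, 2), 0)
  expect_equal(ebv_accuracy(0.75 * 2, 2), 0.5)
  expect_equal(ebv_accuracy(3, 2), 0) # clamped when PEV exceeds sigma_g2
  expect_error(ebv_accuracy(1, 0), "positive")
  expect_error(ebv_accuracy(-1, 1), "non-negative")
})

test_that("adjusted phenotypes remove exactly the fitted fixed effects", {
  st <- med_step1()
  fit <- st$fit
  ystar <- adjusted_phenotype(fit)
  # Y* + fitted fixed effects reconstructs y exactly
  expect_equal(unname(ystar + drop(fit$X %*% fit$coefficients)),
               unname(fit$y))
  expect_lt(abs(mean(ystar)), 0.5 * sd(ystar))
  # prior-dominated animal: no record, no informative relatives
  ped <- rbind(st$sim$pedigree,
               data.frame(id = "LONER", sire = "0", dam = "0"))
  fit2 <- animal_model(value ~ cg + age, st$sim$phenotypes, ped,
                       n_iter = 4000, burn_in = 1000, thin = 5, seed = 8)
  expect_lt(abs(fit2$ebv["LONER"]), 3 * sqrt(fit2$sigma_a2 / 100))
  expect_equal(unname(fit2$pev["LONER"]), fit2$sigma_a2, tolerance = 0.25)
})

test_that("a constant added to one contemporary group is absorbed by its effect", {
  sim <- tiny_population()
  ph <- sim$phenotypes
  fit1 <- animal_model(value ~ cg + age, ph, sim$pedigree,
                       n_iter = 8000, burn_in = 2000, thin = 5, seed = 21)
  ph2 <- ph
  grp <- ph2$cg == ph2$cg[1]
  ph2$value[grp] <- ph2$value[grp] + 50
  fit2 <- animal_model(value ~ cg + age, ph2, sim$pedigree,
                       n_iter = 8000, burn_in = 2000, thin = 5, seed = 21)
  y1 <- adjusted_phenotype(fit1)[ph$animal[grp]]
  y2 <- adjusted_phenotype(fit2)[ph$animal[grp]]
  expect_lt(max(abs(y1 - y2)), 0.1)
  expect_lt(abs(mean(y1 - y2)), 0.05)
})

test_that("h2 is invariant to rescaling the trait", {
  sim <- tiny_population()
  fit1 <- suppressWarnings(
    animal_model(value ~ cg + age, sim$phenotypes, sim$pedigree,
                 n_iter = 8000, burn_in = 2000, thin = 5, seed = 13))
  ph2 <- sim$phenotypes
  ph2$value <- ph2$value * 10
  fit2 <- suppressWarnings(
    animal_model(value ~ cg + age, ph2, sim$pedigree,
                 n_iter = 8000, burn_in = 2000, thin = 5, seed = 13))
  expect_equal(fit1$h2, fit2$h2, tolerance = 0.05)
  expect_equal(fit2$sigma_a2 / fit1$sigma_a2, 100, tolerance = 15)
})

test_that("permuted phenotypes on a structured pedigree yield low heritability", {
  sim <- tiny_population()
  ph <- sim$phenotypes
  set.seed(5)
  ph$value <- sample(ph$value) # destroys family resemblance
  fit <- animal_model(value ~ cg + age, ph, sim$pedigree,
                      n_iter = 10000, burn_in = 2500, thin = 5, seed = 6)
  expect_lt(fit$h2, 0.15)
})

test_that("Y* weights follow the hat-matrix closed forms", {
  # intercept only, V = s2 I: all weights s * sqrt(1 - 1/n)
  n <- 25; s2 <- 4
  X <- matrix(1, n, 1)
  w <- ystar_weights(X, g_var = s2 / 2, r_var = s2 / 2)
  expect_equal(unname(w), rep(sqrt(s2) * sqrt(1 - 1 / n), n))
  w2 <- ystar_weights(matrix(1, 2, 1), g_var = 0.5, r_var = 0.5)
  expect_equal(unname(w2), rep(sqrt(0.5), 2))
  # permutation equivariance
  set.seed(2)
  X3 <- cbind(1, rnorm(30), rbinom(30, 1, 0.4))
  w3 <- ystar_weights(X3, 1, 2)
  perm <- sample(30)
  expect_equal(unname(ystar_weights(X3[perm, ], 1, 2)), unname(w3)[perm])
  expect_error(ystar_weights(cbind(1, rep(0, 5), rep(2, 5)), 1, 1),
               "rank deficient")
})

test_that("EBV weights are the step-1 accuracies and land in a plausible band", {
  st <- med_step1()
  ps <- st$pseudo
  expect_equal(ps$ebv_weight, ps$accuracy)
  expect_equal(ps$accuracy,
               unname(ebv_accuracy(unname(st$fit$pev[ps$animal]),
                                   st$fit$sigma_a2)))
  expect_true(all(ps$accuracy >= 0 & ps$accuracy <= 1))
  # plausibility band around reported EBV accuracies for such designs
  expect_gt(mean(ps$accuracy), 0.2)
  expect_lt(mean(ps$accuracy), 0.7)
  expect_true(all(ps$ystar_weight > 0))
})
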