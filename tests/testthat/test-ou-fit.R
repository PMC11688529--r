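test_that("BM1 maximum likelihood matches the closed-form GLS solution", {
  rp <- random_painted_tree(30, seed = 61)
  prm <- ou_params(ou_model("BM1"), attr(rp$painting, "alphabet"),
                   sigma2 = 0.3, x0 = 2)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 8)
  y <- stats::setNames(sim$trait, sim$species)
  fit <- suppressWarnings(fit_ou(rp$tree, rp$painting, y, model = "BM1"))
  C <- ape::vcv(rp$tree)[rp$tree$tip.label, rp$tree$tip.label]
  yv <- unname(y[rp$tree$tip.label])
  one <- rep(1, 30)
  Ci <- solve(C)
  mu_hat <- as.numeric((t(one) %*% Ci %*% yv) / (t(one) %*% Ci %*% one))
  s2_hat <- as.numeric(t(yv - mu_hat) %*% Ci %*% (yv - mu_hat)) / 30
  expect_equal(unname(fit$params$x0), mu_hat, tolerance = 1e-8)
  expect_equal(unname(fit$params$sigma2[1]), s2_hat, tolerance = 1e-8)
  expect_null(fit$params$theta)
  expect_equal(fit$p, 2L)
})

test_that("Akaike weights follow the closed form and sum to one", {
  w <- aic_weights(c(10, 12))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(aic_weights(rep(4, 5)), rep(0.2, 5))
  expect_equal(sum(aic_weights(c(3, 9, 1, 2.2))), 1, tolerance = 1e-12)
})

test_that("weights refuse fits on different data", {
  rp <- random_painted_tree(12, seed = 3)
  prm <- ou_params(ou_model("OU1"), attr(rp$painting, "alphabet"),
                   theta = 1, alpha = 1, sigma2 = 0.2)
  s1 <- simulate_traits(rp$tree, rp$painting, prm, seed = 1)
  s2 <- simulate_traits(rp$tree, rp$painting, prm, seed = 2)
  f1 <- suppressWarnings(fit_ou(rp$tree, rp$painting,
                                stats::setNames(s1$trait, s1$species), "OU1"))
  f2 <- suppressWarnings(fit_ou(rp$tree, rp$painting,
                                stats::setNames(s2$trait, s2$species), "OU1"))
  expect_error(aic_weights(list(f1, f2)), "identical data")
  expect_error(aic_weights(list(f1)), ">= 2 fits")
})

test_that("parameter counts match the model definitions and AICc >= AIC", {
  rp <- random_painted_tree(40, seed = 85, q = 1.5)
  R <- length(unique(rp$painting$regime))
  expect_equal(R, 3L)
  prm <- ou_params(ou_model("OUM"), c("LS", "CC", "CS"),
                   theta = c(LS = 2.5, CC = 2, CS = 1.5), alpha = 3, sigma2 = 0.2)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 5)
  y <- stats::setNames(sim$trait, sim$species)
  expected_p <- c(BM1 = 2, BMS = R + 1, OU1 = 3, OUM = R + 2,
                  OUMV = 2 * R + 1, OUMA = 2 * R + 1, OUMVA = 3 * R)
  for (nm in names(expected_p)) {
    f <- suppressWarnings(fit_ou(rp$tree, rp$painting, y, model = nm,
                                 n_starts = 2, seed = 1))
    expect_equal(f$p, unname(expected_p[nm]), info = nm)
    expect_gte(f$aicc, f$aic)
  }
})

test_that("nested models never fit worse than their restrictions", {
  rp <- random_painted_tree(50, seed = 20, q = 1.2)
  expect_equal(length(unique(rp$painting$regime)), 3L)
  prm <- ou_params(ou_model("OUMA"), c("LS", "CC", "CS"),
                   theta = c(LS = 2.7, CC = 2.2, CS = 1.8),
                   alpha = c(LS = 1.5, CC = 3, CS = 6), sigma2 = 0.15)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 3)
  y <- stats::setNames(sim$trait, sim$species)
  cmp <- suppressWarnings(fit_ou_models(rp$tree, rp$painting, y,
                                        n_starts = 6, seed = 2))
  ll <- stats::setNames(cmp$loglik, cmp$model)
  expect_gte(ll["OUM"], ll["OU1"] - 1e-4)
  expect_gte(ll["OUMA"], ll["OUM"] - 1e-4)
  expect_gte(ll["OUMV"], ll["OUM"] - 1e-4)
  expect_gte(ll["OUMVA"], ll["OUMA"] - 1e-4)
  expect_gte(ll["OUMVA"], ll["OUMV"] - 1e-4)
  expect_gte(ll["OU1"], ll["BM1"] - 1e-4)
  expect_equal(sum(cmp$aicw), 1, tolerance = 1e-12)
})

test_that("the global-optimum model equals intercept-only GLS under the OU kernel", {
  rp <- random_painted_tree(35, seed = 71)
  prm <- ou_params(ou_model("OU1"), attr(rp$painting, "alphabet"),
                   theta = 2, alpha = 2, sigma2 = 0.3)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 6)
  y <- stats::setNames(sim$trait, sim$species)
  fou <- suppressWarnings(fit_ou(rp$tree, rp$painting, y, model = "OU1"))
  V <- error_covariance(rp$tree, "OUfixedRoot", alpha = unname(fou$params$alpha[1]))
  yv <- unname(y[rp$tree$tip.label])
  ch <- chol(V)
  Xw <- backsolve(ch, rep(1, 35), transpose = TRUE)
  yw <- backsolve(ch, yv, transpose = TRUE)
  b <- sum(Xw * yw) / sum(Xw^2)
  s2 <- sum((yw - Xw * b)^2) / 35
  ll <- -35 / 2 * (log(2 * pi) + log(s2) + 1) - sum(log(diag(ch)))
  expect_equal(fou$loglik, ll, tolerance = 1e-6)
  expect_equal(unname(fou$params$theta[1]), b, tolerance = 1e-6)
})

test_that("tidy and glance return well-formed summaries with standard errors", {
  rp <- random_painted_tree(40, seed = 15, q = 1.2)
  expect_gte(length(unique(rp$painting$regime)), 2L)
  prm <- ou_params(ou_model("OUM"), c("LS", "CC", "CS"),
                   theta = c(LS = 2.5, CC = 2, CS = 1.5), alpha = 3, sigma2 = 0.2)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 4)
  f <- suppressWarnings(fit_ou(rp$tree, rp$painting,
                               stats::setNames(sim$trait, sim$species),
                               model = "OUM", compute_se = TRUE))
  td <- tidy(f)
  expect_true(all(c("term", "regime", "estimate", "mbp") %in% names(td)))
  expect_true(all(10^td$estimate[td$term == "theta"] == td$mbp[td$term == "theta"]))
  if (!is.null(f$se)) expect_true(all(is.finite(td$se[td$term == "theta"])))
  g <- glance(f)
  expect_identical(g$model, "OUM")
  expect_equal(g$n, 40L)
})
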