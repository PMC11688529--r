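test_that("the OU branch transition kernel has the right limits and values", {
  # fixed point: starting at the optimum stays centred on it
  bt <- branch_transition(2.5, theta = 2.5, alpha = 3, sigma2 = 0.1, t = 4)
  expect_equal(bt$mean, 2.5)
  # stationary limit
  bt2 <- branch_transition(9, theta = 2, alpha = 2, sigma2 = 0.5, t = 300)
  expect_equal(bt2$mean, 2, tolerance = 1e-12)
  expect_equal(bt2$var, 0.5 / 4, tolerance = 1e-12)
  # closed form: alpha = 1, sigma2 = 2, t = ln 2 -> var = 0.75
  expect_equal(branch_transition(0, 0, 1, 2, log(2))$var, 0.75, tolerance = 1e-12)
  # BM limit handled smoothly near alpha t -> 0
  expect_equal(branch_transition(1, 5, 1e-9, 0.3, 2)$var, 0.6, tolerance = 1e-6)
  expect_equal(branch_transition(1, 5, 0, 0.3, 2)$mean, 1)
  expect_error(branch_transition(1, 0, 1, 1, -1), "negative")
})

test_that("single-regime limits recover closed-form Gaussian likelihoods", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  p <- paint_regimes(tr, rep("LS", 5), alphabet = "LS")
  y <- c(A = 0.3, B = 0.1, C = -0.2)

  # alpha -> 0 equals Brownian motion with C = sigma2 * shared-path matrix
  prm <- ou_params(ou_model("OU1"), "LS", theta = 0.1, alpha = 1e-10, sigma2 = 0.4)
  Cbm <- 0.4 * rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  oracle <- naive_mvn_loglik(unname(y[c("A", "B", "C")]), rep(0.1, 3), Cbm)
  expect_equal(ou_likelihood(tr, p, prm, y), oracle, tolerance = 1e-5)

  # two-tip star, fixed root: product of two univariate normals
  star <- read_newick("(A:2,B:2);")
  ps <- paint_regimes(star, rep("LS", 3), alphabet = "LS")
  prm2 <- ou_params(ou_model("OU1"), "LS", theta = 1, alpha = 0.7, sigma2 = 0.3)
  v <- 0.3 * (1 - exp(-2 * 0.7 * 2)) / (2 * 0.7)
  y2 <- c(A = 1.4, B = 0.6)
  oracle2 <- sum(dnorm(y2, 1, sqrt(v), log = TRUE))
  expect_equal(ou_likelihood(star, ps, prm2, y2), oracle2, tolerance = 1e-10)
  expect_equal(ou_likelihood(star, ps, prm2, y2, method = "bp"), oracle2,
               tolerance = 1e-10)
})

test_that("MVN and belief-propagation routes agree across all seven models", {
  specs <- c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")
  for (s in 1:4) {
    rp <- random_painted_tree(sample(5:16, 1), seed = 100 + s)
    for (nm in specs) {
      spec <- ou_model(nm)
      prm <- random_ou_params(spec, rp$painting |> attr("alphabet"), seed = 17 * s)
      sim <- simulate_traits(rp$tree, rp$painting, prm, seed = s)
      y <- stats::setNames(sim$trait, sim$species)
      l1 <- suppressWarnings(ou_likelihood(rp$tree, rp$painting, prm, y, method = "mvn"))
      l2 <- suppressWarnings(ou_likelihood(rp$tree, rp$painting, prm, y, method = "bp"))
      expect_equal(l1, l2, tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to a common shift of traits and optima", {
  rp <- random_painted_tree(12, seed = 55)
  spec <- ou_model("OUMA")
  regs <- attr(rp$painting, "alphabet")
  prm <- random_ou_params(spec, regs, seed = 9)
  sim <- simulate_traits(rp$tree, rp$painting, prm, seed = 2)
  y <- stats::setNames(sim$trait, sim$species)
  l0 <- suppressWarnings(ou_likelihood(rp$tree, rp$painting, prm, y))
  shift <- 3.7
  prm_s <- ou_params(spec, regs, theta = prm$theta + shift, alpha = prm$alpha,
                     sigma2 = prm$sigma2)
  expect_equal(suppressWarnings(ou_likelihood(rp$tree, rp$painting, prm_s, y + shift)),
               l0, tolerance = 1e-9)
})

test_that("simulation moments match the analytic mean and covariance", {
  rp <- random_painted_tree(4, seed = 21)
  spec <- ou_model("OUM")
  regs <- attr(rp$painting, "alphabet")
  prm <- ou_params(spec, regs, theta = c(LS = 2, CC = 1, CS = 0),
                   alpha = 2, sigma2 = 0.5)
  td <- ouregime:::ou_tree_data(rp$tree, rp$painting)
  mom <- ouregime:::ou_moments(td, prm$alpha, prm$sigma2, spec)
  mu <- as.numeric(mom$X %*% ouregime:::ou_beta(prm, colnames(mom$X), td$root_regime))
  N <- 4000
  sims <- matrix(0, N, 4)
  for (i in seq_len(N))
    sims[i, ] <- simulate_traits(rp$tree, rp$painting, prm, seed = 5000 + i)$trait
  se_mean <- sqrt(diag(mom$C) / N)
  expect_true(all(abs(colMeans(sims) - mu) < 3.5 * se_mean))
  Chat <- cov(sims)
  # rough s.e. for covariance entries of a Gaussian
  se_cov <- sqrt((mom$C^2 + outer(diag(mom$C), diag(mom$C))) / N)
  expect_true(all(abs(Chat - mom$C) < 4 * se_cov))

  # two-tip star BM: tip covariance ~ 0, variance ~ sigma2 * T
  star <- read_newick("(A:1,B:1);")
  ps <- paint_regimes(star, rep("LS", 3), alphabet = "LS")
  pb <- ou_params(ou_model("BM1"), "LS", sigma2 = 0.8, x0 = 0)
  simsb <- matrix(0, N, 2)
  for (i in seq_len(N)) simsb[i, ] <- simulate_traits(star, ps, pb, seed = i)$trait
  expect_lt(abs(cov(simsb)[1, 2]), 4 * 0.8 / sqrt(N))
  expect_lt(abs(var(simsb[, 1]) - 0.8), 4 * 0.8 * sqrt(2 / N))

  # vanishing diffusion: tips collapse onto the deterministic path
  p0 <- ou_params(ou_model("OU1"), regs, theta = 1.5, alpha = 1, sigma2 = 1e-12)
  s0 <- simulate_traits(rp$tree, rp$painting, p0, seed = 1)
  expect_true(all(abs(s0$trait - 1.5) < 1e-4))
})

test_that("degenerate inputs are rejected with informative errors", {
  rp <- random_painted_tree(6, seed = 4)
  prm <- random_ou_params(ou_model("OU1"), attr(rp$painting, "alphabet"), seed = 1)
  y <- stats::setNames(rnorm(6), rp$tree$tip.label)
  expect_error(ou_likelihood(rp$tree, rp$painting, prm, y[-1]), "missing")
  expect_error(ou_params(ou_model("OU1"), "LS", theta = 1, alpha = -1, sigma2 = 1),
               "alpha")
  expect_error(ou_params(ou_model("BM1"), "LS", sigma2 = 1), "x0")
})
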