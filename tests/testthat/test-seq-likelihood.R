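test_that("JC transition probabilities match the closed form", {
  m <- subst_model("JC")
  eig <- ouregime:::subst_eigen(m)
  for (t in c(0, 0.1, 0.7, 3)) {
    P <- ouregime:::transition_prob(eig, t)
    same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    expect_equal(unname(diag(P)), rep(same, 4), tolerance = 1e-12)
    expect_equal(unname(P[1, 2]), diff, tolerance = 1e-12)
  }
  # stationarity limit
  P_inf <- ouregime:::transition_prob(eig, 500)
  expect_equal(as.numeric(P_inf), rep(0.25, 16), tolerance = 1e-12)
})

test_that("discrete-Gamma category rates follow the mean-of-band convention", {
  for (a in c(0.3, 0.5, 1, 2.7)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    # oracle: numeric integration of x * dgamma over each quantile band
    b <- qgamma(seq(0, 1, 0.25), a, a)
    oracle <- vapply(1:4, function(i)
      4 * integrate(function(x) x * dgamma(x, a, a), b[i], b[i + 1])$value,
      numeric(1))
    expect_equal(r, oracle, tolerance = 1e-6)
  }
  expect_identical(discrete_gamma_rates(0.5, 1), 1)
})

test_that("identical sequences on a near-zero branch give 0.25 per site", {
  tr <- read_newick("(A:1e-9,B:1e-9);")
  aln <- rbind(A = strsplit("ACGTAC", "")[[1]], B = strsplit("ACGTAC", "")[[1]])
  sl <- site_likelihood(tr, aln, subst_model("JC"))
  expect_equal(sl$loglik, rep(log(0.25), 6), tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(31)
  for (case in 1:3) {
    n <- sample(4:6, 1)
    tr <- ape::rcoal(n)
    L <- sample(6:10, 1)
    aln <- matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n,
                  dimnames = list(tr$tip.label, NULL))
    models <- list(subst_model("JC", gamma = TRUE, shape = 0.4, k = 4),
                   subst_model("HKY", kappa = 3,
                               base_freq = c(0.4, 0.1, 0.2, 0.3)))
    for (m in models) {
      ours <- attr(site_likelihood(tr, aln, m), "total")
      oracle <- brute_force_seq_loglik(tr, aln, m)
      expect_equal(ours, oracle, tolerance = 1e-8)
    }
  }
})

test_that("likelihood matches phangorn and is invariant under re-rooting", {
  skip_if_not_installed("phangorn")
  rp <- random_painted_tree(12, seed = 8)
  aln <- simulate_alignment_with_cox_site(rp$tree, rp$history$node_states,
                                          L = 90, site_map = list(10:12, 13:15),
                                          seed = 4)
  m <- subst_model("JC", gamma = TRUE, shape = 0.5, k = 4)
  ours <- attr(site_likelihood(rp$tree, aln, m), "total")
  ph <- phangorn::pml(rp$tree, phangorn::phyDat(aln), k = 4, shape = 0.5)
  expect_equal(ours, ph$logLik, tolerance = 1e-6)

  rerooted <- ape::root(ape::unroot(rp$tree), outgroup = rp$tree$tip.label[5],
                        resolve.root = TRUE)
  expect_equal(attr(site_likelihood(rerooted, aln, m), "total"), ours,
               tolerance = 1e-6)
})

test_that("gaps and ambiguity codes act as partial missing data", {
  tr <- read_newick("(A:0.2,B:0.2);")
  aln_gap <- rbind(A = c("A", "N", "-"), B = c("A", "C", "G"))
  sl <- site_likelihood(tr, aln_gap, subst_model("JC"))
  # fully missing site: likelihood is the stationary probability of the
  # observed base alone
  expect_equal(sl$loglik[3], log(0.25), tolerance = 1e-9)
  aln_r <- rbind(A = "R", B = "A")  # R = A or G
  two <- site_likelihood(tr, aln_r, subst_model("JC"))
  P <- 1 / 4 + 3 / 4 * exp(-4 * 0.4 / 3)
  expect_equal(two$loglik[1], log(0.25 * P + 0.25 * (1 - P) / 3), tolerance = 1e-9)
})

test_that("BIC selects the generating model for rate homogeneity vs heterogeneity", {
  tr <- simulate_yule_tree(6, seed = 10, height = NULL)
  tr$edge.length <- tr$edge.length / tree_height(tr) * 0.8
  cand <- list(subst_model("JC"), subst_model("JC", gamma = TRUE))

  flat <- sim_alignment_with_root(tr, subst_model("JC"), L = 4000, seed = 21)
  tab1 <- select_model_bic(tr, flat$alignment, cand, fit_rescale = FALSE)
  expect_identical(tab1$model[1], "JC")

  het <- sim_alignment_with_root(tr, subst_model("JC", gamma = TRUE, shape = 0.3),
                                 L = 4000, seed = 22)
  tab2 <- select_model_bic(tr, het$alignment, cand, fit_rescale = FALSE)
  expect_identical(tab2$model[1], "JC+G")
  expect_true(all(diff(tab2$bic) >= 0))
  expect_error(select_model_bic(tr, flat$alignment, cand[1]), ">= 2 candidate")
})

test_that("species mismatches are reported by name", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  aln <- rbind(A = c("A", "C"), B = c("A", "C"))
  expect_error(site_likelihood(tr, aln, subst_model("JC")), "C")
})
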