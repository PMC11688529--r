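make_state_data <- function(n, seed, q = 0.8, effect = c(CC = -0.4, CS = -0.7),
                            error_model_truth = "BM", sigma2 = 0.1, alpha = 3) {
  rp <- random_painted_tree(n, seed = seed, q = q)
  st <- rp$history$node_states[seq_len(n)]
  prm <- if (error_model_truth == "BM")
    ou_params(ou_model("BM1"), c("LS", "CC", "CS"), sigma2 = sigma2, x0 = 0)
  else
    ou_params(ou_model("OU1"), c("LS", "CC", "CS"), theta = 0, alpha = alpha,
              sigma2 = sigma2)
  resid <- simulate_traits(rp$tree, rp$painting, prm, seed = seed + 5000L)
  shift <- c(LS = 0, effect)[st]
  list(tree = rp$tree,
       data = tibble::tibble(species = resid$species,
                             value = resid$trait + unname(shift),
                             cox_state = st))
}

test_that("a star phylogeny reduces PGLS to ordinary least squares", {
  n <- 30
  tr <- read_newick(paste0("(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  set.seed(2)
  st <- sample(c("LS", "CC", "CS"), n, TRUE, prob = c(0.4, 0.4, 0.2))
  y <- rnorm(n) + c(LS = 0, CC = -0.5, CS = -1)[st]
  dat <- tibble::tibble(species = paste0("t", 1:n), value = y, cox_state = st)
  f <- fit_pgls(dat, tr, "value", "cox_state", error_model = "BM")
  ols <- lm(y ~ factor(st, levels = c("LS", "CC", "CS")))
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)
  # group-mean contrasts are exact on iid data
  mns <- tapply(y, st, mean)
  expect_equal(unname(f$coefficients[2]), unname(mns["CC"] - mns["LS"]),
               tolerance = 1e-10)
})

test_that("BM PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  md <- make_state_data(45, seed = 9)
  f <- suppressWarnings(fit_pgls(md$data, md$tree, "value", "cox_state",
                                 error_model = "BM"))
  df <- as.data.frame(md$data)
  g <- nlme::gls(value ~ factor(cox_state, levels = c("LS", "CC", "CS")),
                 data = df,
                 correlation = ape::corBrownian(1, md$tree, form = ~species),
                 method = "ML")
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-7)
})

test_that("OU error covariance kernels match their closed forms", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  # alpha -> 0 limit of the fixed-root OU kernel is the BM kernel
  Vsmall <- error_covariance(tr, "OUfixedRoot", alpha = 1e-7)
  Vbm <- error_covariance(tr, "BM")
  expect_equal(Vsmall, Vbm, tolerance = 1e-5)
  # tips diverging at the root are uncorrelated under fixed-root OU
  V <- error_covariance(tr, "OUfixedRoot", alpha = 1)
  expect_equal(unname(V["A", "C"]), 0, tolerance = 1e-12)
  # closed form for the cherry: t_AB = 1, d_AB = 2
  expect_equal(unname(V["A", "B"]), exp(-2) * (1 - exp(-2)) / 2, tolerance = 1e-12)
  # stationary kernel
  Vr <- error_covariance(tr, "OUrandomRoot", alpha = 1)
  expect_equal(unname(Vr["A", "B"]), exp(-2) / 2, tolerance = 1e-12)
  expect_equal(unname(diag(Vr)), rep(0.5, 3), tolerance = 1e-12)
  expect_error(error_covariance(tr, "OUfixedRoot", alpha = 0), "alpha")
})

test_that("group offsets are recovered and R-squared conventions are reported", {
  md <- make_state_data(120, seed = 31, q = 0.5,
                        error_model_truth = "OU", sigma2 = 0.2)
  f <- suppressWarnings(fit_pgls(md$data, md$tree, "value", "cox_state",
                                 error_model = "OUfixedRoot"))
  co <- tidy(f)
  expect_identical(co$term[1], "(Intercept) LS")
  expect_lt(co$estimate[co$term == "offset CC"], 0)
  expect_lt(abs(co$estimate[co$term == "offset CC"] - (-0.4)), 3 * co$std_error[2])
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
  g <- glance(f)
  expect_lt(g$adj_r2, g$r2)
  expect_lt(g$adj_r2_alt, g$adj_r2)
  expect_gt(g$alpha, 0)
})

test_that("error-model selection favours the generating structure and flags ties", {
  wins <- 0L
  for (s in 1:12) {
    md <- make_state_data(80, seed = 300 + s, error_model_truth = "BM")
    sel <- suppressWarnings(select_error_model(md$data, md$tree, "value",
                                               "cox_state"))
    wins <- wins + (sel$error_model[1] == "BM")
  }
  expect_gte(wins, 8L)  # scaled-down version of the >80%-of-replicates design

  md <- make_state_data(50, seed = 77)
  dup <- suppressWarnings(select_error_model(md$data, md$tree, "value", "cox_state",
                                             candidates = c("BM", "BM")))
  expect_equal(dup$aicw, c(0.5, 0.5), tolerance = 1e-12)
  expect_true(dup$comparable[1])
})

test_that("species are reconciled and degenerate designs are rejected", {
  md <- make_state_data(25, seed = 13)
  dat <- md$data
  dat$value[3] <- NA                               # dropped: missing trait
  extra <- tibble::tibble(species = "not_on_tree", value = 1, cox_state = "LS")
  f <- suppressWarnings(fit_pgls(dplyr::bind_rows(dat, extra), md$tree,
                                 "value", "cox_state", error_model = "BM"))
  expect_equal(f$n, 24L)
  one_level <- tibble::tibble(species = md$data$species, value = md$data$value,
                              cox_state = "LS")
  expect_error(fit_pgls(one_level, md$tree, "value", "cox_state"),
               "single level")
})

test_that("the t-test of a null group offset keeps its nominal size", {
  # true null: single-regime OU residuals, states purely historical
  n_rej <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    md <- make_state_data(60, seed = 1000 + s, effect = c(CC = 0, CS = 0),
                          error_model_truth = "OU", sigma2 = 0.2)
    if (length(unique(md$data$cox_state)) < 2 ||
        sum(md$data$cox_state == "CC") < 3) next
    f <- suppressWarnings(fit_pgls(md$data, md$tree, "value", "cox_state",
                                   error_model = "OUfixedRoot"))
    pv <- f$p_value[grep("offset CC", names(f$p_value))]
    if (length(pv) && pv < 0.05) n_rej <- n_rej + 1L
  }
  # loose 3-sigma band around 5% for this reduced replicate count
  expect_lt(n_rej / n_rep, 0.17)
})
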