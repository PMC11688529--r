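test_that("Yule trees have the promised shape, scaling and labels", {
  two <- simulate_yule_tree(2, seed = 1, height = 0.7)
  expect_equal(ape::Ntip(two), 2L)
  expect_equal(unname(two$edge.length), c(0.7, 0.7))

  tr <- simulate_yule_tree(37, seed = 4)
  expect_equal(tr$Nnode, 36L)
  expect_equal(nrow(tr$edge), 72L)
  expect_true(as.logical(check_ultrametric(tr)))
  expect_equal(tree_height(tr), 1, tolerance = 1e-12)
  expect_identical(tr$tip.label[1], "sp0001")
  expect_identical(simulate_yule_tree(20, seed = 9)$edge.length,
                   simulate_yule_tree(20, seed = 9)$edge.length)
})

test_that("Yule node ages follow the conditional truncated-exponential law", {
  # for a pure-birth tree conditioned on n tips, given the crown age T the
  # non-root node ages are iid Exp(lambda) truncated to [0, T]
  lam <- 1
  tr <- simulate_yule_tree(1500, birth_rate = lam, height = NULL, seed = 20)
  dep <- ouregime:::node_depths(tr)
  crown <- max(dep[1:1500])
  ages <- crown - dep[(1500 + 2):(1500 + tr$Nnode)]
  ks <- suppressWarnings(stats::ks.test(
    ages, function(a) (1 - exp(-lam * a)) / (1 - exp(-lam * crown))))
  expect_gt(ks$p.value, 0.01)
})

test_that("study bundles are deterministic, complete and internally consistent", {
  cfg <- synthetic_study_config(n_tips = 40, seq_coverage = 0.5)
  st1 <- build_synthetic_study(cfg, seed = 3)
  st2 <- build_synthetic_study(cfg, seed = 3)
  expect_identical(st1$traits, st2$traits)
  expect_identical(st1$alignment, st2$alignment)

  expect_equal(nrow(st1$traits), 40L)
  expect_equal(st1$traits$mean_chromosome_size_Mbp * st1$traits$chromosome_number,
               st1$traits$genome_size_1C_Mbp, tolerance = 1e-12)
  # sequenced subset classifies back to the true states
  cls <- classify_cox_tips(st1$alignment, st1$config$site_map)
  truth <- st1$truth$node_states[match(cls$species, st1$tree$tip.label)]
  expect_identical(cls$cox_state, truth)
  # taxonomy encodes the generating regime via the genus rule
  expect_true(all((st1$taxonomy$genus == "Utricularia") ==
                    (st1$truth$node_states[1:40] == "CC")))
  # states table: sequenced species have states, the rest are NA
  expect_equal(sum(!is.na(st1$states$cox_state)), 20L)
})

test_that("bundles written to disk round-trip through the file interfaces", {
  dir <- withr::local_tempdir()
  st <- build_synthetic_study(synthetic_study_config(n_tips = 25), seed = 8)
  write_study_bundle(st, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "alignment.fasta",
                                               "traits.csv", "truth.json")))))
  tr <- read_newick(file = file.path(dir, "tree.nwk"))
  expect_equal(ape::Ntip(tr), 25L)
  aln <- read_fasta(file.path(dir, "alignment.fasta"))
  expect_identical(aln, ouregime:::as_alignment_matrix(st$alignment))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$sigma2, st$truth$sigma2)
})

test_that("regime histories in bundles respect the composition bands", {
  for (s in c(2, 9, 31)) {
    st <- build_synthetic_study(synthetic_study_config(n_tips = 60), seed = s)
    frac <- table(factor(st$truth$node_states[1:60],
                         levels = c("LS", "CC", "CS"))) / 60
    expect_gte(frac[["LS"]], 0.2); expect_lte(frac[["LS"]], 0.7)
    expect_gte(frac[["CC"]], 0.2); expect_lte(frac[["CC"]], 0.7)
    expect_gte(frac[["CS"]], 0.05)
  }
})

test_that("ancestral reconstruction on a synthetic study recovers the root state", {
  # moderate-size single check; the full recovery-rate harness runs in the
  # acceptance suite
  st <- build_synthetic_study(synthetic_study_config(n_tips = 50,
                                                     seq_coverage = 1),
                              seed = 21)
  m <- subst_model("JC", gamma = TRUE, shape = 0.5)
  fit <- ouregime:::fit_subst_model(st$tree, st$alignment, m, fit_rescale = TRUE)
  asr <- marginal_asr(st$tree, st$alignment, fit$model, rescale = fit$rescale)
  root_state <- classify_cox_state(asr, st$config$site_map, node = 51L)
  expect_identical(as.character(root_state),
                   st$truth$node_states[51])
})
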