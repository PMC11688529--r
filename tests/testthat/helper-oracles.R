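# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: sequence likelihoods by exhaustive
# enumeration over internal states, Gaussian densities via determinant/solve,
# and small closed forms.

# Exhaustive-enumeration log-likelihood of an alignment under a (possibly
# discrete-Gamma) substitution model; feasible for <= 6 tips.
brute_force_seq_loglik <- function(tree, aln, model, rescale = 1) {
  m <- toupper(as.matrix(aln))
  m <- m[match(tree$tip.label, rownames(m)), , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  eig <- ouregime:::subst_eigen(model)
  rates <- if (model$gamma) discrete_gamma_rates(model$shape, model$k) else 1
  pi <- model$base_freq
  grid <- as.matrix(expand.grid(replicate(n_int, 1:4, simplify = FALSE)))
  total <- 0
  for (s in seq_len(ncol(m))) {
    tip_idx <- match(m[, s], bases)
    lik <- 0
    for (r in rates) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        ouregime:::transition_prob(eig, r * tree$edge.length[e] * rescale))
      for (g in seq_len(nrow(grid))) {
        st <- c(tip_idx, grid[g, ])
        pr <- unname(pi[st[n_tip + 1L]]) / length(rates)
        for (e in seq_len(nrow(tree$edge)))
          pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
        lik <- lik + pr
      }
    }
    total <- total + log(lik)
  }
  total
}

# Exhaustive marginal posterior over internal-node states at one site.
brute_force_asr_posterior <- function(tree, aln, model, site, rescale = 1) {
  m <- toupper(as.matrix(aln))
  m <- m[match(tree$tip.label, rownames(m)), , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  eig <- ouregime:::subst_eigen(model)
  rates <- if (model$gamma) discrete_gamma_rates(model$shape, model$k) else 1
  pi <- model$base_freq
  grid <- as.matrix(expand.grid(replicate(n_int, 1:4, simplify = FALSE)))
  tip_idx <- match(m[, site], bases)
  num <- matrix(0, n_int, 4)
  tot <- 0
  for (r in rates) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      ouregime:::transition_prob(eig, r * tree$edge.length[e] * rescale))
    for (g in seq_len(nrow(grid))) {
      st <- c(tip_idx, grid[g, ])
      pr <- pi[st[n_tip + 1L]] / length(rates)
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      tot <- tot + pr
      for (v in seq_len(n_int)) num[v, grid[g, v]] <- num[v, grid[g, v]] + pr
    }
  }
  num / tot
}

# Gaussian log-density via determinant + solve (independent of the
# package's Cholesky/backsolve path).
naive_mvn_loglik <- function(y, mu, C) {
  k <- length(y)
  r <- y - mu
  as.numeric(-0.5 * (k * log(2 * pi) + determinant(C, logarithm = TRUE)$modulus +
                       t(r) %*% solve(C, r)))
}

# Random ultrametric tree + painted regime history for property tests.
random_painted_tree <- function(n_tips, seed, q = 1) {
  tr <- simulate_yule_tree(n_tips, seed = seed)
  h <- simulate_regime_history(tr, q = q, seed = seed + 1000L)
  list(tree = tr, history = h, painting = h$painting)
}

# Random full parameter set for a given model spec and regime set.
random_ou_params <- function(spec, regimes, seed) {
  ouregime:::with_seed(seed, {
    th <- if (spec$theta != "none")
      stats::setNames(stats::runif(length(regimes), 1, 3), regimes)
    if (spec$theta == "global" && length(th) > 1) th[] <- th[1]
    al <- if (spec$alpha == "zero") 0
          else stats::setNames(10^stats::runif(length(regimes), -1, 1), regimes)
    if (spec$alpha == "global" && length(al) > 1) al[] <- al[1]
    s2 <- stats::setNames(10^stats::runif(length(regimes), -1.5, 0), regimes)
    if (spec$sigma == "global") s2[] <- s2[1]
    x0 <- if (spec$theta == "none" || spec$root == "free") stats::runif(1, 1, 3)
    ou_params(spec, regimes, theta = th, alpha = al, sigma2 = s2, x0 = x0)
  })
}

# Simulate a nucleotide alignment under a substitution model, returning the
# true root sequence as well (used by ASR consistency checks). Independent
# of simulate_alignment_with_cox_site.
sim_alignment_with_root <- function(tree, model, L, rescale = 1, seed = 1) {
  ouregime:::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    eig <- ouregime:::subst_eigen(model)
    rates <- if (model$gamma) discrete_gamma_rates(model$shape, model$k) else 1
    site_rate <- sample(rates, L, replace = TRUE)
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    seqs <- matrix(NA_integer_, n_all, L)
    root <- n_tip + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    for (e in ouregime:::preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      for (r in unique(site_rate)) {
        P <- ouregime:::transition_prob(eig, r * tree$edge.length[e] * rescale)
        sel <- which(site_rate == r)
        seqs[chl, sel] <- vapply(seqs[par, sel], function(b)
          sample.int(4L, 1L, prob = P[b, ]), integer(1))
      }
    }
    list(alignment = matrix(bases[seqs[seq_len(n_tip), ]], n_tip, L,
                            dimnames = list(tree$tip.label, NULL)),
         root_seq = bases[seqs[root, ]])
  })
}
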