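# Multi-regime OU likelihood: explicit multivariate-normal route and
# Gaussian belief-propagation route. The two must agree to high precision
# (and are cross-checked in the test suite); the MVN route exposes the mean
# design used to profile optima during fitting.

# Precompute tree/painting geometry reused across likelihood evaluations.
ou_tree_data <- function(tree, painting) {
  stopifnot(inherits(painting, "regime_painting"))
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  edge_of <- integer(n_all)        # edge index above each node (0 for root)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_of <- integer(n_all)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  list(tree = tree, painting = painting, n_tip = n_tip, n_all = n_all,
       root = n_tip + 1L,
       edge_of = edge_of, parent_of = parent_of,
       pre = preorder_edges(tree),
       depths = node_depths(tree),
       height = tree_height(tree),
       mrca = ape::mrca(tree),
       desc = desc_tips(tree),
       regimes = sort_regimes(painting),
       root_regime = attr(painting, "root_regime"))
}

# Regimes actually present, ordered by the painting's alphabet; warns on
# degenerate regimes carried by < 2 branches.
sort_regimes <- function(painting) {
  alpha <- attr(painting, "alphabet")
  present <- union(intersect(alpha, unique(painting$regime)),
                   attr(painting, "root_regime"))
  counts <- table(factor(painting$regime, levels = present))
  thin <- names(counts)[counts < 2]
  thin <- setdiff(thin, character(0))
  if (length(thin))
    warning("regime(s) on < 2 branches: ", paste(thin, collapse = ", "))
  present
}

# Expand per-regime parameter vectors to per-edge vectors.
per_edge <- function(td, v) unname(v[td$painting$regime])

# Mean design matrix X (tips x columns) and covariance C for given per-edge
# alpha/sigma2. Columns of X are the regime optima (theta), plus an "x0"
# column when the root value is a separate parameter. `sigma_scale` of 1
# with `sigma2_w` weights supports profiling a global scale.
ou_moments <- function(td, alpha_r, sigma2_r, spec) {
  tree <- td$tree
  alpha_e <- per_edge(td, alpha_r)
  sigma_e <- per_edge(td, sigma2_r)
  len <- tree$edge.length

  acum <- numeric(td$n_all)            # integral of alpha from root to node
  v <- numeric(td$n_all)               # trait variance accumulated from root
  v[td$root] <- if (spec$root == "stationary" && spec$alpha != "zero") {
    a0 <- alpha_r[td$root_regime]
    sigma2_r[td$root_regime] / (2 * a0)
  } else 0
  # per-edge quantities are vectorized outside the (inherently sequential)
  # preorder accumulation
  a_len <- alpha_e * len
  decay2 <- exp(-2 * a_len)
  v_add <- ou_var(sigma_e, alpha_e, len)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  for (e in td$pre) {
    par <- parent[e]; chl <- child[e]
    acum[chl] <- acum[par] + a_len[e]
    v[chl] <- v[par] * decay2[e] + v_add[e]
  }

  tips <- seq_len(td$n_tip)
  has_theta <- spec$theta != "none"
  sep_root <- !has_theta || spec$root == "free"
  cols <- c(if (has_theta) td$regimes, if (sep_root) "x0")
  X <- matrix(0, td$n_tip, length(cols), dimnames = list(tree$tip.label, cols))
  D <- exp(-acum[tips])
  if (has_theta) {
    # edge e contributes exp(acum[child] - acum[tip]) - exp(acum[parent] -
    # acum[tip]) to the optimum column of its regime, for every descendant
    # tip; acum is bounded by alpha_max * height so the exp() split is safe
    ea <- exp(acum)
    reg_col <- match(td$painting$regime, td$regimes)
    vals <- ea[child] - ea[parent]
    for (e in seq_len(nrow(tree$edge))) {
      if (vals[e] == 0) next
      tt <- td$desc[[child[e]]]
      X[tt, reg_col[e]] <- X[tt, reg_col[e]] + vals[e] * D[tt]
    }
  }
  if (sep_root) X[, "x0"] <- D
  else X[, td$root_regime] <- X[, td$root_regime] + D
  if (has_theta && spec$theta == "global") {
    # one shared optimum: collapse the per-regime attraction columns
    Xg <- matrix(rowSums(X[, td$regimes, drop = FALSE]), ncol = 1,
                 dimnames = list(tree$tip.label, "theta"))
    X <- if (sep_root) cbind(Xg, X[, "x0", drop = FALSE]) else Xg
  }

  anc <- td$mrca
  # Cov[i,j] = V(mrca) * d(mrca, i) * d(mrca, j); fused to limit allocations
  C <- matrix(v[anc] * exp(2 * acum[anc]), td$n_tip, td$n_tip) * (D %o% D)
  diag(C) <- v[tips]
  list(X = X, C = C, acum = acum, v = v)
}

# Gaussian log-density with covariance C via Cholesky.
mvn_loglik <- function(y, mu, C) {
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular covariance (condition estimate ", format(kappa(C)), ")",
         call. = FALSE))
  r <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

#' Log-likelihood of tip traits under a painted multi-regime OU/BM model
#'
#' Two interchangeable computations: `"mvn"` builds the analytic
#' multivariate-normal mean (piecewise attraction toward the painted optima
#' along each root-to-tip path) and covariance (piecewise accumulation of
#' diffusion variance with attraction decay), and evaluates the Gaussian
#' density; `"bp"` eliminates nodes post-order by Gaussian belief
#' propagation using the exact branch transition kernels. Both handle
#' regime-specific alpha exactly (piecewise-constant per painted segment).
#'
#' @inheritParams simulate_traits
#' @param traits Named numeric vector (or species/value data frame) of tip
#'   trait values, typically on the log10 scale.
#' @param method `"mvn"` or `"bp"`.
#' @return Log-likelihood (numeric scalar).
#' @export
ou_likelihood <- function(tree, painting, params, traits, method = c("mvn", "bp")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "ou_params"))
  y <- as_trait_vector(traits)
  labs <- species_key(tree$tip.label)
  idx <- match(labs, species_key(names(y)))
  if (anyNA(idx))
    stop("traits missing for: ", paste(labs[is.na(idx)], collapse = ", "),
         call. = FALSE)
  y <- unname(y[idx])
  td <- ou_tree_data(tree, painting)
  spec <- params$spec
  regs <- td$regimes
  missing_par <- setdiff(regs, names(params$alpha))
  if (length(missing_par))
    stop("params missing regime(s): ", paste(missing_par, collapse = ", "),
         call. = FALSE)

  if (method == "mvn") {
    mom <- ou_moments(td, params$alpha, params$sigma2, spec)
    beta <- ou_beta(params, colnames(mom$X), td$root_regime)
    mvn_loglik(y, as.numeric(mom$X %*% beta), mom$C)
  } else {
    ou_loglik_bp(td, params, y)
  }
}

# Coefficient vector matching ou_moments()' design columns.
ou_beta <- function(params, cols, root_regime) {
  beta <- numeric(length(cols))
  names(beta) <- cols
  if (!is.null(params$theta)) {
    if ("theta" %in% cols) beta["theta"] <- params$theta[1L]
    th_cols <- intersect(cols, names(params$theta))
    beta[th_cols] <- params$theta[th_cols]
  }
  if ("x0" %in% cols) beta["x0"] <- ou_root_value(params, root_regime)
  beta
}

# Belief-propagation route: messages are scaled Gaussians in the node value.
ou_loglik_bp <- function(td, params, y) {
  tree <- td$tree
  spec <- params$spec
  alpha_e <- per_edge(td, params$alpha)
  sigma_e <- per_edge(td, params$sigma2)
  theta_e <- if (is.null(params$theta)) rep(0, nrow(tree$edge))
             else per_edge(td, params$theta)
  len <- tree$edge.length

  n_all <- td$n_all
  have <- logical(n_all)
  mlogc <- numeric(n_all); mm <- numeric(n_all); mv <- numeric(n_all)
  mm[seq_len(td$n_tip)] <- y
  have[seq_len(td$n_tip)] <- TRUE

  for (e in rev(td$pre)) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    if (!have[chl]) stop("internal error: postorder violated")
    a <- exp(-alpha_e[e] * len[e])
    b <- theta_e[e] * (1 - a)
    w <- ou_var(sigma_e[e], alpha_e[e], len[e])
    # push child's message through the branch
    c_new <- mlogc[chl] + alpha_e[e] * len[e]
    m_new <- (mm[chl] - b) / a
    v_new <- (mv[chl] + w) / a^2
    if (!have[par] || mv[par] < 0) {
      # first child seen at this parent
    }
    if (par > td$n_tip && !have[par]) {
      mlogc[par] <- c_new; mm[par] <- m_new; mv[par] <- v_new; have[par] <- TRUE
    } else {
      vsum <- mv[par] + v_new
      if (vsum <= 0) stop("degenerate zero-variance cherry", call. = FALSE)
      mlogc[par] <- mlogc[par] + c_new + dnorm(mm[par], m_new, sqrt(vsum), log = TRUE)
      mm[par] <- (mm[par] * v_new + m_new * mv[par]) / vsum
      mv[par] <- mv[par] * v_new / vsum
    }
  }

  root <- td$root
  if (spec$root == "stationary" && spec$alpha != "zero") {
    a0 <- params$alpha[td$root_regime]
    v0 <- params$sigma2[td$root_regime] / (2 * a0)
    mlogc[root] + dnorm(mm[root], ou_root_value(params, td$root_regime),
                        sqrt(mv[root] + v0), log = TRUE)
  } else {
    x0 <- ou_root_value(params, td$root_regime)
    if (mv[root] <= 0) stop("degenerate root message", call. = FALSE)
    mlogc[root] + dnorm(x0, mm[root], sqrt(mv[root]), log = TRUE)
  }
}
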