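#' Specify one of the seven BM/OU trait-evolution models
#'
#' The model family follows the standard multi-regime Hansen framework:
#' `BM1` (one Brownian rate), `BMS` (per-regime Brownian rates), `OU1`
#' (one optimum), `OUM` (per-regime optima, shared alpha and sigma^2),
#' `OUMV` (per-regime optima and sigma^2), `OUMA` (per-regime optima and
#' alpha), `OUMVA` (everything per-regime).
#'
#' @param name Model name, one of
#'   `c("BM1","BMS","OU1","OUM","OUMV","OUMA","OUMVA")`.
#' @param root Root handling: `"tied"` fixes the root value at the root
#'   regime's optimum (the smallest parameterization, the default),
#'   `"free"` estimates a separate root value, `"stationary"` draws the
#'   root from the stationary distribution of the root regime.
#' @return An object of class `ou_model`.
#' @export
ou_model <- function(name = c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA"),
                     root = c("tied", "free", "stationary")) {
  name <- match.arg(name)
  root <- match.arg(root)
  kinds <- switch(name,
    BM1   = list(theta = "none",   alpha = "zero",   sigma = "global"),
    BMS   = list(theta = "none",   alpha = "zero",   sigma = "regime"),
    OU1   = list(theta = "global", alpha = "global", sigma = "global"),
    OUM   = list(theta = "regime", alpha = "global", sigma = "global"),
    OUMV  = list(theta = "regime", alpha = "global", sigma = "regime"),
    OUMA  = list(theta = "regime", alpha = "regime", sigma = "global"),
    OUMVA = list(theta = "regime", alpha = "regime", sigma = "regime"))
  if (kinds$theta == "none" && root %in% c("tied", "stationary"))
    root <- "free"  # BM has no optimum to tie the root to; root value is a parameter
  structure(c(list(name = name, root = root), kinds), class = "ou_model")
}

#' @export
print.ou_model <- function(x, ...) {
  cat("<ou_model>", x$name, sprintf("(theta: %s, alpha: %s, sigma2: %s, root: %s)\n",
                                    x$theta, x$alpha, x$sigma, x$root))
  invisible(x)
}

# Free-parameter count given R regimes (root value counted when estimated).
ou_n_params <- function(spec, R) {
  p_theta <- switch(spec$theta, none = 0L, global = 1L, regime = R)
  p_alpha <- switch(spec$alpha, zero = 0L, global = 1L, regime = R)
  p_sigma <- switch(spec$sigma, global = 1L, regime = R)
  p_root <- if (spec$theta == "none" || spec$root == "free") 1L else 0L
  p_theta + p_alpha + p_sigma + p_root
}

#' Bundle full parameter values for a multi-regime OU model
#'
#' @param spec An [ou_model()].
#' @param regimes Character vector of regime labels.
#' @param theta Optima: scalar or vector named by regime (omit for BM).
#' @param alpha Attraction strengths (1/time): scalar or named vector; 0 for BM.
#' @param sigma2 Diffusion variances (trait^2/time): scalar or named vector.
#' @param x0 Root value (required for BM models and `root = "free"`).
#' @return An object of class `ou_params` with per-regime expanded vectors.
#' @export
ou_params <- function(spec, regimes, theta = NULL, alpha = NULL, sigma2, x0 = NULL) {
  expand <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) == 1L && is.null(names(v))) v <- setNames(rep(v, length(regimes)), regimes)
    if (is.null(names(v)) && length(v) == length(regimes)) names(v) <- regimes
    if (!all(regimes %in% names(v)))
      stop(what, " must cover every regime", call. = FALSE)
    v[regimes]
  }
  if (spec$alpha == "zero") alpha <- setNames(rep(0, length(regimes)), regimes)
  if (spec$theta == "none") theta <- NULL
  alpha <- expand(alpha, "alpha")
  sigma2 <- expand(sigma2, "sigma2")
  theta <- expand(theta, "theta")
  if (spec$theta == "global" && length(unique(theta)) > 1L)
    stop("a global-optimum model takes a single theta value", call. = FALSE)
  if (spec$alpha == "global" && length(unique(alpha)) > 1L)
    stop("a global-alpha model takes a single alpha value", call. = FALSE)
  if (spec$sigma == "global" && length(unique(sigma2)) > 1L)
    stop("a global-sigma2 model takes a single sigma2 value", call. = FALSE)
  if (any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0", call. = FALSE)
  if (is.null(x0) && (spec$theta == "none"))
    stop("BM models need an explicit root value x0", call. = FALSE)
  structure(list(spec = spec, regimes = regimes, theta = theta, alpha = alpha,
                 sigma2 = sigma2, x0 = x0),
            class = "ou_params")
}

# Root value implied by params + painting (tied root: optimum of root regime).
ou_root_value <- function(params, root_regime) {
  if (!is.null(params$x0)) return(params$x0)
  if (is.null(params$theta))
    stop("BM models need an explicit root value x0", call. = FALSE)
  unname(params$theta[root_regime])
}

#' Conditional mean and variance of an OU branch transition
#'
#' Over a branch of length `t` in a regime with optimum `theta`, attraction
#' `alpha` and diffusion variance `sigma2`, the trait at the child end given
#' the parent value `x_parent` is normal with
#' mean `theta + (x_parent - theta) exp(-alpha t)` and variance
#' `sigma2 (1 - exp(-2 alpha t)) / (2 alpha)`; the `alpha -> 0` Brownian
#' limit (mean `x_parent`, variance `sigma2 t`) is handled with a
#' series-safe branch.
#'
#' @param x_parent Parent trait value(s).
#' @param theta Regime optimum (ignored when `alpha = 0`).
#' @param alpha Attraction strength, `>= 0`.
#' @param sigma2 Diffusion variance, `> 0`.
#' @param t Branch length, `>= 0`.
#' @return List with `mean` and `var`.
#' @export
branch_transition <- function(x_parent, theta, alpha, sigma2, t) {
  if (any(t < 0)) stop("negative branch length", call. = FALSE)
  stopifnot(alpha >= 0, sigma2 > 0)
  if (alpha == 0) {
    list(mean = x_parent, var = sigma2 * t)
  } else {
    list(mean = theta + (x_parent - theta) * exp(-alpha * t),
         var = ou_var(sigma2, alpha, t))
  }
}

# sigma2 (1 - e^{-2 a t}) / (2 a), robust for a t -> 0.
ou_var <- function(sigma2, a, t) {
  x <- 2 * a * t
  ifelse(x < 1e-6, sigma2 * t * (1 - x / 2 + x^2 / 6),
         sigma2 * (-expm1(-x)) / (2 * a))
}

#' Simulate tip traits under a painted multi-regime OU/BM model
#'
#' Pre-order recursion applying the exact branch transition kernel; the root
#' value is the root regime's optimum (tied root), the supplied `x0`, or a
#' draw from the root regime's stationary distribution.
#'
#' @param tree Ultrametric `phylo`.
#' @param painting A [paint_regimes()] result for `tree`.
#' @param params An [ou_params()].
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return Tibble with columns `species`, `trait`.
#' @export
simulate_traits <- function(tree, painting, params, seed = NULL) {
  stopifnot(inherits(params, "ou_params"))
  if (nrow(painting) != nrow(tree$edge))
    stop("painting does not match tree (unpainted branch?)", call. = FALSE)
  if (anyNA(painting$regime)) stop("unpainted branch", call. = FALSE)
  spec <- params$spec
  root_regime <- attr(painting, "root_regime")
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    x <- numeric(n_tip + tree$Nnode)
    root <- n_tip + 1L
    x[root] <- if (spec$root == "stationary" && spec$alpha != "zero") {
      a0 <- params$alpha[root_regime]
      rnorm(1, ou_root_value(params, root_regime),
            sqrt(params$sigma2[root_regime] / (2 * a0)))
    } else ou_root_value(params, root_regime)
    for (e in preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      r <- painting$regime[e]
      bt <- branch_transition(x[par],
                              theta = if (is.null(params$theta)) 0 else params$theta[r],
                              alpha = params$alpha[r], sigma2 = params$sigma2[r],
                              t = tree$edge.length[e])
      x[chl] <- rnorm(1, bt$mean, sqrt(bt$var))
    }
    tibble(species = tree$tip.label, trait = x[seq_len(n_tip)])
  })
}
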