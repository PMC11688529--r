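# Phylogenetic generalized least squares of a log-scale trait on the COX
# state, with BM / OU error structures selected by Akaike weight.

#' Tree-derived error covariance structures for PGLS
#'
#' Unscaled residual covariance kernels on an ultrametric tree:
#' `BM`: `V_ij = t_ij` (shared root-to-MRCA path length);
#' `OUfixedRoot`: `V_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha)`;
#' `OUrandomRoot` (stationary): `V_ij = exp(-alpha d_ij) / (2 alpha)`;
#' `lambda`: BM with off-diagonals multiplied by `lambda`.
#' `d_ij` is the patristic distance between tips.
#'
#' @param tree Ultrametric `phylo`.
#' @param model One of `"BM"`, `"OUfixedRoot"`, `"OUrandomRoot"`, `"lambda"`.
#' @param alpha OU attraction (1/time), required `> 0` for OU models.
#' @param lambda Pagel's lambda in `[0, 1]` for `"lambda"`.
#' @return n x n covariance matrix (unit diffusion variance).
#' @export
error_covariance <- function(tree, model = c("BM", "OUfixedRoot", "OUrandomRoot",
                                             "lambda"),
                             alpha = NULL, lambda = NULL) {
  model <- match.arg(model)
  n <- ape::Ntip(tree)
  dep <- node_depths(tree)
  anc <- ape::mrca(tree)
  t_ij <- matrix(dep[anc], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(t_ij) <- dep[seq_len(n)]
  d_ij <- outer(dep[seq_len(n)], dep[seq_len(n)], "+") - 2 * t_ij
  switch(model,
    BM = t_ij,
    lambda = {
      stopifnot(!is.null(lambda), lambda >= 0, lambda <= 1)
      V <- t_ij * lambda
      diag(V) <- dep[seq_len(n)]
      V
    },
    OUfixedRoot = {
      if (is.null(alpha) || alpha <= 0) stop("alpha must be > 0 for OU", call. = FALSE)
      exp(-alpha * d_ij) * (-expm1(-2 * alpha * t_ij)) / (2 * alpha)
    },
    OUrandomRoot = {
      if (is.null(alpha) || alpha <= 0) stop("alpha must be > 0 for OU", call. = FALSE)
      exp(-alpha * d_ij) / (2 * alpha)
    })
}

#' Phylogenetic regression of a log-trait on the COX state
#'
#' ML joint fit of regression coefficients, residual diffusion variance and
#' (for OU error models) the attraction strength alpha: at fixed alpha the
#' coefficients and variance have closed GLS forms, and alpha is profiled by
#' one-dimensional optimization of the log-likelihood on the log scale.
#' The categorical predictor uses `ref_level` (default `"LS"`, the
#' ancestral state) as reference, so the intercept is that level's mean and
#' the other coefficients are offsets from it. t-tests use `n - p` degrees
#' of freedom and the small-sample variance correction `n / (n - p)`.
#'
#' @param data Data frame with species, trait and state columns.
#' @param tree Ultrametric `phylo` covering the species.
#' @param trait Name of the numeric response column (already log10
#'   transformed).
#' @param state Name of the categorical predictor column.
#' @param error_model Residual covariance kernel (see [error_covariance()]).
#' @param species Name of the species column (default `"species"`).
#' @param ref_level Reference level of the predictor.
#' @param lambda_fixed Optional fixed lambda for `error_model = "lambda"`;
#'   if `NULL`, lambda is profiled like alpha.
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @export
fit_pgls <- function(data, tree, trait, state, error_model = "OUfixedRoot",
                     species = "species", ref_level = "LS", lambda_fixed = NULL) {
  df <- as.data.frame(data)
  stopifnot(all(c(species, trait, state) %in% names(df)))
  keep <- complete.cases(df[, c(species, trait, state)])
  df <- df[keep, , drop = FALSE]
  key <- species_key(df[[species]])
  labs <- species_key(tree$tip.label)
  df <- df[key %in% labs, , drop = FALSE]
  key <- species_key(df[[species]])
  if (any(duplicated(key))) stop("duplicated species in data", call. = FALSE)
  if (nrow(df) < 3L) stop("too few species with complete data", call. = FALSE)
  tr <- prune_to(tree, key)
  ord <- match(species_key(tr$tip.label), key)
  df <- df[ord, , drop = FALSE]

  lev_all <- unique(as.character(df[[state]]))
  levs <- c(intersect(ref_level, lev_all), setdiff(lev_all, ref_level))
  if (length(levs) < 2L) stop("predictor has a single level", call. = FALSE)
  counts <- table(factor(df[[state]], levels = levs))
  if (any(counts == 1L))
    warning("state level(s) with a single species: ",
            paste(names(counts)[counts == 1L], collapse = ", "))
  fac <- factor(df[[state]], levels = levs)
  X <- model.matrix(~fac)
  colnames(X) <- c(paste0("(Intercept) ", levs[1]), paste0("offset ", levs[-1]))
  if (qr(X)$rank < ncol(X)) stop("singular design", call. = FALSE)
  y <- as.numeric(df[[trait]])
  n <- length(y)

  gls_at <- function(V) {
    ch <- chol(V)
    Xw <- backsolve(ch, X, transpose = TRUE)
    yw <- backsolve(ch, y, transpose = TRUE)
    qrx <- qr(Xw)
    beta <- qr.coef(qrx, yw)
    rw <- yw - Xw %*% beta
    s2 <- sum(rw^2) / n
    ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) - sum(log(diag(ch)))
    list(beta = beta, s2 = s2, loglik = ll, ch = ch, Xw = Xw, yw = yw, rss = sum(rw^2))
  }

  h <- tree_height(tr)
  par_est <- NULL
  # tree geometry shared across all alpha evaluations
  n_t <- ape::Ntip(tr)
  dep <- node_depths(tr)
  anc <- ape::mrca(tr)
  t_ij <- matrix(dep[anc], n_t, n_t)
  diag(t_ij) <- dep[seq_len(n_t)]
  d_ij <- outer(dep[seq_len(n_t)], dep[seq_len(n_t)], "+") - 2 * t_ij
  kernel <- function(model, alpha = NULL, lambda = NULL) {
    switch(model,
           BM = t_ij,
           lambda = { V <- t_ij * lambda; diag(V) <- dep[seq_len(n_t)]; V },
           OUfixedRoot = exp(-alpha * d_ij) *
             (-expm1(-2 * alpha * t_ij)) / (2 * alpha),
           OUrandomRoot = exp(-alpha * d_ij) / (2 * alpha))
  }
  if (error_model %in% c("OUfixedRoot", "OUrandomRoot")) {
    nll <- function(la) -gls_at(kernel(error_model, alpha = exp(la)))$loglik
    grid <- seq(log(0.01 / h), log(50 / h), length.out = 25)
    vals <- vapply(grid, nll, numeric(1))
    i0 <- which.min(vals)
    op <- optimize(nll, lower = grid[max(1, i0 - 1)], upper = grid[min(25, i0 + 1)])
    la <- if (op$objective < vals[i0]) op$minimum else grid[i0]
    par_est <- c(alpha = exp(la))
    V <- kernel(error_model, alpha = exp(la))
    extra_p <- 2L
  } else if (error_model == "lambda") {
    if (is.null(lambda_fixed)) {
      nll <- function(lam) -gls_at(kernel("lambda", lambda = lam))$loglik
      op <- optimize(nll, lower = 0, upper = 1)
      par_est <- c(lambda = op$minimum)
    } else par_est <- c(lambda = lambda_fixed)
    V <- kernel("lambda", lambda = unname(par_est["lambda"]))
    extra_p <- 2L
  } else {
    V <- kernel("BM")
    extra_p <- 1L
  }
  g <- gls_at(V)
  p <- ncol(X)
  s2_unbiased <- g$s2 * n / (n - p)
  XtVX_inv <- chol2inv(qr.R(qr(g$Xw)))
  se <- sqrt(diag(XtVX_inv) * s2_unbiased)
  tval <- as.numeric(g$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)

  # whitened R^2 against the intercept-only model under the same correlation
  X0 <- matrix(1, n, 1)
  ch <- g$ch
  X0w <- backsolve(ch, X0, transpose = TRUE)
  b0 <- qr.coef(qr(X0w), g$yw)
  rss0 <- sum((g$yw - X0w %*% b0)^2)
  r2 <- 1 - g$rss / rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  adj_r2_alt <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  structure(list(
    coefficients = setNames(as.numeric(g$beta), colnames(X)),
    se = setNames(se, colnames(X)), t_value = setNames(tval, colnames(X)),
    p_value = setNames(pval, colnames(X)),
    sigma2 = g$s2, error_model = error_model, error_param = par_est,
    loglik = g$loglik, n = n, p = p + extra_p, df_residual = n - p,
    aic = 2 * (p + extra_p) - 2 * g$loglik,
    aicc = 2 * (p + extra_p) - 2 * g$loglik +
      2 * (p + extra_p) * (p + extra_p + 1) / max(n - (p + extra_p) - 1, 1e-12),
    r2 = r2, adj_r2 = adj_r2, adj_r2_alt = adj_r2_alt,
    levels = levs, tree = tr, data = df,
    traits = setNames(y, tr$tip.label)), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit> error model:", x$error_model,
      if (!is.null(x$error_param))
        paste0("(", paste(names(x$error_param), "=",
                          signif(x$error_param, 4), collapse = ", "), ")"), "\n")
  print(tidy(x))
  cat(sprintf("n = %d  lnL = %.4f  adj. R2 = %.4f (alt %.4f)\n",
              x$n, x$loglik, x$adj_r2, x$adj_r2_alt))
  invisible(x)
}

#' Tidy a PGLS fit into a coefficient table
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std_error = unname(x$se), statistic = unname(x$t_value),
         p_value = unname(x$p_value))
}

#' One-row summary of a PGLS fit
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pgls_fit <- function(x, ...) {
  tibble(error_model = x$error_model, n = x$n, p = x$p, loglik = x$loglik,
         aic = x$aic, aicc = x$aicc, sigma2 = x$sigma2,
         alpha = unname(x$error_param["alpha"] %|na|% NA_real_),
         r2 = x$r2, adj_r2 = x$adj_r2, adj_r2_alt = x$adj_r2_alt)
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Select the PGLS error model by Akaike weight
#'
#' Each candidate error structure is fitted by ML and weighted by AICc (the
#' analysis sample sizes here are modest). When the top two candidates have
#' a weight ratio below `exp(1) ~ 2.7`, their performance is flagged as
#' comparable.
#'
#' @inheritParams fit_pgls
#' @param candidates Character vector of error models to compare.
#' @param criterion `"AICc"` or `"AIC"`.
#' @return Tibble ranked by descending weight with the fits in the `fit`
#'   list-column and a `comparable` flag on the top row.
#' @export
select_error_model <- function(data, tree, trait, state,
                               candidates = c("BM", "OUfixedRoot", "OUrandomRoot"),
                               species = "species", ref_level = "LS",
                               criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 2L) stop("need >= 2 candidate error models", call. = FALSE)
  fits <- list(); rows <- list()
  for (i in seq_along(candidates)) {
    f <- tryCatch(fit_pgls(data, tree, trait, state, error_model = candidates[i],
                           species = species, ref_level = ref_level),
                  error = function(e) e)
    fits[[i]] <- f
    rows[[i]] <- if (inherits(f, "error")) {
      tibble(error_model = candidates[i], loglik = NA_real_, p = NA_integer_,
             aic = NA_real_, aicc = NA_real_, failed = conditionMessage(f))
    } else {
      tibble(error_model = candidates[i], loglik = f$loglik, p = f$p,
             aic = f$aic, aicc = f$aicc, failed = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  crit <- if (criterion == "AICc") out$aicc else out$aic
  ok <- is.finite(crit)
  w <- rep(NA_real_, nrow(out))
  w[ok] <- aic_weights(crit[ok])
  out$aicw <- w
  out$fit <- fits
  out <- dplyr::arrange(out, dplyr::desc(.data$aicw))
  out$comparable <- FALSE
  if (sum(ok) >= 2L) {
    ratio <- out$aicw[1] / out$aicw[2]
    out$comparable[1] <- is.finite(ratio) && ratio < exp(1)
  }
  out
}
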