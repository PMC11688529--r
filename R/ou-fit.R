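# Maximum-likelihood fitting of the seven BM/OU models. The regime optima
# (and the root value, when separate) are profiled out by GLS at fixed
# alpha/sigma structure, and a global sigma^2 scale is profiled analytically,
# so the numeric search runs only over log-alpha values and log sigma-ratio
# weights -- 0 to 2R-1 dimensions depending on the model.

# Free numeric-search parameterization for a spec with regimes `regs`:
# log alphas (0, 1 or R values) then log sigma weights (R-1 values, first
# regime's weight fixed at 1) when sigma is per-regime.
ou_phi_info <- function(spec, regs) {
  n_alpha <- switch(spec$alpha, zero = 0L, global = 1L, regime = length(regs))
  n_w <- if (spec$sigma == "regime") length(regs) - 1L else 0L
  nm <- c(if (n_alpha == 1L) "lalpha" else if (n_alpha > 1L) paste0("lalpha_", regs),
          if (n_w > 0L) paste0("lw_", regs[-1L]))
  list(n_alpha = n_alpha, n_w = n_w, names = nm, dim = n_alpha + n_w)
}

ou_phi_expand <- function(phi, info, spec, regs) {
  R <- length(regs)
  alpha_r <- setNames(rep(0, R), regs)
  if (info$n_alpha == 1L) alpha_r[] <- exp(phi[1L])
  if (info$n_alpha > 1L) alpha_r[] <- exp(phi[seq_len(R)])
  w_r <- setNames(rep(1, R), regs)
  if (info$n_w > 0L) w_r[-1L] <- exp(phi[info$n_alpha + seq_len(info$n_w)])
  list(alpha = alpha_r, w = w_r)
}

# Profile log-likelihood at fixed shape parameters; returns the GLS pieces.
ou_profile <- function(phi, info, spec, td, y) {
  pars <- ou_phi_expand(phi, info, spec, td$regimes)
  mom <- tryCatch(ou_moments(td, pars$alpha, pars$w, spec), error = function(e) NULL)
  if (is.null(mom)) return(list(loglik = -Inf))
  ch <- tryCatch(chol(mom$C), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Xw <- backsolve(ch, mom$X, transpose = TRUE)
  colnames(Xw) <- colnames(mom$X)
  yw <- backsolve(ch, y, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw)) return(list(loglik = -Inf))
  beta <- qr.coef(qrx, yw)
  rw <- yw - Xw %*% beta
  n <- length(y)
  scale <- sum(rw^2) / n
  if (!is.finite(scale) || scale <= 0) return(list(loglik = -Inf))
  ll <- -n / 2 * (log(2 * pi) + log(scale) + 1) - sum(log(diag(ch)))
  list(loglik = ll, beta = beta, scale = scale, alpha = pars$alpha,
       sigma2 = pars$w * scale, X = mom$X, C = mom$C * scale)
}

#' Fit a multi-regime OU/BM trait-evolution model by maximum likelihood
#'
#' Optima and the sigma^2 scale are profiled analytically; attraction
#' strengths and sigma^2 ratios are optimized on the log scale by
#' derivative-free simplex search refined with box-constrained
#' quasi-Newton, from `n_starts` dispersed deterministic starts. Alpha is
#' bounded in `[1e-8, 50/tree height]`.
#'
#' @inheritParams simulate_traits
#' @param traits Named numeric vector or species/value data frame of tip
#'   traits (log10 scale recommended).
#' @param model Model name (see [ou_model()]) or an `ou_model` object.
#' @param root Root handling (see [ou_model()]).
#' @param n_starts Number of optimizer starts for models with >= 2 free
#'   shape parameters.
#' @param seed Seed for the dispersed starts.
#' @param warm_start Optional `ou_fit` whose estimates seed the first start
#'   (used by the parametric bootstrap).
#' @param compute_se Compute standard errors from the observed information
#'   matrix (numerical Hessian of the full likelihood).
#' @param .td Internal: precomputed tree data, shared across refits.
#' @return An object of class `ou_fit`.
#' @export
fit_ou <- function(tree, painting, traits, model = "OUMA",
                   root = c("tied", "free", "stationary"),
                   n_starts = 8, seed = 1, warm_start = NULL,
                   compute_se = FALSE, .td = NULL) {
  spec <- if (inherits(model, "ou_model")) model else ou_model(model, match.arg(root))
  y_named <- as_trait_vector(traits)
  labs <- species_key(tree$tip.label)
  idx <- match(labs, species_key(names(y_named)))
  if (anyNA(idx))
    stop("traits missing for: ", paste(labs[is.na(idx)], collapse = ", "), call. = FALSE)
  y <- unname(y_named[idx])
  if (var(y) <= 0) stop("trait variance is zero", call. = FALSE)
  td <- .td %||% ou_tree_data(tree, painting)
  regs <- td$regimes
  if (td$n_tip < length(regs) + 2L)
    stop("need at least R + 2 tips", call. = FALSE)
  info <- ou_phi_info(spec, regs)
  h <- td$height
  la_lo <- log(1e-8); la_hi <- log(50 / h)
  lower <- c(rep(la_lo, info$n_alpha), rep(-12, info$n_w))
  upper <- c(rep(la_hi, info$n_alpha), rep(12, info$n_w))
  obj <- function(phi) -ou_profile(phi, info, spec, td, y)$loglik

  starts_log <- list()
  if (info$dim == 0L) {
    best_phi <- numeric(0)
    starts_log[[1]] <- tibble(start = 1L, loglik = -obj(best_phi), convergence = 0L)
  } else if (info$dim == 1L) {
    # spans down to the near-BM boundary so the alpha -> 0 limit is reachable
    grid <- seq(la_lo, la_hi, length.out = 45)
    vals <- vapply(grid, obj, numeric(1))
    i0 <- which.min(vals)
    br <- c(grid[max(1, i0 - 1L)], grid[min(length(grid), i0 + 1L)])
    op <- optimize(obj, lower = br[1], upper = br[2])
    best_phi <- op$minimum
    if (vals[i0] < op$objective) best_phi <- grid[i0]
    starts_log[[1]] <- tibble(start = 1L, loglik = -min(op$objective, vals[i0]),
                              convergence = 0L)
  } else {
    start_mat <- make_starts(info, spec, regs, h, n_starts, seed, warm_start)
    results <- vector("list", nrow(start_mat))
    for (s in seq_len(nrow(start_mat))) {
      phi0 <- pmin(pmax(start_mat[s, ], lower), upper)
      # the profiled objective is smooth in the log parameters, so
      # quasi-Newton from each start is usually enough; fall back to
      # simplex + refine when it fails
      o2 <- tryCatch(optim(phi0, obj, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(maxit = 200, factr = 1e6)),
                     error = function(e) NULL)
      if (is.null(o2) || !is.finite(o2$value)) {
        o1 <- tryCatch(optim(phi0, obj, method = "Nelder-Mead",
                             control = list(maxit = 400, reltol = 1e-9)),
                       error = function(e) NULL)
        p1 <- if (is.null(o1)) phi0 else o1$par
        o2 <- tryCatch(optim(pmin(pmax(p1, lower), upper), obj, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 200, factr = 1e6)),
                       error = function(e) o1)
      }
      if (is.null(o2)) {
        results[[s]] <- list(par = phi0, value = obj(phi0), convergence = 99L)
      } else results[[s]] <- o2
      starts_log[[s]] <- tibble(start = s, loglik = -results[[s]]$value,
                                convergence = results[[s]]$convergence %||% 99L)
    }
    vals <- vapply(results, function(r) r$value, numeric(1))
    if (all(!is.finite(vals))) stop("all optimizer starts failed", call. = FALSE)
    best_phi <- results[[which.min(vals)]]$par
  }

  prof <- ou_profile(best_phi, info, spec, td, y)
  if (!is.finite(prof$loglik)) stop("all optimizer starts failed", call. = FALSE)
  if (info$n_alpha > 0 && any(prof$alpha > 0.98 * 50 / h))
    warning("alpha at upper bound: near-white-noise fit")

  beta <- prof$beta
  theta <- NULL; x0 <- NULL
  if (spec$theta == "global") {
    theta <- setNames(rep(as.numeric(beta["theta"]), length(regs)), regs)
  } else if (spec$theta == "regime") {
    th_cols <- intersect(names(beta) %||% colnames(prof$X), regs)
    theta <- setNames(as.numeric(beta[th_cols]), th_cols)
  }
  if ("x0" %in% colnames(prof$X)) x0 <- unname(beta["x0"])
  params <- ou_params(spec, regs, theta = theta,
                      alpha = pmax(prof$alpha, 0), sigma2 = prof$sigma2, x0 = x0)
  p <- ou_n_params(spec, length(regs))
  n <- td$n_tip
  aic <- 2 * p - 2 * prof$loglik
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf

  fit <- structure(list(
    model = spec$name, spec = spec, params = params, regimes = regs,
    loglik = prof$loglik, n = n, p = p, aic = aic, aicc = aicc,
    tree = tree, painting = td$painting, traits = setNames(y, tree$tip.label),
    starts = dplyr::bind_rows(starts_log), phi = best_phi,
    convergence = 0L, se = NULL), class = "ou_fit")
  if (compute_se) fit$se <- tryCatch(ou_fit_se(fit), error = function(e) NULL)
  fit
}

make_starts <- function(info, spec, regs, h, n_starts, seed, warm_start) {
  center <- c(rep(log(log(2) / (0.3 * h)), info$n_alpha), rep(0, info$n_w))
  extra <- with_seed(seed, {
    if (n_starts > 1L)
      t(replicate(n_starts - 1L,
                  c(runif(info$n_alpha, log(0.05 / h), log(20 / h)),
                    runif(info$n_w, -2.3, 2.3))))
    else NULL
  })
  m <- rbind(center, extra)
  if (!is.null(warm_start) && inherits(warm_start, "ou_fit") &&
      length(warm_start$phi) == info$dim) {
    m <- rbind(warm_start$phi, m)
  }
  m
}

# Observed-information standard errors on the full parameter vector
# (theta / x0 on the natural scale, alpha and sigma2 on the log scale).
ou_fit_se <- function(fit) {
  spec <- fit$spec; regs <- fit$regimes; prm <- fit$params
  pack <- c(if (spec$theta == "global") c(theta = unname(prm$theta[1])),
            if (spec$theta == "regime") setNames(prm$theta, paste0("theta_", regs)),
            if (!is.null(prm$x0)) c(x0 = prm$x0),
            if (spec$alpha == "global") c(lalpha = log(prm$alpha[1])),
            if (spec$alpha == "regime") setNames(log(prm$alpha), paste0("lalpha_", regs)),
            if (spec$sigma == "global") c(lsigma2 = log(prm$sigma2[1])),
            if (spec$sigma == "regime") setNames(log(prm$sigma2), paste0("lsigma2_", regs)))
  negll <- function(v) {
    th <- if (spec$theta == "global") setNames(rep(unname(v["theta"]), length(regs)), regs)
          else if (spec$theta == "regime") setNames(v[paste0("theta_", regs)], regs)
    x0 <- if (!is.null(prm$x0)) unname(v["x0"])
    al <- if (spec$alpha == "zero") 0
          else if (spec$alpha == "global") exp(unname(v["lalpha"]))
          else setNames(exp(v[paste0("lalpha_", regs)]), regs)
    s2 <- if (spec$sigma == "global") exp(unname(v["lsigma2"]))
          else setNames(exp(v[paste0("lsigma2_", regs)]), regs)
    pr <- ou_params(spec, regs, theta = th, alpha = al, sigma2 = s2, x0 = x0)
    -ou_likelihood(fit$tree, fit$painting, pr, fit$traits, method = "mvn")
  }
  H <- optimHess(pack, negll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA, length(pack), length(pack),
                                                     dimnames = list(names(pack), names(pack))))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(pack)
  se
}

#' @export
print.ou_fit <- function(x, ...) {
  cat("<ou_fit>", x$model, sprintf("(n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  lnL = %.4f  AIC = %.3f  AICc = %.3f\n", x$loglik, x$aic, x$aicc))
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ou_fit <- function(x, ...) {
  prm <- x$params
  rows <- list()
  if (!is.null(prm$theta))
    rows$theta <- tibble(term = "theta", regime = names(prm$theta),
                         estimate = unname(prm$theta),
                         mbp = 10^unname(prm$theta))
  rows$alpha <- tibble(term = "alpha", regime = names(prm$alpha),
                       estimate = unname(prm$alpha), mbp = NA_real_)
  rows$sigma2 <- tibble(term = "sigma2", regime = names(prm$sigma2),
                        estimate = unname(prm$sigma2), mbp = NA_real_)
  if (!is.null(prm$x0))
    rows$x0 <- tibble(term = "x0", regime = NA_character_,
                      estimate = prm$x0, mbp = 10^prm$x0)
  out <- dplyr::bind_rows(rows)
  if (!is.null(x$se)) {
    key <- ifelse(out$term %in% c("alpha", "sigma2"),
                  paste0("l", out$term, ifelse(is.na(out$regime), "",
                                               paste0("_", out$regime))),
                  ifelse(out$term == "x0", "x0", paste0("theta_", out$regime)))
    # global alpha/sigma2 are stored without the regime suffix
    key[out$term == "alpha" & x$spec$alpha == "global"] <- "lalpha"
    key[out$term == "sigma2" & x$spec$sigma == "global"] <- "lsigma2"
    out$se <- unname(x$se[key])
  }
  out
}

#' @exportS3Method generics::glance
glance.ou_fit <- function(x, ...) {
  tibble(model = x$model, n = x$n, p = x$p, loglik = x$loglik,
         aic = x$aic, aicc = x$aicc)
}

#' Akaike weights for a set of fitted models
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = crit_i - min(crit)`.
#'
#' @param fits List of `ou_fit`/`pgls_fit` objects fitted to the same data,
#'   or a numeric vector of criterion values.
#' @param criterion `"AICc"` (default; small-sample corrected) or `"AIC"`.
#' @return Numeric vector of weights summing to 1.
#' @export
aic_weights <- function(fits, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (is.numeric(fits)) {
    crit <- fits
  } else {
    if (length(fits) < 2L) stop("need >= 2 fits", call. = FALSE)
    ns <- vapply(fits, function(f) f$n, numeric(1))
    if (length(unique(ns)) != 1L)
      stop("fits are not on identical data (different n)", call. = FALSE)
    ys <- lapply(fits, function(f) round(unname(f$traits), 10))
    if (length(unique(vapply(ys, function(v) paste(v, collapse = ","), character(1)))) != 1L)
      stop("fits are not on identical data", call. = FALSE)
    crit <- vapply(fits, function(f) if (criterion == "AICc") f$aicc else f$aic,
                   numeric(1))
  }
  d <- crit - min(crit)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and rank the seven trait-evolution models
#'
#' @inheritParams fit_ou
#' @param models Character vector of model names to compare.
#' @param criterion Weighting criterion, `"AICc"` or `"AIC"`.
#' @return Tibble of class `ou_model_comparison`, ranked by descending
#'   weight, with the fits in the `fit` list-column.
#' @export
fit_ou_models <- function(tree, painting, traits,
                          models = c("BM1", "BMS", "OU1", "OUM", "OUMV",
                                     "OUMA", "OUMVA"),
                          root = "tied", criterion = c("AICc", "AIC"),
                          n_starts = 8, seed = 1, compute_se = FALSE) {
  criterion <- match.arg(criterion)
  td <- ou_tree_data(tree, painting)
  fits <- lapply(models, function(m)
    fit_ou(tree, painting, traits, model = m, root = root,
           n_starts = n_starts, seed = seed, compute_se = compute_se, .td = td))
  names(fits) <- models
  w <- aic_weights(fits, criterion = criterion)
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$aicw <- w
  out$criterion <- criterion
  out <- dplyr::arrange(out, dplyr::desc(.data$aicw))
  out$fit <- fits[out$model]
  structure(out, class = c("ou_model_comparison", class(out)))
}

#' Extract the best fit from a model comparison
#' @param comparison A [fit_ou_models()] result.
#' @export
best_fit <- function(comparison) {
  comparison$fit[[1L]]
}
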