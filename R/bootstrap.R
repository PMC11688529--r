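# Parametric bootstrap of regime optima and rank-based comparison of the
# bootstrap theta distributions.

#' Parametric bootstrap of the regime optima of a fitted OU model
#'
#' For each replicate, tip traits are simulated under the fitted model
#' (exact branch transitions) and the same model specification is refitted;
#' the per-regime optima are collected on the analysis (log10) and
#' back-transformed (Mbp) scales. Replicate seeds derive from the master
#' seed by a counter scheme so partial reruns are reproducible. Refits use
#' the original estimate as a warm start plus a few fresh starts.
#'
#' @param fit An [fit_ou()] result whose model has regime optima.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Master seed.
#' @param n_starts Fresh optimizer starts per refit (in addition to the
#'   warm start).
#' @return An object of class `ou_bootstrap`: tibble with columns
#'   `replicate`, `regime`, `theta`, `theta_mbp`; attributes `summary`,
#'   `n_failed`, `fit`, `seed`.
#' @export
parametric_bootstrap_theta <- function(fit, n_replicates = 100, seed = 1,
                                       n_starts = 3) {
  stopifnot(inherits(fit, "ou_fit"), n_replicates >= 2)
  if (is.null(fit$params$theta))
    stop("fitted model has no optima to bootstrap (BM model)", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * n_replicates)
  td <- ou_tree_data(fit$tree, fit$painting)
  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (b in seq_len(n_replicates)) {
    sim <- simulate_traits(fit$tree, fit$painting, fit$params,
                           seed = seeds[b])
    refit <- tryCatch(
      suppressWarnings(
        fit_ou(fit$tree, fit$painting, sim, model = fit$spec,
               n_starts = n_starts, seed = seeds[n_replicates + b],
               warm_start = fit, .td = td)),
      error = function(e) NULL)
    if (is.null(refit)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[b]] <- tibble(replicate = b, regime = names(refit$params$theta),
                        theta = unname(refit$params$theta),
                        theta_mbp = 10^unname(refit$params$theta))
  }
  if (n_failed > 0.2 * n_replicates)
    stop(n_failed, " of ", n_replicates, " bootstrap refits failed; ",
         "review the model specification and optimizer bounds", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::group_by(.data$regime) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$theta),
                     q2.5 = quantile(.data$theta, 0.025),
                     q97.5 = quantile(.data$theta, 0.975),
                     median_mbp = median(.data$theta_mbp),
                     q2.5_mbp = quantile(.data$theta_mbp, 0.025),
                     q97.5_mbp = quantile(.data$theta_mbp, 0.975),
                     .groups = "drop")
  structure(out, class = c("ou_bootstrap", class(out)),
            summary = summ, n_failed = n_failed, fit = fit, seed = seed)
}

#' @export
print.ou_bootstrap <- function(x, ...) {
  cat("<ou_bootstrap>", max(x$replicate), "replicates requested,",
      attr(x, "n_failed"), "failed\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test between two samples
#'
#' `U` counts pairs with `x_i > y_j` plus half the ties. The exact mode
#' enumerates the permutation distribution (delegated to
#' [stats::wilcox.test()], feasible for small samples without ties); the
#' normal mode uses the z approximation with tie and continuity
#' corrections, which is the appropriate choice for 100-vs-100 bootstrap
#' samples.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"` (exact when `|x| + |y| <= 12` and tie-free),
#'   `"exact"`, or `"normal"`.
#' @return Tibble with columns `U`, `z`, `p_value`, `mode`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p = 1")
    return(tibble(U = U, z = 0, p_value = 1, mode = "degenerate"))
  }
  if (mode == "auto") mode <- if (n1 + n2 <= 12 && !has_ties) "exact" else "normal"
  if (mode == "exact") {
    if (has_ties) warning("ties present; exact p is approximate")
    p <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value)
    z <- NA_real_
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sg <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sg
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble(U = U, z = z, p_value = p, mode = mode)
}

#' Pairwise comparison of bootstrap regime-optimum distributions
#'
#' Mann-Whitney tests between every pair of regimes' bootstrap theta
#' samples, with a directional summary (which regime's distribution is
#' larger by median). No multiplicity adjustment by default; a Holm switch
#' is available. Note the anticonservatism of testing bootstrap samples of
#' the same fit: the replicates are not independent observations of two
#' populations, so p-values overstate evidence — they are reported the way
#' the field reports them, and the behaviour under equal-optima nulls is
#' characterized in the test suite.
#'
#' @param result An [parametric_bootstrap_theta()] result.
#' @param adjust `"none"` (default) or `"holm"`.
#' @param mode Test mode passed to [mann_whitney()] (default `"normal"`).
#' @return Tibble with one row per regime pair.
#' @export
compare_regime_optima <- function(result, adjust = c("none", "holm"),
                                  mode = "normal") {
  adjust <- match.arg(adjust)
  stopifnot(inherits(result, "ou_bootstrap"))
  split_th <- split(result$theta, result$regime)
  split_th <- split_th[order(match(names(split_th),
                                   attr(attr(result, "fit")$painting, "alphabet")))]
  ok <- lengths(split_th) >= 2L
  if (any(!ok))
    warning("regime(s) with < 2 surviving replicates excluded: ",
            paste(names(split_th)[!ok], collapse = ", "))
  split_th <- split_th[ok]
  if (length(split_th) < 2L) stop("need >= 2 regimes with replicates", call. = FALSE)
  pairs <- combn(names(split_th), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    mw <- mann_whitney(split_th[[a]], split_th[[b]], mode = mode)
    dplyr::mutate(mw,
                  regime_a = a, regime_b = b,
                  larger = if (median(split_th[[a]]) >= median(split_th[[b]])) a else b,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p_value, "holm")
  out
}
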