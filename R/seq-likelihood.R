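# Felsenstein pruning likelihood with discrete-Gamma mixtures, BIC model
# selection, and marginal ancestral sequence reconstruction.

# Coerce alignment input (character matrix, named character vector of
# sequences, or ape DNAbin) to an upper-case character matrix species x site.
as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    alignment <- as.character(as.matrix(alignment))
  }
  if (is.character(alignment) && is.null(dim(alignment))) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("sequences differ in length", call. = FALSE)
    alignment <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(alignment) <- names(alignment) %||% rownames(alignment)
  }
  m <- toupper(as.matrix(alignment))
  if (is.null(rownames(m))) stop("alignment must have species names", call. = FALSE)
  known <- names(iupac_partials())
  bad <- setdiff(unique(as.vector(m)), known)
  if (length(bad))
    stop("invalid alignment character(s): ", paste(bad, collapse = " "), call. = FALSE)
  m
}

#' Read / write aligned FASTA
#'
#' @param file Path to a FASTA file.
#' @return `read_fasta()`: a character matrix (species x site);
#'   `write_fasta()`: the path, invisibly.
#' @export
read_fasta <- function(file) {
  as_alignment_matrix(ape::read.FASTA(file))
}

#' @rdname read_fasta
#' @param alignment Character matrix species x site.
#' @export
write_fasta <- function(alignment, file) {
  m <- as_alignment_matrix(alignment)
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(m))) {
    writeLines(c(paste0(">", rownames(m)[i]), paste(m[i, ], collapse = "")), con)
  }
  invisible(file)
}

# Internal engine: per-category postorder partial likelihoods with per-site
# scaling. Returns partials at every node plus per-site log-likelihoods.
prune_engine <- function(tree, alignment, model, rescale = 1, keep_partials = FALSE) {
  m <- as_alignment_matrix(alignment)
  labs <- species_key(tree$tip.label)
  idx <- match(labs, species_key(rownames(m)))
  if (anyNA(idx))
    stop("alignment missing species: ",
         paste(labs[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- m[idx, , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  L <- ncol(m)
  eig <- subst_eigen(model)
  rates <- if (model$gamma) discrete_gamma_rates(model$shape, model$k) else 1
  k <- length(rates)
  pi <- model$base_freq
  part_lookup <- iupac_partials()

  tip_part <- lapply(seq_len(n_tip), function(i) {
    vapply(m[i, ], function(ch) part_lookup[[ch]], numeric(4))
  })

  post <- rev(preorder_edges(tree))      # postorder edge traversal
  edge_len <- tree$edge.length * rescale

  cat_sitelik <- matrix(0, k, L)         # site likelihood per category (linear, scaled)
  cat_logscale <- matrix(0, k, L)        # per-site log scaling accumulated to root
  down_all <- if (keep_partials) vector("list", k)
  P_all <- if (keep_partials) vector("list", k)

  for (c_i in seq_len(k)) {
    Pe <- lapply(seq_along(edge_len), function(e)
      transition_prob(eig, rates[c_i] * edge_len[e]))
    down <- vector("list", n_all)
    logscale <- matrix(0, n_all, L)
    for (i in seq_len(n_tip)) down[[i]] <- tip_part[[i]]
    for (e in post) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      msg <- Pe[[e]] %*% down[[chl]]
      if (is.null(down[[par]])) {
        down[[par]] <- msg
        logscale[par, ] <- logscale[chl, ]
      } else {
        down[[par]] <- down[[par]] * msg
        logscale[par, ] <- logscale[par, ] + logscale[chl, ]
      }
      # per-site rescale to avoid underflow
      dp <- down[[par]]
      mx <- pmax(dp[1, ], dp[2, ], dp[3, ], dp[4, ])
      mx[mx <= 0] <- 1
      down[[par]] <- dp / rep(mx, each = 4L)
      logscale[par, ] <- logscale[par, ] + log(mx)
    }
    root <- n_tip + 1L
    cat_sitelik[c_i, ] <- as.numeric(pi %*% down[[root]])
    cat_logscale[c_i, ] <- logscale[root, ]
    if (keep_partials) {
      down_all[[c_i]] <- down
      P_all[[c_i]] <- Pe
    }
  }
  # mixture over equal-weight categories, in log space per site
  lw <- log(1 / k)
  site_log <- apply(lw + log(cat_sitelik) + cat_logscale, 2, function(v) {
    mx <- max(v); mx + log(sum(exp(v - mx)))
  })
  if (any(!is.finite(site_log)))
    stop("non-finite likelihood at site(s): ",
         paste(which(!is.finite(site_log)), collapse = ", "), call. = FALSE)
  list(site_log = site_log, total = sum(site_log),
       cat_sitelik = cat_sitelik, cat_logscale = cat_logscale,
       down = down_all, P = P_all, alignment = m, rates = rates, pi = pi,
       edge_len = edge_len)
}

#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a [subst_model()]; with discrete-Gamma rates the
#' site likelihood is the equal-weight mixture over category rates.
#'
#' @param tree A `phylo` object whose tips cover the alignment (prune first
#'   if needed); branch lengths in substitutions/site after `rescale`.
#' @param alignment Character matrix (species x site), named sequence vector,
#'   or `DNAbin`.
#' @param model A [subst_model()].
#' @param rescale Global branch-length multiplier (use when the tree is in
#'   time units rather than substitutions/site).
#' @return A tibble with columns `site`, `loglik`; attribute `total` holds
#'   the summed log-likelihood.
#' @export
site_likelihood <- function(tree, alignment, model, rescale = 1) {
  eng <- prune_engine(tree, alignment, model, rescale = rescale)
  structure(tibble(site = seq_along(eng$site_log), loglik = eng$site_log),
            total = eng$total)
}

# Count free parameters for BIC (empirical HKY frequencies count as 3).
subst_n_params <- function(model, fit_rescale = FALSE) {
  p <- switch(model$family, JC = 0L, K2P = 1L, HKY = 4L)
  if (model$gamma) p <- p + 1L
  if (fit_rescale) p <- p + 1L
  p
}

# ML-fit the free parameters (Gamma shape, kappa, optional global branch
# rescale) of one candidate model by box-constrained quasi-Newton on log
# scales. Frequencies for HKY are empirical counts.
fit_subst_model <- function(tree, alignment, model, fit_rescale = FALSE) {
  m <- as_alignment_matrix(alignment)
  if (model$family == "HKY") {
    counts <- table(factor(as.vector(m), levels = c("A", "C", "G", "T")))
    model$base_freq <- setNames(as.numeric(counts + 1) / sum(counts + 1),
                                c("A", "C", "G", "T"))
  }
  par <- numeric(0)
  if (model$gamma) par <- c(par, lshape = log(model$shape))
  if (model$family %in% c("K2P", "HKY")) par <- c(par, lkappa = log(model$kappa))
  if (fit_rescale) par <- c(par, lrescale = 0)
  obj <- function(p) {
    mod <- model
    if (model$gamma) mod$shape <- exp(p[["lshape"]])
    if (model$family %in% c("K2P", "HKY")) mod$kappa <- exp(p[["lkappa"]])
    rs <- if (fit_rescale) exp(p[["lrescale"]]) else 1
    -tryCatch(attr(site_likelihood(tree, m, mod, rescale = rs), "total"),
              error = function(e) Inf)
  }
  if (length(par) == 0L) {
    return(list(model = model, rescale = 1,
                loglik = attr(site_likelihood(tree, m, model), "total"),
                convergence = 0L))
  }
  opt <- optim(par, obj, method = "L-BFGS-B",
               lower = rep(log(1e-4), length(par)),
               upper = rep(log(1e4), length(par)),
               control = list(maxit = 200))
  if (model$gamma) model$shape <- exp(opt$par[["lshape"]])
  if (model$family %in% c("K2P", "HKY")) model$kappa <- exp(opt$par[["lkappa"]])
  list(model = model,
       rescale = if (fit_rescale) exp(opt$par[["lrescale"]]) else 1,
       loglik = -opt$value, convergence = opt$convergence)
}

#' Rank candidate substitution models by BIC
#'
#' Each candidate's free parameters are ML-optimized; BIC = -2 lnL + p ln(n)
#' with n the number of alignment sites. Non-converged candidates are flagged
#' but retained.
#'
#' @inheritParams site_likelihood
#' @param candidates List of [subst_model()] objects (default the six-model
#'   set JC, JC+G, K2P, K2P+G, HKY, HKY+G).
#' @param fit_rescale Also optimize a single global branch-length multiplier
#'   per candidate (recommended for time-calibrated trees).
#' @return Tibble ranked by ascending BIC, with the fitted models in the
#'   `fit` list-column.
#' @export
select_model_bic <- function(tree, alignment, candidates = default_candidates(),
                             fit_rescale = TRUE) {
  if (length(candidates) < 2L) stop("need >= 2 candidate models", call. = FALSE)
  m <- as_alignment_matrix(alignment)
  n <- ncol(m)
  rows <- purrr::map(candidates, function(cand) {
    fit <- fit_subst_model(tree, m, cand, fit_rescale = fit_rescale)
    p <- subst_n_params(cand, fit_rescale = fit_rescale)
    tibble(model = paste0(cand$family, if (cand$gamma) "+G" else ""),
           loglik = fit$loglik, n_params = p, n_sites = n,
           bic = -2 * fit$loglik + p * log(n),
           converged = fit$convergence == 0L,
           fit = list(fit))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$bic)
  out
}

#' @rdname select_model_bic
#' @export
default_candidates <- function() {
  list(subst_model("JC"), subst_model("JC", gamma = TRUE),
       subst_model("K2P"), subst_model("K2P", gamma = TRUE),
       subst_model("HKY"), subst_model("HKY", gamma = TRUE))
}

#' Marginal maximum-likelihood ancestral sequence reconstruction
#'
#' Inside-outside message passing on the tree: for every internal node and
#' site, the marginal posterior over A/C/G/T mixed over the discrete-Gamma
#' categories, plus the MAP state (posterior-maximizing base; ties broken by
#' A < C < G < T order and flagged).
#'
#' @inheritParams site_likelihood
#' @return Tibble of class `asr_reconstruction` with columns `node`, `site`,
#'   `p_A`, `p_C`, `p_G`, `p_T`, `map`, `tie`; attributes `tree`, `total`
#'   (alignment log-likelihood), `model`.
#' @export
marginal_asr <- function(tree, alignment, model, rescale = 1) {
  eng <- prune_engine(tree, alignment, model, rescale = rescale,
                      keep_partials = TRUE)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  L <- ncol(eng$alignment)
  k <- length(eng$rates)
  pi <- eng$pi

  # per-site category responsibilities gamma_c(site)
  lg <- log(1 / k) + log(eng$cat_sitelik) + eng$cat_logscale
  mx <- apply(lg, 2, max)
  resp <- exp(sweep(lg, 2, mx, "-"))
  resp <- sweep(resp, 2, colSums(resp), "/")

  internal <- seq.int(root, n_all)
  post_mix <- array(0, dim = c(4, L, length(internal)),
                    dimnames = list(c("A", "C", "G", "T"), NULL, NULL))

  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  pre <- preorder_edges(tree)

  for (c_i in seq_len(k)) {
    down <- eng$down[[c_i]]
    Pe <- eng$P[[c_i]]
    up <- vector("list", n_all)
    up[[root]] <- matrix(pi, 4, L)
    for (e in pre) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      if (chl <= n_tip && is.null(children_of[[as.character(chl)]])) {
        # tips need no outside message unless requested
      }
      sib_edges <- setdiff(children_of[[as.character(par)]], e)
      prod_sib <- up[[par]]
      for (se in sib_edges) prod_sib <- prod_sib * (Pe[[se]] %*% down[[tree$edge[se, 2]]])
      msg <- t(Pe[[e]]) %*% prod_sib
      mxv <- pmax(msg[1, ], msg[2, ], msg[3, ], msg[4, ]); mxv[mxv <= 0] <- 1
      up[[chl]] <- msg / rep(mxv, each = 4L)
    }
    for (j in seq_along(internal)) {
      v <- internal[j]
      un <- up[[v]] * down[[v]]
      s <- colSums(un)
      s[s <= 0] <- 1
      post_v <- sweep(un, 2, s, "/")
      post_mix[, , j] <- post_mix[, , j] + post_v * rep(resp[c_i, ], each = 4)
    }
  }

  bases <- c("A", "C", "G", "T")
  rows <- purrr::map(seq_along(internal), function(j) {
    p <- t(post_mix[, , j])
    # MAP with numerically robust tie handling: first base (A < C < G < T)
    # within 1e-12 of the maximum wins, and the tie is flagged
    mx <- apply(p, 1, max)
    map_idx <- max.col(p >= mx - 1e-12, ties.method = "first")
    tie <- rowSums(p >= mx - 1e-12) > 1L
    tibble(node = internal[j], site = seq_len(L),
           p_A = p[, 1], p_C = p[, 2], p_G = p[, 3], p_T = p[, 4],
           map = bases[map_idx], tie = tie)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("asr_reconstruction", class(out)),
            tree = tree, total = eng$total, model = model)
}

#' Extract the MAP sequence of one node from a reconstruction
#'
#' @param asr An [marginal_asr()] result.
#' @param node Internal node number (ape numbering).
#' @return Character vector of bases.
#' @export
asr_map_sequence <- function(asr, node) {
  sub <- asr[asr$node == node, ]
  if (nrow(sub) == 0L) stop("node ", node, " not in reconstruction", call. = FALSE)
  sub$map[order(sub$site)]
}
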