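#' Paint selective regimes onto the branches of a tree
#'
#' Converts per-node states (tip states observed, internal states from an
#' ancestral reconstruction) into a branch painting: each branch carries the
#' state of its tipward (child) node, so regime shifts happen at nodes and
#' affect the subtending branch. The root's own state is recorded separately
#' as the root regime.
#'
#' @param tree A `phylo` object.
#' @param node_states Character vector of states, one per node in ape node
#'   order (tips `1..n`, then internal nodes `n+1..n+Nnode`); alternatively a
#'   vector named by tip label for the first `n` entries.
#' @param alphabet Ordered regime alphabet (default `c("LS","CC","CS")`).
#' @return A tibble of class `regime_painting` with columns `edge`, `parent`,
#'   `child`, `child_label`, `regime`; attributes `tree`, `root_regime`,
#'   `alphabet`, `node_states`.
#' @export
paint_regimes <- function(tree, node_states, alphabet = c("LS", "CC", "CS")) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  node_states <- as.character(node_states)
  if (length(node_states) != n_all)
    stop("node_states must have one state per node (", n_all, " expected, got ",
         length(node_states), ")", call. = FALSE)
  if (!is.null(names(node_states)) && all(nzchar(names(node_states)[seq_len(n_tip)]))) {
    idx <- match(species_key(tree$tip.label), species_key(names(node_states)[seq_len(n_tip)]))
    if (anyNA(idx)) stop("named node_states do not cover all tips", call. = FALSE)
    node_states[seq_len(n_tip)] <- node_states[seq_len(n_tip)][idx]
  }
  missing <- which(is.na(node_states) | !nzchar(node_states))
  if (length(missing))
    stop("missing state for node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(node_states), alphabet)
  if (length(bad))
    stop("state(s) outside regime alphabet: ", paste(bad, collapse = ", "), call. = FALSE)

  child <- tree$edge[, 2]
  out <- tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = child,
    child_label = ifelse(child <= n_tip, tree$tip.label[child], NA_character_),
    regime = node_states[child]
  )
  structure(out,
            class = c("regime_painting", class(out)),
            tree = tree,
            root_regime = node_states[n_tip + 1L],
            alphabet = alphabet,
            node_states = unname(node_states))
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("<regime_painting> root regime:", attr(x, "root_regime"),
      "| alphabet:", paste(attr(x, "alphabet"), collapse = " > "), "\n")
  print(as_tibble(x), ...)
  invisible(x)
}

painting_tree <- function(painting) attr(painting, "tree")

# Per-edge regime as a character vector aligned with tree$edge rows.
edge_regimes <- function(painting) painting$regime

#' Simulate a Markov regime history along a tree
#'
#' Continuous-time Markov jumps from the root state down every branch. The
#' default transition structure mirrors the documented history of the COX
#' mutation: the ancestral state LS can gain CC, CC can decay to CS, and
#' optionally CC can revert to LS (as in *Genlisea* subgenus *Tayloria*);
#' a fully symmetric chain is available for null simulations.
#'
#' @param tree A `phylo` object.
#' @param q Transition rate per unit branch length for each allowed move.
#' @param alphabet Regime alphabet; the first element is the root state.
#' @param reversal Allow the CC -> LS reversal (default `FALSE`).
#' @param symmetric Use a symmetric Mk chain over the alphabet instead of the
#'   sequential gain/decay structure.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return List with `node_states` (character, ape node order) and
#'   `painting` (a [paint_regimes()] result).
#' @export
simulate_regime_history <- function(tree, q, alphabet = c("LS", "CC", "CS"),
                                    reversal = FALSE, symmetric = FALSE,
                                    seed = NULL) {
  stopifnot(q >= 0)
  k <- length(alphabet)
  rates <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
  if (symmetric) {
    rates[] <- q
    diag(rates) <- 0
  } else {
    for (i in seq_len(k - 1L)) rates[i, i + 1L] <- q
    if (reversal && k >= 2L) rates["CC", "LS"] <- q
  }
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    states <- character(n_all)
    root <- n_tip + 1L
    states[root] <- alphabet[1L]
    ord <- preorder_edges(tree)
    for (e in ord) {
      par <- tree$edge[e, 1]
      chl <- tree$edge[e, 2]
      s <- states[par]
      t_left <- tree$edge.length[e]
      repeat {
        out_rate <- sum(rates[s, ])
        if (out_rate <= 0) break
        wait <- rexp(1L, out_rate)
        if (wait >= t_left) break
        t_left <- t_left - wait
        s <- sample(alphabet, 1L, prob = rates[s, ])
      }
      states[chl] <- s
    }
    list(node_states = states,
         painting = paint_regimes(tree, states, alphabet = alphabet))
  })
}

# Edge indices in preorder (root-adjacent edges first).
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  # reorder may permute edges; map back to original edge indices
  match(paste(tr$edge[, 1], tr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
}
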