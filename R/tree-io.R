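#' Read a rooted phylogeny from Newick (or Nexus) text
#'
#' Thin, validating wrapper around [ape::read.tree()]. Accepts a Newick
#' string, a path to a Newick file, or Nexus text/files (the first tree of
#' the `TREES` block is used). The returned tree is an [ape::phylo] object,
#' checked for unique non-empty tip labels and non-negative branch lengths.
#'
#' @param text Newick string (must end in `;`), or `NULL` if `file` given.
#' @param file Path to a Newick or Nexus file.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`", call. = FALSE)
  if (is.null(text)) {
    if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (grepl("#NEXUS", text, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    writeLines(text, tf)
    on.exit(unlink(tf), add = TRUE)
    tr <- ape::read.nexus(tf)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
    return(validate_phylo(tr))
  }
  scan_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failure: ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse failure: no tree found", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_phylo(tr)
}

# Pre-scan for unbalanced parentheses / missing terminator so that parse
# errors can point at a character offset (ape's own messages do not).
scan_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse failure: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse failure: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse failure: missing ';' terminator at character offset ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

validate_phylo <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- species_key(tree$tip.label)
  if (any(!nzchar(labs))) stop("empty tip label in tree", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  tree$tip.label <- labs
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch length in tree", call. = FALSE)
    if (any(tree$edge.length < 0))
      stop("negative branch length in tree", call. = FALSE)
    if (any(tree$edge.length == 0 & tree$edge[, 2] > ape::Ntip(tree)))
      warning("zero-length internal branch(es): treated as soft polytomies")
  }
  if (ape::Ntip(tree) == 1L)
    warning("degenerate single-tip tree")
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (round-trip safe at 12).
#' @return Newick string (invisibly, if `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Depth (time from the root) of every node, in ape node order.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree height (maximum root-to-tip depth, including any root edge)
#' @param tree A `phylo` object with branch lengths.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))]) + (tree$root.edge %||% 0)
}

#' Check whether a tree is ultrametric within a relative tolerance
#'
#' All trait-evolution machinery in this package assumes a time-calibrated
#' (ultrametric) tree; published dated trees carry rounding error, so the
#' check is relative: max |depth(tip) - mean depth| / mean depth <= rel_tol.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param rel_tol Relative tolerance (default `1e-4`).
#' @return Logical scalar with attributes `deviation` (the maximal relative
#'   deviation) and `worst_tip` (the offending tip label when not ultrametric).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-4) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  m <- mean(d)
  if (m <= 0) stop("zero-height tree: ultrametricity undefined", call. = FALSE)
  dev <- abs(d - m) / m
  ok <- max(dev) <= rel_tol
  structure(ok,
            deviation = max(dev),
            worst_tip = if (ok) NA_character_ else tree$tip.label[which.max(dev)])
}

#' Prune a tree to a set of species
#'
#' Induced subtree on `keep`: unary nodes are suppressed with branch lengths
#' summed, so every retained root-to-tip depth is preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (>= 2). Matching is
#'   exact after trimming whitespace and unifying underscores/spaces.
#' @return The pruned `phylo` object.
#' @export
prune_to <- function(tree, keep) {
  keep_key <- unique(species_key(keep))
  labs <- species_key(tree$tip.label)
  unknown <- setdiff(keep_key, labs)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep_key) < 2L) stop("need at least 2 species to keep", call. = FALSE)
  if (length(keep_key) == length(labs)) return(tree)
  mrca_depth <- if (length(keep_key) == 1L) 0 else
    node_depths(tree)[ape::getMRCA(tree, match(keep_key, labs))]
  out <- ape::keep.tip(tree, match(keep_key, labs))
  # the dropped root-to-MRCA path is retained as a root edge, so total
  # root-to-tip depths are preserved
  if (mrca_depth > 0) out$root.edge <- mrca_depth + (tree$root.edge %||% 0)
  out
}
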