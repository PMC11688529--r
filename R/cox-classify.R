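#' Classify the COX helix-3 two-residue state from two codons
#'
#' Translates the two mapped codons with the standard genetic code and maps
#' the amino-acid pair to the COX states used throughout the family:
#' (Lys, Ser) -> `"LS"`, (Cys, Cys) -> `"CC"`, (Cys, Ser) -> `"CS"`, anything
#' else (including gaps or ambiguity codes inside the codons) -> `"other"`.
#'
#' @param x A sequence: character vector of single bases, a single string, a
#'   row of an alignment matrix, or an [marginal_asr()] result (then `node`
#'   is required and the MAP sequence is used).
#' @param site_map List of two integer vectors (length 3 each) giving the
#'   alignment columns of the two codons, e.g. `list(58:60, 61:63)`.
#' @param node Internal node number when `x` is a reconstruction.
#' @return One of `"LS"`, `"CC"`, `"CS"`, `"other"`, with attribute
#'   `residues` (the translated amino-acid pair).
#' @export
classify_cox_state <- function(x, site_map, node = NULL) {
  if (inherits(x, "asr_reconstruction")) {
    if (is.null(node)) stop("supply `node` for a reconstruction input", call. = FALSE)
    x <- asr_map_sequence(x, node)
  }
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  x <- toupper(as.character(x))
  stopifnot(is.list(site_map), length(site_map) == 2L)
  if (any(lengths(site_map) != 3L))
    stop("each site_map entry must give 3 codon columns", call. = FALSE)
  if (max(unlist(site_map)) > length(x))
    stop("site_map outside sequence length", call. = FALSE)
  codons <- vapply(site_map, function(cols) paste(x[cols], collapse = ""), character(1))
  aa <- vapply(codons, translate_codon, character(1))
  state <- if (identical(unname(aa), c("K", "S"))) "LS"
  else if (identical(unname(aa), c("C", "C"))) "CC"
  else if (identical(unname(aa), c("C", "S"))) "CS"
  else "other"
  if (state == "other" && any(is.na(aa) | aa == "X")) {
    warning("gap or ambiguity inside the COX codons; state set to 'other'")
  }
  structure(state, residues = unname(aa))
}

# Standard-code translation of one codon; "X" for anything unresolvable.
translate_codon <- function(codon) {
  codon <- gsub("U", "T", toupper(codon))
  if (!grepl("^[ACGT]{3}$", codon)) return("X")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Classify COX states for every tip of an alignment
#'
#' @param alignment Character matrix species x site.
#' @inheritParams classify_cox_state
#' @return Tibble with columns `species`, `cox_state`, `residues`.
#' @export
classify_cox_tips <- function(alignment, site_map) {
  m <- as_alignment_matrix(alignment)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    st <- suppressWarnings(classify_cox_state(m[i, ], site_map))
    tibble(species = rownames(m)[i], cox_state = as.character(st),
           residues = paste(attr(st, "residues"), collapse = ""))
  })
  dplyr::bind_rows(rows)
}
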