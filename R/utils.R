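# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive reproducible child seeds from a master seed (counter scheme),
# keeping every seed in the 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical species key: trim whitespace, collapse runs of spaces and
# underscores so "Genlisea aurea" and "Genlisea_aurea" match.
species_key <- function(x) {
  gsub("[ _]+", " ", trimws(as.character(x)))
}

# Coerce a trait argument (named numeric, or data frame with species +
# value columns) to a named numeric vector.
as_trait_vector <- function(traits, value_col = NULL) {
  if (is.data.frame(traits)) {
    df <- as.data.frame(traits)
    sp_col <- intersect(c("species", "tip", "taxon"), names(df))[1]
    if (is.na(sp_col)) sp_col <- names(df)[1]
    if (is.null(value_col)) {
      num <- names(df)[vapply(df, is.numeric, logical(1))]
      if (length(num) == 0L) stop("no numeric trait column found", call. = FALSE)
      value_col <- num[1]
    }
    out <- setNames(as.numeric(df[[value_col]]), as.character(df[[sp_col]]))
  } else {
    if (is.null(names(traits))) stop("traits must be named by species", call. = FALSE)
    out <- as.numeric(traits)
    names(out) <- names(traits)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
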