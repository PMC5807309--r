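# Shared helpers.
#
# Model-facing site indices run 1..L from the 3' end (site 1 is adjacent to
# the reverse-transcription priming site), because truncation products extend
# from the primer. Everything a user sees -- files, printed structures, motif
# specifications, pairing matrices -- uses conventional 5'->3' 1-based
# coordinates. `flip_sites()` converts between the two; it is an involution,
# so the same call serves both directions.

#' Convert between 5'->3' display coordinates and 3'->5' model coordinates
#'
#' Model-internal site numbering starts at the 3' end (the reverse
#' transcription priming site); user-facing coordinates are conventional
#' 5'->3'. The mapping `l -> L + 1 - l` is its own inverse.
#'
#' @param sites integer vector of 1-based site indices.
#' @param L transcript length.
#' @return integer vector of flipped indices.
#' @export
#' @examples
#' flip_sites(c(1, 2), 6) # sites next to the 3' end, displayed as 6, 5
flip_sites <- function(sites, L) {
  if (length(sites) == 0) return(integer(0))
  stopifnot(is.numeric(sites), all(sites >= 1), all(sites <= L))
  as.integer(L + 1L - sites)
}

# Run `expr` under a fixed RNG seed when one is given, without disturbing the
# caller's RNG state; with seed = NULL the global RNG stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# nucleotide vector (5'->3') of a sequence string
seq_chars <- function(sequence) {
  strsplit(toupper(gsub("T", "U", sequence, fixed = TRUE)), "")[[1]]
}

assert_prob <- function(x, name, upper_open = FALSE) {
  bad <- !is.finite(x) | x < 0 | x > 1 | (upper_open & x == 1)
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie in [0, 1%s]; offending value: %s",
      name, if (upper_open) ")" else "", format(x[bad][1])
    ))
  }
  invisible(x)
}

# canonical key for a sorted internal site set, used for pattern identity
sites_key <- function(sites) paste(sort(as.integer(sites)), collapse = ",")
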