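`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic schedule of child seeds from one master seed
#'
#' Fans a single master seed out to `n` independent substream seeds so that
#' pipeline stages (or replicates) can be rerun individually while remaining
#' reproducible from the master seed alone. Seeds stay below 2^31.
#'
#' @param master_seed Single integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed), n >= 0)
  if (n == 0L) return(integer(0))
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

assert_prob <- function(x, name = deparse(substitute(x))) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Collapse a set of direction tags to a stable label ("up", "down", "up|down")
collapse_tags <- function(tags) {
  tags <- sort(unique(tags[!is.na(tags) & tags != "ns"]))
  if (length(tags) == 0L) return(NA_character_)
  paste(tags, collapse = "|")
}
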