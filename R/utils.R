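# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "bcbalance_validation_error", ...)
}

#' Split sequences into a character matrix
#'
#' One row per sequence, one column per position. All sequences must have
#' equal length.
#' @noRd
seq_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    abort_validation(sprintf(
      "sequences have ragged lengths: %s",
      paste(sort(unique(nchar(seqs))), collapse = ", ")
    ))
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), ncol = L, byrow = TRUE
  )
}

hamming <- function(a, b) sum(a != b)

# Run `expr` under a temporary seed when `seed` is given, otherwise use the
# session RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
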