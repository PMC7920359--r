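# Weighted barcode sets: the pool actually loaded on a lane. A set is a
# tibble with columns `id` and `weight`, referencing a panel. Weights are
# mixing proportions on an arbitrary scale (e.g. 9:9:9:9:5:5:5:5:5:5);
# every computation normalises them, so rescaling all weights leaves every
# result unchanged.

#' Construct a weighted barcode set
#'
#' @param id Character vector of barcode ids (references into a panel), or
#'   a data frame with columns `id` and optionally `weight`.
#' @param weight Positive mixing proportions, recycled scalar allowed;
#'   `NULL` means equal proportions (weight 1 each), mirroring the
#'   convention that an omitted proportions field means an equimolar pool.
#' @return A `bc_set` tibble with columns `id`, `weight`.
#' @examples
#' bc_set(c("BC01", "BC02"), weight = c(1, 4))
#' bc_set(c("BC01", "BC02")) # equal proportions
#' @export
bc_set <- function(id, weight = NULL) {
  if (is.data.frame(id)) {
    df <- tibble::as_tibble(id)
    if (!"weight" %in% names(df)) df$weight <- 1
    id <- df$id
    weight <- df$weight
  }
  id <- as.character(id)
  if (length(id) == 0) abort_validation("a barcode set must be non-empty")
  if (anyDuplicated(id)) {
    abort_validation(sprintf(
      "duplicate member id in set: '%s'", id[duplicated(id)][1]
    ))
  }
  weight <- weight %||% 1
  weight <- as.numeric(weight)
  if (length(weight) == 1) weight <- rep(weight, length(id))
  if (length(weight) != length(id)) {
    abort_validation("`weight` must have one entry per member (or length 1)")
  }
  if (any(is.na(weight)) || any(weight <= 0)) {
    abort_validation("all weights must be positive")
  }
  structure(
    tibble::tibble(id = id, weight = weight),
    class = c("bc_set", class(tibble::tibble()))
  )
}

#' Read a set specification from TSV
#'
#' Columns `id` and optionally `weight` (absent or NA entries default
#' to 1). Lines starting with `#` are skipped.
#' @param path Path to the set TSV.
#' @return A `bc_set`.
#' @export
read_set <- function(path) {
  df <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(df) <- tolower(names(df))
  if (!"id" %in% names(df)) {
    abort_validation(sprintf("%s: set TSV needs an `id` column", path))
  }
  w <- if ("weight" %in% names(df)) {
    w <- suppressWarnings(as.numeric(df$weight))
    w[is.na(w)] <- 1
    w
  } else {
    NULL
  }
  bc_set(df$id, w)
}

# Resolve a set against a panel: returns list(seqs matrix, w normalised).
# Errors name the first unknown member.
resolve_set <- function(set, panel) {
  set <- bc_set(set)
  panel <- bc_panel(panel)
  idx <- match(set$id, panel$id)
  if (anyNA(idx)) {
    abort_validation(sprintf(
      "set member '%s' not found in panel", set$id[which(is.na(idx))[1]]
    ))
  }
  list(
    ids = set$id,
    seqs = panel$seq[idx],
    S = seq_matrix(panel$seq[idx]),
    # raw weights; dividing by the total only at the end keeps equal
    # weights exactly at count/n
    w = set$weight,
    L = panel_length(panel)
  )
}
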