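# Barcode panels: the universe of identified fixed-length ACGT sequences
# from which pooled sets are drawn. A panel is a tibble with columns `id`
# and `seq`, carrying class "bc_panel" and an `L` attribute (barcode
# length). Barcode length is a property of the panel, not a constant: MGI
# barcodes are 10 nt, but nothing below assumes 10.

#' Construct and validate a barcode panel
#'
#' A panel is the candidate universe of barcodes: each row one barcode,
#' with a unique whitespace-free `id` and a unique sequence over A/C/G/T.
#' All sequences must share one length `L`. Lowercase input is uppercased
#' silently; any character outside A/C/G/T (including IUPAC ambiguity
#' codes) is an error, because the balance computation counts exact
#' nucleotide identities.
#'
#' @param x A data frame with columns `id` and `seq` (or `sequence`).
#' @return A `bc_panel` tibble with columns `id`, `seq` and attribute `L`.
#' @examples
#' bc_panel(data.frame(id = c("BC1", "BC2"),
#'                     seq = c("ACGTACGTAC", "TTTTACGGCA")))
#' @export
bc_panel <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"seq" %in% names(x) && "sequence" %in% names(x)) {
    x <- dplyr::rename(x, seq = "sequence")
  }
  if (!all(c("id", "seq") %in% names(x))) {
    abort_validation("a barcode panel needs columns `id` and `seq`")
  }
  if (nrow(x) == 0) abort_validation("a barcode panel must contain at least one barcode")
  x$id <- as.character(x$id)
  x$seq <- toupper(as.character(x$seq))
  if (any(is.na(x$id)) || any(!nzchar(x$id))) {
    abort_validation("barcode ids must be non-empty")
  }
  bad_id <- grepl("[[:space:]]", x$id)
  if (any(bad_id)) {
    abort_validation(sprintf(
      "barcode id contains whitespace: '%s'", x$id[which(bad_id)[1]]
    ))
  }
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) {
    abort_validation(sprintf("duplicate barcode id: '%s'", dup[1]))
  }
  dup_seq <- x$id[duplicated(x$seq)]
  if (length(dup_seq)) {
    abort_validation(sprintf(
      "duplicate sequence at '%s' (identical to an earlier barcode)", dup_seq[1]
    ))
  }
  lens <- nchar(x$seq)
  if (length(unique(lens)) != 1) {
    abort_validation(sprintf(
      "barcode sequences have ragged lengths: %s",
      paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  bad <- regexpr("[^ACGT]", x$seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort_validation(sprintf(
      "non-ACGT character at %s position %d", x$id[i], bad[i]
    ))
  }
  x <- x[, c("id", "seq")]
  structure(x,
    L = unname(lens[1]),
    class = c("bc_panel", class(tibble::tibble()))
  )
}

#' Barcode length of a panel
#' @param panel A `bc_panel`.
#' @return Integer barcode length.
#' @export
panel_length <- function(panel) {
  attr(panel, "L") %||% unique(nchar(panel$seq))
}

#' Read a barcode panel from TSV or FASTA
#'
#' TSV files are tab-separated with a header naming columns `id` and
#' `sequence` (`seq` also accepted); lines starting with `#` are skipped.
#' FASTA record ids serve as barcode ids. With `format = "auto"` the file
#' is sniffed: a first non-comment character of `>` means FASTA.
#'
#' @param path Path to the panel file.
#' @param format One of `"auto"`, `"tsv"`, `"fasta"`.
#' @return A validated `bc_panel`, rows in file order, sequences uppercased.
#' @export
read_panel <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_validation(sprintf("panel file not found: %s", path))
  }
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[!startsWith(first, "#") & nzchar(first)]
    format <- if (length(first) && startsWith(first[1], ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    rlang::check_installed("Biostrings", reason = "to read FASTA panels")
    ss <- Biostrings::readDNAStringSet(path)
    df <- tibble::tibble(
      id = sub("\\s.*$", "", names(ss)),
      seq = as.character(ss)
    )
  } else {
    df <- readr::read_tsv(path,
      comment = "#", col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    names(df) <- tolower(names(df))
    if (!all(c("id") %in% names(df)) ||
        !any(c("seq", "sequence") %in% names(df))) {
      abort_validation(sprintf(
        "%s: TSV panel needs header columns `id` and `sequence`", path
      ))
    }
  }
  bc_panel(df)
}

#' Write a barcode panel to TSV or FASTA
#'
#' @param panel A `bc_panel`.
#' @param path Output path.
#' @param format One of `"auto"` (by file extension), `"tsv"`, `"fasta"`.
#' @return `path`, invisibly. The written file reads back to an equal panel.
#' @export
write_panel <- function(panel, path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  panel <- bc_panel(panel)
  if (!is.character(path) || length(path) != 1 || !nzchar(path)) {
    abort_validation("`path` must be a single non-empty file path")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
      "fasta"
    } else {
      "tsv"
    }
  }
  if (format == "fasta") {
    writeLines(paste0(">", panel$id, "\n", panel$seq), path)
  } else {
    writeLines(
      c("id\tsequence", paste0(panel$id, "\t", panel$seq)),
      path
    )
  }
  invisible(path)
}

#' Generate a perfectly color-balanced barcode panel
#'
#' Builds `n` barcodes of length `L` such that every position carries each
#' of A/C/G/T in exactly `n/4` barcodes: at equal mixing proportions the
#' per-position nucleotide fractions of the whole panel are exactly 0.25,
#' the ideal the vendor's pre-approved sets realise. Each column is an
#' independent seeded permutation of `n/4` copies of each base; draws are
#' retried in the (rare) event of a duplicated sequence.
#'
#' @param n Number of barcodes; must be a positive multiple of 4.
#' @param L Barcode length.
#' @param seed Optional integer seed for reproducible panels.
#' @param id_prefix Prefix for generated barcode ids.
#' @return A `bc_panel` of `n` barcodes.
#' @export
make_balanced_set <- function(n, L = 10, seed = NULL, id_prefix = "BC") {
  if (n < 4 || n %% 4 != 0) {
    abort_validation("`n` must be a positive multiple of 4")
  }
  with_optional_seed(seed, {
    for (attempt in 1:100) {
      cols <- replicate(L, sample(rep(BASES, n / 4L)))
      seqs <- apply(cols, 1, paste0, collapse = "")
      if (!anyDuplicated(seqs)) break
    }
    if (anyDuplicated(seqs)) {
      abort_validation("could not draw distinct balanced sequences; increase L")
    }
    bc_panel(tibble::tibble(
      id = sprintf("%s%02d", id_prefix, seq_len(n)),
      seq = seqs
    ))
  })
}

#' Generate a random panel with a minimum pairwise Hamming distance
#'
#' Rejection-samples random ACGT sequences, keeping a candidate only if
#' its Hamming distance to every accepted barcode is at least
#' `min_distance`. This emulates the structure of vendor panels, whose
#' pairwise distances are bounded below (4 for the MGI panel) so that
#' mismatch-tolerant demultiplexing cannot merge samples.
#'
#' @param n Number of barcodes.
#' @param L Barcode length.
#' @param min_distance Minimum pairwise Hamming distance (0 = none).
#' @param seed Optional integer seed.
#' @param max_attempts Total candidate draws before giving up.
#' @param id_prefix Prefix for generated barcode ids.
#' @return A `bc_panel`; deterministic for a given seed.
#' @export
make_random_panel <- function(n, L = 10, min_distance = 0, seed = NULL,
                              max_attempts = 20000L * n, id_prefix = "BC") {
  if (n < 1) abort_validation("`n` must be positive")
  if (min_distance > L) {
    abort_validation("`min_distance` cannot exceed the barcode length")
  }
  with_optional_seed(seed, {
    accepted <- matrix(character(0), nrow = 0, ncol = L)
    attempts <- 0L
    while (nrow(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort_validation(paste0(
          "could not place ", n, " barcodes at min_distance ", min_distance,
          " within ", max_attempts, " attempts; reduce `n` or `min_distance`"
        ))
      }
      cand <- sample(BASES, L, replace = TRUE)
      d_ok <- if (nrow(accepted) == 0) {
        TRUE
      } else {
        all(rowSums(accepted != matrix(cand, nrow(accepted), L, byrow = TRUE)) >=
              max(min_distance, 1L))
      }
      if (d_ok) accepted <- rbind(accepted, cand)
    }
    bc_panel(tibble::tibble(
      id = sprintf("%s%02d", id_prefix, seq_len(n)),
      seq = apply(accepted, 1, paste0, collapse = "")
    ))
  })
}

#' @export
print.bc_panel <- function(x, ...) {
  cat(sprintf(
    "# Barcode panel: %d barcodes of length %d\n", nrow(x), panel_length(x)
  ))
  NextMethod()
}
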