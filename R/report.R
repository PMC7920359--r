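# Machine-readable JSON reports. Every report embeds the resolved
# configuration (and seed, where randomness is involved) so a result
# can be traced back to its inputs. Numbers are written at full
# precision; 3-decimal rounding is applied only in human-readable text.

#' Write a JSON report
#'
#' @param payload Named list of results.
#' @param config Named list echoed under `$config` (provenance: resolved
#'   options, paths, seed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(payload, config = list(), path) {
  out <- c(list(config = config), payload)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
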