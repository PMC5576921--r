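#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @import ggplot2
NULL

#' @export
generics::tidy

#' @export
generics::glance

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Hash a configuration or result object for provenance
#'
#' Stable hash of an R object, embedded in output files so a result can be
#' traced back to the exact configuration that produced it.
#'
#' @param x Any R object.
#' @return A character scalar (32-hex-digit hash).
#' @export
config_hash <- function(x) rlang::hash(x)
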