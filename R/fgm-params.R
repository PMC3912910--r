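#' Parameter triple of Fisher's geometric model
#'
#' Bundles the three parameters estimated jointly by the ABC machinery:
#' the genomic rate of fitness-altering mutations `U` (per individual per
#' generation), the number of phenotypic traits `n` under stabilizing
#' selection, and the per-trait mutational displacement standard deviation
#' `sigma`.
#'
#' @param U Genomic mutation rate for fitness-altering mutations, `U > 0`
#'   (a rate of 0 is allowed and means no mutation; useful for degenerate
#'   controls).
#' @param n Number of phenotypic traits, a positive integer.
#' @param sigma Standard deviation of a mutation's displacement on each
#'   trait, `sigma >= 0`.
#'
#' @return An object of class `fgm_params`: a named list with elements
#'   `U`, `n`, `sigma`.
#' @examples
#' fgm_params(U = 0.01, n = 9, sigma = 0.034)
#' @export
fgm_params <- function(U, n, sigma) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U), U >= 0)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n >= 1, n == round(n))
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma >= 0)
  structure(list(U = as.numeric(U), n = as.integer(n), sigma = as.numeric(sigma)),
            class = "fgm_params")
}

#' @export
print.fgm_params <- function(x, ...) {
  cat("Fisher's geometric model parameters\n")
  cat(sprintf("  U     = %g  (fitness-altering mutations / individual / generation)\n", x$U))
  cat(sprintf("  n     = %d  (phenotypic traits)\n", x$n))
  cat(sprintf("  sigma = %g  (per-trait mutational SD)\n", x$sigma))
  cat(sprintf("  E[s] at optimum = %g\n", expected_s_at_optimum(x)))
  invisible(x)
}

#' Serialize / deserialize an FGM parameter triple as JSON
#'
#' @param params An [fgm_params()] object.
#' @param path File path to write to / read from.
#' @return `write_fgm_params()` returns `path` invisibly;
#'   `read_fgm_params()` returns an [fgm_params()] object.
#' @export
write_fgm_params <- function(params, path) {
  stopifnot(inherits(params, "fgm_params"))
  jsonlite::write_json(list(U = params$U, n = params$n, sigma = params$sigma),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fgm_params
#' @export
read_fgm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fgm_params(U = x$U, n = x$n, sigma = x$sigma)
}
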