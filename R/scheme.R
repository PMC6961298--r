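#' Diffusion-weighting scheme
#'
#' A `bvalue_scheme` bundles the b-values of a multi-b-value DWI acquisition
#' with the number of excitations (NEX) averaged at each b. Higher b-values
#' are usually acquired with more excitations because diffusion attenuation
#' lowers the signal-to-noise ratio; averaging NEX excitations reduces the
#' noise standard deviation by a factor of sqrt(NEX).
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2;
#'   strictly increasing, starting at 0.
#' @param nex Integer vector of excitation counts, one per b-value, all >= 1.
#' @return An object of class `bvalue_scheme`: a list with elements
#'   `b_values` and `nex`.
#' @seealso [default_bvalue_scheme()] for the 12-b-value protocol used
#'   throughout, [read_bval()] / [write_bval()] for FSL-style file I/O.
#' @examples
#' sch <- bvalue_scheme(c(0, 100, 500, 1000), c(1, 2, 2, 4))
#' @export
bvalue_scheme <- function(b_values, nex = rep(1L, length(b_values))) {
  if (!is.numeric(b_values) || length(b_values) < 2)
    stopf("b_values must be a numeric vector of length >= 2")
  if (any(!is.finite(b_values)) || b_values[1] != 0)
    stopf("b_values must be finite and start at 0")
  if (any(diff(b_values) <= 0))
    stopf("b_values must be strictly increasing")
  if (length(nex) != length(b_values))
    stopf("nex must have the same length as b_values")
  if (!is_count(nex) || any(nex < 1))
    stopf("nex must be integers >= 1")
  structure(list(b_values = as.numeric(b_values), nex = as.integer(nex)),
            class = "bvalue_scheme")
}

#' The default 12-b-value acquisition scheme
#'
#' b = 0, 10, 25, 50, 75, 100, 150, 200, 400, 800, 1000, 1500 s/mm^2 with
#' NEX = 1, 3, 3, 3, 3, 2, 2, 2, 2, 3, 5, 6. The dense low-b sampling
#' (b <= 200) resolves the perfusion-driven pseudo-diffusion component of
#' the IVIM model; the high-b points constrain the slow-diffusion tail.
#'
#' @return A [bvalue_scheme()].
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(c(0, 10, 25, 50, 75, 100, 150, 200, 400, 800, 1000, 1500),
                c(1L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 3L, 5L, 6L))
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme:", length(x$b_values), "b-values\n")
  cat("  b (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  NEX:       ", paste(x$nex, collapse = ", "), "\n")
  invisible(x)
}

#' Read/write FSL-style .bval files
#'
#' A .bval file is a whitespace-separated list of b-values on one line.
#' NEX counts are not part of the FSL format; they are supplied separately
#' (typically from the pipeline configuration).
#'
#' @param path File path.
#' @param nex Optional excitation counts for the scheme read from `path`;
#'   defaults to 1 for every b-value.
#' @return `read_bval` returns a [bvalue_scheme()]; `write_bval` returns
#'   `path` invisibly.
#' @export
read_bval <- function(path, nex = NULL) {
  b <- scan(path, what = numeric(), quiet = TRUE)
  bvalue_scheme(b, nex %||% rep(1L, length(b)))
}

#' @rdname read_bval
#' @param scheme A [bvalue_scheme()] to write.
#' @export
write_bval <- function(scheme, path) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  writeLines(paste(format(scheme$b_values, trim = TRUE), collapse = " "), path)
  invisible(path)
}
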