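`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Lower median
#'
#' Median of a numeric vector, taking the lower of the two middle values for
#' even lengths.  Used for design constants (numbers of locations, years,
#' zones) that are integer-valued by nature.
#'
#' @param x numeric vector.
#' @return a single value of `x`.
#' @keywords internal
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0L) return(NA_real_)
  x[floor((length(x) + 1) / 2)]
}

# AR1 correlation matrix on (possibly non-contiguous) integer coordinates:
# correlation rho^|i-j| between coordinates i and j.
ar1_cor <- function(coords, rho) {
  stop_if(abs(rho) >= 1, "AR1 correlation must satisfy |rho| < 1")
  outer(coords, coords, function(i, j) rho^abs(i - j))
}

# most-square factorization nx x ny with nx * ny = n, nx >= ny
grid_dims <- function(n) {
  stop_if(n < 1, "grid size must be >= 1")
  ny <- floor(sqrt(n))
  while (n %% ny != 0L) ny <- ny - 1L
  c(nx = as.integer(n / ny), ny = as.integer(ny))
}
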