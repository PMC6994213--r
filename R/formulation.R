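#' Oil component names, in fixed order
#'
#' The droplet formulation space is the 3-simplex of mixing ratios of four
#' oils: octanoic acid, diethyl phthalate (DEP), 1-octanol and 1-pentanol.
#' The component order is fixed package-wide.
#' @export
OIL_COMPONENTS <- c("octanoic_acid", "dep", "octanol", "pentanol")

#' Construct an oil formulation (a point on the mixture simplex)
#'
#' @param ratios numeric 4-vector of mixing fractions in component order
#'   ([OIL_COMPONENTS]); must be non-negative and sum to 1 within 1e-9.
#' @return a named numeric vector of class `oil_formulation`
#' @seealso [normalize_formulation()] to build one from arbitrary weights
#' @export
oil_formulation <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 4L || anyNA(ratios) || any(!is.finite(ratios))) {
    stop("invalid formulation: need 4 finite ratios", call. = FALSE)
  }
  if (any(ratios < 0)) {
    stop("invalid formulation: negative ratio", call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop("invalid formulation: ratios must sum to 1 (got ", sum(ratios), ")",
         call. = FALSE)
  }
  names(ratios) <- OIL_COMPONENTS
  class(ratios) <- "oil_formulation"
  ratios
}

#' Normalize arbitrary non-negative oil weights onto the mixture simplex
#'
#' Scale-invariant: `normalize_formulation(c * x)` equals
#' `normalize_formulation(x)` for any `c > 0`.
#'
#' @param raw numeric 4-vector of non-negative weights with positive sum
#'   (e.g. percentages).
#' @return an [oil_formulation()]
#' @examples
#' normalize_formulation(c(1, 1, 1, 1))
#' # the focus recipe, given as percentages:
#' normalize_formulation(c(1.9, 47.9, 13.5, 36.7))
#' @export
normalize_formulation <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 4L || anyNA(raw) || any(!is.finite(raw))) {
    stop("invalid formulation: need 4 finite non-negative weights",
         call. = FALSE)
  }
  if (any(raw < 0)) {
    stop("invalid formulation: negative weight", call. = FALSE)
  }
  s <- sum(raw)
  if (s <= 0) {
    stop("invalid formulation: weights sum to zero", call. = FALSE)
  }
  oil_formulation(raw / s)
}

#' @export
print.oil_formulation <- function(x, ...) {
  cat("<oil_formulation> ",
      paste(sprintf("%s=%.4f", OIL_COMPONENTS, unclass(x)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Row-wise renormalization of a candidate matrix (n x 4) onto the simplex.
# Rows with non-positive sum map to the uniform mixture.
normalize_rows <- function(m) {
  m[m < 0] <- 0
  s <- rowSums(m)
  bad <- s <= 0
  if (any(bad)) {
    m[bad, ] <- 1
    s[bad] <- 4
  }
  m / s
}
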