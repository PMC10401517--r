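#' Convert a reported log-micromolar activity to pAC50
#'
#' Bioactivity tables report `modl_ga`, the base-10 logarithm of the AC50 in
#' micromolar units. The molar half-maximal concentration is
#' `AC50(M) = 10^modl_ga * 1e-6`, so the negative log-molar potency is
#' `pAC50 = -log10(AC50(M)) = 6 - modl_ga`.
#'
#' @param modl_ga Numeric vector of log10 AC50 values in micromolar units.
#' @return Numeric vector of pAC50 values (-log10 molar).
#' @examples
#' modl_ga_to_pac50(c(0, 6, 1.5))  # 6, 0, 4.5
#' @export
modl_ga_to_pac50 <- function(modl_ga) {
  if (!is.numeric(modl_ga) || any(!is.finite(modl_ga))) {
    stop("modl_ga must be finite numeric", call. = FALSE)
  }
  6 - modl_ga
}

#' Absolute activity difference between two chemicals
#'
#' `|pAC50_i - pAC50_j|`, the quantity thresholded (at 2 log units, i.e. a
#' 100-fold potency change) when calling activity cliffs.
#'
#' @param pac50_i,pac50_j Numeric vectors of pAC50 values; recycled.
#' @return Non-negative numeric vector; symmetric in its arguments.
#' @examples
#' activity_difference(6, 3.5)  # 2.5
#' @export
activity_difference <- function(pac50_i, pac50_j) {
  if (!is.numeric(pac50_i) || !is.numeric(pac50_j) ||
      any(!is.finite(pac50_i)) || any(!is.finite(pac50_j))) {
    stop("pAC50 values must be finite numeric", call. = FALSE)
  }
  abs(pac50_i - pac50_j)
}
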