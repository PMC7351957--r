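#' Expression distance between two transcriptome profiles
#'
#' The dissimilarity between two whole-embryo expression profiles over the
#' same ortholog groups: `1 - rho`, where `rho` is the Spearman rank
#' correlation computed as the Pearson correlation of average ranks (ties
#' averaged). The result lies in `[0, 2]`; 0 means identical ranking, 2 a
#' perfect rank inversion. Because it is rank-based, the distance is
#' invariant to strictly monotone transforms of either profile, so no log
#' transform or expression-level prefilter is applied upstream.
#'
#' @param x,y Numeric vectors of equal length (>= 3), aligned to the same
#'   ortholog-group order.
#' @return A single number in `[0, 2]`.
#' @section Errors: vectors of unequal length are an error; a constant
#'   vector has all-tied ranks and therefore an undefined correlation,
#'   which is raised as an error rather than silently returned as 0.
#' @examples
#' expdist(c(1, 2, 3), c(2, 4, 6)) # 0: same ranking
#' expdist(c(1, 2, 3), c(3, 2, 1)) # 2: inverted ranking
#' expdist(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.2
#' @export
expdist <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop_config("`x` and `y` must be numeric")
  if (length(x) != length(y)) {
    stop_config("length mismatch: %d vs %d", length(x), length(y))
  }
  if (length(x) < 3L) stop_config("need at least 3 ortholog groups")
  if (anyNA(x) || anyNA(y)) stop_config("missing values are not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) {
    stop_undefined_cor("constant profile: correlation (hence expdist) undefined")
  }
  1 - sum(cx * cy) / den
}
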