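#' Logit transform of a proportion
#'
#' Maps a proportion in \code{[0, 1]} to the real line via
#' \eqn{\log(p / (1 - p))}. Percentage traits such as corm damage scores are
#' analysed on this scale throughout the package. Exact 0 or 1 map to
#' \code{-Inf} / \code{Inf}; use [clamp_proportion()] first when boundary
#' observations are possible.
#'
#' @param p Numeric vector of proportions in \code{[0, 1]}. \code{NA} is
#'   propagated; \code{NaN} is an error.
#' @return Numeric vector, \eqn{\log(p/(1-p))}.
#' @seealso [inv_logit()], [clamp_proportion()]
#' @examples
#' logit(0.5)
#' logit(0.0816)
#' @export
logit <- function(p) {
  if (any(is.nan(p))) stop("logit: NaN input")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("logit: input outside [0, 1]")
  log(p / (1 - p))
}

#' Inverse logit (logistic) transform
#'
#' @param x Numeric vector.
#' @return \eqn{e^x / (1 + e^x)}, a proportion in \code{(0, 1)}.
#' @seealso [logit()]
#' @examples
#' inv_logit(0)      # 0.5
#' inv_logit(-2.42)  # ~0.0816
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Clamp proportions away from the 0/1 boundary
#'
#' Percentage observations of exactly 0% or 100% have an infinite logit.
#' Before transformation, proportions are pulled into
#' \code{[delta, 1 - delta]}. The default \code{delta} corresponds to half a
#' unit on the finest recordable percentage scale of a plot of
#' \code{n_plants} plants scored to whole percent
#' (\code{1 / (4 * n_plants * 100)} with the default four plants).
#'
#' @param p Numeric vector of proportions.
#' @param delta Clamping offset, in \code{(0, 0.5)}.
#' @return Clamped proportions.
#' @export
clamp_proportion <- function(p, delta = 1 / 1600) {
  stopifnot(delta > 0, delta < 0.5)
  pmin(pmax(p, delta), 1 - delta)
}

#' Harmonic mean sequencing depth
#'
#' The harmonic mean \eqn{S_T = n / \sum_i 1/d_i} over the non-zero depths
#' \eqn{d_i}. Samples with depth 0 carry no reads and are treated as missing
#' rather than as observations of depth zero (the harmonic mean is undefined
#' at 0). The harmonic mean is the right average here because the
#' measurement-error variance of a read-count allele-frequency estimate
#' scales with \eqn{1/d}.
#'
#' @param depths Non-negative numeric vector of per-sample depths.
#' @return The harmonic mean of the positive depths.
#' @examples
#' harmonic_mean_depth(c(10, 40))   # 16
#' harmonic_mean_depth(c(5, 0, 5))  # 5, zeros excluded
#' @export
harmonic_mean_depth <- function(depths) {
  if (any(is.na(depths))) depths <- depths[!is.na(depths)]
  if (any(depths < 0)) stop("harmonic_mean_depth: negative depth")
  d <- depths[depths > 0]
  if (length(d) == 0L) stop("harmonic_mean_depth: no positive depths")
  length(d) / sum(1 / d)
}

#' Haldane mapping function
#'
#' Converts a recombination fraction to a map distance in centimorgans under
#' the assumption of no crossover interference:
#' \eqn{d = -50 \log(1 - 2r)} cM.
#'
#' @param r Recombination fraction(s) in \code{[0, 0.5)}.
#' @return Map distance in cM.
#' @examples
#' haldane(0.2)  # 25.54 cM
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("haldane: recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping function
#'
#' @param d Map distance(s) in cM, non-negative.
#' @return Recombination fraction \eqn{(1 - e^{-2d/100}) / 2}.
#' @examples
#' haldane_inverse(25.54)  # ~0.2
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("haldane_inverse: negative distance")
  (1 - exp(-2 * d / 100)) / 2
}

# row-wise cumulative sum of a 0/1 matrix via triangular matrix product;
# avoids apply() in the meiosis inner loop
.row_cumsum <- function(m) {
  if (ncol(m) == 0L) return(m)
  m %*% upper.tri(diag(ncol(m)), diag = TRUE)
}
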