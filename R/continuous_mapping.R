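# Continuous mapping: regression of logit-scale adjusted trait means on
# per-individual reference-allele frequencies estimated from read counts.
# Because a read-count frequency is a noisy measurement of the true
# genotype frequency g/ploidy, the regression slope is attenuated; at
# harmonic-mean depth S_T the attenuation factor for triploids is
# 1 / (1 + 2 / S_T), and the estimated effect is corrected by dividing by
# that factor.

#' Attenuation (bias) factor of the allele-substitution effect
#'
#' The multiplicative underestimation of the regression slope caused by
#' read-sampling noise in the allele-frequency predictor at harmonic-mean
#' sequencing depth \eqn{S_T}:
#' \deqn{b(S_T) = \frac{1}{1 + 2 / S_T} \in (0, 1).}
#' It vanishes to 1 as depth grows and falls to 0.5 at a depth of 2.
#'
#' @param S_T Harmonic-mean sequencing depth (positive).
#' @return The attenuation factor in \code{(0, 1)}.
#' @examples
#' bias_factor(2)   # 0.5
#' bias_factor(18)  # 0.9
#' @export
bias_factor <- function(S_T) {
  if (any(S_T <= 0, na.rm = TRUE)) stop("bias_factor: S_T must be positive")
  1 / (1 + 2 / S_T)
}

#' Correct an attenuated allele-substitution effect
#'
#' Divides the raw regression effect by the attenuation factor:
#' \code{beta_corrected = beta_raw * (1 + 2 / S_T)}.
#'
#' @param beta_raw Estimated (attenuated) effect.
#' @param S_T Harmonic-mean sequencing depth.
#' @return The bias-corrected effect.
#' @examples
#' correct_effect(0.9, 18)  # 1.0
#' @export
correct_effect <- function(beta_raw, S_T) {
  beta_raw / bias_factor(S_T)
}

#' Single-marker regression of trait means on allele frequencies
#'
#' Ordinary least squares of the adjusted logit-scale means on the
#' per-individual reference-allele frequencies at one marker, with a
#' two-sided p-value from the t distribution on \code{n - 2} degrees of
#' freedom and \code{R2} the squared Pearson correlation.
#'
#' @param means Numeric vector of per-genotype trait means.
#' @param freqs Numeric vector of per-genotype allele frequencies
#'   (\code{NA} allowed; pairs with a missing value are dropped).
#' @return A list: \code{n}, \code{slope}, \code{se}, \code{t}, \code{p},
#'   \code{minus_log10_p}, \code{r2}. With fewer than 3 complete pairs or
#'   zero frequency variance, the estimates are \code{NA} and
#'   \code{monomorphic_in_sample} is \code{TRUE}.
#' @export
regress_marker <- function(means, freqs) {
  ok <- !is.na(means) & !is.na(freqs)
  n <- sum(ok)
  out <- list(n = n, slope = NA_real_, se = NA_real_, t = NA_real_,
              p = NA_real_, minus_log10_p = NA_real_, r2 = NA_real_,
              monomorphic_in_sample = FALSE)
  if (n < 3) { out$monomorphic_in_sample <- TRUE; return(out) }
  x <- freqs[ok]; y <- means[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * n) {
    out$monomorphic_in_sample <- TRUE
    return(out)
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  sse <- syy - slope * sxy
  se <- sqrt(max(sse, 0) / (n - 2) / sxx)
  tval <- slope / se
  logp <- log(2) + stats::pt(-abs(tval), n - 2, log.p = TRUE)
  out$slope <- slope
  out$se <- se
  out$t <- tval
  out$p <- exp(logp)
  out$minus_log10_p <- -logp / log(10)
  out$r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  out
}

#' Genome-wide continuous-mapping scan
#'
#' Regresses the adjusted trait means on the allele frequencies of every
#' marker, attaches the per-marker harmonic-mean depth \eqn{S_T}, the raw
#' and bias-corrected allele-substitution effects (scaled per
#' reference-allele copy: a one-copy change in a triploid moves the
#' frequency by 1/3) and the explained variance. Individuals with a
#' missing frequency at a marker are dropped for that marker only.
#'
#' @param means Named numeric vector of per-genotype adjusted means, or an
#'   \code{"adjusted_means"} object (its test genotypes are used).
#' @param freqs Samples x markers matrix of allele frequencies (row names
#'   are genotype ids).
#' @param depths Samples x markers matrix of sequencing depths, aligned
#'   with \code{freqs}; used for the per-marker \eqn{S_T}.
#' @param map Optional data frame (\code{marker}, \code{chrom},
#'   \code{pos_bp} and/or \code{pos_cM}) used to order and annotate the
#'   records; defaults to the column order of \code{freqs}.
#' @param alpha Significance threshold on the raw p-value (default 0.001;
#'   no multiple-testing adjustment is applied).
#' @param ploidy Offspring ploidy for the per-copy effect scale.
#' @param effect_scale \code{"per_allele"} (default; slope / ploidy) or
#'   \code{"per_unit"} (raw slope per unit frequency).
#' @param S_T Optional global harmonic-mean depth overriding the
#'   per-marker value.
#' @return A data frame of class \code{"marker_scan"}, one row per marker:
#'   \code{marker}, \code{chrom}, \code{pos_bp}, \code{pos_cM} (when
#'   supplied), \code{n}, \code{slope}, \code{beta_raw},
#'   \code{beta_corrected}, \code{se}, \code{minus_log10_p}, \code{p},
#'   \code{expl_var_percent}, \code{S_T}, \code{significant}. The
#'   threshold is attached as attribute \code{"alpha"}.
#' @export
genome_scan <- function(means, freqs, depths = NULL, map = NULL,
                        alpha = 0.001, ploidy = 3,
                        effect_scale = c("per_allele", "per_unit"),
                        S_T = NULL) {
  effect_scale <- match.arg(effect_scale)
  if (inherits(means, "adjusted_means")) means <- means_vector(means)
  common <- intersect(names(means), rownames(freqs))
  if (length(common) == 0)
    stop("genome_scan: no overlapping genotypes between means and freqs")
  y <- means[common]
  F <- freqs[common, , drop = FALSE]
  m <- ncol(F)

  M <- !is.na(F) & !is.na(y)     # usable cells
  Fz <- ifelse(M, F, 0)
  yv <- ifelse(is.na(y), 0, y)
  n <- colSums(M)
  sy <- drop(crossprod(M, yv))
  sy2 <- drop(crossprod(M, yv^2))
  sx <- colSums(Fz)
  sx2 <- colSums(Fz^2)
  sxy <- drop(crossprod(Fz, yv))
  sxx <- sx2 - sx^2 / pmax(n, 1)
  sxy_c <- sxy - sx * sy / pmax(n, 1)
  syy <- sy2 - sy^2 / pmax(n, 1)

  valid <- n >= 3 & sxx > .Machine$double.eps * pmax(n, 1)
  slope <- ifelse(valid, sxy_c / sxx, NA_real_)
  sse <- pmax(syy - slope * sxy_c, 0)
  se <- ifelse(valid, sqrt(sse / (n - 2) / sxx), NA_real_)
  tval <- slope / se
  logp <- log(2) + stats::pt(-abs(tval), n - 2, log.p = TRUE)
  r2 <- ifelse(valid & syy > 0, sxy_c^2 / (sxx * syy), NA_real_)

  if (is.null(S_T)) {
    if (is.null(depths)) stop("genome_scan: supply depths or a global S_T")
    D <- depths[common, , drop = FALSE]
    pos_n <- colSums(D > 0, na.rm = TRUE)
    inv_sum <- colSums(ifelse(!is.na(D) & D > 0, 1 / D, 0))
    st <- ifelse(pos_n > 0, pos_n / inv_sum, NA_real_)
  } else {
    st <- rep(S_T, m)
  }

  scale_f <- if (effect_scale == "per_allele") 1 / ploidy else 1
  beta_raw <- slope * scale_f
  beta_corrected <- beta_raw * (1 + 2 / st)

  rec <- data.frame(
    marker = colnames(F),
    n = n,
    slope = slope,
    beta_raw = beta_raw,
    beta_corrected = beta_corrected,
    se = se * scale_f,
    minus_log10_p = -logp / log(10),
    p = exp(logp),
    expl_var_percent = 100 * r2,
    S_T = st,
    significant = !is.na(logp) & exp(logp) < alpha,
    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    keep <- intersect(c("marker", "chrom", "pos_bp", "pos_cM"), names(map))
    rec <- merge(map[, keep], rec, by = "marker", sort = FALSE)
    ord <- do.call(order, rec[intersect(c("chrom", "pos_bp", "pos_cM"),
                                        names(rec))])
    rec <- rec[ord, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "alpha") <- alpha
  class(rec) <- c("marker_scan", "data.frame")
  rec
}

#' Significant markers of a scan, in reporting form
#'
#' @param scan A \code{"marker_scan"} data frame from [genome_scan()].
#' @return The significant rows with the reporting columns (marker,
#'   position, -log10 p, corrected effect, explained variance).
#' @export
significant_markers <- function(scan) {
  cols <- intersect(c("marker", "chrom", "pos_bp", "minus_log10_p",
                      "beta_corrected", "expl_var_percent"), names(scan))
  out <- scan[scan$significant %in% TRUE, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot-ready Manhattan table
#'
#' Rows sorted by chromosome and position with the \code{-log10(p)}
#' significance threshold attached as metadata.
#'
#' @param scan A \code{"marker_scan"} data frame (needs \code{chrom} and a
#'   position column).
#' @param alpha Threshold used for the reference line; defaults to the
#'   scan's own alpha.
#' @return Data frame \code{chrom}, \code{pos}, \code{minus_log10_p} with
#'   attribute \code{"threshold"} = \code{-log10(alpha)}; empty input
#'   yields an empty table with a warning.
#' @export
manhattan_table <- function(scan, alpha = attr(scan, "alpha") %||% 0.001) {
  if (nrow(scan) == 0 || !"chrom" %in% names(scan)) {
    if (nrow(scan) == 0) warning("manhattan_table: empty scan")
    out <- data.frame(chrom = character(), pos = numeric(),
                      minus_log10_p = numeric())
    attr(out, "threshold") <- -log10(alpha)
    return(out)
  }
  pos <- if ("pos_bp" %in% names(scan)) scan$pos_bp else scan$pos_cM
  out <- data.frame(chrom = scan$chrom, pos = pos,
                    minus_log10_p = scan$minus_log10_p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- -log10(alpha)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Manhattan plot of a genome scan
#'
#' @param scan A \code{"marker_scan"} data frame.
#' @param alpha Significance threshold drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted table.
#' @export
plot_manhattan <- function(scan, alpha = attr(scan, "alpha") %||% 0.001,
                           ...) {
  tab <- manhattan_table(scan, alpha)
  if (nrow(tab) == 0) return(invisible(tab))
  chrom <- factor(tab$chrom)
  offs <- c(0, cumsum(tapply(tab$pos, chrom, max)))
  x <- tab$pos + offs[as.integer(chrom)]
  graphics::plot(x, tab$minus_log10_p, pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[1 + as.integer(chrom) %% 2],
                 xlab = "genome position", ylab = expression(-log[10](p)),
                 ...)
  graphics::abline(h = attr(tab, "threshold"), col = "blue", lty = 2)
  invisible(tab)
}
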