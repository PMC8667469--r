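#' Reference-allele frequency from allelic depths
#'
#' @param ref_count,alt_count Non-negative integer vectors of reference and
#'   alternative read counts.
#' @return \code{ref / (ref + alt)}, or \code{NA} where total depth is 0.
#' @examples
#' allele_frequency(2, 4)  # 1/3
#' allele_frequency(0, 0)  # NA
#' @export
allele_frequency <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE))
    stop("allele_frequency: negative counts")
  depth <- ref_count + alt_count
  ifelse(depth > 0, ref_count / depth, NA_real_)
}

# expected reference-read probability for dosage g at the given ploidy,
# with per-read error rate epsilon
.p_read_ref <- function(g, ploidy, epsilon) {
  (g / ploidy) * (1 - epsilon) + (1 - g / ploidy) * epsilon
}

#' Genotype likelihood for an allele dosage from read counts
#'
#' The likelihood of observing \code{ref_count} reference reads out of
#' \code{ref_count + alt_count} total reads when the true genotype carries
#' \code{g} of \code{ploidy} reference alleles. Reads are modelled as
#' independent draws with reference probability
#' \eqn{p_g = (g/ploidy)(1-\epsilon) + (1-g/ploidy)\epsilon}, where
#' \eqn{\epsilon} is the per-read sequencing error rate.
#'
#' @param ref_count,alt_count Read counts (scalars or vectors).
#' @param ploidy Ploidy of the individual.
#' @param g Candidate dosage, \code{0..ploidy}.
#' @param epsilon Per-read error rate in \code{[0, 0.5)}.
#' @return Binomial likelihood \eqn{P(D \mid g)}.
#' @examples
#' genotype_likelihood(2, 1, ploidy = 3, g = 2, epsilon = 0)  # 4/9
#' @export
genotype_likelihood <- function(ref_count, alt_count, ploidy, g, epsilon = 0.01) {
  stopifnot(all(g >= 0), all(g <= ploidy), epsilon >= 0, epsilon < 0.5)
  stats::dbinom(ref_count, ref_count + alt_count, .p_read_ref(g, ploidy, epsilon))
}

#' Call an integer allele dosage by maximum likelihood
#'
#' Evaluates the genotype likelihood for every candidate dosage
#' \code{0..ploidy} and calls the maximiser only when it is at least
#' \code{ratio_threshold} times more likely than the runner-up; otherwise
#' the genotype is left missing. With the default threshold of 10 a call is
#' made only when the best genotype is ten times more likely than the second
#' best.
#'
#' @inheritParams genotype_likelihood
#' @param ratio_threshold Minimum likelihood ratio best/second-best
#'   (\code{> 1}) required for a call.
#' @return A list of class \code{"dosage_call"}: \code{g} (integer or
#'   \code{NA}), \code{likelihoods} (named vector over candidate dosages),
#'   and \code{ratio} (best over runner-up; \code{NA} at depth 0).
#' @examples
#' call_dosage(12, 0, ploidy = 2)$g   # 2
#' call_dosage(3, 3, ploidy = 3)$g    # NA: dosages 1 and 2 tie by symmetry
#' @export
call_dosage <- function(ref_count, alt_count, ploidy, epsilon = 0.01,
                        ratio_threshold = 10) {
  stopifnot(length(ref_count) == 1L, length(alt_count) == 1L,
            ratio_threshold > 1)
  gs <- 0:ploidy
  lik <- genotype_likelihood(ref_count, alt_count, ploidy, gs, epsilon)
  names(lik) <- gs
  out <- list(g = NA_integer_, likelihoods = lik, ratio = NA_real_)
  class(out) <- "dosage_call"
  if (ref_count + alt_count == 0 || all(lik == 0)) return(out)
  ord <- order(lik, decreasing = TRUE)
  ratio <- lik[ord[1]] / lik[ord[2]]
  out$ratio <- unname(ratio)
  if (is.finite(ratio) && ratio >= ratio_threshold || is.infinite(ratio))
    out$g <- gs[ord[1]]
  out
}

#' Call dosages for a read-count matrix
#'
#' Vectorised maximum-likelihood dosage calling over a sites-by-samples
#' matrix pair of reference and alternative depths, with the same
#' likelihood-ratio rule as [call_dosage()].
#'
#' @param ref,alt Integer matrices (sites x samples) of allelic depths.
#' @inheritParams call_dosage
#' @return Integer matrix of called dosages (sites x samples), \code{NA}
#'   where no call passes the ratio threshold.
#' @export
call_dosage_matrix <- function(ref, alt, ploidy, epsilon = 0.01,
                               ratio_threshold = 10) {
  stopifnot(identical(dim(ref), dim(alt)), ratio_threshold > 1)
  n <- ref + alt
  # vectorised best / runner-up log-likelihood sweep over the candidate
  # dosages (at most 5), avoiding a per-cell apply()
  best <- stats::dbinom(ref, n, .p_read_ref(0, ploidy, epsilon), log = TRUE)
  best_g <- array(0L, dim = dim(ref))
  second <- array(-Inf, dim = dim(ref))
  for (g in seq_len(ploidy)) {
    ll <- stats::dbinom(ref, n, .p_read_ref(g, ploidy, epsilon), log = TRUE)
    take <- ll > best
    second[take] <- best[take]
    tie2 <- !take & ll > second
    second[tie2] <- ll[tie2]
    best[take] <- ll[take]
    best_g[take] <- g
  }
  calls <- ifelse(best - second >= log(ratio_threshold), best_g, NA_integer_)
  calls[n == 0] <- NA_integer_
  dim(calls) <- dim(ref)
  dimnames(calls) <- dimnames(ref)
  storage.mode(calls) <- "integer"
  calls
}

# dosage -> label, e.g. g4 = 3 -> "RRRA"; R = reference allele
.dosage_label <- function(g, ploidy) {
  vapply(g, function(gi) {
    paste0(strrep("R", gi), strrep("A", ploidy - gi))
  }, character(1))
}

#' Classify a parental dosage combination by segregation status
#'
#' For a biallelic site with tetraploid parent dosage \code{g4} (number of
#' reference alleles, 0..4) and diploid parent dosage \code{g2} (0..2),
#' returns the combination label (e.g. \code{AAAA x RA}) and its
#' segregation status in the triploid offspring:
#' \itemize{
#'   \item \code{monomorphic}: both parents homozygous for the same allele;
#'   \item \code{polymorphic_nonsegregating}: both homozygous, different
#'     alleles (all offspring identical heterozygotes);
#'   \item \code{segregates_P1_only} / \code{segregates_P2_only}: only the
#'     tetraploid (P1) or only the diploid (P2) parent heterozygous;
#'   \item \code{segregates_both}: both parents heterozygous.
#' }
#'
#' @param g4 Tetraploid parent reference-allele dosage, 0..4.
#' @param g2 Diploid parent reference-allele dosage, 0..2.
#' @return A data frame with columns \code{g4}, \code{g2}, \code{label_p1},
#'   \code{label_p2}, \code{class} and \code{status} (one row per input).
#' @examples
#' classify_parental_combination(0, 1)  # AAAA x RA, segregates_P2_only
#' @export
classify_parental_combination <- function(g4, g2) {
  if (any(g4 < 0 | g4 > 4 | g2 < 0 | g2 > 2, na.rm = TRUE))
    stop("classify_parental_combination: dosage out of range")
  het1 <- g4 %in% 1:3
  het2 <- g2 == 1L
  status <- ifelse(het1 & het2, "segregates_both",
            ifelse(het1, "segregates_P1_only",
            ifelse(het2, "segregates_P2_only",
            ifelse((g4 / 4) == (g2 / 2), "monomorphic",
                   "polymorphic_nonsegregating"))))
  data.frame(
    g4 = as.integer(g4), g2 = as.integer(g2),
    label_p1 = .dosage_label(g4, 4), label_p2 = .dosage_label(g2, 2),
    class = paste(.dosage_label(g4, 4), .dosage_label(g2, 2), sep = " x "),
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Tabulate parental dosage combinations across sites
#'
#' Builds the 5 x 3 table of parental genotype combinations (tetraploid
#' dosage class by diploid dosage class) and totals per segregation status.
#'
#' @param g4,g2 Integer vectors of parental dosages per site (sites with a
#'   missing parent call should be excluded beforehand).
#' @param weights Optional non-negative weights (e.g. site counts when
#'   tabulating an already-aggregated table); default 1 per site.
#' @return A list of class \code{"combination_table"}: \code{table} (5 x 3
#'   matrix, rows RRRR..AAAA, columns RR/RA/AA), \code{status_totals}
#'   (named vector over the five segregation statuses),
#'   \code{total_segregating} and \code{total}.
#' @export
tabulate_combinations <- function(g4, g2, weights = NULL) {
  stopifnot(length(g4) == length(g2))
  if (is.null(weights)) weights <- rep(1, length(g4))
  stopifnot(length(weights) == length(g4), all(weights >= 0))
  cls <- classify_parental_combination(g4, g2)
  rows <- factor(cls$label_p1, levels = .dosage_label(4:0, 4))
  cols <- factor(cls$label_p2, levels = .dosage_label(2:0, 2))
  tab <- matrix(0, 5, 3, dimnames = list(levels(rows), levels(cols)))
  for (i in seq_along(g4)) tab[rows[i], cols[i]] <- tab[rows[i], cols[i]] + weights[i]
  statuses <- c("monomorphic", "polymorphic_nonsegregating",
                "segregates_P1_only", "segregates_P2_only", "segregates_both")
  status_totals <- vapply(statuses, function(s) sum(weights[cls$status == s]),
                          numeric(1))
  out <- list(
    table = tab,
    status_totals = status_totals,
    total_segregating = sum(status_totals[grep("^segregates", statuses)]),
    total = sum(weights)
  )
  class(out) <- "combination_table"
  out
}

#' @export
print.combination_table <- function(x, ...) {
  cat("Parental dosage combinations (P1 tetraploid rows x P2 diploid columns)\n")
  print(x$table)
  cat("\nSegregation status totals:\n")
  print(x$status_totals)
  cat("Total segregating:", x$total_segregating, "of", x$total, "sites\n")
  invisible(x)
}

# hypergeometric gamete law of a bivalent-pairing tetraploid:
# P(gamete dosage k | parent dosage g4) = C(g4,k) C(4-g4,2-k) / C(4,2)
.gamete_law_tetraploid <- function(g4) {
  k <- 0:2
  p <- choose(g4, k) * choose(4 - g4, 2 - k) / choose(4, 2)
  names(p) <- k
  p
}

.gamete_law_diploid <- function(g2) {
  p <- c(stats::dbinom(0, 1, g2 / 2), stats::dbinom(1, 1, g2 / 2))
  names(p) <- 0:1
  p
}

#' Expected offspring dosage distribution at an unlinked marker
#'
#' Convolves the tetraploid gamete law (hypergeometric under random bivalent
#' pairing without double reduction) with the diploid Mendelian gamete law
#' to give the distribution of the triploid offspring reference-allele
#' dosage 0..3.
#'
#' @inheritParams classify_parental_combination
#' @return Named numeric vector of probabilities over offspring dosage
#'   \code{0:3}, summing to 1.
#' @examples
#' expected_offspring_distribution(0, 1)  # AAAA x RA: 1/2, 1/2 over {0, 1}
#' expected_offspring_distribution(2, 1)  # 1/12, 5/12, 5/12, 1/12
#' @export
expected_offspring_distribution <- function(g4, g2) {
  stopifnot(length(g4) == 1L, length(g2) == 1L,
            g4 >= 0, g4 <= 4, g2 >= 0, g2 <= 2)
  p4 <- .gamete_law_tetraploid(g4)
  p2 <- .gamete_law_diploid(g2)
  out <- stats::setNames(numeric(4), 0:3)
  for (k in 0:2) for (j in 0:1) {
    out[as.character(k + j)] <- out[as.character(k + j)] + p4[[as.character(k)]] * p2[[as.character(j)]]
  }
  out
}

#' Minor-allele-frequency filter
#'
#' The per-site population reference-allele frequency is the mean of the
#' per-sample allele-frequency estimates over non-missing samples (each
#' sample contributes equally regardless of its depth). A site is retained
#' when its minor allele frequency \code{min(f, 1-f)} is at least
#' \code{threshold}.
#'
#' @param freq Matrix of per-sample allele frequencies (samples x sites),
#'   \code{NA} for depth-0 samples.
#' @param threshold Minimum minor allele frequency (default 0.02).
#' @return Logical vector over sites: \code{TRUE} where retained.
#' @export
maf_filter <- function(freq, threshold = 0.02) {
  f <- colMeans(freq, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  !is.na(maf) & maf >= threshold
}

#' Missing-data filter
#'
#' Retains sites whose fraction of missing samples is strictly below
#' \code{max_missing} (a site with exactly the threshold fraction missing is
#' removed).
#'
#' @param x Matrix (samples x sites) of calls or frequencies with \code{NA}
#'   for missing.
#' @param max_missing Maximum tolerated missingness fraction (default 0.10).
#' @return Logical vector over sites: \code{TRUE} where retained.
#' @export
missingness_filter <- function(x, max_missing = 0.10) {
  miss <- colMeans(is.na(x))
  miss < max_missing
}
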