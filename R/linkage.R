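# Simplex-marker linkage mapping. Markers where the tetraploid parent is
# homozygous (AAAA or RRRR) and the diploid parent heterozygous (RA)
# segregate 1:1 in the triploid offspring, like a backcross, so the
# standard two-point / interval machinery of diploid mapping applies after
# recoding offspring genotypes to carrier (1) / non-carrier (0) of the
# diploid parent's segregating allele.

#' Select and recode simplex markers
#'
#' Keeps markers of parental class (homozygous tetraploid) x (heterozygous
#' diploid), i.e. \code{g4} in \{0, 4\} and \code{g2} = 1, and recodes the
#' offspring dosage to carrier status of the diploid parent's segregating
#' allele: for AAAA x RA the R allele (dosage 1 -> 1, 0 -> 0); for
#' RRRR x RA the A allele (dosage 2 -> 1, 3 -> 0). Dosages impossible
#' under the class become missing.
#'
#' @param map Data frame with columns \code{marker}, \code{g4}, \code{g2}
#'   (parental dosages; e.g. the truth map of a synthetic cross or
#'   high-confidence parental calls).
#' @param offspring Offspring dosage matrix (individuals x markers,
#'   integer 0..3 or \code{NA}).
#' @return A list of class \code{"simplex_markers"}: \code{geno}
#'   (individuals x kept markers binary matrix), \code{info} (the map rows
#'   kept).
#' @export
select_simplex_markers <- function(map, offspring) {
  stopifnot(all(c("marker", "g4", "g2") %in% names(map)))
  keep <- map$g4 %in% c(0L, 4L) & map$g2 == 1L
  info <- map[keep, , drop = FALSE]
  X <- offspring[, info$marker, drop = FALSE]
  G <- matrix(NA_integer_, nrow(X), ncol(X), dimnames = dimnames(X))
  is_aaaa <- info$g4 == 0L
  # AAAA x RA: carrier of R; RRRR x RA: carrier of A
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    G[, j] <- if (is_aaaa[j]) {
      ifelse(x %in% c(0L, 1L), x, NA_integer_)
    } else {
      ifelse(x == 2L, 1L, ifelse(x == 3L, 0L, NA_integer_))
    }
  }
  out <- list(geno = G, info = info)
  class(out) <- "simplex_markers"
  out
}

#' Chi-square goodness-of-fit test against 1:1 segregation
#'
#' @param n0,n1 Counts of the two offspring classes.
#' @return A list: \code{chi2} = \eqn{(n_0-n_1)^2/(n_0+n_1)} and \code{p}
#'   from the chi-square distribution with 1 df.
#' @examples
#' chi_square_1to1(70, 30)  # chi2 = 16, p ~ 6.3e-5
#' @export
chi_square_1to1 <- function(n0, n1) {
  if (any(n0 + n1 <= 0)) stop("chi_square_1to1: empty sample")
  chi2 <- (n0 - n1)^2 / (n0 + n1)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Filter simplex markers on missingness and segregation distortion
#'
#' Retains markers with missingness strictly below \code{max_missing} and
#' no segregation distortion from 1:1 at level \code{alpha} (chi-square
#' goodness of fit).
#'
#' @param sm A \code{"simplex_markers"} object.
#' @param max_missing Maximum tolerated missing fraction (strict; default
#'   0.10).
#' @param alpha Distortion significance level (default 0.001).
#' @return A filtered \code{"simplex_markers"} object; the numbers removed
#'   by each rule are in attribute \code{"removed"}.
#' @export
filter_simplex_markers <- function(sm, max_missing = 0.10, alpha = 0.001) {
  stopifnot(inherits(sm, "simplex_markers"))
  G <- sm$geno
  ok_miss <- colMeans(is.na(G)) < max_missing
  n1 <- colSums(G == 1L, na.rm = TRUE)
  n0 <- colSums(G == 0L, na.rm = TRUE)
  p_seg <- chi_square_1to1(n0, n1)$p
  ok_seg <- p_seg >= alpha
  keep <- ok_miss & ok_seg
  out <- list(geno = G[, keep, drop = FALSE],
              info = sm$info[keep, , drop = FALSE])
  attr(out, "removed") <- c(missingness = sum(!ok_miss),
                            distortion = sum(ok_miss & !ok_seg))
  class(out) <- "simplex_markers"
  out
}

#' Two-point recombination estimate between two simplex markers
#'
#' With \code{k} mismatches among \code{n} jointly scored offspring, the
#' recombination fraction is \code{min(k, n - k) / n}; the phase is
#' coupling when mismatches are the minority class and repulsion
#' otherwise. The LOD score compares the binomial likelihood at the
#' estimate with independence (r = 0.5).
#'
#' @param m1,m2 Binary (0/1/NA) genotype vectors of equal length.
#' @return A list: \code{r}, \code{phase} (\code{"coupling"} /
#'   \code{"repulsion"}), \code{lod}, \code{n} (complete pairs); all
#'   \code{NA} when no complete pair exists.
#' @export
pairwise_recombination <- function(m1, m2) {
  ok <- !is.na(m1) & !is.na(m2)
  n <- sum(ok)
  if (n == 0)
    return(list(r = NA_real_, phase = NA_character_, lod = NA_real_, n = 0L))
  k <- sum(m1[ok] != m2[ok])
  r <- min(k, n - k) / n
  phase <- if (k <= n - k) "coupling" else "repulsion"
  kk <- min(k, n - k)
  lod <- (if (kk > 0) kk * log10(r) else 0) +
    (if (n - kk > 0) (n - kk) * log10(1 - r) else 0) - n * log10(0.5)
  list(r = r, phase = phase, lod = lod, n = n)
}

# all-pairs recombination/phase/count matrices for a binary marker matrix
.recombination_matrices <- function(X) {
  M <- !is.na(X)
  A <- ifelse(M, X, 0)            # ones
  B <- ifelse(M, 1 - X, 0)        # zeros
  n <- crossprod(M)
  agree <- crossprod(A) + crossprod(B)
  mismatch <- n - agree
  r_raw <- ifelse(n > 0, mismatch / n, NA_real_)
  r <- pmin(r_raw, 1 - r_raw)
  phase <- ifelse(is.na(r_raw), NA, r_raw <= 0.5)  # TRUE = coupling
  list(r = r, coupling = phase, n = n)
}

#' Group markers by transitive closure at a recombination threshold
#'
#' Builds the graph whose edges connect marker pairs with estimated
#' recombination fraction at most \code{r_threshold} and returns its
#' connected components (single-linkage grouping). Groups smaller than
#' \code{min_size} are discarded; their number is reported in attribute
#' \code{"n_dropped"}.
#'
#' @param r Symmetric matrix of pairwise recombination estimates
#'   (\code{NA} treated as unlinked).
#' @param r_threshold Linkage threshold (default 0.20).
#' @param min_size Minimum group size kept (default 10).
#' @return A list of character vectors of marker names (the groups),
#'   largest first.
#' @export
group_markers <- function(r, r_threshold = 0.20, min_size = 10) {
  stopifnot(nrow(r) == ncol(r))
  adj <- !is.na(r) & r <= r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  nm <- rownames(r) %||% as.character(seq_len(nrow(r)))
  groups <- split(nm, comp$membership)
  sizes <- lengths(groups)
  kept <- groups[sizes >= min_size]
  kept <- kept[order(-lengths(kept))]
  names(kept) <- NULL
  attr(kept, "n_dropped") <- sum(sizes < min_size)
  kept
}

# sum of adjacent recombination fractions along an order
.order_objective <- function(ord, r) {
  sum(r[cbind(ord[-length(ord)], ord[-1])])
}

#' Order the markers of a linkage group
#'
#' Greedy chain construction (start from the tightest pair, repeatedly
#' append the unplaced marker closest to either end) followed by
#' deterministic 2-opt refinement of the sum of adjacent recombination
#' fractions. If \code{physical} positions are supplied and
#' \code{use_physical_order = TRUE} the physical order is adopted
#' directly.
#'
#' @param markers Character vector of marker names (one group).
#' @param r Pairwise recombination matrix covering the markers.
#' @param physical Optional numeric vector of physical positions named by
#'   marker.
#' @param use_physical_order Adopt the physical order instead of
#'   estimating one.
#' @return Character vector: the markers in estimated order (orientation
#'   is arbitrary; reversing it leaves the objective unchanged).
#' @export
order_markers <- function(markers, r, physical = NULL,
                          use_physical_order = FALSE) {
  if (use_physical_order) {
    stopifnot(!is.null(physical), all(markers %in% names(physical)))
    return(markers[order(physical[markers])])
  }
  m <- length(markers)
  if (m <= 2) return(markers)
  rr <- r[markers, markers]
  rr[is.na(rr)] <- 0.5
  diag(rr) <- Inf
  # greedy chain: seed with the tightest pair
  seed <- which(rr == min(rr), arr.ind = TRUE)[1, ]
  chain <- as.integer(seed)
  left <- setdiff(seq_len(m), chain)
  while (length(left) > 0) {
    head_d <- rr[chain[1], left]
    tail_d <- rr[chain[length(chain)], left]
    if (min(head_d) <= min(tail_d)) {
      pick <- left[which.min(head_d)]
      chain <- c(pick, chain)
    } else {
      pick <- left[which.min(tail_d)]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  # 2-opt: reverse segments while the adjacency objective improves; only
  # the two boundary edges change, so the improvement is evaluated in O(1)
  rr2 <- rr
  diag(rr2) <- 0
  best <- chain
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        old_cost <- (if (i > 1) rr2[best[i - 1], best[i]] else 0) +
          (if (j < m) rr2[best[j], best[j + 1]] else 0)
        new_cost <- (if (i > 1) rr2[best[i - 1], best[j]] else 0) +
          (if (j < m) rr2[best[i], best[j + 1]] else 0)
        if (new_cost < old_cost - 1e-12) {
          best[i:j] <- rev(best[i:j])
          improved <- TRUE
        }
      }
    }
  }
  markers[best]
}

#' Build a simplex-marker linkage map
#'
#' Two-point estimates, single-linkage grouping at \code{r_threshold},
#' within-group ordering, cumulative Haldane cM positions from adjacent
#' recombination estimates, and phase assignment relative to the first
#' marker of each group (walking the order and flipping at repulsion
#' links).
#'
#' @param sm A (filtered) \code{"simplex_markers"} object.
#' @inheritParams group_markers
#' @inheritParams order_markers
#' @return An object of class \code{"genetic_map"}: a list of group data
#'   frames (\code{marker}, \code{cM}, \code{phase}, plus \code{chrom} /
#'   \code{pos_bp} when present in \code{sm$info}), with the genotype
#'   matrix and two-point matrices attached.
#' @export
build_linkage_map <- function(sm, r_threshold = 0.20, min_size = 10,
                              physical = NULL, use_physical_order = FALSE) {
  stopifnot(inherits(sm, "simplex_markers"))
  tp <- .recombination_matrices(sm$geno)
  groups <- group_markers(tp$r, r_threshold, min_size)
  cap <- 0.4999  # adjacent r estimates occasionally stray; keep d finite
  out_groups <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ord <- order_markers(groups[[gi]], tp$r, physical, use_physical_order)
    r_adj <- tp$r[cbind(ord[-length(ord)], ord[-1])]
    d_adj <- haldane(pmin(r_adj, cap))
    coup_adj <- tp$coupling[cbind(ord[-length(ord)], ord[-1])]
    flip <- cumsum(c(FALSE, !coup_adj)) %% 2 == 1
    df <- data.frame(marker = ord,
                     cM = c(0, cumsum(d_adj)),
                     phase = ifelse(flip, "repulsion", "coupling"),
                     stringsAsFactors = FALSE)
    extra <- intersect(c("chrom", "pos_bp"), names(sm$info))
    if (length(extra))
      df <- cbind(df, sm$info[match(ord, sm$info$marker), extra,
                              drop = FALSE])
    rownames(df) <- NULL
    out_groups[[gi]] <- df
  }
  out <- list(groups = out_groups, geno = sm$geno, r = tp$r,
              coupling = tp$coupling,
              n_dropped = attr(groups, "n_dropped"))
  class(out) <- "genetic_map"
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(x$groups), "linkage group(s),",
      sum(vapply(x$groups, nrow, integer(1))), "markers,",
      round(sum(vapply(x$groups, function(g) max(g$cM), numeric(1))), 1),
      "cM total\n")
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    cat(sprintf("  LG%-2d %4d markers %8.1f cM\n", i, nrow(g), max(g$cM)))
  }
  if (x$n_dropped > 0)
    cat("  (", x$n_dropped, "group(s) below the minimum size dropped )\n")
  invisible(x)
}

# genotypes of one group, phase-aligned to the anchor (coupling) marker
.aligned_genotypes <- function(map, gi) {
  g <- map$groups[[gi]]
  X <- map$geno[, g$marker, drop = FALSE]
  flip <- g$phase == "repulsion"
  X[, flip] <- 1L - X[, flip, drop = FALSE]
  X
}

#' Conditional heterozygosity probabilities at an evaluation position
#'
#' For each individual, the probability of the heterozygous (carrier)
#' class at \code{pos_cM}, conditional on the nearest non-missing flanking
#' markers, under the Haldane (no interference) model — the standard
#' backcross flanking-marker formulas. With only one informative flank the
#' single-flank transition applies; with none the prior 0.5.
#'
#' @param positions Marker positions (cM) of one linkage group, ascending.
#' @param geno Phase-aligned binary genotype matrix (individuals x
#'   markers of the group).
#' @param pos_cM Evaluation position.
#' @return Numeric vector of \eqn{P(\mathrm{carrier})} per individual.
#' @export
conditional_genotype_probabilities <- function(positions, geno, pos_cM) {
  stopifnot(ncol(geno) == length(positions), !is.unsorted(positions))
  n <- nrow(geno)
  out <- numeric(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(geno[i, ]))
    if (length(obs) == 0) { out[i] <- 0.5; next }
    op <- positions[obs]
    ov <- geno[i, obs]
    iL <- findInterval(pos_cM, op)
    # an observed marker at the evaluation position decides the genotype
    if (iL >= 1 && op[iL] == pos_cM) { out[i] <- ov[iL]; next }
    iR <- if (iL < length(obs)) iL + 1L else NA_integer_
    has_L <- iL >= 1
    has_R <- !is.na(iR)
    if (has_L && has_R) {
      rL <- haldane_inverse(pos_cM - op[iL])
      rR <- haldane_inverse(op[iR] - pos_cM)
      tL1 <- ov[iL] * (1 - rL) + (1 - ov[iL]) * rL      # P(x = 1 | left)
      tR1 <- ov[iR] * (1 - rR) + (1 - ov[iR]) * rR      # P(right | x = 1)
      tR0 <- ov[iR] * rR + (1 - ov[iR]) * (1 - rR)      # P(right | x = 0)
      out[i] <- tL1 * tR1 / (tL1 * tR1 + (1 - tL1) * tR0)
    } else if (has_L) {
      rL <- haldane_inverse(pos_cM - op[iL])
      out[i] <- ov[iL] * (1 - rL) + (1 - ov[iL]) * rL
    } else if (has_R) {
      rR <- haldane_inverse(op[iR] - pos_cM)
      out[i] <- ov[iR] * (1 - rR) + (1 - ov[iR]) * rR
    } else {
      out[i] <- 0.5
    }
  }
  out
}

# Haley-Knott regression of means on expected genotype, with optional
# cofactor covariates; returns the test-slope statistics
.hk_regression <- function(y, x, covars = NULL) {
  X <- cbind(1, x, covars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!(2 %in% keep))
      return(list(slope = NA_real_, minus_log10_p = NA_real_,
                  p = NA_real_))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  n <- length(y)
  df <- n - qrX$rank
  if (df <= 0 || stats::var(x) < 1e-12)
    return(list(slope = NA_real_, minus_log10_p = NA_real_, p = NA_real_))
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- coef[2] / se
  logp <- log(2) + stats::pt(-abs(tval), df, log.p = TRUE)
  list(slope = unname(coef[2]), minus_log10_p = -logp / log(10),
       p = exp(logp))
}

# evaluation grid of one group: every `step` cM plus the marker positions
.scan_grid <- function(positions, step) {
  sort(unique(c(seq(0, max(positions), by = step), positions)))
}

#' Simple interval mapping scan (Haley-Knott)
#'
#' At every grid position (each \code{step} cM plus the marker positions)
#' the adjusted trait means are regressed on the expected carrier
#' probability given the flanking markers; \code{-log10(p)} comes from the
#' t-test of the slope. Candidate QTL are local maxima of the profile at
#' or above \code{threshold}.
#'
#' @param map A \code{"genetic_map"}.
#' @param means Named numeric vector of per-individual trait means (or an
#'   \code{"adjusted_means"} object; its test genotypes are used).
#' @param step Grid step in cM (default 5).
#' @param threshold Detection threshold on \code{-log10(p)} (default 2).
#' @param peak_separation Minimum distance in cM between reported peaks of
#'   one group; of two closer local maxima the higher is kept (default 30).
#' @return A list of class \code{"qtl_profile"}: \code{profile} (data
#'   frame \code{group}, \code{pos_cM}, \code{n}, \code{effect},
#'   \code{minus_log10_p}), \code{peaks} (rows of the profile that are
#'   local maxima >= threshold), \code{threshold}, \code{step}.
#' @export
sim_scan <- function(map, means, step = 5, threshold = 2,
                     peak_separation = 30) {
  stopifnot(inherits(map, "genetic_map"))
  if (inherits(means, "adjusted_means")) means <- means_vector(means)
  ids <- intersect(rownames(map$geno), names(means))
  if (length(ids) < 20)
    stop("sim_scan: fewer than 20 phenotyped offspring")
  y <- means[ids]
  rows <- list()
  for (gi in seq_along(map$groups)) {
    g <- map$groups[[gi]]
    X <- .aligned_genotypes(map, gi)[ids, , drop = FALSE]
    grid <- .scan_grid(g$cM, step)
    for (p in grid) {
      ex <- conditional_genotype_probabilities(g$cM, X, p)
      fit <- .hk_regression(y, ex)
      rows[[length(rows) + 1]] <- data.frame(
        group = gi, pos_cM = p, n = length(y), effect = fit$slope,
        minus_log10_p = fit$minus_log10_p)
    }
  }
  profile <- do.call(rbind, rows)
  out <- list(profile = profile,
              peaks = .profile_peaks(profile, threshold, peak_separation),
              threshold = threshold, step = step)
  class(out) <- "qtl_profile"
  out
}

# local maxima of -log10(p) at or above the threshold, per group, thinned
# so that no two retained peaks lie within min_separation cM of each other
# (the highest wins; the dense grid otherwise yields a peak per noise
# wiggle of the profile)
.profile_peaks <- function(profile, threshold, min_separation = 30) {
  peaks <- list()
  for (gi in unique(profile$group)) {
    pr <- profile[profile$group == gi, , drop = FALSE]
    v <- pr$minus_log10_p
    v[is.na(v)] <- -Inf
    k <- nrow(pr)
    is_peak <- vapply(seq_len(k), function(i) {
      v[i] >= threshold &&
        (i == 1 || v[i] >= v[i - 1]) && (i == k || v[i] >= v[i + 1])
    }, logical(1))
    cand <- pr[is_peak, , drop = FALSE]
    cand <- cand[order(-cand$minus_log10_p, cand$pos_cM), , drop = FALSE]
    kept <- cand[0, , drop = FALSE]
    while (nrow(cand) > 0) {
      kept <- rbind(kept, cand[1, , drop = FALSE])
      cand <- cand[abs(cand$pos_cM - cand$pos_cM[1]) >= min_separation, ,
                   drop = FALSE]
    }
    kept <- kept[order(kept$pos_cM), , drop = FALSE]
    peaks[[length(peaks) + 1]] <- kept
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' @export
print.qtl_profile <- function(x, ...) {
  cat("QTL profile:", nrow(x$profile), "positions, threshold -log10(p) =",
      x$threshold, "\n")
  if (nrow(x$peaks)) {
    cat("Peaks:\n")
    print(x$peaks)
  } else cat("No peaks above the threshold\n")
  invisible(x)
}

#' Composite interval mapping scan
#'
#' As [sim_scan()], with the expected carrier probabilities at the
#' cofactor positions (typically the peaks of a preceding simple-interval
#' scan) added as covariates. Cofactors within \code{exclusion_window} cM
#' of the test position on the same group are excluded there; collinear
#' cofactors are dropped by the rank check of the regression.
#'
#' @inheritParams sim_scan
#' @param cofactors Data frame \code{group}, \code{pos_cM} of cofactor
#'   positions; \code{NULL} (default) uses the peaks of a fresh SIM scan.
#' @param exclusion_window Half-width of the exclusion window in cM
#'   (default 10).
#' @return A \code{"qtl_profile"}; the cofactors used are attached as
#'   \code{$cofactors}.
#' @export
cim_scan <- function(map, means, cofactors = NULL, step = 5, threshold = 2,
                     exclusion_window = 10, peak_separation = 30) {
  stopifnot(inherits(map, "genetic_map"))
  if (inherits(means, "adjusted_means")) means <- means_vector(means)
  if (is.null(cofactors))
    cofactors <- sim_scan(map, means, step, threshold,
                          peak_separation)$peaks[,
      c("group", "pos_cM"), drop = FALSE]
  ids <- intersect(rownames(map$geno), names(means))
  if (length(ids) < 20)
    stop("cim_scan: fewer than 20 phenotyped offspring")
  y <- means[ids]
  aligned <- lapply(seq_along(map$groups), function(gi)
    .aligned_genotypes(map, gi)[ids, , drop = FALSE])
  cof_x <- if (nrow(cofactors)) {
    vapply(seq_len(nrow(cofactors)), function(ci) {
      gi <- cofactors$group[ci]
      conditional_genotype_probabilities(map$groups[[gi]]$cM,
                                         aligned[[gi]], cofactors$pos_cM[ci])
    }, numeric(length(ids)))
  } else NULL
  rows <- list()
  for (gi in seq_along(map$groups)) {
    g <- map$groups[[gi]]
    X <- aligned[[gi]]
    grid <- .scan_grid(g$cM, step)
    for (p in grid) {
      ex <- conditional_genotype_probabilities(g$cM, X, p)
      use <- if (is.null(cof_x)) NULL else {
        far <- !(cofactors$group == gi &
                   abs(cofactors$pos_cM - p) < exclusion_window)
        if (any(far)) cof_x[, far, drop = FALSE] else NULL
      }
      fit <- .hk_regression(y, ex, use)
      rows[[length(rows) + 1]] <- data.frame(
        group = gi, pos_cM = p, n = length(y), effect = fit$slope,
        minus_log10_p = fit$minus_log10_p)
    }
  }
  profile <- do.call(rbind, rows)
  out <- list(profile = profile,
              peaks = .profile_peaks(profile, threshold, peak_separation),
              threshold = threshold, step = step, cofactors = cofactors)
  class(out) <- "qtl_profile"
  out
}

#' Pairwise linkage disequilibrium of phase-aligned simplex markers
#'
#' \eqn{r^2} is the squared Pearson correlation of the 0/1 genotype
#' vectors over complete pairs. A decay table of \eqn{r^2} against map
#' distance accompanies the matrix when positions are supplied.
#'
#' @param geno Phase-aligned binary genotype matrix (individuals x
#'   markers).
#' @param positions Optional marker positions (cM) for the decay table.
#' @return A list: \code{r2} (matrix; zero-variance markers give
#'   \code{NA}), \code{decay} (data frame \code{dist_cM}, \code{r2} over
#'   marker pairs, or \code{NULL}).
#' @export
pairwise_ld <- function(geno, positions = NULL) {
  suppressWarnings(cc <- stats::cor(geno, use = "pairwise.complete.obs"))
  r2 <- cc^2
  decay <- NULL
  if (!is.null(positions)) {
    stopifnot(length(positions) == ncol(geno))
    ut <- upper.tri(r2)
    decay <- data.frame(
      dist_cM = abs(outer(positions, positions, "-"))[ut],
      r2 = r2[ut])
    decay <- decay[!is.na(decay$r2), , drop = FALSE]
    rownames(decay) <- NULL
  }
  list(r2 = r2, decay = decay)
}

#' Flag linkage groups spanning several physical chromosomes
#'
#' A group is flagged as a candidate translocation when at least two
#' physical chromosomes each contribute at least \code{min_fraction} of
#' its markers (a single stray marker does not trigger the flag).
#'
#' @param map A \code{"genetic_map"} whose groups carry a \code{chrom}
#'   column, or a list of data frames with \code{marker} and \code{chrom}.
#' @param min_fraction Minimum per-chromosome share (default 0.05).
#' @return Data frame \code{group}, \code{n_markers}, \code{chromosomes}
#'   (composition string), \code{flagged}.
#' @export
detect_translocation <- function(map, min_fraction = 0.05) {
  groups <- if (inherits(map, "genetic_map")) map$groups else map
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    stopifnot("chrom" %in% names(g))
    comp <- sort(table(g$chrom), decreasing = TRUE)
    share <- comp / sum(comp)
    data.frame(
      group = gi,
      n_markers = nrow(g),
      chromosomes = paste(sprintf("%s:%d", names(comp), comp),
                          collapse = ","),
      flagged = sum(share >= min_fraction) >= 2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
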