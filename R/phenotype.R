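# Two-run analysis of the replicated percentage traits:
#   run 1: REML with the test genotypes random -> variance components, H2
#   run 2: GLS with all genotypes fixed, variance structure from run 1
#          -> unshrunken adjusted means
# The unit of analysis is the plot mean over plants, logit-transformed.

#' Total cross-section damage from four readings
#'
#' The total cross-section damage is the arithmetic mean of the four corm
#' cross-section readings (upper/lower x outer/inner), each a percentage.
#' A missing reading propagates to a missing result.
#'
#' @param upper_outer,upper_inner,lower_outer,lower_inner Percentages in
#'   \code{[0, 100]} (vectors recycle as usual).
#' @return Mean of the four readings.
#' @examples
#' compute_txd(10, 20, 30, 40)  # 25
#' @export
compute_txd <- function(upper_outer, upper_inner, lower_outer, lower_inner) {
  readings <- cbind(upper_outer, upper_inner, lower_outer, lower_inner)
  if (any(readings < 0 | readings > 100, na.rm = TRUE))
    stop("compute_txd: readings must lie in [0, 100]")
  out <- rowMeans(readings)
  if (length(out) == 1L) out <- unname(out)
  out
}

# plant records -> plot means -> logit; shared by both analysis runs
.plot_logits <- function(obs, trait) {
  stopifnot(all(c("genotype_id", "genotype_role", "batch", "block",
                  "trait", "value_percent") %in% names(obs)))
  obs <- obs[obs$trait == trait & !is.na(obs$value_percent), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations for trait ", trait)
  key <- interaction(obs$genotype_id, obs$batch, obs$block, drop = TRUE)
  agg <- do.call(rbind, lapply(split(obs, key), function(d) {
    data.frame(genotype_id = d$genotype_id[1],
               genotype_role = d$genotype_role[1],
               batch = d$batch[1], block = d$block[1],
               n_plants = nrow(d),
               pct = mean(d$value_percent),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  n_plants <- max(agg$n_plants)
  delta <- 1 / (4 * n_plants * 100)
  agg$y <- logit(clamp_proportion(agg$pct / 100, delta))
  agg$rep <- interaction(agg$batch, agg$block, drop = TRUE)
  agg
}

#' REML variance components and broad-sense heritability (run 1)
#'
#' Fits the logit-scale plot means with the model
#' \code{y ~ batch + genotype_extra + (1 | genotype_test) +
#' (1 | block-within-batch)} by REML: the test genotypes (the segregating
#' offspring) are random so their variance and the entry-mean heritability
#' can be estimated, while parents and checks ("extra" genotypes) are
#' fixed. Heritability is
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / r_h)} with
#' \eqn{r_h} the harmonic mean number of plots per test genotype.
#'
#' @param obs Plant- or plot-level phenotype data frame with columns
#'   \code{genotype_id}, \code{genotype_role} (\code{"test"} for the
#'   offspring, anything else treated as extra), \code{batch},
#'   \code{block}, \code{trait}, \code{value_percent}. Plant records are
#'   averaged to plot means before the logit transform.
#' @param trait Trait name to analyse.
#' @return A list of class \code{"vc_fit"}: \code{components} (named
#'   vector \code{sigma2_genotype}, \code{sigma2_rep},
#'   \code{sigma2_residual}), \code{H2}, \code{r_h}, \code{converged},
#'   \code{data} (the plot-level analysis frame) and \code{fit} (the
#'   underlying \code{lmerMod}).
#' @export
fit_variance_components <- function(obs, trait) {
  agg <- .plot_logits(obs, trait)
  is_test <- agg$genotype_role == "test"
  if (length(unique(agg$genotype_id[is_test])) < 2)
    stop("need at least two test genotypes with replication")
  agg$geno_test <- ifelse(is_test, agg$genotype_id, "_extra_")
  agg$geno_extra <- ifelse(is_test, "_test_", agg$genotype_id)
  fixed <- "y ~ 1"
  if (length(unique(agg$batch)) > 1) fixed <- paste(fixed, "+ batch")
  if (length(unique(agg$geno_extra)) > 1)
    fixed <- paste(fixed, "+ geno_extra")
  form <- stats::as.formula(paste(fixed, "+ (1 | geno_test) + (1 | rep)"))
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12))
  fit <- lme4::lmer(form, data = agg, REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- c(
    sigma2_genotype = vc$vcov[vc$grp == "geno_test"],
    sigma2_rep = vc$vcov[vc$grp == "rep"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"])
  plots_per_geno <- table(agg$genotype_id[is_test])
  r_h <- length(plots_per_geno) / sum(1 / as.numeric(plots_per_geno))
  H2 <- comp[["sigma2_genotype"]] /
    (comp[["sigma2_genotype"]] + comp[["sigma2_residual"]] / r_h)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  out <- list(components = comp, H2 = H2, r_h = r_h, converged = conv,
              trait = trait, data = agg, fit = fit)
  class(out) <- "vc_fit"
  out
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance components (REML), trait", x$trait, "\n")
  print(round(x$components, 4))
  cat("Broad-sense heritability H2 =", round(x$H2, 3),
      "(r_h =", round(x$r_h, 2), "plots/genotype )\n")
  if (!x$converged) cat("WARNING: REML fit did not converge cleanly\n")
  invisible(x)
}

#' Unshrunken adjusted genotype means (run 2)
#'
#' Generalized-least-squares means with every genotype (test and extra)
#' fixed, weighting by the variance structure estimated in run 1
#' (\code{sigma2_rep} at the block-within-batch level plus residual).
#' Because the genotypes are fixed there is no shrinkage toward the grand
#' mean. Means are predicted at the average of the batch effects, so
#' genotypes grown in different batches are comparable through the shared
#' parents/checks connecting the batches.
#'
#' @inheritParams fit_variance_components
#' @param vc A \code{"vc_fit"} from [fit_variance_components()] (run 1).
#' @return A list of class \code{"adjusted_means"}: \code{means} (data
#'   frame \code{genotype_id}, \code{genotype_role}, \code{trait},
#'   \code{mean_logit}, \code{se}), \code{cov} (covariance matrix of the
#'   means), \code{df_residual}, and \code{components}.
#' @export
adjusted_means <- function(obs, vc, trait = vc$trait) {
  agg <- .plot_logits(obs, trait)
  agg$genotype_id <- factor(agg$genotype_id)
  agg$batch <- factor(agg$batch)
  G <- nlevels(agg$genotype_id)
  n_batch <- nlevels(agg$batch)
  X <- if (n_batch > 1) {
    stats::model.matrix(~ 0 + genotype_id + batch, data = agg)
  } else {
    stats::model.matrix(~ 0 + genotype_id, data = agg)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("adjusted_means: design not connected (rank-deficient); ",
         "genotypes and batches cannot be separated")
  Z <- stats::model.matrix(~ 0 + rep, data = agg)
  V <- vc$components[["sigma2_rep"]] * tcrossprod(Z) +
    diag(vc$components[["sigma2_residual"]], nrow(agg))
  W <- solve(V)
  XtW <- crossprod(X, W)
  info <- XtW %*% X
  beta_cov <- solve(info)
  beta <- drop(beta_cov %*% (XtW %*% agg$y))
  # predicted mean per genotype at the average batch effect
  L <- matrix(0, G, ncol(X),
              dimnames = list(levels(agg$genotype_id), colnames(X)))
  for (g in seq_len(G))
    L[g, paste0("genotype_id", levels(agg$genotype_id)[g])] <- 1
  if (n_batch > 1) {
    bcols <- grep("^batch", colnames(X), value = TRUE)
    L[, bcols] <- 1 / n_batch  # treatment coding: baseline batch effect is 0
  }
  mu <- drop(L %*% beta)
  cov_mu <- L %*% beta_cov %*% t(L)
  role <- vapply(levels(agg$genotype_id), function(g)
    agg$genotype_role[match(g, agg$genotype_id)], character(1))
  means <- data.frame(genotype_id = levels(agg$genotype_id),
                      genotype_role = unname(role),
                      trait = trait,
                      mean_logit = unname(mu),
                      se = sqrt(diag(cov_mu)),
                      stringsAsFactors = FALSE)
  rownames(means) <- NULL
  out <- list(means = means, cov = cov_mu,
              df_residual = nrow(agg) - qrX$rank,
              components = vc$components, trait = trait)
  class(out) <- "adjusted_means"
  out
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("Adjusted means (GLS, genotypes fixed), trait", x$trait, ":",
      nrow(x$means), "genotypes\n")
  print(utils::head(x$means))
  if (nrow(x$means) > 6) cat("...\n")
  invisible(x)
}

#' Extract the test-genotype means as a named vector
#'
#' Convenience accessor used by the mapping functions: adjusted logit-scale
#' means of the test (offspring) genotypes, named by genotype id.
#'
#' @param am An \code{"adjusted_means"} object.
#' @param role Roles to keep (default \code{"test"}).
#' @return Named numeric vector.
#' @export
means_vector <- function(am, role = "test") {
  stopifnot(inherits(am, "adjusted_means"))
  keep <- am$means$genotype_role %in% role
  stats::setNames(am$means$mean_logit[keep], am$means$genotype_id[keep])
}

# maximal homogeneous intervals of the descending-sorted means give the
# letter groups (insert-and-absorb); ties in the sort break by genotype id
.letter_groups <- function(mu, nonsig) {
  G <- length(mu)
  ord <- order(-mu, names(mu))
  intervals <- list()
  for (a in seq_len(G)) {
    b <- a
    # [a..b] is all-pairwise non-significant; extend while b+1 fits
    while (b < G && all(nonsig[ord[a:b], ord[b + 1]])) b <- b + 1
    intervals[[a]] <- c(a, b)
  }
  # absorb intervals contained in earlier (longer) ones
  keep <- rep(TRUE, length(intervals))
  for (i in seq_along(intervals)) {
    for (j in seq_along(intervals)) {
      if (i != j && keep[i] &&
          intervals[[j]][1] <= intervals[[i]][1] &&
          intervals[[j]][2] >= intervals[[i]][2] &&
          !identical(intervals[[j]], intervals[[i]])) keep[i] <- FALSE
    }
  }
  intervals <- unique(intervals[keep])
  symbols <- c(letters, as.vector(t(outer(letters, letters, paste0))))
  letters_out <- stats::setNames(rep("", G), names(mu))
  for (k in seq_along(intervals)) {
    span <- ord[intervals[[k]][1]:intervals[[k]][2]]
    letters_out[span] <- paste0(letters_out[span], symbols[k])
  }
  letters_out[ord]
}

#' Least-significant-difference comparison of adjusted means
#'
#' Pairwise LSDs \code{t(1 - alpha/2, df) * SED} from the covariance of the
#' adjusted means, summarised as the minimum, average and maximum over
#' pairs, plus compact letter groups: genotypes sharing a letter do not
#' differ at level \code{alpha}.
#'
#' @param am An \code{"adjusted_means"} object.
#' @param alpha Significance level (default 0.05).
#' @param genotypes Optional subset of genotype ids to compare (e.g. only
#'   parents and checks).
#' @return A list of class \code{"lsd_comparison"}: \code{groups} (data
#'   frame \code{genotype_id}, \code{mean_logit}, \code{letters}, sorted by
#'   descending mean), \code{lsd} (named vector min/average/max) and
#'   \code{alpha}.
#' @export
lsd_compare <- function(am, alpha = 0.05, genotypes = NULL) {
  stopifnot(inherits(am, "adjusted_means"))
  ids <- am$means$genotype_id
  if (!is.null(genotypes)) {
    stopifnot(all(genotypes %in% ids))
    ids <- intersect(ids, genotypes)
  }
  if (length(ids) < 2) stop("lsd_compare: need at least two genotypes")
  idx <- match(ids, am$means$genotype_id)
  mu <- stats::setNames(am$means$mean_logit[idx], ids)
  Vm <- am$cov[idx, idx, drop = FALSE]
  sed <- outer(diag(Vm), diag(Vm), "+") - 2 * Vm
  sed <- sqrt(pmax(sed, 0))
  tcrit <- stats::qt(1 - alpha / 2, am$df_residual)
  lsd_pair <- tcrit * sed
  pairs <- upper.tri(lsd_pair)
  diffs <- abs(outer(mu, mu, "-"))
  nonsig <- diffs <= lsd_pair
  diag(nonsig) <- TRUE
  letters_out <- .letter_groups(mu, nonsig)
  groups <- data.frame(genotype_id = names(letters_out),
                       mean_logit = mu[names(letters_out)],
                       letters = unname(letters_out),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  out <- list(groups = groups,
              lsd = c(min = min(lsd_pair[pairs]),
                      average = mean(lsd_pair[pairs]),
                      max = max(lsd_pair[pairs])),
              alpha = alpha)
  class(out) <- "lsd_comparison"
  out
}

#' @export
print.lsd_comparison <- function(x, ...) {
  cat("LSD comparison at alpha =", x$alpha, "\n")
  print(x$groups)
  cat(sprintf("LSD min / average / max: %.3f / %.3f / %.3f\n",
              x$lsd[["min"]], x$lsd[["average"]], x$lsd[["max"]]))
  invisible(x)
}
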