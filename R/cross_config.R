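# default parental-class frequencies for a whole-genome-duplicated
# tetraploid (mostly nulliplex/duplex/quadruplex loci) crossed to a
# heterozygous diploid; rows = tetraploid dosage class, cols = diploid class
.default_class_counts <- matrix(
  c(499, 9635, 3458,
    451,  189,   48,
    2035, 390,  206,
    243,  109,   84,
    5568, 4619, 9902),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("RRRR", "RRRA", "RRAA", "RAAA", "AAAA"),
                  c("RR", "RA", "AA"))
)

#' Default parental dosage-class frequencies
#'
#' The 15 possible (tetraploid, diploid) dosage-class combinations with the
#' default relative frequencies used by [cross_config()]. The profile
#' emulates a tetraploid that arose by whole-genome duplication of a
#' heterozygous diploid (simplex and triplex loci rare: nulliplex, duplex
#' and quadruplex classes dominate) crossed to an unrelated heterozygous
#' diploid.
#'
#' @return A 5 x 3 matrix of frequencies summing to 1; rows are tetraploid
#'   classes RRRR..AAAA (R = reference allele), columns diploid classes
#'   RR/RA/AA.
#' @export
default_class_freqs <- function() {
  .default_class_counts / sum(.default_class_counts)
}

#' Configuration of a synthetic tetraploid x diploid cross
#'
#' Collects every parameter of the synthetic 4x x 2x -> 3x mapping
#' population: genome layout, parental dosage-class frequencies, QTL
#' effects, the phenotyping design and its variance components, the
#' sequencing depth model and the per-read error rate. Defaults emulate a
#' banana-type mapping study: 138 triploid offspring, 11 chromosomes
#' carrying ~37,000 biallelic SNPs of which roughly half segregate, a
#' 4-batch x 2-block x 4-plant randomized complete block phenotyping
#' design with batches holding disjoint offspring subsets plus shared
#' parents and checks, and low variable sequencing depth.
#'
#' @param n_offspring Number of triploid offspring.
#' @param chromosomes Data frame with columns \code{name},
#'   \code{length_cM}, \code{n_markers}. Markers are placed evenly spaced.
#' @param parental_class_freqs 5 x 3 matrix of class frequencies (rows
#'   RRRR..AAAA, columns RR/RA/AA), normalised internally; must be
#'   non-negative with a positive sum.
#' @param qtls Data frame with columns \code{chrom}, \code{pos_cM},
#'   \code{beta}: additive effect on the logit scale per reference-allele
#'   copy. Each QTL is placed at the nearest marker of its chromosome and
#'   that marker's parental class is set to \code{qtl_class} so the locus
#'   segregates. \code{NULL} for no QTL.
#' @param qtl_class Length-2 integer vector \code{c(g4, g2)}: parental
#'   dosages imposed at QTL markers (default duplex x simplex, giving
#'   offspring dosages 0..3).
#' @param mu Population mean on the logit scale.
#' @param variance_components Named vector with
#'   \code{sigma2_genotype_residual} (polygenic deviation not explained by
#'   the configured QTL), \code{sigma2_rep} (block-within-batch) and
#'   \code{sigma2_plot} (plot error), all on the logit scale.
#' @param sigma2_plant Plant-within-plot variance (default 0: the four
#'   plants of a plot share the plot value).
#' @param design Named vector \code{c(n_batches, n_blocks, n_plants)}.
#' @param batch_effects Fixed batch effects on the logit scale (length
#'   \code{n_batches}).
#' @param extra_genotypes Data frame \code{id}, \code{role}
#'   (\code{"parent"} or \code{"check"}), \code{offset} (fixed deviation
#'   from \code{mu}): entries grown in every batch alongside the offspring.
#' @param depth_model Named vector \code{c(mean_depth, dispersion)} of the
#'   negative-binomial per-site, per-sample depth distribution
#'   (\code{dispersion} is the NB size parameter; depth 0 is allowed and
#'   becomes missing downstream).
#' @param epsilon Per-read sequencing error rate in \code{[0, 0.5)}.
#' @param batches_disjoint If \code{TRUE} (default) offspring are split
#'   into disjoint batch subsets, as when planting material limits each
#'   genotype to one series; if \code{FALSE} every offspring appears in
#'   every batch.
#' @param trait Trait label written to the phenotype table.
#' @param seed Integer seed; all randomness of [simulate_cross()] derives
#'   from it.
#' @return An object of class \code{"cross_config"}.
#' @export
cross_config <- function(n_offspring = 138,
                         chromosomes = data.frame(
                           name = sprintf("chr%02d", 1:11),
                           length_cM = 150,
                           n_markers = 3400),
                         parental_class_freqs = default_class_freqs(),
                         qtls = data.frame(chrom = "chr06", pos_cM = 75,
                                           beta = 0.8),
                         qtl_class = c(g4 = 2L, g2 = 1L),
                         mu = 0.25,
                         variance_components = c(
                           sigma2_genotype_residual = 0.25,
                           sigma2_rep = 0.04,
                           sigma2_plot = 0.16),
                         sigma2_plant = 0,
                         design = c(n_batches = 4, n_blocks = 2,
                                    n_plants = 4),
                         batch_effects = c(0, 0.15, -0.15, 0.05),
                         extra_genotypes = data.frame(
                           id = c("P1_tetraploid", "P2_diploid", "Check1",
                                  "Check2", "Check3", "Check4"),
                           role = c("parent", "parent", "check", "check",
                                    "check", "check"),
                           offset = c(0.03, 0.07, -0.72, -0.36, 0.47, 0.63)),
                         depth_model = c(mean_depth = 20, dispersion = 5),
                         epsilon = 0.01,
                         batches_disjoint = TRUE,
                         trait = "PD",
                         seed = 1L) {
  stopifnot(n_offspring >= 1,
            is.data.frame(chromosomes),
            all(c("name", "length_cM", "n_markers") %in% names(chromosomes)),
            all(chromosomes$n_markers >= 1),
            all(chromosomes$length_cM >= 0))
  pf <- as.matrix(parental_class_freqs)
  if (!identical(dim(pf), c(5L, 3L)) || any(pf < 0) || sum(pf) <= 0)
    stop("cross_config: parental_class_freqs must be a non-negative 5 x 3 matrix with positive sum")
  pf <- pf / sum(pf)
  dimnames(pf) <- dimnames(.default_class_counts)
  vc <- variance_components
  stopifnot(all(c("sigma2_genotype_residual", "sigma2_rep", "sigma2_plot")
                %in% names(vc)),
            all(vc >= 0), sigma2_plant >= 0,
            epsilon >= 0, epsilon < 0.5,
            all(design >= 1),
            length(batch_effects) == design[["n_batches"]])
  if (!is.null(qtls)) {
    stopifnot(all(c("chrom", "pos_cM", "beta") %in% names(qtls)),
              all(qtls$chrom %in% chromosomes$name))
    stopifnot(qtl_class[["g4"]] %in% 0:4, qtl_class[["g2"]] %in% 0:2)
  }
  cfg <- list(
    n_offspring = as.integer(n_offspring),
    chromosomes = chromosomes,
    parental_class_freqs = pf,
    qtls = qtls,
    qtl_class = qtl_class,
    mu = mu,
    variance_components = vc,
    sigma2_plant = sigma2_plant,
    design = design,
    batch_effects = batch_effects,
    extra_genotypes = extra_genotypes,
    depth_model = depth_model,
    epsilon = epsilon,
    batches_disjoint = isTRUE(batches_disjoint),
    trait = trait,
    seed = as.integer(seed)
  )
  class(cfg) <- "cross_config"
  cfg
}

#' @export
print.cross_config <- function(x, ...) {
  cat("Synthetic 4x x 2x cross configuration\n")
  cat("  offspring:", x$n_offspring, "  chromosomes:",
      nrow(x$chromosomes), " (", sum(x$chromosomes$n_markers), "markers )\n")
  cat("  QTL:", if (is.null(x$qtls)) "none" else
    paste(sprintf("%s@%gcM beta=%g", x$qtls$chrom, x$qtls$pos_cM,
                  x$qtls$beta), collapse = ", "), "\n")
  cat("  depth: NB(mean =", x$depth_model[["mean_depth"]], ", size =",
      x$depth_model[["dispersion"]], "), epsilon =", x$epsilon, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
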