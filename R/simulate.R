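# Synthetic 4x x 2x -> 3x cross generator.
#
# Meiosis model: the four tetraploid homologs pair at random into two
# bivalents each meiosis; each bivalent runs an independent Haldane
# (no-interference) crossover process and contributes one chromatid to the
# gamete. No double reduction. At an unlinked marker this yields the
# hypergeometric gamete law C(g4,k) C(4-g4,2-k) / C(4,2).

# sample one recombinant chromatid per row from a bivalent of homologs
# (indices a, b into the homolog allele matrix H, h x m), using Bernoulli
# interval swaps with the Haldane recombination fraction
.sample_chromatids <- function(H, a, b, pos_cM) {
  n <- length(a)
  m <- length(pos_cM)
  start <- stats::rbinom(n, 1, 0.5)
  if (m > 1) {
    r <- haldane_inverse(diff(pos_cM))
    swaps <- matrix(stats::rbinom(n * (m - 1), 1, rep(r, each = n)),
                    nrow = n)
    state <- (start + cbind(0, .row_cumsum(swaps))) %% 2
  } else {
    state <- matrix(start, ncol = 1)
  }
  HA <- H[a, , drop = FALSE]
  HB <- H[b, , drop = FALSE]
  HA * (1 - state) + HB * state
}

#' Simulate a diploid gamete from a tetraploid parent
#'
#' Random bivalent pairing of the four homologs, an independent Haldane
#' crossover process within each bivalent, and one chromatid sampled per
#' bivalent; no double reduction. At an unlinked marker with parental
#' dosage \code{g4} the gamete dosage follows the hypergeometric law
#' \eqn{C(g_4,k) C(4-g_4,2-k) / C(4,2)}.
#'
#' @param homologs 4 x m 0/1 matrix of reference-allele indicators, one row
#'   per homolog.
#' @param pos_cM Marker positions in cM, strictly increasing.
#' @param n Number of gametes to draw.
#' @return n x m integer matrix of gamete dosages (0..2 reference alleles).
#' @export
simulate_gamete_tetraploid <- function(homologs, pos_cM, n = 1) {
  stopifnot(nrow(homologs) == 4, ncol(homologs) == length(pos_cM),
            !is.unsorted(pos_cM))
  # the three ways to partition homologs {1,2,3,4} into two bivalents
  p_a1 <- c(1L, 1L, 1L); p_b1 <- c(2L, 3L, 4L)
  p_a2 <- c(3L, 2L, 2L); p_b2 <- c(4L, 4L, 3L)
  pairing <- sample.int(3L, n, replace = TRUE)
  c1 <- .sample_chromatids(homologs, p_a1[pairing], p_b1[pairing], pos_cM)
  c2 <- .sample_chromatids(homologs, p_a2[pairing], p_b2[pairing], pos_cM)
  g <- c1 + c2
  storage.mode(g) <- "integer"
  g
}

#' Simulate a haploid gamete from a diploid parent
#'
#' Standard meiosis with a Haldane (no interference) crossover process
#' between the two homologs.
#'
#' @param homologs 2 x m 0/1 matrix of reference-allele indicators.
#' @inheritParams simulate_gamete_tetraploid
#' @return n x m integer 0/1 matrix of gamete alleles.
#' @export
simulate_gamete_diploid <- function(homologs, pos_cM, n = 1) {
  stopifnot(nrow(homologs) == 2, ncol(homologs) == length(pos_cM),
            !is.unsorted(pos_cM))
  g <- .sample_chromatids(homologs, rep(1L, n), rep(2L, n), pos_cM)
  storage.mode(g) <- "integer"
  g
}

#' Simulate parental dosage vectors
#'
#' Draws the (tetraploid, diploid) dosage-class combination of every marker
#' from \code{config$parental_class_freqs} and assigns reference alleles to
#' random homologs consistent with the drawn dosages. QTL markers (nearest
#' marker to each configured QTL position) are forced to
#' \code{config$qtl_class} so that the locus segregates.
#'
#' @param config A [cross_config()] object.
#' @return A list: \code{map} (data frame with \code{marker}, \code{chrom},
#'   \code{pos_cM}, \code{pos_bp}, \code{g4}, \code{g2}, \code{class},
#'   \code{status}, \code{is_qtl}), \code{H4} and \code{H2} (homolog
#'   allele matrices, 4 x m and 2 x m), and \code{qtls} (the configured QTL
#'   with their marker ids).
#' @export
simulate_parent_genotypes <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  chroms <- config$chromosomes
  maps <- vector("list", nrow(chroms))
  for (ci in seq_len(nrow(chroms))) {
    m <- chroms$n_markers[ci]
    L <- chroms$length_cM[ci]
    pos <- if (m == 1) L / 2 else seq(0, L, length.out = m)
    maps[[ci]] <- data.frame(
      chrom = chroms$name[ci], pos_cM = pos,
      pos_bp = as.integer(round(pos * 2e4)) + seq_len(m),  # 1 cM ~ 20 kb
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  m_tot <- nrow(map)
  map$marker <- sprintf("%s_%d", map$chrom, map$pos_bp)

  freqs <- config$parental_class_freqs
  # class index 1..15 in row-major (g4 class) x (g2 class) order
  cls_idx <- sample.int(15L, m_tot, replace = TRUE, prob = as.vector(t(freqs)))
  g4_of_row <- c(4L, 3L, 2L, 1L, 0L)   # RRRR..AAAA
  g2_of_col <- c(2L, 1L, 0L)           # RR, RA, AA
  map$g4 <- g4_of_row[(cls_idx - 1L) %/% 3L + 1L]
  map$g2 <- g2_of_col[(cls_idx - 1L) %% 3L + 1L]

  qtls <- config$qtls
  if (!is.null(qtls) && nrow(qtls) > 0) {
    qtls$marker <- NA_character_
    for (qi in seq_len(nrow(qtls))) {
      on_chr <- which(map$chrom == qtls$chrom[qi])
      j <- on_chr[which.min(abs(map$pos_cM[on_chr] - qtls$pos_cM[qi]))]
      map$g4[j] <- as.integer(config$qtl_class[["g4"]])
      map$g2[j] <- as.integer(config$qtl_class[["g2"]])
      qtls$marker[qi] <- map$marker[j]
    }
  }
  cls <- classify_parental_combination(map$g4, map$g2)
  map$class <- cls$class
  map$status <- cls$status
  map$is_qtl <- if (is.null(qtls)) FALSE else map$marker %in% qtls$marker
  bases <- c("A", "C", "G", "T")
  map$ref_base <- sample(bases, m_tot, replace = TRUE)
  map$alt_base <- vapply(map$ref_base,
                         function(b) sample(setdiff(bases, b), 1L),
                         character(1))

  # random homolog assignment of the reference alleles
  H4 <- matrix(0L, 4, m_tot)
  H2 <- matrix(0L, 2, m_tot)
  for (g in 1:4) {
    j <- which(map$g4 == g)
    if (length(j)) {
      pick <- vapply(j, function(x) {
        v <- integer(4); v[sample.int(4L, g)] <- 1L; v
      }, integer(4))
      H4[, j] <- pick
    }
  }
  j <- which(map$g2 == 1L)
  if (length(j)) H2[cbind(sample.int(2L, length(j), replace = TRUE), j)] <- 1L
  H2[, map$g2 == 2L] <- 1L

  rownames(H4) <- paste0("P1_hom", 1:4)
  rownames(H2) <- paste0("P2_hom", 1:2)
  colnames(H4) <- colnames(H2) <- map$marker
  list(map = map[, c("marker", "chrom", "pos_cM", "pos_bp", "ref_base",
                     "alt_base", "g4", "g2", "class", "status", "is_qtl")],
       H4 = H4, H2 = H2, qtls = qtls)
}

# offspring dosages chromosome by chromosome; returns n x m integer matrix
.simulate_offspring <- function(parents, n) {
  map <- parents$map
  out <- matrix(NA_integer_, n, nrow(map))
  for (chr in unique(map$chrom)) {
    j <- which(map$chrom == chr)
    g_tet <- simulate_gamete_tetraploid(parents$H4[, j, drop = FALSE],
                                        map$pos_cM[j], n)
    g_dip <- simulate_gamete_diploid(parents$H2[, j, drop = FALSE],
                                     map$pos_cM[j], n)
    out[, j] <- g_tet + g_dip
  }
  colnames(out) <- map$marker
  rownames(out) <- sprintf("F1_%03d", seq_len(n))
  out
}

#' Simulate plot-level phenotypes for a cross
#'
#' The latent plot value on the logit scale is
#' \code{mu + sum_q beta_q * dosage_q + genotype deviation + batch effect +
#' block(batch) effect + plot error}; the observed percentage is
#' \code{100 * inv_logit(latent)}. Parents and checks are grown in every
#' batch with fixed offsets from \code{mu}; offspring occupy disjoint batch
#' subsets unless \code{config$batches_disjoint} is \code{FALSE}. Each plot
#' holds \code{n_plants} plant records sharing the plot value (plus
#' optional plant noise \code{sigma2_plant}).
#'
#' @param truth A truth set from [simulate_cross()] (or a list with
#'   \code{genetic_values}, a named vector per offspring).
#' @param config The [cross_config()] object.
#' @return Data frame with columns \code{genotype_id}, \code{genotype_role}
#'   (\code{test}/\code{parent}/\code{check}), \code{batch}, \code{block},
#'   \code{plant}, \code{trait}, \code{value_percent}. The realised latent
#'   genotype values (QTL plus polygenic deviation, per offspring) are
#'   attached as attribute \code{"latent_genotype"} for validation against
#'   downstream estimates.
#' @export
simulate_phenotypes <- function(truth, config) {
  vc <- config$variance_components
  des <- config$design
  n_b <- as.integer(des[["n_batches"]])
  n_r <- as.integer(des[["n_blocks"]])
  n_p <- as.integer(des[["n_plants"]])
  ids <- names(truth$genetic_values)
  g_dev <- stats::rnorm(length(ids), 0,
                        sqrt(vc[["sigma2_genotype_residual"]]))
  latent_geno <- config$mu + truth$genetic_values + g_dev
  extras <- config$extra_genotypes
  batch_of <- if (config$batches_disjoint) {
    split(seq_along(ids), rep(seq_len(n_b), length.out = length(ids)))
  } else {
    stats::setNames(rep(list(seq_along(ids)), n_b), seq_len(n_b))
  }
  block_eff <- matrix(stats::rnorm(n_b * n_r, 0, sqrt(vc[["sigma2_rep"]])),
                      n_b, n_r)
  rows <- vector("list", n_b)
  for (b in seq_len(n_b)) {
    test_i <- batch_of[[b]]
    gid <- c(ids[test_i], extras$id)
    role <- c(rep("test", length(test_i)), extras$role)
    lat_g <- c(latent_geno[test_i], config$mu + extras$offset)
    per_block <- vector("list", n_r)
    for (r in seq_len(n_r)) {
      plot_lat <- lat_g + config$batch_effects[b] + block_eff[b, r] +
        stats::rnorm(length(lat_g), 0, sqrt(vc[["sigma2_plot"]]))
      plant_lat <- rep(plot_lat, each = n_p)
      if (config$sigma2_plant > 0)
        plant_lat <- plant_lat + stats::rnorm(length(plant_lat), 0,
                                              sqrt(config$sigma2_plant))
      per_block[[r]] <- data.frame(
        genotype_id = rep(gid, each = n_p),
        genotype_role = rep(role, each = n_p),
        batch = sprintf("B%d", b),
        block = sprintf("R%d", r),
        plant = rep(seq_len(n_p), length(gid)),
        trait = config$trait,
        value_percent = 100 * inv_logit(plant_lat),
        stringsAsFactors = FALSE)
    }
    rows[[b]] <- do.call(rbind, per_block)
  }
  out <- do.call(rbind, rows)
  # total latent genotype value (QTL + polygenic deviation), for validation
  attr(out, "latent_genotype") <- stats::setNames(
    truth$genetic_values + g_dev, ids)
  out
}

#' Simulate allelic read counts for a cross
#'
#' Per site and sample, the total depth is drawn from the configured
#' negative-binomial distribution (depth 0 allowed, treated as missing
#' downstream) and the reference-read count from
#' \code{Binomial(depth, p_g)} with
#' \eqn{p_g = (g/ploidy)(1-\epsilon) + (1-g/ploidy)\epsilon}. The two
#' parents (ploidy 4 and 2) are genotyped alongside the triploid offspring.
#'
#' @param truth Truth set carrying \code{map} (with parental dosages
#'   \code{g4}, \code{g2}) and \code{offspring_dosage} (n x m matrix).
#' @param config The [cross_config()] object.
#' @return A list of class \code{"read_counts"}: \code{sites} (map data
#'   frame), \code{ref} and \code{alt} (sites x samples integer matrices;
#'   columns P1, P2, then offspring), \code{ploidy} (named vector per
#'   sample).
#' @export
simulate_read_counts <- function(truth, config) {
  map <- truth$map
  dos <- truth$offspring_dosage
  m <- nrow(map)
  eps <- config$epsilon
  mu_d <- config$depth_model[["mean_depth"]]
  size_d <- config$depth_model[["dispersion"]]
  # genotype matrix sites x samples, with per-sample ploidy
  G <- cbind(P1 = map$g4, P2 = map$g2, t(dos))
  ploidy <- c(4L, 2L, rep(3L, nrow(dos)))
  names(ploidy) <- colnames(G) <- c("P1", "P2", rownames(dos))
  depth <- matrix(stats::rnbinom(m * ncol(G), mu = mu_d, size = size_d),
                  m, ncol(G))
  p_ref <- sweep(G, 2, ploidy, "/") * (1 - eps) +
    (1 - sweep(G, 2, ploidy, "/")) * eps
  ref <- matrix(stats::rbinom(length(depth), as.vector(depth),
                              as.vector(p_ref)), m, ncol(G))
  alt <- depth - ref
  dimnames(ref) <- dimnames(alt) <- list(map$marker, colnames(G))
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  out <- list(sites = map, ref = ref, alt = alt, ploidy = ploidy)
  class(out) <- "read_counts"
  out
}

#' @export
print.read_counts <- function(x, ...) {
  cat("Read-count matrix:", nrow(x$ref), "sites x", ncol(x$ref),
      "samples\n")
  d <- x$ref + x$alt
  cat("  mean depth:", round(mean(d), 2), "  zero-depth cells:",
      round(100 * mean(d == 0), 2), "%\n")
  invisible(x)
}

#' Simulate a complete synthetic cross
#'
#' Runs the full generator: parental genotypes, offspring meioses,
#' phenotypes and read counts. All randomness derives from
#' \code{config$seed} through per-stage substreams, so a given
#' configuration always regenerates the identical data set.
#'
#' @param config A [cross_config()] object.
#' @return A list of class \code{"synthetic_cross"}: \code{truth} (map
#'   with parental dosages, homolog matrices, offspring dosage matrix,
#'   genetic values, QTL table, config), \code{phenotypes} (plot-level
#'   data frame) and \code{counts} (a \code{read_counts} object).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4L)

  set.seed(stage_seeds[1])
  parents <- simulate_parent_genotypes(config)

  set.seed(stage_seeds[2])
  dos <- .simulate_offspring(parents, config$n_offspring)

  qtls <- parents$qtls
  gv <- numeric(nrow(dos))
  if (!is.null(qtls) && nrow(qtls) > 0) {
    for (qi in seq_len(nrow(qtls)))
      gv <- gv + qtls$beta[qi] * dos[, qtls$marker[qi]]
  }
  names(gv) <- rownames(dos)

  truth <- list(map = parents$map, H4 = parents$H4, H2 = parents$H2,
                offspring_dosage = dos, genetic_values = gv, qtls = qtls,
                config = config)

  set.seed(stage_seeds[3])
  phenotypes <- simulate_phenotypes(truth, config)

  set.seed(stage_seeds[4])
  counts <- simulate_read_counts(truth, config)

  out <- list(truth = truth, phenotypes = phenotypes, counts = counts)
  class(out) <- "synthetic_cross"
  out
}

#' @export
print.synthetic_cross <- function(x, ...) {
  cat("Synthetic 4x x 2x cross:", nrow(x$truth$offspring_dosage),
      "offspring,", nrow(x$truth$map), "markers\n")
  print(x$counts)
  invisible(x)
}

#' Write the outputs of a synthetic cross to disk
#'
#' Writes a VCF 4.2 file with per-sample AD (ref,alt) allelic depths, the
#' plot-level phenotype CSV, and a truth JSON recording the seed, the
#' configuration, the QTL and the parental dosages, from which the data set
#' can be regenerated exactly.
#'
#' @param cross A \code{"synthetic_cross"} object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written
#'   (\code{vcf}, \code{phenotypes}, \code{truth}).
#' @export
write_cross_outputs <- function(cross, dir) {
  stopifnot(inherits(cross, "synthetic_cross"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_vcf_counts(cross$counts, paths[["vcf"]])
  utils::write.csv(cross$phenotypes, paths[["phenotypes"]],
                   row.names = FALSE)
  cfg <- cross$truth$config
  truth_rec <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("chromosomes", "extra_genotypes",
                                       "qtls", "parental_class_freqs"))],
    chromosomes = cfg$chromosomes,
    parental_class_freqs = as.data.frame(as.table(cfg$parental_class_freqs)),
    extra_genotypes = cfg$extra_genotypes,
    qtls = cross$truth$qtls,
    parental_dosages = cross$truth$map[, c("marker", "g4", "g2")],
    genetic_values = as.list(cross$truth$genetic_values)
  )
  jsonlite::write_json(truth_rec, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
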