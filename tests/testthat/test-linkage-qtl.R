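# shared fixture: a two-chromosome all-simplex cross with one QTL on the
# first chromosome, used by the map- and scan-level tests
simplex_cross <- function(seed, n = 200, beta = NULL, qtl_pos = 50) {
  pf <- matrix(0, 5, 3, dimnames = dimnames(triqtl::default_class_freqs()))
  pf["AAAA", "RA"] <- 1
  qtls <- if (is.null(beta)) NULL else
    data.frame(chrom = "c1", pos_cM = qtl_pos, beta = beta)
  cfg <- triqtl::cross_config(
    n_offspring = n,
    chromosomes = data.frame(name = c("c1", "c2"), length_cM = 100,
                             n_markers = 50),
    parental_class_freqs = pf, qtls = qtls,
    qtl_class = c(g4 = 0L, g2 = 1L), seed = seed)
  triqtl::simulate_cross(cfg)
}

test_that("simplex markers are selected and recoded by carrier status", {
  map <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    g4 = c(0L, 4L, 3L, 0L), g2 = c(1L, 1L, 2L, 0L))
  off <- matrix(c(0L, 1L, 2L, 3L,
                  2L, 3L, 2L, 3L,
                  1L, 2L, 1L, 2L,
                  0L, 0L, 1L, 1L), 4, 4,
                dimnames = list(paste0("i", 1:4), map$marker))
  sm <- select_simplex_markers(map, off)
  # the RRRA x RR and AAAA x AA markers are excluded
  expect_identical(colnames(sm$geno), c("m1", "m2"))
  # AAAA x RA: dosage is carrier status of R; impossible dosages missing
  expect_equal(unname(sm$geno[, "m1"]), c(0L, 1L, NA, NA))
  # RRRR x RA: dosage 3 = non-carrier of A -> 0, dosage 2 -> 1
  expect_equal(unname(sm$geno[, "m2"]), c(1L, 0L, 1L, 0L))
})

test_that("the 1:1 chi-square test matches hand-computed values", {
  r1 <- chi_square_1to1(50, 50)
  expect_equal(r1$chi2, 0)
  expect_equal(r1$p, 1)
  r2 <- chi_square_1to1(70, 30)
  expect_equal(r2$chi2, 16)
  expect_equal(r2$p, 6.3e-5, tolerance = 0.01)
  r3 <- chi_square_1to1(60, 40)
  expect_equal(r3$chi2, 4)
  expect_gt(r3$p, 0.001)  # retained at alpha = 0.001
})

test_that("the distortion filter removes about alpha of truly 1:1 markers", {
  set.seed(101)
  n <- 138; m <- 5000
  G <- matrix(rbinom(n * m, 1, 0.5), n, m,
              dimnames = list(NULL, sprintf("m%04d", 1:m)))
  sm <- structure(list(geno = G,
                       info = data.frame(marker = colnames(G),
                                         g4 = 0L, g2 = 1L)),
                  class = "simplex_markers")
  filt <- filter_simplex_markers(sm, max_missing = 1, alpha = 0.001)
  removed <- attr(filt, "removed")[["distortion"]]
  band <- qbinom(c(0.025, 0.975), m, 0.001)
  expect_gte(removed, band[1] - 1)
  expect_lte(removed, band[2])
})

test_that("two-point recombination estimates count mismatches", {
  v <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  same <- pairwise_recombination(v, v)
  expect_equal(same$r, 0)
  expect_identical(same$phase, "coupling")
  comp <- pairwise_recombination(v, 1L - v)
  expect_equal(comp$r, 0)
  expect_identical(comp$phase, "repulsion")
  w <- v; w[1:2] <- 1L - w[1:2]
  two <- pairwise_recombination(v, w)
  expect_equal(two$r, 0.2)
  expect_gt(same$lod, two$lod)
  none <- pairwise_recombination(c(NA, NA), c(0L, 1L))
  expect_true(is.na(none$r))
})

test_that("grouping is a transitive closure and respects the size floor", {
  r <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(r) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.1
  r["b", "c"] <- r["c", "b"] <- 0.1
  r["a", "c"] <- r["c", "a"] <- 0.25  # linked only through b
  g <- group_markers(r, min_size = 3)
  expect_length(g, 1)
  expect_setequal(g[[1]], c("a", "b", "c"))
  expect_equal(attr(g, "n_dropped"), 1)  # the singleton d

  # nothing linked: no group survives the floor
  r2 <- matrix(0.5, 12, 12)
  diag(r2) <- 0
  expect_length(group_markers(r2, min_size = 10), 0)
})

test_that("ordering recovers additive configurations and is reversal-symmetric", {
  r <- matrix(0.5, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(r) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.05
  r["b", "c"] <- r["c", "b"] <- 0.05
  r["a", "c"] <- r["c", "a"] <- 0.10
  ord <- order_markers(c("a", "b", "c"), r)
  expect_true(identical(ord, c("a", "b", "c")) ||
                identical(ord, c("c", "b", "a")))
  obj <- function(o) sum(r[cbind(o[-3], o[-1])])
  expect_equal(obj(ord), obj(rev(ord)))
  # physical order short-circuit
  phys <- c(a = 300, b = 100, c = 200)
  expect_identical(order_markers(c("a", "b", "c"), r, phys,
                                 use_physical_order = TRUE),
                   c("b", "c", "a"))
})

test_that("the Haldane map function and its inverse are consistent", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.2), 25.54, tolerance = 1e-4)
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(haldane_inverse(haldane(r)), r, tolerance = 1e-12)
  expect_error(haldane(0.5), "0.5")
  expect_error(haldane_inverse(-1), "negative")
})

test_that("conditional carrier probabilities obey observation, symmetry and limits", {
  pos <- c(0, 10, 20)
  g <- rbind(c(1L, NA, 0L))
  # at an observed marker the observation decides
  expect_equal(conditional_genotype_probabilities(pos, rbind(c(1L, 0L, 1L)),
                                                  10), 0)
  # symmetric flanks (1, 0) at equal distance: exactly 0.5
  expect_equal(conditional_genotype_probabilities(pos, g, 10), 0.5)
  # both flanks 1 and tight linkage: probability near 1
  g2 <- rbind(c(1L, NA, 1L))
  expect_gt(conditional_genotype_probabilities(pos, g2, 10), 0.95)
  # no information: prior 0.5
  g3 <- rbind(c(NA_integer_, NA_integer_, NA_integer_))
  expect_equal(conditional_genotype_probabilities(pos, g3, 10), 0.5)
  # single flank: Haldane transition from the observed side
  g4 <- rbind(c(1L, NA, NA))
  expect_equal(conditional_genotype_probabilities(pos, g4, 20),
               1 - haldane_inverse(20))
})

test_that("simulated chromosomes are recovered as groups with consistent map lengths", {
  set.seed(102)
  lengths_ok <- 0
  for (s in 1:5) {
    cr <- simplex_cross(seed = 200 + s)
    sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
    mp <- build_linkage_map(sm)
    expect_length(mp$groups, 2)
    for (g in mp$groups) {
      expect_length(unique(g$chrom), 1)   # no cross-chromosome mixing
      if (abs(max(g$cM) - 100) <= 25) lengths_ok <- lengths_ok + 1
    }
  }
  expect_gte(lengths_ok, 8)  # 80% of the 10 chromosome maps
})

test_that("SIM at a fully observed marker equals the single-marker regression", {
  cr <- simplex_cross(seed = 210, beta = 0.7)
  sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
  mp <- build_linkage_map(sm)
  set.seed(210)
  y <- stats::setNames(
    0.7 * cr$truth$offspring_dosage[, cr$truth$qtls$marker] +
      rnorm(nrow(mp$geno), 0, 0.6), rownames(mp$geno))
  pr <- sim_scan(mp, y)
  for (gi in seq_along(mp$groups)) {
    g <- mp$groups[[gi]]
    for (j in c(1, 17, nrow(g))) {
      x <- mp$geno[names(y), g$marker[j]]
      if (g$phase[j] == "repulsion") x <- 1L - x
      mr <- regress_marker(y, x)
      pv <- pr$profile[pr$profile$group == gi &
                         abs(pr$profile$pos_cM - g$cM[j]) < 1e-9, ]
      expect_equal(pv$minus_log10_p, mr$minus_log10_p, tolerance = 1e-8)
      expect_equal(pv$effect, mr$slope, tolerance = 1e-8)
    }
  }
  # the profile grid is the 5 cM lattice plus the marker positions
  grid1 <- pr$profile$pos_cM[pr$profile$group == 1]
  expect_true(all(seq(0, max(mp$groups[[1]]$cM), by = 5) %in% grid1))
  expect_true(all(mp$groups[[1]]$cM %in% grid1))
})

test_that("a simulated QTL is detected near its true position by SIM", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cr <- simplex_cross(seed = 300 + s, beta = 0.7)
    sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
    mp <- build_linkage_map(sm)
    am_y <- attr(cr$phenotypes, "latent_genotype")  # noise-free means proxy
    set.seed(300 + s)
    y <- am_y + rnorm(length(am_y), 0, 0.4)
    pr <- sim_scan(mp, y)
    if (nrow(pr$peaks) == 0) next
    # locate the QTL marker's mapped position
    qmk <- cr$truth$qtls$marker
    gi <- which(vapply(mp$groups, function(g) qmk %in% g$marker,
                       logical(1)))
    if (length(gi) != 1) next
    qpos <- mp$groups[[gi]]$cM[mp$groups[[gi]]$marker == qmk]
    best <- pr$peaks[which.max(pr$peaks$minus_log10_p), ]
    if (best$group == gi && abs(best$pos_cM - qpos) <= 10)
      hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("CIM reduces to SIM without cofactors and conditions on them otherwise", {
  cr <- simplex_cross(seed = 400, beta = 0.7)
  sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
  mp <- build_linkage_map(sm)
  set.seed(400)
  y <- stats::setNames(
    0.7 * cr$truth$offspring_dosage[, cr$truth$qtls$marker] +
      rnorm(nrow(mp$geno), 0, 0.6), rownames(mp$geno))
  pr_sim <- sim_scan(mp, y)
  pr_cim0 <- cim_scan(mp, y,
                      cofactors = data.frame(group = integer(),
                                             pos_cM = numeric()))
  expect_equal(pr_cim0$profile$minus_log10_p, pr_sim$profile$minus_log10_p)

  # a cofactor at the QTL kills the signal there (exclusion window aside)
  qmk <- cr$truth$qtls$marker
  gi <- which(vapply(mp$groups, function(g) qmk %in% g$marker, logical(1)))
  qpos <- mp$groups[[gi]]$cM[mp$groups[[gi]]$marker == qmk]
  pr_cim <- cim_scan(mp, y, cofactors = data.frame(group = gi,
                                                   pos_cM = qpos),
                     exclusion_window = 0.5)
  far_other <- pr_cim$profile$group != gi
  near_q <- pr_cim$profile$group == gi &
    abs(pr_cim$profile$pos_cM - qpos) > 2 &
    abs(pr_cim$profile$pos_cM - qpos) < 30
  sim_near <- pr_sim$profile$minus_log10_p[near_q]
  cim_near <- pr_cim$profile$minus_log10_p[near_q]
  expect_lt(mean(cim_near), mean(sim_near))  # signal absorbed by cofactor
})

test_that("linked QTL are separated at least as often by CIM as by SIM", {
  pf <- matrix(0, 5, 3, dimnames = dimnames(default_class_freqs()))
  pf["AAAA", "RA"] <- 1
  sim_both <- 0; cim_both <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    cfg <- cross_config(
      n_offspring = 200,
      chromosomes = data.frame(name = "c1", length_cM = 120,
                               n_markers = 41),
      parental_class_freqs = pf,
      qtls = data.frame(chrom = "c1", pos_cM = c(30, 90),
                        beta = c(0.7, 0.7)),
      qtl_class = c(g4 = 0L, g2 = 1L), seed = 500 + s)
    cr <- simulate_cross(cfg)
    sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
    mp <- build_linkage_map(sm)
    lat <- attr(cr$phenotypes, "latent_genotype")
    set.seed(500 + s)
    y <- lat + rnorm(length(lat), 0, 0.4)
    qpos <- vapply(cr$truth$qtls$marker, function(mk) {
      g <- mp$groups[[1]]
      if (mk %in% g$marker) g$cM[g$marker == mk] else NA_real_
    }, numeric(1))
    if (any(is.na(qpos)) || length(mp$groups) != 1) next
    found_both <- function(peaks) {
      nrow(peaks) > 0 &&
        all(vapply(qpos, function(q) any(abs(peaks$pos_cM - q) <= 15),
                   logical(1)))
    }
    if (found_both(sim_scan(mp, y, peak_separation = 25)$peaks))
      sim_both <- sim_both + 1
    if (found_both(cim_scan(mp, y, peak_separation = 25)$peaks))
      cim_both <- cim_both + 1
  }
  expect_gte(cim_both, sim_both)
  expect_gt(cim_both, 0)
})

test_that("LD is 1 on the diagonal, near 1/n between unlinked markers, and decays with distance", {
  set.seed(103)
  n <- 200
  G <- matrix(rbinom(n * 40, 1, 0.5), n, 40)  # independent markers
  ld0 <- pairwise_ld(G)
  expect_equal(unname(diag(ld0$r2)), rep(1, 40))
  ut <- upper.tri(ld0$r2)
  expect_lt(abs(mean(ld0$r2[ut]) - 1 / n), 2e-3)

  # linked chromosome: r2 falls off with map distance
  cr <- simplex_cross(seed = 104)
  sm <- select_simplex_markers(cr$truth$map, cr$truth$offspring_dosage)
  mp <- build_linkage_map(sm)
  X <- mp$geno[, mp$groups[[1]]$marker]
  flip <- mp$groups[[1]]$phase == "repulsion"
  X[, flip] <- 1L - X[, flip]
  ld <- pairwise_ld(X, positions = mp$groups[[1]]$cM)
  expect_lt(cor(ld$decay$dist_cM, ld$decay$r2, method = "spearman"), -0.5)

  # zero-variance marker yields missing entries
  G2 <- cbind(G[, 1:3], const = 0L)
  ldz <- pairwise_ld(G2)
  expect_true(all(is.na(ldz$r2["const", 1:3])))
})

test_that("groups spanning two physical chromosomes are flagged as translocations", {
  pure <- list(data.frame(marker = paste0("m", 1:20), chrom = "chr1"),
               data.frame(marker = paste0("n", 1:20), chrom = "chr2"))
  rep_pure <- detect_translocation(pure)
  expect_false(any(rep_pure$flagged))

  fused <- list(data.frame(marker = paste0("m", 1:30),
                           chrom = rep(c("chr3", "chr8"), c(18, 12))))
  expect_true(detect_translocation(fused)$flagged)

  # one stray marker below the 5% floor does not trigger the flag
  stray <- list(data.frame(marker = paste0("m", 1:41),
                           chrom = c(rep("chr1", 40), "chr9")))
  expect_false(detect_translocation(stray)$flagged)
})
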