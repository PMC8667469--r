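test_that("parental class frequencies follow the configured distribution", {
  # degenerate configuration: all mass on AAAA x RA
  pf <- matrix(0, 5, 3, dimnames = dimnames(default_class_freqs()))
  pf["AAAA", "RA"] <- 1
  cfg <- cross_config(chromosomes = data.frame(name = "c1", length_cM = 50,
                                               n_markers = 200),
                      parental_class_freqs = pf, qtls = NULL, seed = 1)
  set.seed(1)
  par <- simulate_parent_genotypes(cfg)
  expect_true(all(par$map$class == "AAAA x RA"))
  expect_true(all(par$map$g4 == 0L & par$map$g2 == 1L))

  # default frequencies at many markers: the RRRR x RA class converges to
  # its configured share (~25.7%)
  cfg2 <- cross_config(chromosomes = data.frame(name = "c1",
                                                length_cM = 100,
                                                n_markers = 20000),
                       qtls = NULL, seed = 2)
  set.seed(2)
  par2 <- simulate_parent_genotypes(cfg2)
  share <- mean(par2$map$class == "RRRR x RA")
  expect_equal(share, default_class_freqs()["RRRR", "RA"], tolerance = 0.05)

  # invalid frequency matrix is rejected
  expect_error(cross_config(parental_class_freqs = matrix(-1, 5, 3)),
               "parental_class_freqs")
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_cross_config(seed = 99)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$truth$offspring_dosage, b$truth$offspring_dosage)
  expect_identical(a$counts$ref, b$counts$ref)
  expect_identical(a$phenotypes$value_percent, b$phenotypes$value_percent)
})

test_that("tetraploid gametes follow the hypergeometric law", {
  set.seed(31)
  # g4 = 2: dosage {0,1,2} with probabilities {1/6, 2/3, 1/6}
  H <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  g <- simulate_gamete_tetraploid(H, 10, n = 20000)
  emp <- tabulate(g + 1L, 3) / 20000
  expect_equal(emp, c(1 / 6, 2 / 3, 1 / 6), tolerance = 0.03)

  # g4 = 4: always dosage 2
  H4 <- matrix(1L, 4, 1)
  expect_true(all(simulate_gamete_tetraploid(H4, 0, n = 500) == 2L))

  # markers at identical positions are fully co-inherited
  Hm <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 0L))
  g2 <- simulate_gamete_tetraploid(Hm, c(25, 25), n = 2000)
  expect_true(all(g2[, 1] == g2[, 2]))
})

test_that("diploid gametes recombine at the Haldane rate", {
  set.seed(32)
  H <- rbind(c(1L, 1L), c(0L, 0L))  # coupling-phase pair
  d <- 20
  n <- 10000
  g <- simulate_gamete_diploid(H, c(0, d), n = n)
  r_obs <- mean(g[, 1] != g[, 2])
  r_exp <- haldane_inverse(d)
  mc_se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(r_obs - r_exp), 3 * mc_se)

  # g2 = 1: reference transmitted half the time
  H1 <- matrix(c(1L, 0L), 2, 1)
  expect_equal(mean(simulate_gamete_diploid(H1, 0, n = 10000)), 0.5,
               tolerance = 0.02)
})

test_that("offspring dosages match the enumerated gamete-law convolution", {
  set.seed(33)
  for (cls in list(c(2L, 1L), c(3L, 2L), c(1L, 0L), c(4L, 1L))) {
    H4 <- matrix(c(rep(1L, cls[1]), rep(0L, 4 - cls[1])), 4, 1)
    H2 <- matrix(c(rep(1L, cls[2]), rep(0L, 2 - cls[2])), 2, 1)
    n <- 10000
    dos <- simulate_gamete_tetraploid(H4, 0, n) +
      simulate_gamete_diploid(H2, 0, n)
    expected <- oracle_offspring_distribution(cls[1], cls[2])
    obs <- tabulate(dos + 1L, 4)
    keep <- expected > 0
    expect_gt(stats::chisq.test(obs[keep], p = expected[keep])$p.value,
              1e-4)
    # the analytical law agrees with the enumeration oracle exactly
    expect_equal(expected_offspring_distribution(cls[1], cls[2]), expected)
  }
  # ploidy invariant: dosage never exceeds 3
  cr <- simulate_cross(small_cross_config(seed = 5))
  expect_true(all(cr$truth$offspring_dosage >= 0L &
                    cr$truth$offspring_dosage <= 3L))
})

test_that("AAAA x RA markers segregate 1:1 across seeds", {
  set.seed(34)
  H4 <- matrix(0L, 4, 1)
  H2 <- matrix(c(1L, 0L), 2, 1)
  ok <- vapply(1:100, function(s) {
    dos <- simulate_gamete_tetraploid(H4, 0, 138) +
      simulate_gamete_diploid(H2, 0, 138)
    expect_true(all(dos %in% 0:1))
    chi_square_1to1(sum(dos == 0), sum(dos == 1))$p >= 0.001
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("phenotypes are additive on the logit scale and noise-free when configured so", {
  cfg <- cross_config(
    chromosomes = data.frame(name = "c1", length_cM = 20, n_markers = 5),
    qtls = data.frame(chrom = "c1", pos_cM = 10, beta = 1),
    variance_components = c(sigma2_genotype_residual = 0, sigma2_rep = 0,
                            sigma2_plot = 0),
    batch_effects = rep(0, 4), mu = 0.25, seed = 8)
  cr <- simulate_cross(cfg)
  ph <- cr$phenotypes[cr$phenotypes$genotype_role == "test", ]
  lat <- logit(ph$value_percent / 100)
  qm <- cr$truth$qtls$marker
  dos_of <- unname(cr$truth$offspring_dosage[ph$genotype_id, qm])
  # every observation equals mu + beta * dosage exactly
  expect_equal(lat, 0.25 + 1 * dos_of, tolerance = 1e-12)
  # dosage classes are separated by exactly 1 on the logit scale
  classes <- sort(unique(round(lat, 9)))
  expect_true(all(abs(diff(classes) - 1) < 1e-9))

  # fully null configuration: constant observations at 100 * inv_logit(mu)
  cfg0 <- cross_config(
    chromosomes = data.frame(name = "c1", length_cM = 20, n_markers = 5),
    qtls = NULL,
    variance_components = c(sigma2_genotype_residual = 0, sigma2_rep = 0,
                            sigma2_plot = 0),
    batch_effects = rep(0, 4), mu = 0.25, seed = 9)
  cr0 <- simulate_cross(cfg0)
  ph0 <- cr0$phenotypes[cr0$phenotypes$genotype_role == "test", ]
  expect_equal(ph0$value_percent,
               rep(100 * inv_logit(0.25), nrow(ph0)), tolerance = 1e-12)
})

test_that("read counts follow the depth and error model", {
  # quadruplex reference with no error: never an alternative read
  cfg <- cross_config(chromosomes = data.frame(name = "c1", length_cM = 10,
                                               n_markers = 30),
                      parental_class_freqs = local({
                        pf <- matrix(0, 5, 3)
                        pf[1, 1] <- 1  # RRRR x RR: all offspring RRR
                        pf
                      }),
                      qtls = NULL, epsilon = 0, seed = 21)
  cr <- simulate_cross(cfg)
  off <- setdiff(colnames(cr$counts$ref), c("P1", "P2"))
  expect_true(all(cr$counts$alt[, off] == 0L))

  # depth 0 cells yield missing frequencies
  fr <- allele_frequency_matrix(cr$counts)
  dp <- depth_matrix(cr$counts)
  expect_true(all(is.na(fr[dp == 0])))
  expect_true(all(!is.na(fr[dp > 0])))

  # simplex offspring (dosage 1 of 3): pooled reference fraction near 1/3
  set.seed(22)
  n_reads <- stats::rbinom(3000, size = 1, prob = 1 / 3)
  truth <- list(
    map = data.frame(marker = "m1", chrom = "c1", pos_cM = 5, pos_bp = 1,
                     ref_base = "A", alt_base = "C", g4 = 0L, g2 = 1L,
                     class = "AAAA x RA", status = "segregates_P2_only",
                     is_qtl = FALSE),
    offspring_dosage = matrix(1L, 100, 1,
                              dimnames = list(sprintf("F1_%03d", 1:100),
                                              "m1")))
  cfg2 <- cross_config(chromosomes = data.frame(name = "c1",
                                                length_cM = 10,
                                                n_markers = 1),
                       qtls = NULL, epsilon = 0,
                       depth_model = c(mean_depth = 30, dispersion = 5),
                       seed = 23)
  counts <- simulate_read_counts(truth, cfg2)
  off <- setdiff(colnames(counts$ref), c("P1", "P2"))
  tot_ref <- sum(counts$ref[, off])
  tot <- sum(counts$ref[, off] + counts$alt[, off])
  se <- sqrt((1 / 3) * (2 / 3) / tot)
  expect_lt(abs(tot_ref / tot - 1 / 3), 4 * se)
})

test_that("written outputs round-trip exactly", {
  cfg <- small_cross_config(seed = 44)
  cr <- simulate_cross(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cross_outputs(cr, dir)
  expect_true(all(file.exists(paths)))

  # VCF declares 4.2 and has a column per sample
  head1 <- readLines(paths[["vcf"]], n = 1)
  expect_identical(head1, "##fileformat=VCFv4.2")
  hdr <- grep("^#CHROM", readLines(paths[["vcf"]]), value = TRUE)
  expect_length(strsplit(hdr, "\t")[[1]], 9 + ncol(cr$counts$ref))

  # allelic depths survive the round trip bit-for-bit
  rt <- read_vcf_counts(paths[["vcf"]])
  expect_identical(unname(rt$ref), unname(cr$counts$ref))
  expect_identical(unname(rt$alt), unname(cr$counts$alt))
  expect_identical(rt$sites$marker, cr$counts$sites$marker)

  # phenotypes round-trip and the truth file records the seed
  ph <- utils::read.csv(paths[["phenotypes"]])
  expect_equal(nrow(ph), nrow(cr$phenotypes))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 44)
  # regeneration from the recorded seed reproduces the data
  again <- simulate_cross(cfg)
  expect_identical(again$counts$ref, cr$counts$ref)
})
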