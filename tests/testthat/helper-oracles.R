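# Independent oracles used by the tests. These deliberately use brute-force
# enumeration or textbook closed forms, not the package's own code paths.

# offspring dosage distribution by exhaustive enumeration of every
# (unordered homolog pair from the tetraploid) x (diploid homolog) gamete
# combination, with explicit allele assignments
oracle_offspring_distribution <- function(g4, g2) {
  h4 <- c(rep(1L, g4), rep(0L, 4 - g4))
  h2 <- c(rep(1L, g2), rep(0L, 2 - g2))
  p <- setNames(numeric(4), 0:3)
  pairs <- utils::combn(4, 2)
  for (k in seq_len(ncol(pairs))) {
    tet <- sum(h4[pairs[, k]])
    for (j in 1:2) {
      d <- tet + h2[j]
      p[as.character(d)] <- p[as.character(d)] + (1 / 6) * (1 / 2)
    }
  }
  p
}

# naive closest-gene scan: loop over every gene on the chromosome
oracle_closest_gene <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  best_d <- Inf
  best_id <- character(0)
  for (i in seq_len(nrow(g))) {
    d <- if (pos >= g$start[i] && pos <= g$end[i]) 0 else
      min(abs(pos - g$start[i]), abs(pos - g$end[i]))
    if (d < best_d) {
      best_d <- d
      best_id <- g$gene_id[i]
    } else if (d == best_d) {
      best_id <- c(best_id, g$gene_id[i])
    }
  }
  list(distance = best_d, gene_id = sort(best_id))
}

# random synthetic gene table for property tests
random_gene_table <- function(n_genes, chroms = c("chr1", "chr2"),
                              span = 1e6) {
  starts <- sample.int(span, n_genes, replace = TRUE)
  widths <- sample.int(5000, n_genes, replace = TRUE)
  data.frame(chrom = sample(chroms, n_genes, replace = TRUE),
             start = starts, end = starts + widths,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             gene_id = sprintf("G%04d", seq_len(n_genes)),
             description = NA_character_, stringsAsFactors = FALSE)
}

# plot-level phenotype frame on a balanced single-batch design from
# logit-scale values (one batch so batch terms drop out of the model)
balanced_obs <- function(y_matrix) {
  g <- nrow(y_matrix); r <- ncol(y_matrix)
  data.frame(
    genotype_id = rep(sprintf("G%03d", seq_len(g)), r),
    genotype_role = "test",
    batch = "B1",
    block = rep(sprintf("R%d", seq_len(r)), each = g),
    plant = 1L,
    trait = "PD",
    value_percent = 100 * triqtl::inv_logit(as.vector(y_matrix)),
    stringsAsFactors = FALSE)
}

# small cross configuration shared by several tests
small_cross_config <- function(seed, ...) {
  triqtl::cross_config(
    chromosomes = data.frame(name = c("chr01", "chr02"),
                             length_cM = 60, n_markers = 40),
    qtls = NULL, seed = seed, ...)
}
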