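#' Write a read-count matrix as a VCF 4.2 file with AD
#'
#' Emits one biallelic record per site with the per-sample FORMAT field
#' \code{AD} (comma-separated reference and alternative depths) and
#' \code{DP}. Genotypes themselves are left unassigned (\code{GT} is
#' \code{./.}): downstream analysis works from the allelic depths.
#'
#' @param counts A \code{"read_counts"} object (see
#'   [simulate_read_counts()]), with \code{sites} providing \code{chrom},
#'   \code{pos_bp}, \code{ref_base}, \code{alt_base}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_vcf_counts <- function(counts, path) {
  stopifnot(inherits(counts, "read_counts"))
  s <- counts$sites
  samples <- colnames(counts$ref)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triqtl_synthetic_cross",
    sprintf("##contig=<ID=%s>", unique(s$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  dp <- counts$ref + counts$alt
  cells <- matrix(paste0("./.:", counts$ref, ",", counts$alt, ":", dp),
                  nrow = nrow(counts$ref))
  body <- paste(s$chrom, s$pos_bp, s$marker, s$ref_base, s$alt_base, ".",
                "PASS", ".", "GT:AD:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read allelic depths from a VCF with AD
#'
#' Parses a VCF (plain or gzipped) via \pkg{vcfR} and extracts the
#' per-sample reference/alternative allelic depths of biallelic SNP
#' records. Multiallelic sites are dropped with a message.
#'
#' @param path VCF file path.
#' @param ploidy Optional named vector of per-sample ploidies attached to
#'   the result (defaults to \code{NA}).
#' @return A \code{"read_counts"} object: \code{sites} data frame
#'   (\code{marker}, \code{chrom}, \code{pos_bp}, \code{ref_base},
#'   \code{alt_base}), \code{ref}/\code{alt} integer matrices (sites x
#'   samples) and \code{ploidy}.
#' @export
read_vcf_counts <- function(path, ploidy = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message("read_vcf_counts: dropping ", sum(multi), " multiallelic sites")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- vcfR::masplit(ad, record = 1, sort = FALSE)
  alt <- vcfR::masplit(ad, record = 2, sort = FALSE)
  ref[is.na(ref)] <- 0
  alt[is.na(alt)] <- 0
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, "_", fix$POS), fix$ID)
  sites <- data.frame(marker = id, chrom = fix$CHROM,
                      pos_bp = as.integer(fix$POS),
                      ref_base = fix$REF, alt_base = fix$ALT,
                      stringsAsFactors = FALSE)
  rownames(ref) <- rownames(alt) <- sites$marker
  if (is.null(ploidy))
    ploidy <- stats::setNames(rep(NA_integer_, ncol(ref)), colnames(ref))
  out <- list(sites = sites, ref = ref, alt = alt, ploidy = ploidy)
  class(out) <- "read_counts"
  out
}

#' Per-sample allele-frequency matrix from read counts
#'
#' @param counts A \code{"read_counts"} object.
#' @return Numeric matrix (samples x sites) of reference-allele
#'   frequencies, \code{NA} where depth is 0.
#' @export
allele_frequency_matrix <- function(counts) {
  stopifnot(inherits(counts, "read_counts"))
  t(allele_frequency(counts$ref, counts$alt))
}

#' Per-sample depth matrix from read counts
#'
#' @param counts A \code{"read_counts"} object.
#' @return Integer matrix (samples x sites) of total depths.
#' @export
depth_matrix <- function(counts) {
  stopifnot(inherits(counts, "read_counts"))
  t(counts$ref + counts$alt)
}
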