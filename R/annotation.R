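# Closest-gene annotation of significant SNPs from a GFF3 gene annotation,
# mirroring a closestBed-style query: the nearest gene on either strand,
# distance 0 when the SNP lies inside the gene.

#' Parse gene features from a GFF3 file
#'
#' Extracts records of type \code{"gene"}; coordinates are kept 1-based
#' inclusive as in GFF3 (an internal 0-based half-open view is used for
#' interval arithmetic). The gene identifier is taken from the \code{ID}
#' attribute (falling back to \code{Name}), the description from
#' \code{description}, \code{Note} or \code{product} when present.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to extract (default \code{"gene"}).
#' @return Data frame: \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}, \code{gene_id}, \code{description}.
#' @export
parse_gff3 <- function(path, feature_type = "gene") {
  gff <- ape::read.gff(path)
  genes <- gff[gff$type == feature_type, , drop = FALSE]
  if (nrow(genes) == 0) stop("parse_gff3: no '", feature_type,
                             "' features in ", path)
  get_attr <- function(attr, keys) {
    for (k in keys) {
      m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", k, "=([^;]+)"),
                                    attr))
      v <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
                  character(1))
      if (any(!is.na(v))) return(v)
    }
    rep(NA_character_, length(attr))
  }
  ids <- get_attr(genes$attributes, c("ID", "Name", "gene_id"))
  desc <- get_attr(genes$attributes, c("description", "Note", "product"))
  out <- data.frame(chrom = as.character(genes$seqid),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    gene_id = ids, description = desc,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("parse_gff3: start > end")
  if (anyDuplicated(out$gene_id))
    warning("parse_gff3: duplicated gene ids")
  rownames(out) <- NULL
  out
}

#' Export gene features as BED intervals
#'
#' Converts 1-based inclusive gene coordinates to the 0-based half-open
#' BED convention, preserving interval length.
#'
#' @param genes Data frame from [parse_gff3()].
#' @param path Optional output path; when given, a 6-column BED file is
#'   written.
#' @return Data frame \code{chrom}, \code{start} (0-based), \code{end},
#'   \code{name}, \code{score}, \code{strand}, invisibly when written.
#' @export
genes_to_bed <- function(genes, path = NULL) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id, score = 0L,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Distance bin of a SNP-gene distance
#'
#' \code{0} maps to \code{within_gene}; \code{(0, 1000)} to
#' \code{lt_1kb}; \code{[1000, 4500]} to \code{1kb_to_4.5kb}; beyond to
#' \code{gt_4.5kb}. The boundary at exactly 1 kb falls in the second bin
#' ("less than 1 kb" is strict).
#'
#' @param distance Non-negative distance(s) in bp.
#' @return Character vector of bin labels.
#' @export
bin_distance <- function(distance) {
  if (any(distance < 0, na.rm = TRUE)) stop("bin_distance: negative distance")
  ifelse(distance == 0, "within_gene",
  ifelse(distance < 1000, "lt_1kb",
  ifelse(distance <= 4500, "1kb_to_4.5kb", "gt_4.5kb")))
}

#' Closest gene to a SNP position
#'
#' Finds the gene minimising the gap (in bp) between the SNP position and
#' the gene interval, on either strand; the distance is 0 when the SNP
#' lies within the gene. Exact ties are all returned, ordered by gene id.
#'
#' @param chrom,pos SNP chromosome and 1-based position (scalars).
#' @param genes Gene table from [parse_gff3()].
#' @return Data frame of the closest gene(s): \code{gene_id},
#'   \code{distance}, \code{bin}, \code{description}; zero rows (with a
#'   warning) when the chromosome has no genes.
#' @export
closest_feature <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) {
    warning("closest_feature: no genes on ", chrom)
    return(data.frame(gene_id = character(), distance = numeric(),
                      bin = character(), description = character()))
  }
  d <- pmax(g$start - pos, pos - g$end, 0)
  dmin <- min(d)
  hit <- g[d == dmin, , drop = FALSE]
  hit <- hit[order(hit$gene_id), , drop = FALSE]
  data.frame(gene_id = hit$gene_id, distance = dmin,
             bin = bin_distance(dmin), description = hit$description,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate SNPs with their closest gene
#'
#' Runs [closest_feature()] for every SNP and summarises the distance
#' bins. When a SNP ties between several genes, the lexicographically
#' first gene id is reported in the main table (all ties remain available
#' through [closest_feature()]).
#'
#' @param snps Data frame with columns \code{marker} (or \code{snp}),
#'   \code{chrom}, \code{pos_bp} (or \code{pos}).
#' @param genes Gene table from [parse_gff3()].
#' @return A list of class \code{"annotation_hits"}: \code{hits} (data
#'   frame \code{marker}, \code{chrom}, \code{pos_bp}, \code{gene_id},
#'   \code{distance}, \code{bin}, \code{description}) and
#'   \code{bin_counts} (named vector over the four bins).
#' @export
annotate_snps <- function(snps, genes) {
  marker <- snps[[intersect(c("marker", "snp"), names(snps))[1]]]
  pos <- snps[[intersect(c("pos_bp", "pos"), names(snps))[1]]]
  rows <- lapply(seq_along(marker), function(i) {
    hit <- closest_feature(snps$chrom[i], pos[i], genes)
    if (nrow(hit) == 0)
      return(data.frame(marker = marker[i], chrom = snps$chrom[i],
                        pos_bp = pos[i], gene_id = NA_character_,
                        distance = NA_real_, bin = NA_character_,
                        description = NA_character_))
    data.frame(marker = marker[i], chrom = snps$chrom[i], pos_bp = pos[i],
               gene_id = hit$gene_id[1], distance = hit$distance[1],
               bin = hit$bin[1], description = hit$description[1],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  bins <- c("within_gene", "lt_1kb", "1kb_to_4.5kb", "gt_4.5kb")
  bin_counts <- vapply(bins, function(b) sum(hits$bin == b, na.rm = TRUE),
                       integer(1))
  out <- list(hits = hits, bin_counts = bin_counts)
  class(out) <- "annotation_hits"
  out
}

#' @export
print.annotation_hits <- function(x, ...) {
  cat("Closest-gene annotation:", nrow(x$hits), "SNPs\n")
  print(x$bin_counts)
  invisible(x)
}
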