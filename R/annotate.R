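#' Positional candidate genes for significant regions
#'
#' Reports every gene whose interval, extended by `flank_bp` upstream
#' and downstream (strand-ignored, boundary inclusive), intersects a
#' significant region.  All coordinates are 1-based closed; the 100 kb
#' default flank reflects typical linkage-disequilibrium extent in
#' cattle.
#'
#' @param regions `data.frame` from [call_regions()] (`chrom`,
#'   `start_bp`, `end_bp`).
#' @param genes `data.frame` from [read_gene_annotation()] (`chrom`,
#'   `start`, `end`, `gene_id`, `strand`).
#' @param flank_bp Flanking distance in bp (default 100000).
#' @return `data.frame`: `region`, `chrom`, `region_start`,
#'   `region_end`, `gene_id`, `overlap_type` (`contained`,
#'   `overlapping` or `within_flank`) and `distance_bp` (0 for
#'   overlaps).
#' @export
annotate_regions <- function(regions, genes, flank_bp = 100000) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(regions)),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  empty <- data.frame(region = integer(0), chrom = character(0),
                      region_start = integer(0), region_end = integer(0),
                      gene_id = character(0), overlap_type = character(0),
                      distance_bp = integer(0))
  if (!nrow(regions)) return(empty)
  rch <- as.character(regions$chrom)
  gch <- as.character(genes$chrom)
  unmatched <- setdiff(unique(rch), unique(gch))
  if (length(unmatched)) {
    stop("region chromosome(s) absent from the gene annotation: ",
         paste(unmatched, collapse = ", "))
  }
  rgr <- GenomicRanges::GRanges(rch,
           IRanges::IRanges(regions$start_bp, regions$end_bp))
  ggr <- GenomicRanges::GRanges(gch,
           IRanges::IRanges(genes$start, genes$end))
  ## intersect [gene_start - flank, gene_end + flank] with the region in
  ## 1-based closed coordinates: a coordinate gap of exactly flank_bp
  ## still counts (GRanges gap convention is off by one from that)
  hits <- GenomicRanges::findOverlaps(rgr, ggr, maxgap = flank_bp - 1L)
  if (!length(hits)) return(empty)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ov <- genes$start[gi] <= regions$end_bp[ri] &
    genes$end[gi] >= regions$start_bp[ri]
  dist <- ifelse(ov, 0L,
                 pmax(regions$start_bp[ri] - genes$end[gi],
                      genes$start[gi] - regions$end_bp[ri]))
  within <- genes$start[gi] >= regions$start_bp[ri] &
    genes$end[gi] <= regions$end_bp[ri]
  type <- ifelse(within, "contained",
                 ifelse(ov, "overlapping", "within_flank"))
  out <- data.frame(region = ri, chrom = rch[ri],
                    region_start = regions$start_bp[ri],
                    region_end = regions$end_bp[ri],
                    gene_id = genes$gene_id[gi],
                    overlap_type = type, distance_bp = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$region, out$distance_bp, out$gene_id), ]
  rownames(out) <- NULL
  out
}
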