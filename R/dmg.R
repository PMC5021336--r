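# DMR-to-gene annotation: gene body +/- 2 kb regions, DMG direction
# assignment, cross-comparison overlap and body/flank partition summaries.

#' Gene body and strand-aware 2 kb flank intervals
#'
#' For a plus-strand gene, upstream = `[start - flank, start - 1]` and
#' downstream = `[end + 1, end + flank]`; mirrored for minus-strand genes.
#' Flanks are clipped to `[1, chrom_length]`; a flank fully off the
#' chromosome is empty (NA bounds).
#'
#' @param genes Gene-model data.frame.
#' @param chrom_lengths Named chromosome lengths in bp; genes on chromosomes
#'   absent from it are clipped only at 1.
#' @param flank Flank length in bp (default 2,000).
#' @return Data.frame: gene_id, chrom, strand, body_start, body_end,
#'   up_start, up_end, down_start, down_end (NA for empty flanks).
#' @export
gene_regions <- function(genes, chrom_lengths = NULL, flank = 2000L) {
  plus <- genes$strand != "-"
  up_start <- ifelse(plus, genes$start - flank, genes$end + 1L)
  up_end <- ifelse(plus, genes$start - 1L, genes$end + flank)
  down_start <- ifelse(plus, genes$end + 1L, genes$start - flank)
  down_end <- ifelse(plus, genes$end + flank, genes$start - 1L)
  clip <- function(s, e) {
    s <- pmax(s, 1L)
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[genes$chrom]
      e <- ifelse(is.na(len), e, pmin(e, len))
    }
    bad <- s > e
    s[bad] <- NA_integer_; e[bad] <- NA_integer_
    list(s = as.integer(s), e = as.integer(e))
  }
  up <- clip(up_start, up_end)
  down <- clip(down_start, down_end)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, body_start = genes$start,
             body_end = genes$end, up_start = up$s, up_end = up$e,
             down_start = down$s, down_end = down$e,
             stringsAsFactors = FALSE)
}

# Overlap hits (>= 1 bp) between DMRs and one class of gene regions.
region_hits <- function(dmrs, regions, start_col, end_col, region) {
  ok <- !is.na(regions[[start_col]])
  if (!any(ok) || !nrow(dmrs)) {
    return(data.frame(gene_id = character(), dmr_idx = integer(),
                      region = character(), stringsAsFactors = FALSE))
  }
  reg <- regions[ok, , drop = FALSE]
  q <- GenomicRanges::GRanges(dmrs$chrom,
                              IRanges::IRanges(dmrs$start, dmrs$end))
  s <- GenomicRanges::GRanges(reg$chrom,
                              IRanges::IRanges(reg[[start_col]],
                                               reg[[end_col]]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  data.frame(gene_id = reg$gene_id[S4Vectors::subjectHits(hits)],
             dmr_idx = S4Vectors::queryHits(hits),
             region = rep_len(region, length(hits)),
             stringsAsFactors = FALSE)
}

#' Annotate differentially methylated genes
#'
#' A gene is a DMG when at least one DMR intersects (by >= 1 bp) its body
#' or its 2 kb upstream or downstream flank. A DMR may hit several genes
#' and a gene may collect several DMRs; every (gene, DMR, region) hit is
#' recorded. Each DMG is assigned one exclusive direction (see
#' [direction_assign()]). Only features of class "gene" become DMGs.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param genes Gene-model data.frame.
#' @param chrom_lengths Optional named chromosome lengths for flank
#'   clipping.
#' @param flank Flank length in bp (default 2,000).
#' @return List: `dmgs` (gene_id, direction, best_p_adj, in_body, in_up,
#'   in_down, n_dmrs) and `hits` (gene_id, dmr_idx, region, direction,
#'   p_adj, span).
#' @export
annotate_dmgs <- function(dmrs, genes, chrom_lengths = NULL, flank = 2000L) {
  genes <- genes[genes$feature_class == "gene", , drop = FALSE]
  regions <- gene_regions(genes, chrom_lengths, flank)
  hits <- rbind(
    region_hits(dmrs, regions, "body_start", "body_end", "body"),
    region_hits(dmrs, regions, "up_start", "up_end", "upstream"),
    region_hits(dmrs, regions, "down_start", "down_end", "downstream"))
  empty <- data.frame(gene_id = character(), direction = character(),
                      best_p_adj = numeric(), in_body = logical(),
                      in_up = logical(), in_down = logical(),
                      n_dmrs = integer(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(list(dmgs = empty, hits = hits))
  hits$direction <- dmrs$direction[hits$dmr_idx]
  hits$p_adj <- dmrs$best_p_adj[hits$dmr_idx]
  hits$span <- dmrs$length[hits$dmr_idx]
  dmgs <- do.call(rbind, lapply(split(hits, hits$gene_id), function(h) {
    data.frame(gene_id = h$gene_id[1],
               direction = direction_assign(h),
               best_p_adj = min(h$p_adj),
               in_body = any(h$region == "body"),
               in_up = any(h$region == "upstream"),
               in_down = any(h$region == "downstream"),
               n_dmrs = length(unique(h$dmr_idx)),
               stringsAsFactors = FALSE)
  }))
  dmgs <- dmgs[order(dmgs$gene_id), , drop = FALSE]
  rownames(dmgs) <- NULL
  list(dmgs = dmgs, hits = hits)
}

#' Assign one exclusive direction to a DMG
#'
#' If every member DMR shares a direction, that direction is used.
#' Otherwise the direction of the member with the smallest adjusted p wins;
#' ties go to the direction with the larger total span, then to hyper.
#'
#' @param hits Data.frame of member DMR hits with columns `direction`,
#'   `p_adj`, `span` (one row per hit; duplicate DMRs are collapsed).
#' @return "hyper" or "hypo".
#' @export
direction_assign <- function(hits) {
  if ("dmr_idx" %in% names(hits))
    hits <- hits[!duplicated(hits$dmr_idx), , drop = FALSE]
  dirs <- unique(hits$direction)
  if (length(dirs) == 1L) return(dirs)
  best <- min(hits$p_adj)
  cand <- unique(hits$direction[hits$p_adj == best])
  if (length(cand) == 1L) return(cand)
  spans <- vapply(cand, function(d)
    sum(hits$span[hits$direction == d]), numeric(1))
  cand <- cand[spans == max(spans)]
  if (length(cand) == 1L) return(cand)
  "hyper"
}

#' Cross-comparison DMG overlap summary
#'
#' Counts genes shared between two DMG sets for every direction
#' combination (hyper/hyper, hypo/hypo, hyper/hypo and hypo/hyper), with
#' the percentage computed against the first set's direction class
#' (the named reference).
#'
#' @param dmgs_1,dmgs_2 DMG data.frames from [annotate_dmgs()].
#' @param names Labels for the two comparisons.
#' @return Data.frame: direction_1, direction_2, n_overlap, n_reference,
#'   percent, reference.
#' @export
overlap_analysis <- function(dmgs_1, dmgs_2, names = c("set1", "set2")) {
  combos <- expand.grid(direction_1 = c("hyper", "hypo"),
                        direction_2 = c("hyper", "hypo"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    g1 <- dmgs_1$gene_id[dmgs_1$direction == combos$direction_1[i]]
    g2 <- dmgs_2$gene_id[dmgs_2$direction == combos$direction_2[i]]
    n_ref <- length(g1)
    n_ov <- length(intersect(g1, g2))
    data.frame(direction_1 = combos$direction_1[i],
               direction_2 = combos$direction_2[i],
               n_overlap = n_ov, n_reference = n_ref,
               percent = if (n_ref > 0) 100 * n_ov / n_ref else NA_real_,
               reference = paste0(names[1], ":", combos$direction_1[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Body/flank partition of DMGs
#'
#' Places every DMG in exactly one of the seven cells of the Venn partition
#' over {body, upstream, downstream}; cell counts sum to the number of
#' DMGs.
#'
#' @param dmgs DMG data.frame from [annotate_dmgs()].
#' @return Data.frame: bucket, n.
#' @export
region_partition <- function(dmgs) {
  buckets <- c("body_only", "upstream_only", "downstream_only",
               "body_upstream", "body_downstream", "upstream_downstream",
               "body_upstream_downstream")
  key <- paste0(ifelse(dmgs$in_body, "B", ""),
                ifelse(dmgs$in_up, "U", ""),
                ifelse(dmgs$in_down, "D", ""))
  map <- c(B = "body_only", U = "upstream_only", D = "downstream_only",
           BU = "body_upstream", BD = "body_downstream",
           UD = "upstream_downstream", BUD = "body_upstream_downstream")
  counts <- table(factor(map[key], levels = buckets))
  data.frame(bucket = buckets, n = as.integer(counts),
             stringsAsFactors = FALSE)
}
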