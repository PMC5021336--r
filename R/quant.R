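# Site-level methylation, context summaries, density profiles,
# conversion-rate QC.

#' Per-site methylation level under the fourfold-coverage rule
#'
#' The methylation level of a cytosine is the number of reads covering it
#' as methylated divided by the total effective reads at the site, and is
#' defined only for sites with at least `min_coverage` (default 4) reads.
#'
#' @param n_meth,n_unmeth Methylated / unmethylated read counts (vectors).
#' @param min_coverage Minimum total reads for the level to be defined.
#' @return Data.frame with columns `level` (NA when not qualifying) and
#'   `qualifies`.
#' @export
site_level <- function(n_meth, n_unmeth, min_coverage = 4L) {
  if (any(n_meth < 0 | n_unmeth < 0, na.rm = TRUE))
    stop_methmap("negative read counts")
  total <- n_meth + n_unmeth
  qualifies <- total >= min_coverage
  level <- ifelse(qualifies, n_meth / total, NA_real_)
  data.frame(level = level, qualifies = qualifies)
}

#' Context-resolved weighted methylation summary
#'
#' Per context (CG, CHG, CHH) and over all contexts ("Total"), the weighted
#' methylation percent over qualifying sites:
#' `100 * sum(n_meth) / sum(n_meth + n_unmeth)`, i.e. the pooled-count
#' level rather than a mean of per-site levels. Optionally restricted to
#' sites inside a feature set.
#'
#' @param sample A [methylome_sample()].
#' @param features Optional gene-model data.frame; only sites inside these
#'   intervals (any strand) are summarised.
#' @param feature_class Optional class filter on `features`
#'   ("gene" or "transposable_element").
#' @param min_coverage Qualifying-coverage floor (default 4).
#' @return Data.frame: context, percent (NA when no qualifying sites, with
#'   `defined` FALSE), n_sites (qualifying site count).
#' @export
context_summary <- function(sample, features = NULL, feature_class = NULL,
                            min_coverage = 4L) {
  rec <- as.data.frame(sample)
  if (!is.null(features)) {
    if (!is.null(feature_class))
      features <- features[features$feature_class %in% feature_class, ,
                           drop = FALSE]
    rec <- rec[sites_in_features(rec, features), , drop = FALSE]
  }
  total <- rec$n_meth + rec$n_unmeth
  qual <- total >= min_coverage
  one <- function(idx) {
    n <- sum(idx)
    tot <- sum(total[idx])
    data.frame(
      percent = if (n == 0 || tot == 0) NA_real_
                else 100 * sum(rec$n_meth[idx]) / tot,
      n_sites = n, defined = n > 0 && tot > 0)
  }
  rows <- lapply(CONTEXTS, function(ctx) one(qual & rec$context == ctx))
  rows <- c(rows, list(one(qual)))
  out <- cbind(data.frame(context = c(CONTEXTS, "Total"),
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# Logical index of records falling in any feature interval.
sites_in_features <- function(rec, features) {
  if (!nrow(features) || !nrow(rec)) return(rep(FALSE, nrow(rec)))
  q <- GenomicRanges::GRanges(rec$chrom,
                              IRanges::IRanges(rec$pos, rec$pos))
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start, features$end))
  suppressWarnings(IRanges::overlapsAny(q, s))
}

#' Chromosome-scale normalized methylation density profile
#'
#' Bins the genome (default 100 kb) and, per context, sums the site-level
#' methylation mass of qualifying sites in each bin (raw density). Each
#' context's profile is normalized so that its highest-density bin is 100%;
#' a context with no methylation anywhere stays at 0 throughout.
#'
#' @param sample A [methylome_sample()].
#' @param bin_size Bin width in bp (default 100,000).
#' @param min_coverage Qualifying-coverage floor.
#' @return Data.frame: chrom, bin_start, bin_end (1-based inclusive),
#'   context, raw, normalized.
#' @export
density_profile <- function(sample, bin_size = 100000L, min_coverage = 4L) {
  if (bin_size <= 0) stop_methmap("bin_size must be > 0")
  rec <- as.data.frame(sample)
  sl <- site_level(rec$n_meth, rec$n_unmeth, min_coverage)
  rec <- rec[sl$qualifies, , drop = FALSE]
  lev <- sl$level[sl$qualifies]
  if (!nrow(rec)) {
    return(data.frame(chrom = character(), bin_start = integer(),
                      bin_end = integer(), context = character(),
                      raw = numeric(), normalized = numeric()))
  }
  bin <- (rec$pos - 1L) %/% bin_size
  out <- do.call(rbind, lapply(split(seq_len(nrow(rec)),
                                     list(rec$chrom, bin, rec$context),
                                     drop = TRUE), function(idx) {
    data.frame(chrom = rec$chrom[idx[1]],
               bin_start = bin[idx[1]] * bin_size + 1L,
               bin_end = (bin[idx[1]] + 1L) * bin_size,
               context = rec$context[idx[1]],
               raw = sum(lev[idx]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$bin_start, out$context), , drop = FALSE]
  rownames(out) <- NULL
  maxima <- tapply(out$raw, out$context, max)
  denom <- as.numeric(maxima[out$context])
  out$normalized <- ifelse(denom > 0, 100 * out$raw / denom, 0)
  out
}

#' Bisulfite conversion rate from an unmethylated organellar genome
#'
#' The chloroplast genome is unmethylated, so its apparent methylation is
#' entirely conversion failure. The conversion rate is
#' `100 * (1 - sum(n_meth) / sum(n_meth + n_unmeth))` over all covered
#' organellar cytosines, with no coverage floor.
#'
#' @param sample A [methylome_sample()] that includes the organellar
#'   chromosome.
#' @param organellar_chrom Name of the organellar chromosome.
#' @return Conversion rate in percent.
#' @export
conversion_rate <- function(sample, organellar_chrom = "ChrC") {
  rec <- as.data.frame(sample)
  rec <- rec[rec$chrom == organellar_chrom, , drop = FALSE]
  total <- sum(rec$n_meth + rec$n_unmeth)
  if (!nrow(rec) || total == 0)
    stop_methmap("organellar chromosome '", organellar_chrom,
                 "' absent or without covered cytosines")
  100 * (1 - sum(rec$n_meth) / total)
}
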