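# Bulk segregant analysis: per-marker pool allele frequencies, moving
# average smoothing, candidate-interval calling.

#' Per-marker allele-frequency difference between F2 pools
#'
#' For each marker, the mutant-parent allele frequency in the high and
#' normal pools (`f = mutant count / total chromosomes`) and their
#' difference `delta = f_high - f_normal`. Markers where a pool has zero
#' chromosomes are flagged undefined rather than dropped.
#'
#' @param markers A marker table (see [read_marker_table()]).
#' @return Data.frame: chrom, pos, f_high, f_norm, delta, n_high, n_norm,
#'   defined.
#' @export
allele_freq_diff <- function(markers) {
  m <- as.data.frame(markers)
  counts <- m[, c("allele_high_mut", "allele_high_wt",
                  "allele_norm_mut", "allele_norm_wt")]
  if (any(counts < 0)) stop_methmap("negative allele counts")
  n_high <- m$allele_high_mut + m$allele_high_wt
  n_norm <- m$allele_norm_mut + m$allele_norm_wt
  defined <- n_high > 0 & n_norm > 0
  f_high <- ifelse(n_high > 0, m$allele_high_mut / n_high, NA_real_)
  f_norm <- ifelse(n_norm > 0, m$allele_norm_mut / n_norm, NA_real_)
  data.frame(chrom = m$chrom, pos = m$pos, f_high = f_high, f_norm = f_norm,
             delta = f_high - f_norm, n_high = n_high, n_norm = n_norm,
             defined = defined, stringsAsFactors = FALSE)
}

#' Smooth an allele-frequency-difference profile
#'
#' Centred moving average over `k` markers within each chromosome; at
#' chromosome ends the window is truncated to the available markers.
#' `k = 1` is the identity.
#'
#' @param afd Profile from [allele_freq_diff()] (markers in map order).
#' @param k Odd window width in markers (default 5).
#' @return `afd` with a `delta_smooth` column appended.
#' @export
smooth_profile <- function(afd, k = 5L) {
  if (k < 1 || k %% 2 == 0) stop_methmap("k must be odd and >= 1")
  half <- (k - 1L) %/% 2L
  afd$delta_smooth <- NA_real_
  for (idx in split(seq_len(nrow(afd)), afd$chrom)) {
    x <- afd$delta[idx]
    n <- length(x)
    sm <- vapply(seq_len(n), function(i) {
      mean(x[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
    }, numeric(1))
    afd$delta_smooth[idx] <- sm
  }
  afd
}

#' Call candidate intervals from a smoothed profile
#'
#' Maximal runs of consecutive markers whose smoothed difference reaches
#' `threshold` become candidate intervals, bounded by their outermost
#' member markers; the peak is the member with the largest smoothed value.
#'
#' @param afd Smoothed profile from [smooth_profile()].
#' @param threshold Calling threshold on the smoothed difference, in (0, 1].
#' @return Data.frame: chrom, start, end, n_markers, peak_pos, peak_delta.
#'   Empty (not an error) when no marker reaches the threshold.
#' @export
candidate_intervals <- function(afd, threshold = 0.4) {
  if (threshold <= 0 || threshold > 1)
    stop_methmap("threshold must be in (0, 1]")
  out <- list()
  for (idx in split(seq_len(nrow(afd)), afd$chrom)) {
    above <- !is.na(afd$delta_smooth[idx]) & afd$delta_smooth[idx] >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      rows <- idx[starts[r]:ends[r]]
      peak <- rows[which.max(afd$delta_smooth[rows])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = afd$chrom[rows[1]], start = min(afd$pos[rows]),
        end = max(afd$pos[rows]), n_markers = length(rows),
        peak_pos = afd$pos[peak], peak_delta = afd$delta_smooth[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_markers = integer(),
                      peak_pos = numeric(), peak_delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' One-call BSA scan
#'
#' Computes the allele-frequency-difference profile, smooths it and calls
#' candidate intervals.
#'
#' @param markers Marker table.
#' @param k Smoothing window (markers, odd; default 5).
#' @param threshold Interval-calling threshold (default 0.4).
#' @return List: `profile` (smoothed AFD per marker) and `intervals`.
#' @export
bsa_scan <- function(markers, k = 5L, threshold = 0.4) {
  afd <- smooth_profile(allele_freq_diff(markers), k = k)
  list(profile = afd, intervals = candidate_intervals(afd, threshold))
}
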