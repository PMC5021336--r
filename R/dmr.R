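# Sliding-window differential methylation: five same-context cytosines per
# window advancing one cytosine at a time, Fisher's exact test on pooled
# counts, BH FDR within one (comparison x context) family, merge of
# overlapping passing windows into DMRs with a 200 bp length floor.

#' Build sliding windows over the shared cytosine inventory
#'
#' Windows cover five consecutive cytosines of one context in chromosome
#' order (both strands interleaved, "+" before "-" at equal position),
#' advancing one cytosine at a time. Sites are taken from the union of the
#' two samples' inventories, so window positions are sample-independent; a
#' member site is *qualifying* iff it has at least `min_coverage` reads in
#' BOTH samples, and only qualifying sites contribute to the pooled counts.
#'
#' @param sample_a,sample_b Two [methylome_sample()]s on one reference.
#' @param context "CG", "CHG" or "CHH".
#' @param min_coverage Per-site qualifying-coverage floor (default 4).
#' @param window_size Member cytosines per window (default 5).
#' @return List: `windows` (data.frame: chrom, context, start, end,
#'   site_from, site_to (row indices into `sites`), M_a, U_a, M_b, U_b,
#'   n_qualifying, covered_fraction) and `sites` (the merged per-site
#'   table with qualifying flags). Chromosomes with fewer than
#'   `window_size` context cytosines contribute no windows.
#' @export
build_windows <- function(sample_a, sample_b, context,
                          min_coverage = 4L, window_size = 5L) {
  stopifnot(context %in% CONTEXTS)
  a <- as.data.frame(sample_a)
  b <- as.data.frame(sample_b)
  a <- a[a$context == context, c("chrom", "pos", "strand", "n_meth",
                                 "n_unmeth")]
  b <- b[b$context == context, c("chrom", "pos", "strand", "n_meth",
                                 "n_unmeth")]
  sites <- merge(a, b, by = c("chrom", "pos", "strand"), all = TRUE,
                 suffixes = c("_a", "_b"))
  for (col in c("n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b"))
    sites[[col]][is.na(sites[[col]])] <- 0L
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  cov_a <- sites$n_meth_a + sites$n_unmeth_a
  cov_b <- sites$n_meth_b + sites$n_unmeth_b
  sites$qualifying <- cov_a >= min_coverage & cov_b >= min_coverage

  w <- window_size
  empty <- data.frame(chrom = character(), context = character(),
                      start = integer(), end = integer(),
                      site_from = integer(), site_to = integer(),
                      M_a = integer(), U_a = integer(), M_b = integer(),
                      U_b = integer(), n_qualifying = integer(),
                      covered_fraction = numeric(), stringsAsFactors = FALSE)
  per_chrom <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    n <- length(idx)
    if (n < w) return(NULL)
    roll <- function(x) {
      cs <- cumsum(c(0, x))
      cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    }
    q <- sites$qualifying[idx]
    first <- idx[1:(n - w + 1)]
    data.frame(
      chrom = sites$chrom[first], context = context,
      start = sites$pos[first], end = sites$pos[idx[w:n]],
      site_from = first, site_to = idx[w:n],
      M_a = roll(sites$n_meth_a[idx] * q),
      U_a = roll(sites$n_unmeth_a[idx] * q),
      M_b = roll(sites$n_meth_b[idx] * q),
      U_b = roll(sites$n_unmeth_b[idx] * q),
      n_qualifying = roll(as.integer(q)),
      stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, c(per_chrom, list(empty[, 1:11])))
  rownames(windows) <- NULL
  windows$covered_fraction <- windows$n_qualifying / w
  list(windows = windows, sites = sites)
}

#' Two-sided Fisher's exact p-value for 2x2 count tables
#'
#' Exact hypergeometric two-sided p: with the table's margins fixed, all
#' outcomes whose probability does not exceed that of the observed table
#' (to within a relative tolerance of 1e-7) are summed. A table with a zero
#' row or column margin carries no information and returns p = 1.
#' Vectorised over tables.
#'
#' @param m_a,u_a,m_b,u_b Methylated/unmethylated counts in samples A and B.
#' @return p-values in (0, 1].
#' @export
fisher_p <- function(m_a, u_a, m_b, u_b) {
  n <- max(length(m_a), length(u_a), length(m_b), length(u_b))
  m_a <- rep_len(m_a, n); u_a <- rep_len(u_a, n)
  m_b <- rep_len(m_b, n); u_b <- rep_len(u_b, n)
  if (any(c(m_a, u_a, m_b, u_b) < 0)) stop_methmap("negative counts")
  vapply(seq_len(n), function(i) {
    a <- m_a[i]; b <- u_a[i]; c_ <- m_b[i]; d <- u_b[i]
    N <- a + b + c_ + d
    n1 <- a + b          # sample A reads
    m1 <- a + c_         # methylated reads
    if (N == 0 || n1 == 0 || n1 == N || m1 == 0 || m1 == N) return(1)
    lo <- max(0L, m1 - (N - n1))
    hi <- min(m1, n1)
    dens <- dhyper(lo:hi, n1, N - n1, m1)
    p_obs <- dens[a - lo + 1L]
    min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1
#' and returned in the input order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_methmap("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test sliding windows for differential methylation
#'
#' Windows whose covered-site fraction exceeds `min_covered_fraction` form
#' the testing family: each gets a two-sided Fisher's exact p on its pooled
#' 2x2 table (methylated vs unmethylated reads x sample), adjusted by
#' Benjamini-Hochberg within the family. Pooled levels, fold change
#' (max/min level; +Inf when exactly one level is 0) and direction (hyper
#' iff sample B's level exceeds sample A's) are reported. A window passes
#' iff adjusted p <= `max_fdr`, fold change > `min_fold_change` and covered
#' fraction > `min_covered_fraction`; windows with both levels 0 or an
#' empty pooled sample fail.
#'
#' @param windows Window data.frame from [build_windows()].
#' @param max_fdr Adjusted-p ceiling (default 0.05).
#' @param min_fold_change Fold-change floor, strict (default 2).
#' @param min_covered_fraction Covered-site-fraction floor, strict
#'   (default 0.6).
#' @return The window data.frame with columns level_a, level_b,
#'   fold_change, direction, p, p_adj, pass appended.
#' @export
test_windows <- function(windows, max_fdr = 0.05, min_fold_change = 2,
                         min_covered_fraction = 0.6) {
  tot_a <- windows$M_a + windows$U_a
  tot_b <- windows$M_b + windows$U_b
  windows$level_a <- ifelse(tot_a > 0, windows$M_a / tot_a, NA_real_)
  windows$level_b <- ifelse(tot_b > 0, windows$M_b / tot_b, NA_real_)
  lo <- pmin(windows$level_a, windows$level_b)
  hi <- pmax(windows$level_a, windows$level_b)
  windows$fold_change <- ifelse(is.na(lo), NA_real_,
                                ifelse(hi == 0, NA_real_,
                                       ifelse(lo == 0, Inf, hi / lo)))
  windows$direction <- ifelse(
    is.na(windows$level_a) | is.na(windows$level_b) |
      windows$level_a == windows$level_b, NA_character_,
    ifelse(windows$level_b > windows$level_a, "hyper", "hypo"))
  eligible <- windows$covered_fraction > min_covered_fraction &
    tot_a > 0 & tot_b > 0
  windows$p <- NA_real_
  windows$p_adj <- NA_real_
  if (any(eligible)) {
    windows$p[eligible] <- fisher_p(windows$M_a[eligible],
                                    windows$U_a[eligible],
                                    windows$M_b[eligible],
                                    windows$U_b[eligible])
    windows$p_adj[eligible] <- bh_adjust(windows$p[eligible])
  }
  windows$pass <- eligible &
    !is.na(windows$p_adj) & windows$p_adj <= max_fdr &
    !is.na(windows$fold_change) & windows$fold_change > min_fold_change &
    !is.na(windows$direction)
  windows
}

#' Merge passing windows into differentially methylated regions
#'
#' Passing windows of one context and comparison whose genomic spans
#' overlap and that share a direction are merged transitively. A DMR's
#' bounds are the outermost member-cytosine positions of its merged
#' windows; its pooled counts are recomputed over the unique qualifying
#' member sites. Regions shorter than `min_length` bp are dropped. If a
#' hyper and a hypo region overlap after merging (rare), the one with the
#' larger best adjusted p is dropped so that emitted same-context DMRs
#' never overlap.
#'
#' @param tests Window-test data.frame from [test_windows()].
#' @param sites Per-site table from [build_windows()].
#' @param min_length Minimum DMR span in bp (default 200).
#' @return Data.frame: chrom, context, start, end, length, direction,
#'   n_windows, M_a, U_a, M_b, U_b, level_a, level_b, best_p_adj. An
#'   attribute `n_dropped_short` records how many merged regions failed the
#'   length floor.
#' @export
merge_to_dmrs <- function(tests, sites, min_length = 200L) {
  empty <- data.frame(chrom = character(), context = character(),
                      start = integer(), end = integer(), length = integer(),
                      direction = character(), n_windows = integer(),
                      M_a = integer(), U_a = integer(), M_b = integer(),
                      U_b = integer(), level_a = numeric(),
                      level_b = numeric(), best_p_adj = numeric(),
                      stringsAsFactors = FALSE)
  pass <- tests[tests$pass, , drop = FALSE]
  if (!nrow(pass)) {
    attr(empty, "n_dropped_short") <- 0L
    return(empty)
  }
  clusters <- list()
  for (grp in split(pass, list(pass$chrom, pass$direction), drop = TRUE)) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    members <- list(cur)
    flush <- function(members) {
      m <- do.call(rbind, members)
      site_idx <- unique(unlist(Map(seq, m$site_from, m$site_to)))
      s <- sites[site_idx, , drop = FALSE]
      s <- s[s$qualifying, , drop = FALSE]
      M_a <- sum(s$n_meth_a); U_a <- sum(s$n_unmeth_a)
      M_b <- sum(s$n_meth_b); U_b <- sum(s$n_unmeth_b)
      data.frame(
        chrom = m$chrom[1], context = m$context[1],
        start = min(m$start), end = max(m$end),
        length = max(m$end) - min(m$start) + 1L,
        direction = m$direction[1], n_windows = nrow(m),
        M_a = M_a, U_a = U_a, M_b = M_b, U_b = U_b,
        level_a = if (M_a + U_a > 0) M_a / (M_a + U_a) else NA_real_,
        level_b = if (M_b + U_b > 0) M_b / (M_b + U_b) else NA_real_,
        best_p_adj = min(m$p_adj), stringsAsFactors = FALSE)
    }
    if (nrow(grp) > 1) {
      for (i in 2:nrow(grp)) {
        row <- grp[i, , drop = FALSE]
        if (row$start <= max(vapply(members, function(x) x$end, numeric(1)))) {
          members <- c(members, list(row))
        } else {
          clusters <- c(clusters, list(flush(members)))
          members <- list(row)
        }
      }
    }
    clusters <- c(clusters, list(flush(members)))
  }
  dmrs <- do.call(rbind, clusters)
  short <- dmrs$length < min_length
  n_dropped <- sum(short)
  dmrs <- dmrs[!short, , drop = FALSE]
  # resolve rare cross-direction overlaps: weakest (largest best p) goes
  if (nrow(dmrs) > 1) {
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
    repeat {
      drop_idx <- NULL
      for (i in seq_len(nrow(dmrs) - 1)) {
        j <- i + 1
        if (dmrs$chrom[i] == dmrs$chrom[j] && dmrs$start[j] <= dmrs$end[i]) {
          drop_idx <- if (dmrs$best_p_adj[i] > dmrs$best_p_adj[j]) i else j
          break
        }
      }
      if (is.null(drop_idx)) break
      dmrs <- dmrs[-drop_idx, , drop = FALSE]
    }
  }
  rownames(dmrs) <- NULL
  attr(dmrs, "n_dropped_short") <- n_dropped
  dmrs
}

#' Call DMRs between two methylome samples
#'
#' Runs the full window pipeline independently per context: build sliding
#' windows, Fisher-test the eligible ones, adjust within the
#' (comparison x context) family, apply the pass criteria and merge into
#' DMRs of at least `min_dmr_length` bp. Direction is reported for sample B
#' relative to sample A (hyper = more methylated in B).
#'
#' @param sample_a,sample_b Two [methylome_sample()]s.
#' @param contexts Contexts to analyse (default all three).
#' @param min_coverage,window_size,max_fdr,min_fold_change,
#'   min_covered_fraction,min_dmr_length Pipeline thresholds; defaults are
#'   [default_params()].
#' @param exclude_chroms Chromosomes excluded from calling (e.g. the
#'   organellar genome).
#' @return List: `dmrs` (combined DMR data.frame across contexts) and
#'   `windows` (named list of full per-context window-test tables).
#' @export
call_dmrs <- function(sample_a, sample_b, contexts = CONTEXTS,
                      min_coverage = 4L, window_size = 5L, max_fdr = 0.05,
                      min_fold_change = 2, min_covered_fraction = 0.6,
                      min_dmr_length = 200L, exclude_chroms = "ChrC") {
  drop_excluded <- function(s) {
    d <- as.data.frame(s)
    methylome_sample(d[!d$chrom %in% exclude_chroms, , drop = FALSE],
                     sample_id = attr(s, "sample_id") %||% "sample")
  }
  sample_a <- drop_excluded(sample_a)
  sample_b <- drop_excluded(sample_b)
  window_tables <- list()
  dmr_list <- list()
  for (ctx in contexts) {
    built <- build_windows(sample_a, sample_b, ctx,
                           min_coverage = min_coverage,
                           window_size = window_size)
    tests <- test_windows(built$windows, max_fdr = max_fdr,
                          min_fold_change = min_fold_change,
                          min_covered_fraction = min_covered_fraction)
    window_tables[[ctx]] <- tests
    dmr_list[[ctx]] <- merge_to_dmrs(tests, built$sites,
                                     min_length = min_dmr_length)
  }
  dmrs <- do.call(rbind, dmr_list)
  rownames(dmrs) <- NULL
  list(dmrs = dmrs, windows = window_tables)
}
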