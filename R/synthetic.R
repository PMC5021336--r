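# Synthetic WGBS and F2-pool data with full ground truth.

#' Simulation configuration for synthetic methylomes
#'
#' @param seed Integer seed; fixing it makes every generated object (and the
#'   files written from it) byte-identical across runs.
#' @param mean_depth Mean sequencing depth per cytosine (reads/site); per-site
#'   depth is Poisson with this mean. Default 30.
#' @param conversion_failure Probability `f` in `[0, 1)` that an unmethylated
#'   cytosine escapes bisulfite conversion and is read as methylated. A real
#'   experiment with a conversion rate of 99.57% corresponds to f = 0.0043.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param gc GC content of the generated reference (A. thaliana-like 0.36).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, mean_depth = 30, conversion_failure = 0.005,
                       chrom_lengths = c(Chr1 = 200000L), gc = 0.36) {
  if (conversion_failure < 0 || conversion_failure >= 1)
    stop_methmap("conversion_failure must be in [0, 1)")
  if (any(chrom_lengths < 10))
    stop_methmap("chromosome lengths must be >= 10 bp")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_methmap("chrom_lengths must be a named vector")
  structure(
    list(seed = as.integer(seed), mean_depth = mean_depth,
         conversion_failure = conversion_failure,
         chrom_lengths = chrom_lengths, gc = gc),
    class = "sim_config"
  )
}

#' Generate a random reference genome and its cytosine inventory
#'
#' Draws i.i.d. bases at the configured GC content and lists every cytosine
#' on both strands: each C on the plus strand and each G on the minus strand
#' (a cytosine when read 5'->3' on that strand) appears exactly once, with
#' its sequence context (CG, CHG or CHH with H = A, C or T) and
#' trinucleotide. At chromosome ends, bases beyond the sequence are treated
#' as H and the trinucleotide is padded with N.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector, one string per
#'   chromosome) and `inventory` (data.frame: chrom, pos (1-based), strand,
#'   context, trinucleotide), sorted by (chrom, pos, strand).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- vapply(config$chrom_lengths, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  inv <- do.call(rbind, lapply(names(seqs), function(chrom) {
    cytosine_inventory(seqs[[chrom]], chrom)
  }))
  rownames(inv) <- NULL
  list(sequences = seqs, inventory = inv)
}

# Inventory of strand-specific cytosines for one chromosome sequence.
cytosine_inventory <- function(sequence, chrom) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop_methmap("reference sequence contains non-ACGT characters")
  n <- length(bases)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  at <- function(i) ifelse(i >= 1 & i <= n, bases[pmax(pmin(i, n), 1)], "N")

  plus <- which(bases == "C")
  p1 <- at(plus + 1); p2 <- at(plus + 2)
  ctx_p <- ifelse(p1 == "G", "CG", ifelse(p2 == "G", "CHG", "CHH"))
  tri_p <- if (length(plus)) paste0("C", p1, p2) else character(0)

  minus <- which(bases == "G")
  m1 <- at(minus - 1); m2 <- at(minus - 2)
  # read 5'->3' on the minus strand: complement of upstream plus-strand bases
  c1 <- ifelse(m1 == "N", "N", comp[m1])
  c2 <- ifelse(m2 == "N", "N", comp[m2])
  ctx_m <- ifelse(c1 == "G", "CG", ifelse(c2 == "G", "CHG", "CHH"))
  tri_m <- if (length(minus)) paste0("C", c1, c2) else character(0)

  inv <- data.frame(
    chrom = chrom,
    pos = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    context = c(ctx_p, ctx_m),
    trinucleotide = c(tri_p, tri_m),
    stringsAsFactors = FALSE
  )
  inv[order(inv$pos, inv$strand), , drop = FALSE]
}

#' Plant differentially methylated regions into a truth methylome pair
#'
#' Builds two truth methylomes (samples A and B) over a cytosine inventory.
#' Outside planted regions the true methylation probability of every site is
#' its context baseline, identical in A and B; inside a planted region the
#' sites of the planted context have probability `m_A` in A and `m_B` in B.
#' Regions are placed uniformly at random, do not overlap, and each must
#' contain at least `min_sites` cytosines of the target context.
#'
#' @param inventory Cytosine inventory from [generate_reference()].
#' @param n_dmrs Number of regions to plant (0 gives identical truths).
#' @param context Context of the planted signal ("CG", "CHG" or "CHH").
#' @param m_A,m_B True methylation rates inside regions in samples A and B.
#' @param min_sites Minimum context cytosines a region must contain.
#' @param region_len Region length in bp.
#' @param baselines Named per-context baseline rates. The defaults
#'   (CG 0.28, CHG 0.10, CHH 0.03) reproduce typical wild-type
#'   A. thaliana shoot levels.
#' @param seed Integer seed for region placement.
#' @return List of class `truth_methylome_pair`: `truth_A`, `truth_B`
#'   (inventory plus column `m`), `planted` (data.frame: chrom, start, end,
#'   context, m_A, m_B, n_sites) and `baselines`.
#' @export
plant_dmrs <- function(inventory, n_dmrs, context = "CG", m_A = 0.1,
                       m_B = 0.8, min_sites = 10L, region_len = 1000L,
                       baselines = c(CG = 0.28, CHG = 0.10, CHH = 0.03),
                       seed = 1L) {
  stopifnot(context %in% CONTEXTS, all(CONTEXTS %in% names(baselines)))
  if (n_dmrs > 0 && m_A == m_B)
    stop_methmap("planted regions require m_A != m_B")
  m_base <- unname(baselines[inventory$context])
  truth_A <- cbind(inventory, m = m_base)
  truth_B <- cbind(inventory, m = m_base)
  planted <- data.frame(chrom = character(), start = integer(),
                        end = integer(), context = character(),
                        m_A = numeric(), m_B = numeric(),
                        n_sites = integer(), stringsAsFactors = FALSE)
  if (n_dmrs > 0) {
    set.seed(seed)
    chrom_max <- tapply(inventory$pos, inventory$chrom, max)
    ctx_rows <- inventory[inventory$context == context, , drop = FALSE]
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n_dmrs
    while (placed < n_dmrs && attempts < max_attempts) {
      attempts <- attempts + 1L
      chrom <- sample(names(chrom_max), 1L)
      hi <- chrom_max[[chrom]] - region_len + 1L
      if (hi < 1L) next
      start <- sample.int(hi, 1L)
      end <- start + region_len - 1L
      same <- planted$chrom == chrom
      if (any(same & planted$start <= end & planted$end >= start)) next
      in_region <- ctx_rows$chrom == chrom & ctx_rows$pos >= start &
        ctx_rows$pos <= end
      n_sites <- sum(in_region)
      if (n_sites < min_sites) next
      hit <- inventory$chrom == chrom & inventory$context == context &
        inventory$pos >= start & inventory$pos <= end
      truth_A$m[hit] <- m_A
      truth_B$m[hit] <- m_B
      planted <- rbind(planted, data.frame(
        chrom = chrom, start = start, end = end, context = context,
        m_A = m_A, m_B = m_B, n_sites = n_sites, stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
    if (placed < n_dmrs)
      stop_methmap("could not place ", n_dmrs, " disjoint regions of ",
                   region_len, " bp with >= ", min_sites, " ", context,
                   " sites each; placed ", placed)
  }
  structure(list(truth_A = truth_A, truth_B = truth_B, planted = planted,
                 baselines = baselines),
            class = "truth_methylome_pair")
}

#' Simulate bisulfite read counts from a truth methylome
#'
#' Per site, total reads `n ~ Poisson(mean_depth)` and methylated calls
#' `~ Binomial(n, m + (1 - m) f)` where `f` is the conversion-failure rate:
#' a truly unmethylated read appears methylated with probability `f`.
#' Over-conversion of methylated cytosines is not modelled.
#'
#' @param truth Data.frame with inventory columns plus `m` (true rate).
#' @param config A [sim_config()].
#' @param sample_id,genotype,tissue Sample metadata labels.
#' @param seed Seed for the count draws (defaults to the config seed).
#' @return A `methylome_sample` (see [methylome_sample()]).
#' @export
simulate_counts <- function(truth, config, sample_id = "sample",
                            genotype = NA_character_, tissue = NA_character_,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), "m" %in% names(truth))
  f <- config$conversion_failure
  set.seed(seed)
  n <- rpois(nrow(truth), config$mean_depth)
  p_call <- truth$m + (1 - truth$m) * f
  n_meth <- rbinom(nrow(truth), n, p_call)
  rec <- data.frame(
    chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
    n_meth = n_meth, n_unmeth = n - n_meth,
    context = truth$context, trinucleotide = truth$trinucleotide,
    stringsAsFactors = FALSE
  )
  methylome_sample(rec, sample_id = sample_id, genotype = genotype,
                   tissue = tissue)
}

#' Simulate an unmethylated organellar (chloroplast) chromosome
#'
#' The chloroplast genome is unmethylated, so every methylated call on it is
#' a conversion failure; the pipeline estimates the conversion rate from it.
#'
#' @param length Chromosome length in bp (0 gives an empty table).
#' @param config A [sim_config()]; depth and conversion failure are taken
#'   from it.
#' @param chrom Chromosome name to emit (default "ChrC").
#' @param seed Seed for sequence and count draws.
#' @return A `methylome_sample` holding only the organellar records.
#' @export
simulate_chloroplast <- function(length, config, chrom = "ChrC",
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer(), context = character(),
                      trinucleotide = character(), stringsAsFactors = FALSE)
  if (length == 0)
    return(methylome_sample(empty, sample_id = "organellar"))
  sub <- sim_config(seed = seed, mean_depth = config$mean_depth,
                    conversion_failure = config$conversion_failure,
                    chrom_lengths = setNames(as.integer(length), chrom),
                    gc = config$gc)
  ref <- generate_reference(sub)
  truth <- cbind(ref$inventory, m = 0)
  simulate_counts(truth, sub, sample_id = "organellar", seed = seed + 1L)
}

#' Generate synthetic gene and transposable-element annotations
#'
#' Places non-overlapping gene bodies (and optionally transposable elements)
#' uniformly on the configured chromosomes with random strands, for use as
#' DMG-annotation input.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_genes,n_te Numbers of genes and transposable elements.
#' @param mean_len Mean feature length (bp); lengths are Poisson about it
#'   with a 200 bp floor.
#' @param seed Integer seed.
#' @return Data.frame of gene models (gene_id, chrom, strand, start, end,
#'   feature_class), sorted by position.
#' @export
generate_genes <- function(chrom_lengths, n_genes = 40L, n_te = 10L,
                           mean_len = 2000L, seed = 1L) {
  set.seed(seed)
  n <- n_genes + n_te
  feats <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), feature_class = character(),
                      stringsAsFactors = FALSE)
  classes <- rep(c("gene", "transposable_element"), c(n_genes, n_te))
  attempts <- 0L
  i <- 1L
  while (i <= n && attempts < 200L * n) {
    attempts <- attempts + 1L
    chrom <- sample(names(chrom_lengths), 1L)
    len <- max(200L, rpois(1L, mean_len))
    hi <- chrom_lengths[[chrom]] - len + 1L
    if (hi < 1L) next
    start <- sample.int(hi, 1L)
    end <- start + len - 1L
    same <- feats$chrom == chrom
    if (any(same & feats$start <= end & feats$end >= start)) next
    feats <- rbind(feats, data.frame(
      gene_id = sprintf("%s%04d", ifelse(classes[i] == "gene", "G", "TE"), i),
      chrom = chrom, strand = sample(c("+", "-"), 1L),
      start = start, end = end, feature_class = classes[i],
      stringsAsFactors = FALSE))
    i <- i + 1L
  }
  if (i <= n)
    stop_methmap("could not place ", n, " non-overlapping features")
  feats[order(feats$chrom, feats$start), , drop = FALSE]
}

#' Configuration for F2 pool simulation
#'
#' @param map_length Genetic map length of the simulated chromosome in cM.
#' @param n_markers Number of markers; by default evenly spaced over the map.
#' @param marker_pos Optional explicit marker positions (cM).
#' @param causal_pos Position of the recessive causal locus (cM).
#' @param pool_size Individuals per pool (the classic design uses 40).
#' @param seed Integer seed.
#' @return Object of class `pool_sim_config`.
#' @export
pool_sim_config <- function(map_length = 100, n_markers = 100L,
                            marker_pos = NULL, causal_pos = 40,
                            pool_size = 40L, seed = 1L) {
  if (pool_size <= 0) stop_methmap("pool_size must be > 0")
  if (causal_pos < 0 || causal_pos > map_length)
    stop_methmap("causal_pos must lie within the map")
  if (is.null(marker_pos))
    marker_pos <- seq(0, map_length, length.out = n_markers)
  structure(list(map_length = map_length, marker_pos = sort(marker_pos),
                 causal_pos = causal_pos, pool_size = as.integer(pool_size),
                 seed = as.integer(seed)),
            class = "pool_sim_config")
}

# One gamete per row: allele (1 = mutant parent) at each locus, simulated as
# a Markov chain along the map with Haldane recombination fractions.
simulate_gametes <- function(n, loci_cM) {
  k <- length(loci_cM)
  g <- matrix(0L, n, k)
  g[, 1] <- rbinom(n, 1L, 0.5)
  if (k > 1) {
    r <- 0.5 * (1 - exp(-2 * diff(loci_cM) / 100))
    for (j in 2:k) {
      flip <- rbinom(n, 1L, r[j - 1])
      g[, j] <- ifelse(flip == 1L, 1L - g[, j - 1], g[, j - 1])
    }
  }
  g
}

#' Simulate allele counts in phenotypically selected F2 pools
#'
#' F2 individuals are formed from two independent F1 gametes, each a
#' recombinant chromosome under Haldane's map function. The "high" pool
#' contains individuals homozygous for the mutant allele at the recessive
#' causal locus; the "normal" pool draws from the phenotypically normal
#' classes (homozygous wild-type : heterozygous in their natural 1 : 2
#' ratio). Per-marker counts tally all `2 * pool_size` chromosomes.
#'
#' @param config A [pool_sim_config()].
#' @return Data.frame of class `marker_table` (chrom, pos (cM),
#'   allele_high_mut, allele_high_wt, allele_norm_mut, allele_norm_wt) with
#'   attributes `causal_pos` and `pool_size`.
#' @export
simulate_f2_pools <- function(config) {
  stopifnot(inherits(config, "pool_sim_config"))
  set.seed(config$seed)
  loci <- sort(unique(c(config$marker_pos, config$causal_pos)))
  causal_idx <- match(config$causal_pos, loci)
  marker_idx <- match(config$marker_pos, loci)
  draw_pool <- function(want_high) {
    need <- config$pool_size
    tally <- integer(length(loci))
    got <- 0L
    while (got < need) {
      batch <- max(4L * (need - got), 32L)
      g1 <- simulate_gametes(batch, loci)
      g2 <- simulate_gametes(batch, loci)
      geno_causal <- g1[, causal_idx] + g2[, causal_idx]
      keep <- if (want_high) geno_causal == 2L else geno_causal < 2L
      keep_n <- min(sum(keep), need - got)
      if (keep_n > 0) {
        rows <- which(keep)[seq_len(keep_n)]
        sel <- g1[rows, , drop = FALSE] + g2[rows, , drop = FALSE]
        tally <- tally + colSums(sel)
        got <- got + keep_n
      }
    }
    tally
  }
  high <- draw_pool(TRUE)
  norm <- draw_pool(FALSE)
  total <- 2L * config$pool_size
  out <- data.frame(
    chrom = "Chr1", pos = config$marker_pos,
    allele_high_mut = high[marker_idx],
    allele_high_wt = total - high[marker_idx],
    allele_norm_mut = norm[marker_idx],
    allele_norm_wt = total - norm[marker_idx],
    stringsAsFactors = FALSE
  )
  attr(out, "causal_pos") <- config$causal_pos
  attr(out, "pool_size") <- config$pool_size
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Simulate a matched pair of methylome samples with planted DMRs
#'
#' Convenience wrapper: generates a reference, plants regions, simulates
#' counts for both samples with independent seeds, and optionally appends an
#' unmethylated organellar chromosome to each sample.
#'
#' @param config A [sim_config()].
#' @param n_dmrs,context,m_A,m_B,min_sites,region_len Passed to
#'   [plant_dmrs()].
#' @param chloroplast_length If > 0, length of the appended organellar
#'   chromosome (named "ChrC").
#' @return List: `sample_A`, `sample_B` (methylome samples), `truth`
#'   (the `truth_methylome_pair`), `reference`.
#' @export
simulate_methylome_pair <- function(config, n_dmrs = 0L, context = "CG",
                                    m_A = 0.1, m_B = 0.8, min_sites = 10L,
                                    region_len = 1000L,
                                    chloroplast_length = 0L) {
  ref <- generate_reference(config)
  truth <- plant_dmrs(ref$inventory, n_dmrs = n_dmrs, context = context,
                      m_A = m_A, m_B = m_B, min_sites = min_sites,
                      region_len = region_len, seed = config$seed + 1L)
  a <- simulate_counts(truth$truth_A, config, sample_id = "sample_A",
                       seed = config$seed + 2L)
  b <- simulate_counts(truth$truth_B, config, sample_id = "sample_B",
                       seed = config$seed + 3L)
  if (chloroplast_length > 0) {
    ca <- simulate_chloroplast(chloroplast_length, config,
                               seed = config$seed + 4L)
    cb <- simulate_chloroplast(chloroplast_length, config,
                               seed = config$seed + 5L)
    a <- methylome_sample(rbind(as.data.frame(a), as.data.frame(ca)),
                          sample_id = "sample_A")
    b <- methylome_sample(rbind(as.data.frame(b), as.data.frame(cb)),
                          sample_id = "sample_B")
  }
  list(sample_A = a, sample_B = b, truth = truth, reference = ref)
}
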