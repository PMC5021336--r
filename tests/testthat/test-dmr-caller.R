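# Sliding windows, Fisher's exact test, BH adjustment, window evaluation,
# merging, and whole-caller symmetry/null behaviour.

test_that("windows slide one cytosine at a time over the shared inventory", {
  pos <- c(10, 30, 50, 70, 90, 110, 130)
  a <- make_sample(pos, n_meth = 5, n_unmeth = 5)
  b <- make_sample(pos, n_meth = 5, n_unmeth = 5)
  built <- build_windows(a, b, "CG")
  expect_equal(nrow(built$windows), 3L)  # n - 4
  expect_equal(built$windows$start, c(10, 30, 50))
  expect_equal(built$windows$end, c(90, 110, 130))
  expect_equal(built$windows$covered_fraction, rep(1, 3))
  expect_equal(built$windows$M_a, rep(25L, 3))

  # fewer than 5 context cytosines: zero windows, no error
  few <- build_windows(make_sample(1:4 * 10, 1, 1),
                       make_sample(1:4 * 10, 1, 1), "CG")
  expect_equal(nrow(few$windows), 0L)
})

test_that("a member site qualifies only with >= 4x coverage in both samples", {
  pos <- c(10, 30, 50, 70, 90)
  a <- make_sample(pos, n_meth = c(5, 5, 5, 5, 2), n_unmeth = c(5, 5, 5, 5, 1))
  b <- make_sample(pos, n_meth = 5, n_unmeth = 5)
  w <- build_windows(a, b, "CG")$windows
  expect_equal(w$covered_fraction, 0.8)       # 4 of 5, eligible (> 0.6)
  expect_equal(w$M_a, 20L)                    # last site excluded from pools
  expect_equal(w$M_b, 20L)

  a2 <- make_sample(pos, n_meth = c(5, 5, 5, 2, 2), n_unmeth = c(5, 5, 5, 1, 1))
  w2 <- build_windows(a2, b, "CG")$windows
  expect_equal(w2$covered_fraction, 0.6)      # 3 of 5 fails the strict > 0.6
  t2 <- test_windows(w2)
  expect_true(is.na(t2$p))
  expect_false(t2$pass)
})

test_that("fisher_p matches enumeration, fisher.test and the stated examples", {
  expect_equal(fisher_p(0, 10, 0, 10), 1)
  expect_equal(fisher_p(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_p(3, 7, 9, 1), fisher_oracle(3, 7, 9, 1),
               tolerance = 1e-12)
  # zero margins carry no information
  expect_equal(fisher_p(0, 0, 0, 0), 1)
  expect_equal(fisher_p(3, 0, 5, 0), 1)
  expect_error(fisher_p(-1, 1, 1, 1), "negative")

  set.seed(42)
  for (i in 1:200) {
    tab <- rpois(4, 8)
    p <- fisher_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("bh_adjust reproduces the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    # adjusted values are monotone non-decreasing in raw-p rank
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("window evaluation applies the level, fold-change and zero rules", {
  w <- data.frame(chrom = "Chr1", context = "CG", start = 1L, end = 100L,
                  site_from = 1L, site_to = 5L,
                  M_a = c(20L, 20L, 0L, 0L, 10L),
                  U_a = c(80L, 80L, 100L, 100L, 0L),
                  M_b = c(50L, 30L, 40L, 0L, 10L),
                  U_b = c(50L, 70L, 60L, 100L, 0L),
                  n_qualifying = 5L, covered_fraction = 1,
                  stringsAsFactors = FALSE)
  t <- test_windows(w)
  expect_equal(t$fold_change[1], 2.5)          # 0.2 vs 0.5
  expect_equal(t$fold_change[2], 1.5)          # 0.2 vs 0.3: fails > 2
  expect_false(t$pass[2])
  expect_equal(t$fold_change[3], Inf)          # 0 vs 0.4: passes the FC rule
  expect_true(t$pass[3])
  expect_true(is.na(t$fold_change[4]))         # both levels 0: fails
  expect_false(t$pass[4])
  expect_true(is.na(t$direction[5]))           # equal levels: no direction
  expect_equal(t$direction[1:3], c("hyper", "hyper", "hyper"))

  w_zero <- w[1, ]
  w_zero$M_b <- 0L; w_zero$U_b <- 0L
  expect_false(test_windows(w_zero)$pass)      # empty pooled sample fails
})

test_that("merging unions overlapping same-direction windows, floors at 200 bp", {
  sites <- data.frame(chrom = "Chr1", pos = seq(100, 700, by = 25),
                      strand = "+", n_meth_a = 2L, n_unmeth_a = 8L,
                      n_meth_b = 8L, n_unmeth_b = 2L, qualifying = TRUE,
                      stringsAsFactors = FALSE)
  mk <- function(start, end, from, to, dir, p_adj) {
    data.frame(chrom = "Chr1", context = "CG", start = start, end = end,
               site_from = from, site_to = to, M_a = 10L, U_a = 40L,
               M_b = 40L, U_b = 10L, n_qualifying = 5L,
               covered_fraction = 1, level_a = 0.2, level_b = 0.8,
               fold_change = 4, direction = dir, p = p_adj / 10,
               p_adj = p_adj, pass = TRUE, stringsAsFactors = FALSE)
  }
  tests <- rbind(mk(100, 250, 1, 7, "hyper", 1e-6),
                 mk(200, 350, 5, 11, "hyper", 1e-4))
  dmrs <- merge_to_dmrs(tests, sites)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(c(dmrs$start, dmrs$end, dmrs$length), c(100, 350, 251))
  expect_equal(dmrs$n_windows, 2L)
  expect_equal(dmrs$best_p_adj, 1e-6)
  # pooled over the 11 unique member sites, not double-counting overlap
  expect_equal(dmrs$M_a, 11L * 2L)

  # lone short region dropped by the 200 bp floor
  short <- merge_to_dmrs(mk(100, 180, 1, 4, "hyper", 1e-6), sites)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "n_dropped_short"), 1L)

  # opposite directions are never merged into one region
  two <- merge_to_dmrs(rbind(mk(100, 300, 1, 9, "hyper", 1e-6),
                             mk(400, 650, 13, 23, "hypo", 1e-3)),
                       sites)
  expect_equal(nrow(two), 2L)
  expect_setequal(two$direction, c("hyper", "hypo"))

  # overlapping opposite-direction regions: the weaker one is not emitted,
  # so same-context DMRs never overlap
  res <- merge_to_dmrs(rbind(mk(100, 300, 1, 9, "hyper", 1e-6),
                             mk(250, 500, 7, 17, "hypo", 1e-3)),
                       sites)
  expect_equal(nrow(res), 1L)
  expect_equal(res$direction, "hyper")
})

test_that("identical samples yield no DMRs in any context", {
  cfg <- sim_config(seed = 17, chrom_lengths = c(Chr1 = 30000L))
  ref <- generate_reference(cfg)
  tr <- plant_dmrs(ref$inventory, n_dmrs = 0)
  s <- simulate_counts(tr$truth_A, cfg, seed = 18)
  res <- call_dmrs(s, s)
  expect_equal(nrow(res$dmrs), 0L)
})

test_that("swapping sample order flips directions, coordinates unchanged", {
  cfg <- sim_config(seed = 23, chrom_lengths = c(Chr1 = 80000L))
  pair <- simulate_methylome_pair(cfg, n_dmrs = 2, region_len = 1500,
                                  min_sites = 12)
  ab <- call_dmrs(pair$sample_A, pair$sample_B, contexts = "CG")
  ba <- call_dmrs(pair$sample_B, pair$sample_A, contexts = "CG")
  expect_gt(nrow(ab$dmrs), 0L)
  expect_equal(ba$dmrs$start, ab$dmrs$start)
  expect_equal(ba$dmrs$end, ab$dmrs$end)
  expect_equal(ba$dmrs$direction,
               ifelse(ab$dmrs$direction == "hyper", "hypo", "hyper"))
  expect_equal(ba$dmrs$best_p_adj, ab$dmrs$best_p_adj)
})

test_that("planted CG regions are recovered by overlapping calls", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = seed, chrom_lengths = c(Chr1 = 60000L))
    pair <- simulate_methylome_pair(cfg, n_dmrs = 1, region_len = 300,
                                    min_sites = 12)
    res <- call_dmrs(pair$sample_A, pair$sample_B, contexts = "CG")
    tp <- pair$truth$planted
    expect_true(any(res$dmrs$start <= tp$end & res$dmrs$end >= tp$start),
                info = paste("seed", seed))
  }
})
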