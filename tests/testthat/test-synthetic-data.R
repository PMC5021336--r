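# Synthetic-data generator: context classification, planted truth,
# binomial count model, organellar chromosome, F2 pools.

test_that("cytosine contexts follow the CG/CHG/CHH definitions", {
  inv <- methmap:::cytosine_inventory("ACGTT", "c")
  expect_equal(inv$context[inv$pos == 2 & inv$strand == "+"], "CG")
  inv <- methmap:::cytosine_inventory("ACAGA", "c")
  expect_equal(inv$context[inv$pos == 2 & inv$strand == "+"], "CHG")
  inv <- methmap:::cytosine_inventory("ACTTA", "c")
  expect_equal(inv$context[inv$pos == 2 & inv$strand == "+"], "CHH")
  # minus strand: the G at pos 3 of ACGTT is a CG cytosine read 5'->3'
  inv <- methmap:::cytosine_inventory("ACGTT", "c")
  expect_equal(inv$context[inv$pos == 3 & inv$strand == "-"], "CG")
  expect_error(methmap:::cytosine_inventory("ACGNX", "c"), "non-ACGT")
})

test_that("the inventory lists every strand-specific cytosine exactly once", {
  cfg <- sim_config(seed = 11, chrom_lengths = c(Chr1 = 2000L, Chr2 = 500L))
  ref <- generate_reference(cfg)
  for (chrom in names(ref$sequences)) {
    bases <- strsplit(ref$sequences[[chrom]], "")[[1]]
    inv <- ref$inventory[ref$inventory$chrom == chrom, ]
    expect_setequal(inv$pos[inv$strand == "+"], which(bases == "C"))
    expect_setequal(inv$pos[inv$strand == "-"], which(bases == "G"))
    expect_false(anyDuplicated(paste(inv$pos, inv$strand)) > 0)
    expect_true(all(inv$context %in% c("CG", "CHG", "CHH")))
  }
  # deterministic under the seed
  expect_identical(ref, generate_reference(cfg))
})

test_that("planted regions carry the requested rates, baselines elsewhere", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(Chr1 = 60000L))
  ref <- generate_reference(cfg)
  null <- plant_dmrs(ref$inventory, n_dmrs = 0)
  expect_identical(null$truth_A, null$truth_B)
  expect_equal(nrow(null$planted), 0L)

  tr <- plant_dmrs(ref$inventory, n_dmrs = 3, context = "CG", m_A = 0.1,
                   m_B = 0.8, min_sites = 10, region_len = 800, seed = 5)
  expect_equal(nrow(tr$planted), 3L)
  expect_true(all(tr$planted$n_sites >= 10))
  # regions pairwise disjoint
  p <- tr$planted[order(tr$planted$start), ]
  expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  inside <- rep(FALSE, nrow(ref$inventory))
  for (i in seq_len(nrow(p))) {
    inside <- inside | (ref$inventory$chrom == p$chrom[i] &
                          ref$inventory$pos >= p$start[i] &
                          ref$inventory$pos <= p$end[i] &
                          ref$inventory$context == "CG")
  }
  expect_true(all(tr$truth_A$m[inside] == 0.1))
  expect_true(all(tr$truth_B$m[inside] == 0.8))
  expect_identical(tr$truth_A$m[!inside], tr$truth_B$m[!inside])
  base <- c(CG = 0.28, CHG = 0.10, CHH = 0.03)
  expect_equal(tr$truth_A$m[!inside],
               unname(base[ref$inventory$context[!inside]]))
  # truth intervals round-trip against the inventory
  for (i in seq_len(nrow(p))) {
    n_in <- sum(ref$inventory$context == "CG" &
                  ref$inventory$pos >= p$start[i] &
                  ref$inventory$pos <= p$end[i])
    expect_equal(n_in, p$n_sites[i])
  }
  expect_error(
    plant_dmrs(ref$inventory, n_dmrs = 500, region_len = 5000, seed = 1),
    "disjoint")
})

test_that("count simulation follows Binomial(n, m + (1-m)f)", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(Chr1 = 5000L),
                    conversion_failure = 0)
  ref <- generate_reference(cfg)
  tr1 <- cbind(ref$inventory, m = 1)
  s1 <- simulate_counts(tr1, cfg, seed = 1)
  expect_true(all(s1$n_unmeth == 0))
  tr0 <- cbind(ref$inventory, m = 0)
  s0 <- simulate_counts(tr0, cfg, seed = 1)
  expect_true(all(s0$n_meth == 0))

  # conversion failure alone: pooled methylated fraction ~ f within 3 SE
  cfg_f <- sim_config(seed = 9, chrom_lengths = c(Chr1 = 20000L),
                      conversion_failure = 0.005)
  sf <- simulate_counts(cbind(generate_reference(cfg_f)$inventory, m = 0),
                        cfg_f, seed = 2)
  calls <- sum(sf$n_meth + sf$n_unmeth)
  expect_gt(calls, 1e5)
  frac <- sum(sf$n_meth) / calls
  se <- sqrt(0.005 * 0.995 / calls)
  expect_lt(abs(frac - 0.005), 3 * se)

  expect_error(sim_config(conversion_failure = 1), "conversion_failure")
})

test_that("unplanted empirical methylation matches the context baselines", {
  cfg <- sim_config(seed = 21, chrom_lengths = c(Chr1 = 100000L),
                    conversion_failure = 0)
  ref <- generate_reference(cfg)
  tr <- plant_dmrs(ref$inventory, n_dmrs = 0)
  s <- simulate_counts(tr$truth_A, cfg, seed = 22)
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- s[s$context == ctx, ]
    tot <- sum(sub$n_meth + sub$n_unmeth)
    m <- c(CG = 0.28, CHG = 0.10, CHH = 0.03)[[ctx]]
    se <- sqrt(m * (1 - m) / tot)
    expect_lt(abs(sum(sub$n_meth) / tot - m), 3 * se)
  }
})

test_that("seeds control reproducibility and variation", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(Chr1 = 5000L))
  ref <- generate_reference(cfg)
  tr <- cbind(ref$inventory, m = 0.3)
  expect_identical(simulate_counts(tr, cfg, seed = 7),
                   simulate_counts(tr, cfg, seed = 7))
  s8 <- simulate_counts(tr, cfg, seed = 8)
  expect_false(identical(as.data.frame(simulate_counts(tr, cfg, seed = 7)),
                         as.data.frame(s8)))
})

test_that("the organellar chromosome is methylated only by conversion failure", {
  cfg0 <- sim_config(seed = 2, conversion_failure = 0)
  cc <- simulate_chloroplast(5000, cfg0)
  expect_true(all(cc$n_meth == 0))
  expect_true(all(cc$chrom == "ChrC"))
  empty <- simulate_chloroplast(0, cfg0)
  expect_equal(nrow(empty), 0L)
  expect_error(conversion_rate(empty), "absent")
})

test_that("F2 pools obey Mendelian expectations at the causal locus", {
  cfg <- pool_sim_config(map_length = 100, n_markers = 101,
                         causal_pos = 40, pool_size = 40, seed = 31)
  m <- simulate_f2_pools(cfg)
  expect_equal(nrow(m), 101L)
  expect_true(all(m$allele_high_mut + m$allele_high_wt == 80L))
  expect_true(all(m$allele_norm_mut + m$allele_norm_wt == 80L))
  at_causal <- which(m$pos == 40)
  expect_length(at_causal, 1L)
  # high pool is homozygous mutant at the causal locus by construction
  expect_equal(m$allele_high_mut[at_causal], 80L)
  # normal pool: expected mutant-allele frequency 1/3 under 1:2 WT:het
  f_norm <- m$allele_norm_mut[at_causal] / 80
  expect_lt(abs(f_norm - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 80))
  expect_identical(m, simulate_f2_pools(cfg))
  expect_error(pool_sim_config(causal_pos = 500), "within the map")
  expect_error(pool_sim_config(pool_size = 0), "pool_size")
})
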