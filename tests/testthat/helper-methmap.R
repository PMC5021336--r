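# Fixture builders shared across the suite.

# A methylome sample from compact per-site vectors.
make_sample <- function(pos, n_meth, n_unmeth, context = "CG",
                        chrom = "Chr1", strand = "+",
                        trinucleotide = NULL, sample_id = "fix") {
  if (is.null(trinucleotide))
    trinucleotide <- unname(c(CG = "CGA", CHG = "CAG", CHH = "CAT")[context])
  methylome_sample(data.frame(
    chrom = chrom, pos = pos, strand = strand, n_meth = n_meth,
    n_unmeth = n_unmeth, context = context,
    trinucleotide = trinucleotide, stringsAsFactors = FALSE),
    sample_id = sample_id)
}

# Independent two-sided Fisher oracle: direct enumeration over all tables
# with the observed margins, probabilities from binomial coefficients.
fisher_oracle <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  n1 <- a + b
  m1 <- a + c_
  if (N == 0 || n1 == 0 || n1 == N || m1 == 0 || m1 == N) return(1)
  x <- max(0, m1 - (N - n1)):min(m1, n1)
  logp <- lchoose(n1, x) + lchoose(N - n1, m1 - x) - lchoose(N, m1)
  pr <- exp(logp)
  p_obs <- pr[x == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Independent BH oracle: explicit sort-based step-up with cumulative min.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Base-pair overlap between two interval sets on one chromosome scale.
bp_overlap <- function(a_start, a_end, b_start, b_end) {
  if (!length(a_start) || !length(b_start)) return(0L)
  a <- IRanges::reduce(IRanges::IRanges(a_start, a_end))
  b <- IRanges::reduce(IRanges::IRanges(b_start, b_end))
  sum(IRanges::width(IRanges::intersect(a, b)))
}
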