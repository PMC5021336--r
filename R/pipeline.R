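# Pipeline orchestration: stages chained on files under one run directory,
# with deterministic seeding, a resolved-config record and a manifest.

SUBCOMMANDS <- c("simulate", "qc", "summarize", "profile", "dmr", "dmg",
                 "bsa", "all")

validate_params <- function(p) {
  defaults <- default_params()
  p <- utils::modifyList(defaults, p[names(p) %in% names(defaults)])
  with(p, {
    if (min_coverage < 0) stop_methmap("min_coverage out of range")
    if (window_size < 1) stop_methmap("window_size out of range")
    if (max_fdr <= 0 || max_fdr > 1) stop_methmap("max_fdr out of range")
    if (min_fold_change <= 0) stop_methmap("min_fold_change out of range")
    if (min_covered_fraction < 0 || min_covered_fraction >= 1)
      stop_methmap("min_covered_fraction out of range")
    if (min_dmr_length < 0) stop_methmap("min_dmr_length out of range")
    if (flank < 0) stop_methmap("flank out of range")
    if (bin_size <= 0) stop_methmap("bin_size out of range")
  })
  p
}

require_inputs <- function(paths) {
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths))
    stop_methmap("missing input file(s): ",
                 paste(missing_paths, collapse = ", "))
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages as subcommands chained on files under
#' one output directory:
#' \describe{
#'   \item{simulate}{write synthetic sample CX reports (with an organellar
#'     chromosome), gene GFF3, F2 marker table and the planted truth}
#'   \item{qc}{conversion-rate estimates from the organellar chromosome}
#'   \item{summarize}{context-resolved methylation summaries, genome-wide
#'     and per feature class}
#'   \item{profile}{binned normalized methylation density profiles}
#'   \item{dmr}{sliding-window DMR calling; BED plus per-context window
#'     tables}
#'   \item{dmg}{DMG annotation with region partition}
#'   \item{bsa}{bulk-segregant allele-frequency scan}
#'   \item{all}{everything above in order}
#' }
#' Every run rewrites `config.txt` (the resolved parameters), `run_log.txt`
#' and `manifest.tsv` (files and row counts), and is byte-identical when
#' rerun with the same seed and inputs.
#'
#' @param subcommand One of `simulate`, `qc`, `summarize`, `profile`,
#'   `dmr`, `dmg`, `bsa`, `all`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling every stochastic stage.
#' @param params Named list overriding [default_params()].
#' @param sample_a,sample_b CX report paths (default: the `simulate`
#'   outputs in `out_dir`).
#' @param genes_path GFF3 path (default: simulate output).
#' @param markers_path Marker TSV path (default: simulate output).
#' @param sim Named list of simulation options: chrom_lengths, mean_depth,
#'   conversion_failure, chloroplast_length, n_dmrs, context, m_A, m_B,
#'   min_sites, region_len, n_genes, n_te, pool (a [pool_sim_config()]).
#' @param organellar_chrom Organellar chromosome name (default "ChrC").
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(subcommand, out_dir, seed = 1L,
                         params = list(),
                         sample_a = file.path(out_dir, "sample_A.cx"),
                         sample_b = file.path(out_dir, "sample_B.cx"),
                         genes_path = file.path(out_dir, "genes.gff3"),
                         markers_path = file.path(out_dir, "markers.tsv"),
                         sim = list(), organellar_chrom = "ChrC") {
  if (!subcommand %in% SUBCOMMANDS)
    stop_methmap("unknown subcommand '", subcommand, "'; expected one of: ",
                 paste(SUBCOMMANDS, collapse = ", "))
  p <- validate_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  log_lines <- c(paste0("methmap ", as.character(packageVersion("methmap"))),
                 paste0("subcommand: ", subcommand),
                 paste0("seed: ", seed),
                 paste0("params: ",
                        paste(names(p), unlist(p), sep = "=",
                              collapse = " ")))
  note <- function(name, path, n) {
    written[[name]] <<- path
    log_lines <<- c(log_lines, paste0(basename(path), ": ", n, " rows"))
  }

  stages <- if (subcommand == "all") {
    c("simulate", "qc", "summarize", "profile", "dmr", "dmg", "bsa")
  } else subcommand

  if ("simulate" %in% stages) {
    s <- utils::modifyList(list(
      chrom_lengths = c(Chr1 = 200000L), mean_depth = 30,
      conversion_failure = 0.005, chloroplast_length = 20000L,
      n_dmrs = 4L, context = "CG", m_A = 0.1, m_B = 0.8, min_sites = 12L,
      region_len = 2000L, n_genes = 40L, n_te = 10L,
      pool = pool_sim_config(seed = seed + 10L)), sim)
    cfg <- sim_config(seed = seed, mean_depth = s$mean_depth,
                      conversion_failure = s$conversion_failure,
                      chrom_lengths = s$chrom_lengths)
    pair <- simulate_methylome_pair(cfg, n_dmrs = s$n_dmrs,
                                    context = s$context, m_A = s$m_A,
                                    m_B = s$m_B, min_sites = s$min_sites,
                                    region_len = s$region_len,
                                    chloroplast_length = s$chloroplast_length)
    write_cx_report(pair$sample_A, sample_a)
    note("sample_a", sample_a, nrow(pair$sample_A))
    write_cx_report(pair$sample_B, sample_b)
    note("sample_b", sample_b, nrow(pair$sample_B))
    genes <- generate_genes(s$chrom_lengths, n_genes = s$n_genes,
                            n_te = s$n_te, seed = seed + 20L)
    write_gff3_genes(genes, genes_path)
    note("genes", genes_path, nrow(genes))
    markers <- simulate_f2_pools(s$pool)
    write_marker_table(markers, markers_path)
    note("markers", markers_path, nrow(markers))
    truth_path <- file.path(out_dir, "truth_dmrs.tsv")
    write_tsv_table(pair$truth$planted, truth_path)
    note("truth_dmrs", truth_path, nrow(pair$truth$planted))
  }

  if (any(c("qc", "summarize", "profile", "dmr") %in% stages))
    require_inputs(c(sample_a, sample_b))

  samples <- NULL
  load_samples <- function() {
    if (is.null(samples))
      samples <<- list(A = read_cx_report(sample_a, "sample_A"),
                       B = read_cx_report(sample_b, "sample_B"))
    samples
  }

  if ("qc" %in% stages) {
    ss <- load_samples()
    qc <- data.frame(
      sample = c("sample_A", "sample_B"),
      conversion_rate_pct = c(
        conversion_rate(ss$A, organellar_chrom),
        conversion_rate(ss$B, organellar_chrom)),
      stringsAsFactors = FALSE)
    path <- file.path(out_dir, "qc.tsv")
    write_tsv_table(qc, path)
    note("qc", path, nrow(qc))
  }

  if ("summarize" %in% stages) {
    ss <- load_samples()
    require_inputs(genes_path)
    genes <- read_gff3_genes(genes_path)
    rows <- list()
    for (nm in names(ss)) {
      nuclear <- as.data.frame(ss[[nm]])
      nuclear <- methylome_sample(
        nuclear[nuclear$chrom != organellar_chrom, , drop = FALSE])
      for (scope in c("genome", "gene", "transposable_element")) {
        cs <- if (scope == "genome") {
          context_summary(nuclear, min_coverage = p$min_coverage)
        } else {
          context_summary(nuclear, features = genes, feature_class = scope,
                          min_coverage = p$min_coverage)
        }
        rows[[length(rows) + 1L]] <-
          cbind(sample = paste0("sample_", nm), scope = scope, cs)
      }
    }
    summary_df <- do.call(rbind, rows)
    path <- file.path(out_dir, "summary.tsv")
    write_tsv_table(summary_df, path)
    note("summary", path, nrow(summary_df))
  }

  if ("profile" %in% stages) {
    ss <- load_samples()
    prof <- rbind(
      cbind(sample = "sample_A",
            density_profile(ss$A, bin_size = p$bin_size,
                            min_coverage = p$min_coverage)),
      cbind(sample = "sample_B",
            density_profile(ss$B, bin_size = p$bin_size,
                            min_coverage = p$min_coverage)))
    path <- file.path(out_dir, "profile.tsv")
    write_tsv_table(prof, path)
    note("profile", path, nrow(prof))
  }

  dmr_path <- file.path(out_dir, "dmrs.tsv")
  if ("dmr" %in% stages) {
    ss <- load_samples()
    res <- call_dmrs(ss$A, ss$B, min_coverage = p$min_coverage,
                     window_size = p$window_size, max_fdr = p$max_fdr,
                     min_fold_change = p$min_fold_change,
                     min_covered_fraction = p$min_covered_fraction,
                     min_dmr_length = p$min_dmr_length,
                     exclude_chroms = organellar_chrom)
    bed_path <- file.path(out_dir, "dmrs.bed")
    write_dmr_bed(res$dmrs, bed_path)
    note("dmrs_bed", bed_path, nrow(res$dmrs))
    write_tsv_table(res$dmrs, dmr_path)
    note("dmrs", dmr_path, nrow(res$dmrs))
    for (ctx in names(res$windows)) {
      wp <- file.path(out_dir, paste0("windows_", ctx, ".tsv"))
      write_window_table(res$windows[[ctx]], wp)
      note(paste0("windows_", ctx), wp, nrow(res$windows[[ctx]]))
    }
  }

  if ("dmg" %in% stages) {
    require_inputs(c(dmr_path, genes_path))
    dmrs <- read_tsv_table(dmr_path)
    genes <- read_gff3_genes(genes_path)
    ann <- annotate_dmgs(dmrs, genes, flank = p$flank)
    path <- file.path(out_dir, "dmgs.tsv")
    write_tsv_table(ann$dmgs, path)
    note("dmgs", path, nrow(ann$dmgs))
    part <- region_partition(ann$dmgs)
    ppath <- file.path(out_dir, "dmg_partition.tsv")
    write_tsv_table(part, ppath)
    note("dmg_partition", ppath, nrow(part))
  }

  if ("bsa" %in% stages) {
    require_inputs(markers_path)
    markers <- read_marker_table(markers_path)
    scan <- bsa_scan(markers)
    path <- file.path(out_dir, "bsa_profile.tsv")
    write_tsv_table(scan$profile, path)
    note("bsa_profile", path, nrow(scan$profile))
    ipath <- file.path(out_dir, "bsa_intervals.tsv")
    write_tsv_table(scan$intervals, ipath)
    note("bsa_intervals", ipath, nrow(scan$intervals))
  }

  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(c(paste0("subcommand=", subcommand), paste0("seed=", seed),
               paste(names(p), unlist(p), sep = "=")), cfg_path)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  manifest <- data.frame(file = basename(unlist(written)),
                         stringsAsFactors = FALSE)
  write_tsv_table(manifest[order(manifest$file), , drop = FALSE],
                  file.path(out_dir, "manifest.tsv"))
  invisible(written)
}
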