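# Readers and writers: CX-style cytosine reports, GFF3 gene models,
# BED6 DMRs, window and marker tables. All text, UTF-8, tab-delimited;
# TSV tables carry one header line starting with "#".

CX_COLS <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context",
             "trinucleotide")

#' Construct a methylome sample
#'
#' One WGBS sample: strand-specific per-cytosine methylated/unmethylated
#' read counts with sequence context. Records are validated and sorted by
#' (chrom, pos, strand) with "+" before "-".
#'
#' @param records Data.frame with columns chrom, pos, strand, n_meth,
#'   n_unmeth, context, trinucleotide.
#' @param sample_id,genotype,tissue Metadata labels.
#' @return Data.frame of class `methylome_sample` with attributes
#'   `sample_id`, `genotype`, `tissue`.
#' @export
methylome_sample <- function(records, sample_id = "sample",
                             genotype = NA_character_,
                             tissue = NA_character_) {
  missing_cols <- setdiff(CX_COLS, names(records))
  if (length(missing_cols))
    stop_methmap("missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, CX_COLS]
  if (nrow(records)) {
    if (any(records$n_meth < 0 | records$n_unmeth < 0))
      stop_methmap("negative read counts")
    if (!all(records$context %in% CONTEXTS))
      stop_methmap("unknown context token: ",
                   paste(unique(setdiff(records$context, CONTEXTS)),
                         collapse = ", "))
    if (!all(records$strand %in% c("+", "-")))
      stop_methmap("strand must be '+' or '-'")
    key <- paste(records$chrom, records$pos, records$strand)
    if (anyDuplicated(key))
      stop_methmap("duplicate (chrom, pos, strand) records: ",
                   key[which(duplicated(key))[1]])
    records <- records[order(records$chrom, records$pos, records$strand), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  structure(records, class = c("methylome_sample", "data.frame"),
            sample_id = sample_id, genotype = genotype, tissue = tissue)
}

#' Read a CX-style cytosine report
#'
#' Parses the 7-column tab-separated cytosine report dialect
#' (chrom, 1-based position, strand, methylated count, unmethylated count,
#' context, trinucleotide). Malformed rows abort with their line numbers;
#' both covered and uncovered cytosines are allowed.
#'
#' @param path File path.
#' @param sample_id Sample label (defaults to the file name).
#' @return A [methylome_sample()], sorted on load.
#' @export
read_cx_report <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop_methmap("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || all(!nzchar(lines))) {
    warning("empty cytosine report: ", path)
    return(methylome_sample(
      data.frame(chrom = character(), pos = integer(), strand = character(),
                 n_meth = integer(), n_unmeth = integer(),
                 context = character(), trinucleotide = character(),
                 stringsAsFactors = FALSE),
      sample_id = sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop_methmap("malformed rows (expected 7 tab-separated fields) at ",
                 "line(s): ", paste(utils::head(bad, 10), collapse = ", "))
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  n_meth <- suppressWarnings(as.integer(m[, 4]))
  n_unmeth <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad))
    stop_methmap("non-numeric pos/counts at line(s): ",
                 paste(utils::head(bad, 10), collapse = ", "))
  rec <- data.frame(chrom = m[, 1], pos = pos, strand = m[, 3],
                    n_meth = n_meth, n_unmeth = n_unmeth, context = m[, 6],
                    trinucleotide = m[, 7], stringsAsFactors = FALSE)
  methylome_sample(rec, sample_id = sample_id)
}

#' Write a CX-style cytosine report
#'
#' @param sample A [methylome_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cx_report <- function(sample, path) {
  write.table(as.data.frame(sample)[, CX_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene and transposable-element models from GFF3
#'
#' Keeps features typed `gene` or `transposable_element`; all other feature
#' types are ignored (with a warning if nothing remains). Rows with
#' start > end are rejected individually with a message; 1-based inclusive
#' coordinates are preserved.
#'
#' @param path GFF3 file path.
#' @return Data.frame of gene models (gene_id, chrom, strand, start, end,
#'   feature_class).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop_methmap("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), feature_class = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) {
    warning("no gene or transposable_element features in ", path)
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  if (any(!ok))
    warning(sum(!ok), " malformed GFF3 row(s) dropped")
  fields <- fields[ok]
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  keep <- m[, 3] %in% c("gene", "transposable_element")
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) {
    warning("no gene or transposable_element features in ", path)
    return(empty)
  }
  start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad)) {
    warning("rejecting ", length(bad),
            " row(s) with start > end or non-numeric coordinates")
    m <- m[-bad, , drop = FALSE]
    start <- start[-bad]; end <- end[-bad]
  }
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  no_id <- !grepl("ID=", m[, 9])
  ids[no_id] <- sprintf("feature_%d", which(no_id))
  data.frame(gene_id = ids, chrom = m[, 1], strand = m[, 7],
             start = start, end = end, feature_class = m[, 3],
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model data.frame as returned by [generate_genes()] or
#'   [read_gff3_genes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tmethmap\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$feature_class, genes$start,
                       genes$end, genes$strand, genes$gene_id), con)
  }
  invisible(path)
}

#' Write DMRs as BED6
#'
#' Coordinates convert from 1-based inclusive to BED's 0-based half-open.
#' The name field is "context:direction"; the score is
#' `min(1000, round(-10 log10(adjusted p)))`.
#'
#' @param dmrs DMR data.frame from [call_dmrs()] / [merge_to_dmrs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- if (nrow(dmrs)) {
    pmin(1000, round(-10 * log10(pmax(dmrs$best_p_adj, 1e-300))))
  } else numeric(0)
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = paste0(dmrs$context, ":", dmrs$direction),
                    score = score, strand = rep(".", nrow(dmrs)),
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Generic headered-TSV writer: one header line beginning "#".
write_tsv_table <- function(df, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

read_tsv_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- tryCatch(
    read.delim(path, header = FALSE, skip = 1L, sep = "\t",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df)) {
    df <- as.data.frame(setNames(
      rep(list(character(0)), length(strsplit(header, "\t")[[1]])),
      strsplit(header, "\t")[[1]]))
    return(df)
  }
  names(df) <- strsplit(header, "\t")[[1]]
  df
}

#' Write the per-window test table
#'
#' TSV carrying, per window: coordinates, pooled counts, methylation levels,
#' fold change, covered-site fraction, raw and adjusted p, direction and
#' pass flag.
#'
#' @param tests Window-test data.frame from [test_windows()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_table <- function(tests, path) {
  cols <- c("chrom", "context", "start", "end", "M_a", "U_a", "M_b", "U_b",
            "covered_fraction", "level_a", "level_b", "fold_change",
            "p", "p_adj", "direction", "pass")
  write_tsv_table(as.data.frame(tests)[, cols], path)
}

#' Read / write a marker allele-count table
#'
#' TSV with columns chrom, pos, allele_high_mut, allele_high_wt,
#' allele_norm_mut, allele_norm_wt (per-pool counts of mutant-parent and
#' wild-parent alleles).
#'
#' @param path File path.
#' @return `read_marker_table`: data.frame of class `marker_table`.
#' @export
read_marker_table <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "pos", "allele_high_mut", "allele_high_wt",
            "allele_norm_mut", "allele_norm_wt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_methmap("marker table missing columns: ",
                 paste(missing_cols, collapse = ", "))
  counts <- df[, need[-(1:2)]]
  if (any(counts < 0)) stop_methmap("negative allele counts")
  class(df) <- c("marker_table", "data.frame")
  df
}

#' @rdname read_marker_table
#' @param markers Marker data.frame.
#' @export
write_marker_table <- function(markers, path) {
  write_tsv_table(as.data.frame(markers), path)
}
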