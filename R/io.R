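#' Read a gene-level expression TSV
#'
#' Expected layout: first column = gene ID, header row = sample IDs,
#' remaining columns = FPKM values.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (any(m < 0)) stop("negative FPKM values in ", path)
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene IDs in ", path)
  m
}

#' @rdname read_expression_matrix
#' @param matrix genes x samples matrix to write.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet (sample, condition, replicate)
#'
#' @param path CSV file path.
#' @return data.frame with at least `sample` and `condition` columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition")
  if (!all(need %in% names(df))) {
    stop(path, " must carry columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in ", path)
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe count CSV (probe_id, class, one column per lane)
#'
#' @param path CSV path.
#' @param sheet sample sheet covering the lane columns.
#' @return a [probe_count_table()].
#' @export
read_probe_counts <- function(path, sheet) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "class") %in% names(df))) {
    stop(path, " must carry columns probe_id and class before the lane columns")
  }
  counts <- as.matrix(df[, setdiff(names(df), c("probe_id", "class")), drop = FALSE])
  rownames(counts) <- df$probe_id
  probe_count_table(counts, df$class, sheet)
}

#' @rdname read_probe_counts
#' @param table a `probe_count_table` to write.
#' @export
write_probe_counts <- function(table, path) {
  df <- data.frame(probe_id = rownames(table$counts), class = table$probe_class,
                   table$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Bismark's coverage dialect is tab-separated with 1-based inclusive
#' coordinates: chrom, start, end, percent methylation, count methylated,
#' count unmethylated. Positions are converted to the package's internal
#' 0-based convention on read.
#'
#' @param path coverage file path.
#' @return data.frame: `chrom`, `pos` (0-based), `coverage`, `n_meth`,
#'   `freq`.
#' @export
read_bismark_cov <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) {
    stop(path, ": expected the 6-column Bismark coverage dialect ",
         "(chrom, start, end, %meth, count_meth, count_unmeth)")
  }
  names(df)[1:6] <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
  cov <- df$n_meth + df$n_unmeth
  out <- data.frame(chrom = as.character(df$chrom), pos = df$start - 1,
                    coverage = cov, n_meth = df$n_meth, freq = df$n_meth / cov,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' @rdname read_bismark_cov
#' @param calls data.frame with `chrom`, `pos` (0-based), `coverage`,
#'   `n_meth` to write in the Bismark dialect.
#' @export
write_bismark_cov <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$pos + 1,
                   end = calls$pos + 1,
                   pct = round(100 * calls$n_meth / calls$coverage, 4),
                   n_meth = calls$n_meth,
                   n_unmeth = calls$coverage - calls$n_meth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED6 gene models (0-based half-open)
#'
#' @param path BED file path.
#' @return data.frame: `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop(path, ": expected 6 BED columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(df$start >= df$end)) stop(path, ": BED intervals need start < end")
  df[, 1:6]
}

#' @rdname read_bed6
#' @param genes data.frame of gene models to write.
#' @export
write_bed6 <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an externally produced DE list (gene, log2fc, p, q)
#'
#' Accepts a tab-separated table so DE results from any engine can be fed to
#' the overlap/concordance analyses in place of the built-in one.
#'
#' @param path TSV path with header columns `gene` (or `feature_id`),
#'   `log2fc`, `p`, `q`.
#' @param q_threshold significance cutoff applied to `q`.
#' @return a `de_table`.
#' @export
read_de_table <- function(path, q_threshold = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("gene", "feature_id", "probe_id"), names(df))[1]
  if (is.na(idcol) || !all(c("log2fc", "p", "q") %in% names(df))) {
    stop(path, " must carry columns gene/feature_id, log2fc, p, q")
  }
  out <- data.frame(feature_id = as.character(df[[idcol]]), log2fc = df$log2fc,
                    p = df$p, q = df$q, significant = df$q <= q_threshold,
                    direction = sign(df$log2fc), stringsAsFactors = FALSE)
  attr(out, "pool") <- out$feature_id
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Produces `expression.tsv`, `samples.csv`, `mirna_counts.csv`, one
#' `<sample>.cov` Bismark coverage file per sample, `genes.bed`, and a
#' `truth.json` sidecar recording all planted structure.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(bundle$expression$matrix, file.path(dir, "expression.tsv"))
  write_sample_sheet(bundle$expression$samples, file.path(dir, "samples.csv"))
  write_probe_counts(bundle$mirna$table, file.path(dir, "mirna_counts.csv"))
  for (s in names(bundle$methylation$samples)) {
    write_bismark_cov(bundle$methylation$samples[[s]],
                      file.path(dir, paste0(s, ".cov")))
  }
  write_bed6(bundle$methylation$genes, file.path(dir, "genes.bed"))
  truth <- list(
    config = unclass(bundle$config),
    expression = lapply(bundle$expression$truth, unclass),
    mirna = lapply(bundle$mirna$truth, unclass),
    methylation = lapply(bundle$methylation$truth, unclass))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir directory produced by [write_bundle()] (or hand-assembled real
#'   data in the same layout; `truth.json` is optional).
#' @return list with `expression` (`matrix`, `samples`), `mirna` (`table`),
#'   `methylation` (`samples`, `genes`), and `truth` when present.
#' @export
read_bundle <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  mat <- read_expression_matrix(file.path(dir, "expression.tsv"))
  tab <- read_probe_counts(file.path(dir, "mirna_counts.csv"), sheet)
  cov_files <- file.path(dir, paste0(sheet$sample, ".cov"))
  meth <- lapply(cov_files, read_bismark_cov)
  names(meth) <- sheet$sample
  genes <- read_bed6(file.path(dir, "genes.bed"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(expression = list(matrix = mat, samples = sheet),
       mirna = list(table = tab, samples = sheet),
       methylation = list(samples = meth, sheet = sheet, genes = genes),
       truth = truth)
}
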