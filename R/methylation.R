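#' Filter CpG site calls by coverage
#'
#' Per sample: sites with coverage at or below `min_coverage_exclusive` are
#' dropped (the "coverage > 5X" rule); then the `ceiling(top_coverage_fraction
#' * n_kept)` highest-coverage sites are dropped (PCR-artefact guard), with
#' coverage ties broken by position, descending; finally any blacklisted
#' positions (e.g. positions confounded by genetic variation) are removed
#' from every sample.
#'
#' @param samples named list of per-sample data.frames with columns `chrom`,
#'   `pos`, `coverage`, `n_meth` (and optionally `freq`).
#' @param min_coverage_exclusive strict coverage floor (keep `coverage >`
#'   this; default 5).
#' @param top_coverage_fraction fraction of kept sites removed from the top
#'   of the coverage distribution (default 0.001, the top 0.1%).
#' @param blacklist optional data.frame (`chrom`, `pos`) of positions to drop
#'   everywhere.
#' @return the filtered list of per-sample data.frames (with `freq`
#'   recomputed).
#' @export
filter_sites <- function(samples, min_coverage_exclusive = 5,
                         top_coverage_fraction = 0.001, blacklist = NULL) {
  lapply(samples, function(s) {
    s <- s[s$coverage > min_coverage_exclusive, , drop = FALSE]
    n_kept <- nrow(s)
    if (n_kept > 0 && top_coverage_fraction > 0) {
      n_drop <- ceiling(top_coverage_fraction * n_kept)
      ord <- order(-s$coverage, s$chrom, -s$pos)
      s <- s[-ord[seq_len(n_drop)], , drop = FALSE]
    }
    if (!is.null(blacklist) && nrow(blacklist) > 0) {
      key <- paste(s$chrom, s$pos)
      s <- s[!(key %in% paste(blacklist$chrom, blacklist$pos)), , drop = FALSE]
    }
    s$freq <- s$n_meth / s$coverage
    rownames(s) <- NULL
    s
  })
}

#' CpG positions present in every sample
#'
#' The cluster universe for a comparison: positions that survived filtering
#' in all samples being compared, so every cluster has a methylation
#' frequency in every sample.
#'
#' @param samples list of per-sample site data.frames.
#' @return data.frame (`chrom`, `pos`), sorted.
#' @export
common_sites <- function(samples) {
  keys <- lapply(samples, function(s) paste(s$chrom, s$pos))
  shared <- Reduce(intersect, keys)
  first <- samples[[1]]
  out <- first[paste(first$chrom, first$pos) %in% shared, c("chrom", "pos")]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call CpG clusters with the 50 bp rule
#'
#' Maximal runs of CpG sites in which consecutive positions are at most
#' `max_gap` bp apart; runs with fewer than `min_sites` sites are discarded.
#' Output clusters are sorted and non-overlapping, and every retained site
#' belongs to exactly one cluster.
#'
#' @param sites data.frame (`chrom`, `pos`) of the site universe, sorted and
#'   unique within chromosome.
#' @param max_gap maximum joining distance in bp (default 50; a gap of
#'   exactly 50 joins, 51 does not).
#' @param min_sites minimum sites per cluster (default 2).
#' @return list with `clusters` (data.frame `cluster_id`, `chrom`, `start`,
#'   `end` (0-based half-open over the member sites), `n_sites`) and `sites`
#'   (data.frame `cluster_id`, `chrom`, `pos` for every clustered site).
#' @export
call_clusters <- function(sites, max_gap = 50, min_sites = 2) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  parts <- split(sites$pos, sites$chrom)
  clus_list <- list(); site_list <- list()
  counter <- 0L
  for (chrom in names(parts)) {
    pos <- parts[[chrom]]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions must be sorted and unique within each chromosome")
    }
    if (length(pos) == 0) next
    run <- cumsum(c(0L, diff(pos) > max_gap))
    for (r in split(pos, run)) {
      if (length(r) < min_sites) next
      counter <- counter + 1L
      id <- sprintf("cluster_%05d", counter)
      clus_list[[counter]] <- data.frame(
        cluster_id = id, chrom = chrom, start = min(r), end = max(r) + 1,
        n_sites = length(r), stringsAsFactors = FALSE)
      site_list[[counter]] <- data.frame(
        cluster_id = id, chrom = chrom, pos = r, stringsAsFactors = FALSE)
    }
  }
  clusters <- if (counter) do.call(rbind, clus_list) else
    data.frame(cluster_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_sites = integer(0))
  site_map <- if (counter) do.call(rbind, site_list) else
    data.frame(cluster_id = character(0), chrom = character(0), pos = numeric(0))
  rownames(clusters) <- rownames(site_map) <- NULL
  list(clusters = clusters, sites = site_map)
}

# sites x samples frequency matrix over the common site universe
freq_matrix <- function(samples, sites) {
  key <- paste(sites$chrom, sites$pos)
  mat <- vapply(samples, function(s) {
    idx <- match(key, paste(s$chrom, s$pos))
    if (anyNA(idx)) stop("a sample is missing sites of the common universe")
    s$freq[idx]
  }, numeric(length(key)))
  rownames(mat) <- key
  mat
}

#' Per-cluster differential methylation t-tests
#'
#' For each cluster, the observations are the per-site per-sample methylation
#' frequencies pooled within each group (the default "site" mode); a Welch
#' t-test compares the two groups. The alternative "site_mean" mode first
#' averages each site across the cluster within a sample, testing per-sample
#' cluster means instead.
#'
#' @param clustering output of [call_clusters()].
#' @param samples filtered per-sample site data.frames (all carrying every
#'   clustered site).
#' @param group_a,group_b character vectors of sample names.
#' @param value_mode `"site"` (pool site x sample frequencies) or
#'   `"site_mean"` (per-sample cluster means).
#' @return data.frame of class `cluster_tests`: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_sites`, `mean_freq_a`, `mean_freq_b`, `delta`
#'   (A - B), `t`, `df`, `p`.
#' @export
test_clusters <- function(clustering, samples, group_a, group_b,
                          value_mode = c("site", "site_mean")) {
  value_mode <- match.arg(value_mode)
  stopifnot(all(c(group_a, group_b) %in% names(samples)))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples")
  }
  cl <- clustering$clusters
  sm <- clustering$sites
  if (nrow(cl) == 0) {
    return(structure(cbind(cl, mean_freq_a = numeric(0), mean_freq_b = numeric(0),
                           delta = numeric(0), t = numeric(0), df = numeric(0),
                           p = numeric(0)),
                     class = c("cluster_tests", "data.frame")))
  }
  fm <- freq_matrix(samples[c(group_a, group_b)], sm)
  idx <- match(sm$cluster_id, cl$cluster_id)
  group_stats <- function(cols) {
    x <- fm[, cols, drop = FALSE]
    if (value_mode == "site_mean") {
      x <- matrix(vapply(seq_len(ncol(x)),
                         function(j) tapply(x[, j], idx, mean),
                         numeric(nrow(cl))),
                  nrow = nrow(cl))
      n <- rep(ncol(x), nrow(cl))
      m <- rowMeans(x)
      v <- rowSums((x - m)^2) / (n - 1)
    } else {
      n <- cl$n_sites * length(cols)
      s1 <- rowsum(rowSums(x), idx)[, 1]
      s2 <- rowsum(rowSums(x^2), idx)[, 1]
      m <- s1 / n
      v <- (s2 - n * m^2) / (n - 1)
      v <- pmax(v, 0)
    }
    list(n = n, m = m, v = v)
  }
  ga <- group_stats(group_a); gb <- group_stats(group_b)
  delta <- ga$m - gb$m
  se2 <- ga$v / ga$n + gb$v / gb$n
  df <- se2^2 / ((ga$v / ga$n)^2 / (ga$n - 1) + (gb$v / gb$n)^2 / (gb$n - 1))
  tstat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  deg <- se2 == 0
  if (any(deg)) {
    zd <- deg & delta == 0; tstat[zd] <- 0; p[zd] <- 1
    id <- deg & delta != 0; tstat[id] <- sign(delta[id]) * Inf; p[id] <- 0
    df[deg] <- ga$n[deg] + gb$n[deg] - 2
  }
  out <- cbind(cl, mean_freq_a = ga$m, mean_freq_b = gb$m, delta = delta,
               t = tstat, df = df, p = p)
  rownames(out) <- NULL
  class(out) <- c("cluster_tests", "data.frame")
  out
}

#' Flag genome-wide significant clusters
#'
#' Bonferroni (default): flag clusters with `p <= alpha / m` over the `m`
#' tested clusters. BH: flag clusters with BH q-value `<= alpha`. The method
#' and alpha are deliberate, logged run parameters.
#'
#' @param results a `cluster_tests` data.frame.
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha significance level (default 0.05).
#' @return `results` with added columns `genome_wide_significant` (logical)
#'   and, for BH, `q`.
#' @export
significant_clusters <- function(results, method = c("bonferroni", "bh"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  m <- nrow(results)
  if (method == "bonferroni") {
    results$genome_wide_significant <- if (m) results$p <= alpha / m else logical(0)
  } else {
    results$q <- bh_fdr(results$p)
    results$genome_wide_significant <- results$q <= alpha
  }
  attr(results, "significance") <- list(method = method, alpha = alpha, m = m)
  results
}

cluster_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Hypergeometric overlap of significant clusters between two analyses
#'
#' Two clusters overlap when their genomic intervals share at least one base.
#' The test draws from the universe of all tested clusters: `N` = number of
#' tested clusters, `K` = significant in analysis A, `n` = significant in
#' analysis B, `k` = A-side significant clusters overlapping any B-side one.
#'
#' @param sig_a,sig_b data.frames of significant clusters (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param universe data.frame of all tested clusters.
#' @return an `overlap_result` (with `intersection_ids` = overlapping A-side
#'   cluster IDs when available).
#' @export
cluster_overlap <- function(sig_a, sig_b, universe) {
  N <- nrow(universe); K <- nrow(sig_a); n <- nrow(sig_b)
  k <- 0L; ids <- character(0)
  if (K > 0 && n > 0) {
    hits <- GenomicRanges::countOverlaps(cluster_granges(sig_a),
                                         cluster_granges(sig_b))
    k <- sum(hits > 0)
    if ("cluster_id" %in% names(sig_a)) ids <- sig_a$cluster_id[hits > 0]
  }
  res <- list(pool_size = N, set_a_size = K, set_b_size = n,
              intersection_size = k,
              p_hyper = hypergeometric_tail(N, K, n, min(k, n)),
              intersection_ids = ids)
  class(res) <- "overlap_result"
  res
}

#' Map clusters to genes through strand-aware flanking windows
#'
#' A cluster links to a gene when it intersects the gene body extended by
#' `upstream` bp on the 5' side and `downstream` bp on the 3' side - for a
#' plus-strand gene `[start - upstream, end + downstream)`, for a minus-strand
#' gene `[start - downstream, end + upstream)`. A cluster may link to several
#' genes.
#'
#' @param clusters data.frame (`cluster_id`, `chrom`, `start`, `end`),
#'   0-based half-open.
#' @param genes BED6-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`), 0-based half-open.
#' @param upstream,downstream flank sizes in bp (defaults 5000 and 2000).
#' @return data.frame of links: `cluster_id`, `gene_id`, plus the window
#'   coordinates used.
#' @export
map_clusters_to_genes <- function(clusters, genes, upstream = 5000,
                                  downstream = 2000) {
  if (nrow(clusters) == 0 || nrow(genes) == 0) {
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      window_start = numeric(0), window_end = numeric(0)))
  }
  plus <- genes$strand != "-"
  win_start <- ifelse(plus, genes$start - upstream, genes$start - downstream)
  win_end <- ifelse(plus, genes$end + downstream, genes$end + upstream)
  win_start <- pmax(win_start, 0)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(start = win_start + 1,
                                                      end = win_end))
  gr_clus <- cluster_granges(clusters)
  hits <- GenomicRanges::findOverlaps(gr_clus, gr_genes)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(cluster_id = clusters$cluster_id[qi],
             gene_id = genes$name[si],
             window_start = win_start[si], window_end = win_end[si],
             stringsAsFactors = FALSE)
}

#' Mean methylation frequency per cluster in a sample group
#'
#' @param clustering output of [call_clusters()].
#' @param samples filtered per-sample site data.frames.
#' @param group character vector of sample names.
#' @return named numeric vector: mean of the site x sample frequencies of
#'   each cluster over the group.
#' @export
cluster_mean_freqs <- function(clustering, samples, group) {
  fm <- freq_matrix(samples[group], clustering$sites)
  idx <- clustering$sites$cluster_id
  out <- rowsum(rowMeans(fm), idx)[, 1]
  out[clustering$clusters$cluster_id]
}

#' Correlate knockdown cluster methylation with two reference states
#'
#' Over a common cluster set (typically the clusters significant in both the
#' knockdown and the cell-state analysis), correlates the knockdown mean
#' methylation frequencies with a proliferating-reference vector and with a
#' differentiating-reference vector. A higher correlation with the
#' differentiating reference indicates the knockdown methylome resembles the
#' differentiating state more closely.
#'
#' @param kd_freqs,ref_freqs_a,ref_freqs_b equal-length numeric vectors of
#'   per-cluster mean methylation frequencies (A = first reference, e.g.
#'   proliferating; B = second, e.g. differentiating).
#' @return list: `r_a`, `p_a`, `r_b`, `p_b`, `n`, `defined`.
#' @export
cluster_state_correlation <- function(kd_freqs, ref_freqs_a, ref_freqs_b) {
  if (length(kd_freqs) != length(ref_freqs_a) ||
      length(kd_freqs) != length(ref_freqs_b)) {
    stop("the three frequency vectors must cover the same clusters")
  }
  ca <- pearson_with_p(kd_freqs, ref_freqs_a)
  cb <- pearson_with_p(kd_freqs, ref_freqs_b)
  list(r_a = ca$r, p_a = ca$p, r_b = cb$r, p_b = cb$p,
       n = length(kd_freqs), defined = ca$defined && cb$defined)
}
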