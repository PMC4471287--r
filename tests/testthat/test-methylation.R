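site_df <- function(pos, coverage, n_meth = round(coverage * 0.5), chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, coverage = coverage, n_meth = n_meth,
             freq = n_meth / coverage, stringsAsFactors = FALSE)
}

test_that("site filtering applies the strict coverage floor and ceiling rule", {
  s <- site_df(c(10, 20, 30), c(3, 6, 10))
  f <- filter_sites(list(a = s), top_coverage_fraction = 0)
  expect_equal(f$a$coverage, c(6, 10))   # coverage > 5, strictly

  # 1000 kept sites -> exactly ceiling(1) = 1 removed, the highest coverage
  s2 <- site_df(seq_len(1000) * 100, c(rep(10, 999), 99))
  f2 <- filter_sites(list(a = s2))
  expect_equal(nrow(f2$a), 999)
  expect_false(99 %in% f2$a$coverage)

  # 999 kept sites -> still 1 removed (ceiling of 0.999)
  f3 <- filter_sites(list(a = s2[-1, ]))
  expect_equal(nrow(f3$a), 998)

  # coverage ties broken by position, descending
  s4 <- site_df(c(100, 200, 300), rep(50, 3))
  f4 <- filter_sites(list(a = s4))
  expect_equal(f4$a$pos, c(100, 200))

  # blacklist positions vanish from every sample
  bl <- data.frame(chrom = "chr1", pos = 200)
  f5 <- filter_sites(list(a = s4, b = s4), top_coverage_fraction = 0,
                     blacklist = bl)
  expect_equal(f5$a$pos, c(100, 300))
  expect_equal(f5$b$pos, c(100, 300))
})

test_that("shipped coverage fixture filters to hand-verified counts", {
  path <- system.file("extdata", "cpg_toy.cov", package = "convergeomics")
  calls <- read_bismark_cov(path)
  expect_equal(nrow(calls), 1000)
  expect_true(all(calls$coverage > 5))
  expect_equal(calls$pos, sort(calls$pos))       # 0-based, sorted
  f <- filter_sites(list(s = calls))
  expect_equal(nrow(f$s), 999)                   # ceiling(0.001 * 1000) = 1
  expect_false(4235 %in% f$s$pos)                # the unique max-coverage site
  f2 <- filter_sites(list(s = calls[-1, ]))      # 999 sites in
  expect_equal(nrow(f2$s), 998)
})

test_that("bismark coverage files round-trip through the 1-based dialect", {
  path <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr2\t101\t101\t75\t3\t1", "chr2\t151\t151\t0\t0\t5"), path)
  calls <- read_bismark_cov(path)
  expect_equal(calls$pos, c(100, 150))   # converted to 0-based
  expect_equal(calls$coverage, c(4, 5))
  expect_equal(calls$freq, c(0.75, 0))
  out <- withr::local_tempfile(fileext = ".cov")
  write_bismark_cov(calls, out)
  expect_equal(read_bismark_cov(out), calls)
  bad <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t100\t100", bad)
  expect_error(read_bismark_cov(bad), "dialect")
})

test_that("cluster calling follows the 50 bp rule with exact boundaries", {
  cl <- call_clusters(data.frame(chrom = "chr1", pos = c(100, 130, 175, 300, 340)))
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$start, c(100, 300))
  expect_equal(cl$clusters$end, c(176, 341))
  expect_equal(cl$clusters$n_sites, c(3, 2))

  # single site: below min_sites
  expect_equal(nrow(call_clusters(data.frame(chrom = "chr1", pos = 100))$clusters), 0)
  # gap of exactly 50 joins, 51 does not
  expect_equal(nrow(call_clusters(data.frame(chrom = "chr1", pos = c(100, 150)))$clusters), 1)
  expect_equal(nrow(call_clusters(data.frame(chrom = "chr1", pos = c(100, 151)))$clusters), 0)
  expect_error(call_clusters(data.frame(chrom = "chr1", pos = c(5, 2))), "sorted")
})

test_that("cluster calling matches the naive pairwise-linkage oracle", {
  set.seed(99)
  for (i in 1:300) {
    pos <- if (i %% 2 == 0) {
      sort(sample.int(2000, sample(5:40, 1)))
    } else {  # clustered placements
      n_cl <- sample(2:6, 1)
      sort(unique(unlist(lapply(seq_len(n_cl), function(j) {
        start <- j * 500 + sample.int(100, 1)
        start + cumsum(sample.int(60, sample(2:6, 1)))
      }))))
    }
    got <- clusters_as_list(call_clusters(data.frame(chrom = "c", pos = pos)))
    want <- cluster_oracle(pos)
    expect_identical(got, want)
  }
})

test_that("clusters partition retained sites and commute with chrom splitting", {
  sim <- simulate_methylome(tiny_config(55, n_cpg_sites = 2000))
  sites <- common_sites(filter_sites(sim$samples))
  whole <- call_clusters(sites)
  # each clustered site belongs to exactly one cluster
  expect_false(anyDuplicated(paste(whole$sites$chrom, whole$sites$pos)) > 0)
  # per-chromosome processing gives the same clusters
  per <- lapply(split(sites, sites$chrom), call_clusters)
  n_per <- sum(vapply(per, function(x) nrow(x$clusters), 1L))
  expect_equal(nrow(whole$clusters), n_per)
  for (chrom in names(per)) {
    w <- whole$clusters[whole$clusters$chrom == chrom, c("start", "end")]
    p <- per[[chrom]]$clusters[, c("start", "end")]
    rownames(w) <- rownames(p) <- NULL
    expect_equal(w, p)
  }
})

test_that("per-cluster t-tests recover a strong planted difference", {
  pos <- c(100, 120, 140, 160, 180)
  mk <- function(freqs) site_df(pos, coverage = 100, n_meth = round(100 * freqs))
  set.seed(1)
  samples <- c(lapply(1:4, function(i) mk(0.8 + runif(5, -0.05, 0.05))),
               lapply(1:4, function(i) mk(0.2 + runif(5, -0.05, 0.05))))
  names(samples) <- c(paste0("a", 1:4), paste0("b", 1:4))
  clustering <- call_clusters(data.frame(chrom = "chr1", pos = pos))
  res <- test_clusters(clustering, samples, paste0("a", 1:4), paste0("b", 1:4))
  expect_lt(res$p, 1e-3)
  expect_equal(res$delta, 0.6, tolerance = 0.05)
  # identical groups: t = 0, p = 1
  res2 <- test_clusters(clustering, samples, paste0("a", 1:4), paste0("a", 1:4))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  # site_mean mode agrees on the delta
  res3 <- test_clusters(clustering, samples, paste0("a", 1:4), paste0("b", 1:4),
                        value_mode = "site_mean")
  expect_equal(res3$delta, res$delta, tolerance = 1e-12)
})

test_that("genome-wide significance follows the chosen correction exactly", {
  base <- data.frame(cluster_id = sprintf("c%03d", 1:100), chrom = "chr1",
                     start = (1:100) * 1000, end = (1:100) * 1000 + 50,
                     n_sites = 3, p = rep(0.5, 100))
  base$p[1] <- 4e-4; base$p[2] <- 6e-4
  flagged <- significant_clusters(base)
  expect_true(flagged$genome_wide_significant[1])    # 4e-4 <= 0.05/100
  expect_false(flagged$genome_wide_significant[2])   # 6e-4 > 5e-4
  expect_false(any(significant_clusters(
    transform(base, p = 1))$genome_wide_significant))
  bh <- significant_clusters(base, method = "bh")
  expect_true(all(c("q") %in% names(bh)))
  expect_equal(bh$q, bh_fdr(base$p))
})

test_that("cluster overlap counts interval hits over the tested universe", {
  universe <- data.frame(cluster_id = sprintf("c%03d", 1:100), chrom = "chr1",
                         start = (1:100) * 1000, end = (1:100) * 1000 + 60)
  sig_a <- universe[1:10, ]
  ov_same <- cluster_overlap(sig_a, sig_a, universe)
  expect_equal(ov_same$intersection_size, 10)
  sig_b <- universe[6:15, ]
  ov <- cluster_overlap(sig_a, sig_b, universe)
  expect_equal(ov$intersection_size, 5)
  expect_equal(ov$p_hyper, phyper(4, 10, 90, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  disjoint <- universe[20:29, ]
  expect_equal(cluster_overlap(sig_a, disjoint, universe)$p_hyper, 1)
  # partial-bp overlap counts as a hit
  shifted <- transform(sig_a, start = start + 59, end = end + 59)
  expect_equal(cluster_overlap(sig_a, shifted, universe)$intersection_size, 10)
})

test_that("the five-overlap example matches the exhaustive enumeration oracle", {
  # frozen from the enumeration oracle at (N, K, n, k) = (12, 4, 4, 2):
  expect_equal(hypergeometric_tail(12, 4, 4, 2), hyper_tail_enum(12, 4, 4, 2))
  # and the large-pool case agrees with the exact summation cross-check
  expect_equal(hypergeometric_tail(100, 10, 10, 5),
               phyper(4, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("gene mapping windows are strand-aware with exact boundaries", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000, 10000), end = c(12000, 12000),
                      name = c("plus_gene", "minus_gene"), score = 0,
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  clus <- function(start, end) {
    data.frame(cluster_id = "cl", chrom = "chr1", start = start, end = end)
  }
  # + strand window [5000, 14000): 4900-4960 misses, 5000-5050 hits
  expect_equal(nrow(merge(map_clusters_to_genes(clus(4900, 4960), genes[1, ]),
                          data.frame(gene_id = "plus_gene"))), 0)
  expect_equal(map_clusters_to_genes(clus(5000, 5050), genes[1, ])$gene_id,
               "plus_gene")
  # - strand window [8000, 17000): 16900-16950 hits, 17050 misses
  expect_equal(map_clusters_to_genes(clus(16900, 16950), genes[2, ])$gene_id,
               "minus_gene")
  expect_equal(nrow(map_clusters_to_genes(clus(17050, 17100), genes[2, ])), 0)
  # a cluster can link to several genes
  both <- map_clusters_to_genes(clus(9000, 9050), genes)
  expect_setequal(both$gene_id, c("plus_gene", "minus_gene"))
})

test_that("state correlation ranks the matching reference higher", {
  set.seed(8)
  base <- runif(50, 0.2, 0.8)
  delta <- runif(50, -0.3, 0.3)
  kd <- pmin(pmax(base + delta + rnorm(50, 0, 0.02), 0), 1)
  ref_pro <- base + rnorm(50, 0, 0.02)
  ref_dif <- pmin(pmax(base + delta + rnorm(50, 0, 0.02), 0), 1)
  res <- cluster_state_correlation(kd, ref_pro, ref_dif)
  expect_true(res$defined)
  expect_gt(res$r_b, res$r_a)
  expect_equal(res$r_b, 1, tolerance = 0.05)
  # degenerate cases flagged, not NaN
  expect_false(cluster_state_correlation(rep(0.5, 5), ref_pro[1:5],
                                         ref_dif[1:5])$defined)
  expect_error(cluster_state_correlation(kd, ref_pro[1:10], ref_dif), "same clusters")
})
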