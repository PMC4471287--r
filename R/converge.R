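#' Default orchestrator parameters
#'
#' All the thresholds the analysis leaves adjustable, with defaults matching
#' the study conventions: FPKM > 1 detection, expression significance at BH
#' q <= 0.05, miRNA nominal p < 0.05 and FDR q < 0.10, coverage > 5X with the
#' top 0.1% of coverages removed, 50 bp cluster gap, Bonferroni genome-wide
#' significance at alpha 0.05, and 5 kb 5' / 2 kb 3' gene windows. Every
#' value is echoed into the convergence report.
#'
#' @param ... overrides for any listed parameter.
#' @return named list of parameters.
#' @export
converge_params <- function(...) {
  p <- list(
    kd_condition = "kd", prolif_condition = "nt_prolif", diff_condition = "nt_diff",
    fpkm_threshold = 1, pool_rule = "either_mean", expr_q_threshold = 0.05,
    mirna_p_threshold = 0.05, mirna_q_threshold = 0.10,
    presence_min_a = NULL, presence_min_b = NULL,
    min_coverage_exclusive = 5, top_coverage_fraction = 0.001,
    max_gap = 50, min_sites = 2, meth_value_mode = "site",
    meth_method = "bonferroni", meth_alpha = 0.05,
    upstream = 5000, downstream = 2000)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Run the full multi-omic convergence analysis
#'
#' Executes the expression, miRNA and methylation layers on a bundle (a
#' directory in the pipeline's input layout, or the in-memory output of
#' [simulate_bundle()] / [read_bundle()]) and aggregates the per-layer
#' overlap, concordance and correlation statistics into one machine-readable
#' report. Deterministic given the inputs and parameters.
#'
#' @param bundle a bundle directory path or an in-memory bundle list.
#' @param params a [converge_params()] list.
#' @param layers subset of `c("mrna", "mirna", "methylation")` to run.
#' @return list of class `convergence_report`: one entry per layer plus
#'   `parameters` and `provenance`.
#' @export
run_converge <- function(bundle, params = converge_params(),
                         layers = c("mrna", "mirna", "methylation")) {
  provenance <- list(package_version = as.character(utils::packageVersion("convergeomics")))
  if (is.character(bundle)) {
    dir <- bundle
    files <- list.files(dir, full.names = TRUE)
    files <- files[!grepl("truth\\.json$", files)]
    provenance$inputs <- as.list(tools::md5sum(sort(files)))
    bundle <- read_bundle(dir)
  } else if (inherits(bundle, "sim_config")) {
    bundle <- simulate_bundle(bundle)
  }
  report <- list(parameters = params, provenance = provenance)

  if ("mrna" %in% layers) {
    expr <- bundle$expression
    de_kd <- differential_expression(expr$matrix, expr$samples,
                                     c(params$kd_condition, params$prolif_condition),
                                     q_threshold = params$expr_q_threshold,
                                     fpkm_threshold = params$fpkm_threshold,
                                     pool_rule = params$pool_rule)
    de_state <- differential_expression(expr$matrix, expr$samples,
                                        c(params$diff_condition, params$prolif_condition),
                                        q_threshold = params$expr_q_threshold,
                                        fpkm_threshold = params$fpkm_threshold,
                                        pool_rule = params$pool_rule)
    conv <- kd_state_convergence(de_kd, de_state)
    report$mrna <- list(
      n_detectable_kd = length(de_pool(de_kd)),
      n_detectable_state = length(de_pool(de_state)),
      pool_size = conv$pool_size,
      n_significant_kd = sum(de_kd$significant),
      n_significant_state = sum(de_state$significant),
      convergence = conv,
      de_kd = de_kd, de_state = de_state)
  }

  if ("mirna" %in% layers) {
    norm <- normalize_counts(bundle$mirna$table)
    lanes <- norm$lanes
    na <- sum(lanes$condition == params$prolif_condition)
    nb <- sum(lanes$condition == params$kd_condition)
    min_a <- if (is.null(params$presence_min_a)) max(1, na - 1) else params$presence_min_a
    min_b <- if (is.null(params$presence_min_b)) max(1, nb - 1) else params$presence_min_b
    kept <- presence_filter(norm, params$prolif_condition, params$kd_condition,
                            min_a, min_b)
    de_mir <- differential_mirna(norm, c(params$kd_condition, params$prolif_condition),
                                 probes = kept,
                                 p_threshold = params$mirna_p_threshold,
                                 q_threshold = params$mirna_q_threshold)
    conc <- mirna_state_concordance(de_mir, norm,
                                    c(params$diff_condition, params$prolif_condition))
    de_state_mir <- differential_mirna(norm,
                                       c(params$diff_condition, params$prolif_condition),
                                       probes = kept,
                                       p_threshold = params$mirna_p_threshold,
                                       q_threshold = params$mirna_q_threshold)
    ov <- overlap_test(as_directional_set(de_mir),
                       as_directional_set(de_state_mir), kept)
    report$mirna <- list(
      n_retained = length(kept),
      n_nominal_kd = sum(de_mir$significant),
      n_fdr_kd = sum(de_mir$fdr_significant),
      n_nominal_state = sum(de_state_mir$significant),
      presence_min = c(controls = min_a, kd = min_b),
      overlap = ov, concordance = conc,
      de_kd = de_mir, de_state = de_state_mir)
  }

  if ("methylation" %in% layers) {
    sheet <- bundle$methylation$sheet
    if (is.null(sheet)) sheet <- bundle$expression$samples
    meth <- filter_sites(bundle$methylation$samples,
                         min_coverage_exclusive = params$min_coverage_exclusive,
                         top_coverage_fraction = params$top_coverage_fraction)
    universe <- common_sites(meth)
    clustering <- call_clusters(universe, max_gap = params$max_gap,
                                min_sites = params$min_sites)
    kd_samp <- sheet$sample[sheet$condition == params$kd_condition]
    pro_samp <- sheet$sample[sheet$condition == params$prolif_condition]
    dif_samp <- sheet$sample[sheet$condition == params$diff_condition]
    tests_kd <- significant_clusters(
      test_clusters(clustering, meth, kd_samp, pro_samp,
                    value_mode = params$meth_value_mode),
      method = params$meth_method, alpha = params$meth_alpha)
    tests_state <- significant_clusters(
      test_clusters(clustering, meth, dif_samp, pro_samp,
                    value_mode = params$meth_value_mode),
      method = params$meth_method, alpha = params$meth_alpha)
    sig_kd <- tests_kd[tests_kd$genome_wide_significant, , drop = FALSE]
    sig_state <- tests_state[tests_state$genome_wide_significant, , drop = FALSE]
    ov <- cluster_overlap(sig_kd, sig_state, tests_kd)
    links <- map_clusters_to_genes(sig_kd, bundle$methylation$genes,
                                   upstream = params$upstream,
                                   downstream = params$downstream)
    both <- intersect(sig_kd$cluster_id, sig_state$cluster_id)
    state_corr <- NULL
    if (length(both) >= 3) {
      keep_cl <- clustering$sites$cluster_id %in% both
      sub <- list(clusters = clustering$clusters[
                    match(both, clustering$clusters$cluster_id), , drop = FALSE],
                  sites = clustering$sites[keep_cl, , drop = FALSE])
      kd_f <- cluster_mean_freqs(sub, meth, kd_samp)
      pro_f <- cluster_mean_freqs(sub, meth, pro_samp)
      dif_f <- cluster_mean_freqs(sub, meth, dif_samp)
      state_corr <- cluster_state_correlation(kd_f, pro_f, dif_f)
    }
    report$methylation <- list(
      n_sites_universe = nrow(universe),
      n_clusters_tested = nrow(clustering$clusters),
      n_significant_kd = nrow(sig_kd),
      n_significant_state = nrow(sig_state),
      n_significant_both = length(both),
      overlap = ov,
      n_gene_links = nrow(links),
      state_correlation = state_corr,
      tests_kd = tests_kd, tests_state = tests_state, gene_links = links)
  }

  class(report) <- "convergence_report"
  report
}

#' Write a convergence report as JSON (statistics only, tables dropped)
#'
#' @param report a `convergence_report`.
#' @param path output path.
#' @export
write_convergence_report <- function(report, path) {
  slim <- report
  if (!is.null(slim$mrna)) slim$mrna[c("de_kd", "de_state")] <- NULL
  if (!is.null(slim$mirna)) slim$mirna[c("de_kd", "de_state")] <- NULL
  if (!is.null(slim$methylation)) {
    slim$methylation[c("tests_kd", "tests_state", "gene_links")] <- NULL
  }
  slim <- rapply(unclass(slim), unclass, how = "replace")
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Multi-omic convergence report\n")
  if (!is.null(x$mrna)) {
    m <- x$mrna
    cat(sprintf(" mRNA: pool %d; %d KD / %d state significant; overlap %d (P = %.3g); Pearson r = %.3f\n",
                m$pool_size, m$n_significant_kd, m$n_significant_state,
                m$convergence$overlap_all$intersection_size,
                m$convergence$overlap_all$p_hyper,
                m$convergence$concordance$pearson_r))
  }
  if (!is.null(x$mirna)) {
    m <- x$mirna
    cat(sprintf(" miRNA: %d retained; %d KD / %d state nominal; overlap %d (P = %.3g); state concordance r = %.3f\n",
                m$n_retained, m$n_nominal_kd, m$n_nominal_state,
                m$overlap$intersection_size, m$overlap$p_hyper,
                m$concordance$pearson_r))
  }
  if (!is.null(x$methylation)) {
    m <- x$methylation
    corr <- if (is.null(m$state_correlation)) "undefined (<3 shared clusters)"
            else sprintf("r(prolif) = %.3f, r(diff) = %.3f", m$state_correlation$r_a,
                         m$state_correlation$r_b)
    cat(sprintf(" methylation: %d clusters tested; %d KD / %d state significant; overlap %d (P = %.3g); %s\n",
                m$n_clusters_tested, m$n_significant_kd, m$n_significant_state,
                m$overlap$intersection_size, m$overlap$p_hyper, corr))
  }
  invisible(x)
}
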