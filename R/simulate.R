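#' Configuration for the synthetic multi-omics generator
#'
#' The defaults mirror the study design the pipeline targets: three groups of
#' four samples (knockdown = 2 shRNA constructs x 2 replicates, non-target
#' proliferating, non-target differentiating), an mRNA universe sized like the
#' detectable FPKM > 1 pool (~13,000 genes), an nCounter-scale miRNA panel,
#' and an RRBS-like methylome where CpG sites arrive in spatial clusters
#' separable by the 50 bp rule. The cell-state contrast receives effects
#' `state_effect_multiplier` (default 2) times the knockdown effects, matching
#' the observation that state differences are the more pronounced signature.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @param n_genes,n_mirna,n_cpg_sites universe sizes per layer.
#' @param samples_per_group samples in each of the three groups.
#' @param rho_shared fraction of knockdown-perturbed features also perturbed
#'   (concordantly) in the cell-state contrast.
#' @param frac_de fraction of features perturbed per contrast.
#' @param effect_log2fc knockdown effect size: the fixed |log2 fold change|
#'   under `effect_model = "fixed"`, or the effect standard deviation under
#'   `"correlated"`.
#' @param state_effect_multiplier scale of cell-state effects relative to
#'   knockdown effects.
#' @param effect_model `"fixed"` plants +/-`effect_log2fc` (half up, half
#'   down); `"correlated"` draws shared-feature effect pairs from a bivariate
#'   normal with correlation `effect_cor`.
#' @param effect_cor planted correlation of knockdown vs cell-state log2
#'   effects over shared features (`"correlated"` model only).
#' @param fpkm_dispersion sd of per-sample noise on the log2 FPKM scale.
#' @param fpkm_log2_mean,fpkm_log2_sd distribution of gene baseline log2 FPKM.
#' @param mirna_lane_scales per-lane scale factors (length = 3 groups x
#'   `samples_per_group`); `NULL` draws mild log-normal lane effects from the
#'   seed.
#' @param coverage_mean mean per-site sequencing coverage of the methylome.
#' @param delta_meth |methylation-frequency difference| planted in
#'   differentially methylated clusters (knockdown contrast; the state
#'   contrast is scaled by `state_effect_multiplier` and clamped).
#' @param meth_baseline_range range of per-cluster baseline methylation
#'   frequencies.
#' @param sites_per_cluster mean CpG sites per planted cluster (minimum 2).
#' @param cluster_gap_mean mean within-cluster gap between consecutive CpG
#'   sites (bp, capped below 50 so planted clusters hold together).
#' @param intercluster_gap_min minimum gap between planted clusters (bp,
#'   must exceed 50 so the cluster caller can separate them).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 13000,
                       n_mirna = 800,
                       n_cpg_sites = 10000,
                       samples_per_group = 4,
                       rho_shared = 0.6,
                       frac_de = 0.05,
                       effect_log2fc = 2,
                       state_effect_multiplier = 2,
                       effect_model = c("fixed", "correlated"),
                       effect_cor = 0.8,
                       fpkm_dispersion = 0.35,
                       fpkm_log2_mean = 3,
                       fpkm_log2_sd = 1.5,
                       mirna_lane_scales = NULL,
                       coverage_mean = 30,
                       delta_meth = 0.3,
                       meth_baseline_range = c(0.25, 0.75),
                       sites_per_cluster = 5,
                       cluster_gap_mean = 20,
                       intercluster_gap_min = 200) {
  effect_model <- match.arg(effect_model)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_mirna = as.integer(n_mirna), n_cpg_sites = as.integer(n_cpg_sites),
              samples_per_group = as.integer(samples_per_group),
              rho_shared = rho_shared, frac_de = frac_de,
              effect_log2fc = effect_log2fc,
              state_effect_multiplier = state_effect_multiplier,
              effect_model = effect_model, effect_cor = effect_cor,
              fpkm_dispersion = fpkm_dispersion,
              fpkm_log2_mean = fpkm_log2_mean, fpkm_log2_sd = fpkm_log2_sd,
              mirna_lane_scales = mirna_lane_scales,
              coverage_mean = coverage_mean, delta_meth = delta_meth,
              meth_baseline_range = meth_baseline_range,
              sites_per_cluster = sites_per_cluster,
              cluster_gap_mean = cluster_gap_mean,
              intercluster_gap_min = as.integer(intercluster_gap_min))
  if (is.na(cfg$seed)) stop("seed is required and must be an integer")
  counts <- c(cfg$n_genes, cfg$n_mirna, cfg$n_cpg_sites, cfg$samples_per_group)
  if (any(counts <= 0)) stop("all counts must be positive")
  for (f in c("rho_shared", "frac_de")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$effect_model == "correlated" &&
      (cfg$effect_cor < -1 || cfg$effect_cor > 1)) {
    stop("effect_cor must lie in [-1, 1]")
  }
  if (cfg$coverage_mean <= 0 || cfg$fpkm_dispersion < 0) {
    stop("coverage_mean must be positive and fpkm_dispersion non-negative")
  }
  if (cfg$cluster_gap_mean >= 50 || cfg$cluster_gap_mean < 2) {
    stop("cluster_gap_mean must lie in [2, 50)")
  }
  if (cfg$intercluster_gap_min <= 50) {
    stop("intercluster_gap_min must exceed 50 so planted clusters are separable")
  }
  if (cfg$sites_per_cluster < 2) stop("sites_per_cluster must be >= 2")
  if (length(cfg$meth_baseline_range) != 2 ||
      any(cfg$meth_baseline_range < 0) || any(cfg$meth_baseline_range > 1) ||
      diff(cfg$meth_baseline_range) < 0) {
    stop("meth_baseline_range must be an increasing pair in [0, 1]")
  }
  if (!is.null(cfg$mirna_lane_scales)) {
    if (any(cfg$mirna_lane_scales <= 0)) stop("lane scales must be positive")
    if (length(cfg$mirna_lane_scales) != 3 * cfg$samples_per_group) {
      stop("mirna_lane_scales must have one entry per lane (3 groups x samples_per_group)")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_sheet <- function(config) {
  n <- config$samples_per_group
  data.frame(
    sample = sprintf("s%02d", seq_len(3 * n)),
    condition = rep(c("kd", "nt_prolif", "nt_diff"), each = n),
    replicate = rep(seq_len(n), times = 3),
    stringsAsFactors = FALSE
  )
}

# Plant per-feature effects for the KD and cell-state contrasts.
# Returns numeric effect vectors over the whole universe plus index bookkeeping.
plant_effects <- function(config, n_features, prefix, eligible = seq_len(n_features)) {
  ids <- sprintf("%s%05d", prefix, seq_len(n_features))
  e_kd <- numeric(n_features)
  e_state <- numeric(n_features)
  empty <- list(ids = ids, e_kd = e_kd, e_state = e_state,
                kd_idx = integer(0), state_idx = integer(0),
                shared_idx = integer(0))
  if (config$effect_log2fc == 0 || config$frac_de == 0) return(empty)
  n_de <- round(config$frac_de * n_features)
  if (n_de == 0) return(empty)
  n_shared <- round(config$rho_shared * n_de)
  if (length(eligible) < 2 * n_de - n_shared) {
    stop("not enough detectably expressed features to plant the requested effects")
  }
  kd_idx <- sort(safe_sample(eligible, n_de))
  shared_idx <- sort(safe_sample(kd_idx, n_shared))
  state_only <- sort(safe_sample(setdiff(eligible, kd_idx), n_de - n_shared))
  state_idx <- sort(c(shared_idx, state_only))
  mult <- config$state_effect_multiplier
  if (config$effect_model == "fixed") {
    sgn_kd <- rep_len(c(1, -1), n_de)
    e_kd[kd_idx] <- sgn_kd * config$effect_log2fc
    e_state[shared_idx] <- mult * e_kd[shared_idx]     # concordant in the state contrast
    sgn_so <- rep_len(c(1, -1), length(state_only))
    e_state[state_only] <- sgn_so * mult * config$effect_log2fc
  } else {
    sd_kd <- config$effect_log2fc
    sd_state <- mult * config$effect_log2fc
    rho <- config$effect_cor
    z1 <- stats::rnorm(n_shared)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_shared)
    e_kd[shared_idx] <- sd_kd * z1
    e_state[shared_idx] <- sd_state * z2
    kd_only <- setdiff(kd_idx, shared_idx)
    e_kd[kd_only] <- sd_kd * stats::rnorm(length(kd_only))
    e_state[state_only] <- sd_state * stats::rnorm(length(state_only))
  }
  list(ids = ids, e_kd = e_kd, e_state = e_state,
       kd_idx = kd_idx, state_idx = state_idx, shared_idx = shared_idx)
}

truth_set <- function(ids, effects, idx) {
  directional_set(ids[idx], effects[idx])
}

# sample() without the scalar-x surprise
safe_sample <- function(x, n) x[sample.int(length(x), n)]

#' Simulate an FPKM expression matrix with planted differential expression
#'
#' Gene baselines are log-normal on the FPKM scale; a `frac_de` subset is
#' shifted by the knockdown effect in the KD group and an overlapping subset
#' (controlled by `rho_shared`) is shifted concordantly, and more strongly, in
#' the differentiating group. Identical configs give identical output.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (genes x samples FPKM), `samples` (sample
#'   sheet), and `truth` (`de_kd`, `de_state` as [directional_set()]s plus
#'   `shared_ids`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sheet <- sim_sample_sheet(config)
  mu <- stats::rnorm(config$n_genes, config$fpkm_log2_mean, config$fpkm_log2_sd)
  # effects are planted on genes whose baseline clears the detection floor:
  # differential expression of an undetectable gene is not a recoverable signal
  eligible <- which(mu > 1)             # baseline FPKM > 2
  pl <- plant_effects(config, config$n_genes, "gene", eligible)
  n_samp <- nrow(sheet)
  log2x <- matrix(stats::rnorm(config$n_genes * n_samp, 0, config$fpkm_dispersion),
                  nrow = config$n_genes) + mu
  log2x[, sheet$condition == "kd"] <- log2x[, sheet$condition == "kd"] + pl$e_kd
  log2x[, sheet$condition == "nt_diff"] <- log2x[, sheet$condition == "nt_diff"] + pl$e_state
  fpkm <- 2^log2x
  dimnames(fpkm) <- list(pl$ids, sheet$sample)
  truth <- list(de_kd = truth_set(pl$ids, pl$e_kd, pl$kd_idx),
                de_state = truth_set(pl$ids, pl$e_state, pl$state_idx),
                shared_ids = pl$ids[pl$shared_idx])
  list(matrix = fpkm, samples = sheet, truth = truth)
}

#' Simulate an nCounter-style miRNA probe count table
#'
#' Endogenous probes follow a negative binomial around log-normal baselines,
#' scaled per lane; positive spike-ins sit at a fixed concentration ladder
#' times the lane scale; negative control probes are low Poisson background.
#' Differential effects are planted exactly as in [simulate_expression()].
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [probe_count_table()]), `samples`, `truth`,
#'   and `lane_scales` (the realised per-lane scale factors).
#' @export
simulate_mirna <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sheet <- sim_sample_sheet(config)
  n_lane <- nrow(sheet)
  scales <- config$mirna_lane_scales
  if (is.null(scales)) scales <- exp(stats::rnorm(n_lane, 0, 0.2))
  base <- 2^stats::rnorm(config$n_mirna, 6, 2)
  # plant only on probes expressed above the hybridisation background,
  # mirroring panels where many probes are simply not expressed
  pl <- plant_effects(config, config$n_mirna, "mir", which(base >= 30))
  counts_endo <- matrix(0L, config$n_mirna, n_lane)
  for (j in seq_len(n_lane)) {
    eff <- switch(sheet$condition[j],
                  kd = pl$e_kd, nt_diff = pl$e_state, numeric(config$n_mirna))
    mu <- base * 2^eff * scales[j]
    counts_endo[, j] <- stats::rnbinom(config$n_mirna, mu = mu, size = 30)
  }
  pos_conc <- c(128, 32, 8, 2, 0.5, 0.125)
  counts_pos <- matrix(0L, length(pos_conc), n_lane)
  for (j in seq_len(n_lane)) {
    counts_pos[, j] <- stats::rnbinom(length(pos_conc),
                                      mu = pos_conc * 60 * scales[j], size = 200)
  }
  counts_neg <- matrix(stats::rpois(8 * n_lane, 2), 8, n_lane)
  counts <- rbind(counts_endo, counts_pos, counts_neg)
  probe_id <- c(pl$ids, sprintf("POS_%s", LETTERS[seq_along(pos_conc)]),
                sprintf("NEG_%d", 1:8))
  class_vec <- c(rep("endogenous", config$n_mirna),
                 rep("positive", length(pos_conc)), rep("negative", 8))
  dimnames(counts) <- list(probe_id, sheet$sample)
  tab <- probe_count_table(counts, class_vec, sheet)
  truth <- list(de_kd = truth_set(pl$ids, pl$e_kd, pl$kd_idx),
                de_state = truth_set(pl$ids, pl$e_state, pl$state_idx),
                shared_ids = pl$ids[pl$shared_idx])
  list(table = tab, samples = sheet, truth = truth, lane_scales = scales)
}

#' Simulate Bismark-style per-sample CpG methylation calls
#'
#' CpG positions are laid down as spatial clusters: within-cluster gaps have
#' mean `cluster_gap_mean` and never reach 50 bp, and clusters are separated
#' by at least `intercluster_gap_min` bp, so the 50 bp cluster caller recovers
#' the planted clusters exactly. Each cluster has one baseline methylation
#' frequency; differentially methylated clusters shift it by `delta_meth`
#' (knockdown) and `state_effect_multiplier * delta_meth` (differentiating
#' group), clamped into [0.05, 0.95] - the realised (post-clamp) deltas are
#' what the truth records. Per-site per-sample coverage is negative binomial
#' around `coverage_mean`; methylated counts are binomial. Gene models are
#' tiled near a quarter of the clusters, on both strands, for mapping tests.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (named list of per-sample data.frames:
#'   `chrom`, `pos` (0-based), `coverage`, `n_meth`, `freq`), `sheet`,
#'   `genes` (BED6-style data.frame), and `truth` (planted cluster table plus
#'   KD/state/shared differentially methylated cluster IDs).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sheet <- sim_sample_sheet(config)
  n_clusters <- max(1L, round(config$n_cpg_sites / config$sites_per_cluster))
  n_sites <- 2L + stats::rpois(n_clusters, config$sites_per_cluster - 2)
  chrom <- rep(c("chr1", "chr2"), length.out = n_clusters)

  cluster_id <- sprintf("cl%05d", seq_len(n_clusters))
  pos_list <- vector("list", n_clusters)
  cur <- c(chr1 = 1000L, chr2 = 1000L)
  for (i in seq_len(n_clusters)) {
    gaps <- pmin(2L + stats::rpois(n_sites[i] - 1L, config$cluster_gap_mean - 2), 49L)
    p <- cur[[chrom[i]]] + cumsum(c(0L, gaps))
    pos_list[[i]] <- p
    cur[[chrom[i]]] <- p[length(p)] + config$intercluster_gap_min +
      stats::rpois(1, 100)
  }

  base <- stats::runif(n_clusters, config$meth_baseline_range[1],
                       config$meth_baseline_range[2])
  pl <- plant_effects_meth(config, n_clusters)
  target_kd <- pmin(pmax(base + pl$d_kd, 0.05), 0.95)
  target_state <- pmin(pmax(base + pl$d_state, 0.05), 0.95)
  realised_kd <- target_kd - base
  realised_state <- target_state - base

  site_cluster <- rep(seq_len(n_clusters), times = n_sites)
  site_chrom <- chrom[site_cluster]
  site_pos <- unlist(pos_list)
  n_site_total <- length(site_pos)
  samples <- vector("list", nrow(sheet))
  names(samples) <- sheet$sample
  for (j in seq_len(nrow(sheet))) {
    pi_cluster <- switch(sheet$condition[j],
                         kd = target_kd, nt_diff = target_state, base)
    pi_site <- pi_cluster[site_cluster]
    cov <- pmax(stats::rnbinom(n_site_total, mu = config$coverage_mean, size = 8), 1L)
    n_meth <- stats::rbinom(n_site_total, cov, pi_site)
    df <- data.frame(chrom = site_chrom, pos = site_pos,
                     coverage = cov, n_meth = n_meth,
                     freq = n_meth / cov, stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    samples[[j]] <- df
  }

  starts <- vapply(pos_list, min, numeric(1))
  ends <- vapply(pos_list, max, numeric(1)) + 1
  clusters_truth <- data.frame(
    cluster_id = cluster_id, chrom = chrom, start = starts, end = ends,
    n_sites = n_sites, baseline = base,
    delta_kd = realised_kd, delta_state = realised_state,
    dm_kd = seq_len(n_clusters) %in% pl$kd_idx,
    dm_state = seq_len(n_clusters) %in% pl$state_idx,
    stringsAsFactors = FALSE)
  clusters_truth <- clusters_truth[order(clusters_truth$chrom,
                                         clusters_truth$start), , drop = FALSE]
  rownames(clusters_truth) <- NULL

  gene_rows <- seq(1, n_clusters, by = 4)
  genes <- data.frame(
    chrom = chrom[gene_rows],
    start = ends[gene_rows] + 100,
    end = ends[gene_rows] + 1100,
    name = sprintf("gene%05d", seq_along(gene_rows)),
    score = 0L,
    strand = rep_len(c("+", "-"), length(gene_rows)),
    stringsAsFactors = FALSE)

  truth <- list(clusters = clusters_truth,
                dm_kd_ids = cluster_id[pl$kd_idx],
                dm_state_ids = cluster_id[pl$state_idx],
                shared_ids = cluster_id[pl$shared_idx])
  list(samples = samples, sheet = sheet, genes = genes, truth = truth)
}

# Cluster-level effect planting for the methylome (delta scale, not log2fc).
plant_effects_meth <- function(config, n_clusters) {
  empty <- list(d_kd = numeric(n_clusters), d_state = numeric(n_clusters),
                kd_idx = integer(0), state_idx = integer(0),
                shared_idx = integer(0))
  if (config$delta_meth == 0 || config$frac_de == 0) return(empty)
  n_dm <- round(config$frac_de * n_clusters)
  if (n_dm == 0) return(empty)
  n_shared <- round(config$rho_shared * n_dm)
  kd_idx <- sort(sample.int(n_clusters, n_dm))
  shared_idx <- sort(safe_sample(kd_idx, n_shared))
  state_only <- sort(safe_sample(setdiff(seq_len(n_clusters), kd_idx), n_dm - n_shared))
  state_idx <- sort(c(shared_idx, state_only))
  d_kd <- numeric(n_clusters); d_state <- numeric(n_clusters)
  sgn <- rep_len(c(1, -1), n_dm)
  d_kd[kd_idx] <- sgn * config$delta_meth
  mult <- config$state_effect_multiplier
  d_state[shared_idx] <- mult * d_kd[shared_idx]
  d_state[state_only] <- rep_len(c(1, -1), length(state_only)) *
    mult * config$delta_meth
  list(d_kd = d_kd, d_state = d_state, kd_idx = kd_idx,
       state_idx = state_idx, shared_idx = shared_idx)
}

#' Simulate all three omic layers from one configuration
#'
#' @param config a [sim_config()].
#' @return list with `config`, `expression`, `mirna`, `methylation`.
#' @export
simulate_bundle <- function(config) {
  list(config = config,
       expression = simulate_expression(config),
       mirna = simulate_mirna(config),
       methylation = simulate_methylome(config))
}
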