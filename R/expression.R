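#' Detectable gene pool from an FPKM matrix
#'
#' A gene counts as detectable when its expression strictly exceeds
#' `fpkm_threshold` under the chosen rule. The default rule takes the mean
#' FPKM per condition and requires it to exceed the threshold in at least one
#' of the two conditions (the most permissive reading of "detected"); the
#' alternatives require every sample, or any single sample, to exceed it.
#'
#' @param matrix genes x samples FPKM matrix with dimnames.
#' @param samples sample sheet (`sample`, `condition`).
#' @param conditions character pair of condition labels.
#' @param fpkm_threshold strict lower bound (default 1).
#' @param rule detection rule, see Details.
#' @return character vector of detectable gene IDs.
#' @export
detectable_pool <- function(matrix, samples, conditions, fpkm_threshold = 1,
                            rule = c("either_mean", "all_samples", "any_sample")) {
  rule <- match.arg(rule)
  stopifnot(length(conditions) == 2)
  missing_cond <- setdiff(conditions, samples$condition)
  if (length(missing_cond)) {
    stop("condition(s) absent from the sample sheet: ",
         paste(missing_cond, collapse = ", "))
  }
  cols <- lapply(conditions, function(cc) samples$sample[samples$condition == cc])
  keep <- switch(rule,
    either_mean = {
      m1 <- rowMeans(matrix[, cols[[1]], drop = FALSE])
      m2 <- rowMeans(matrix[, cols[[2]], drop = FALSE])
      m1 > fpkm_threshold | m2 > fpkm_threshold
    },
    all_samples = {
      x <- matrix[, c(cols[[1]], cols[[2]]), drop = FALSE]
      apply(x > fpkm_threshold, 1, all)
    },
    any_sample = {
      x <- matrix[, c(cols[[1]], cols[[2]]), drop = FALSE]
      apply(x > fpkm_threshold, 1, any)
    })
  rownames(matrix)[keep]
}

#' Differential expression between two conditions
#'
#' A deliberately simple DE engine over FPKM tables: genes are restricted to
#' the detectable pool for the contrast, tested with a row-wise Welch t-test
#' on `log2(FPKM + 1)`, and FDR-adjusted by Benjamini-Hochberg. The log2 fold
#' change is the difference of group means on that scale (contrast group over
#' reference). Externally produced DE tables can be substituted anywhere a
#' `de_table` is consumed (see [read_de_table()]).
#'
#' @param matrix genes x samples FPKM matrix.
#' @param samples sample sheet.
#' @param contrast character pair `c(group, reference)`.
#' @param q_threshold significance cutoff on the BH q-value.
#' @param fpkm_threshold detection threshold passed to [detectable_pool()].
#' @param pool_rule detection rule passed to [detectable_pool()].
#' @return data.frame of class `de_table` with columns `feature_id`, `log2fc`,
#'   `p`, `q`, `significant`, `direction`, and attribute `pool` (the
#'   detectable gene IDs tested).
#' @export
differential_expression <- function(matrix, samples, contrast,
                                    q_threshold = 0.05, fpkm_threshold = 1,
                                    pool_rule = "either_mean") {
  stopifnot(length(contrast) == 2)
  cols_a <- samples$sample[samples$condition == contrast[1]]
  cols_b <- samples$sample[samples$condition == contrast[2]]
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("each contrast group needs at least 2 samples")
  }
  pool <- detectable_pool(matrix, samples, contrast,
                          fpkm_threshold = fpkm_threshold, rule = pool_rule)
  x <- log2(matrix[pool, , drop = FALSE] + 1)
  tw <- row_welch(x, cols_a, cols_b)
  q <- bh_fdr(tw$p)
  out <- data.frame(feature_id = pool, log2fc = tw$delta, p = tw$p, q = q,
                    significant = q <= q_threshold,
                    direction = sign(tw$delta),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pool") <- pool
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("de_table", "data.frame")
  out
}

#' Coerce a DE table (or subset of it) to a directional feature set
#'
#' @param de a `de_table`.
#' @param which `"significant"` (default), `"nominal"` (`p < p_threshold`) or
#'   `"all"`.
#' @param direction optionally keep only one direction (`1` or `-1`).
#' @param p_threshold nominal p cutoff used when `which = "nominal"`.
#' @return a [directional_set()].
#' @export
as_directional_set <- function(de, which = c("significant", "nominal", "all"),
                               direction = NULL, p_threshold = 0.05) {
  which <- match.arg(which)
  keep <- switch(which,
                 significant = de$significant,
                 nominal = de$p < p_threshold,
                 all = rep(TRUE, nrow(de)))
  if (!is.null(direction)) keep <- keep & de$direction == direction
  de <- de[keep & !is.na(keep), , drop = FALSE]
  directional_set(de$feature_id, de$log2fc, de$direction, de$p, de$q)
}

de_pool <- function(de) {
  p <- attr(de, "pool")
  if (is.null(p)) de$feature_id else p
}

#' Convergence of a knockdown contrast with the cell-state contrast
#'
#' The central expression-layer analysis: for the genes significantly
#' increased and decreased in the knockdown, how strongly do they overlap the
#' cell-state (differentiating vs proliferating) significant genes, in which
#' direction, and how well do the log2 fold changes correlate? The background
#' pool for every hypergeometric test is the intersection of the two
#' contrasts' detectable pools, so both lists are drawable from it. Because
#' membership in the state list can be read with or without requiring the
#' same direction of change, both fractions are reported.
#'
#' @param de_kd,de_state `de_table`s for the knockdown and cell-state
#'   contrasts (built on the same gene universe).
#' @return list of class `convergence_result`: `pool_size`, per-direction
#'   overlap results (`overlap_up`, `overlap_down`) each carrying
#'   `frac_in_state` and `frac_in_state_same_direction`, an overall overlap,
#'   and `concordance` (a [directional_concordance()] over the shared
#'   significant genes).
#' @export
kd_state_convergence <- function(de_kd, de_state) {
  pool <- intersect(de_pool(de_kd), de_pool(de_state))
  if (length(pool) == 0) stop("the two detectable pools do not intersect")
  sig_state <- as_directional_set(de_state)
  per_direction <- lapply(c(up = 1, down = -1), function(d) {
    sig_kd_d <- as_directional_set(de_kd, direction = d)
    ov <- overlap_test(sig_kd_d, sig_state, pool)
    n_kd <- ov$set_a_size
    ids <- ov$intersection_ids
    same_dir <- if (length(ids)) {
      mean(sig_state$direction[match(ids, sig_state$feature_id)] == d)
    } else NA_real_
    ov$frac_in_state <- if (n_kd > 0) ov$intersection_size / n_kd else NA_real_
    ov$frac_in_state_same_direction <- if (n_kd > 0 && length(ids)) {
      sum(sig_state$direction[match(ids, sig_state$feature_id)] == d) / n_kd
    } else if (n_kd > 0) 0 else NA_real_
    ov$frac_shared_same_direction <- same_dir
    ov
  })
  sig_kd <- as_directional_set(de_kd)
  overall <- overlap_test(sig_kd, sig_state, pool)
  conc <- directional_concordance(sig_kd, sig_state)
  res <- list(pool_size = length(pool),
              overlap_up = per_direction$up,
              overlap_down = per_direction$down,
              overlap_all = overall,
              concordance = conc)
  class(res) <- "convergence_result"
  res
}

#' Overlap of significant genes between two knockdown models
#'
#' Intersects the significant gene lists of two reduced-dosage models over
#' the shared detectable pool, computes the hypergeometric tail probability,
#' and flags, per shared gene, whether the direction of change is identical.
#'
#' @param de_a,de_b `de_table`s for the two models.
#' @return list: `overlap` (an `overlap_result`), `shared` (data.frame with
#'   `feature_id`, `log2fc_a`, `log2fc_b`, `direction_identical`).
#' @export
cross_model_gene_overlap <- function(de_a, de_b) {
  pool <- intersect(de_pool(de_a), de_pool(de_b))
  if (length(pool) == 0) stop("the two detectable pools do not intersect")
  sa <- as_directional_set(de_a)
  sb <- as_directional_set(de_b)
  ov <- overlap_test(sa, sb, pool)
  ids <- ov$intersection_ids
  ia <- match(ids, sa$feature_id); ib <- match(ids, sb$feature_id)
  shared <- data.frame(feature_id = ids,
                       log2fc_a = sa$log2fc[ia], log2fc_b = sb$log2fc[ib],
                       direction_identical = sa$direction[ia] == sb$direction[ib],
                       stringsAsFactors = FALSE)
  list(overlap = ov, shared = shared)
}
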