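#' Construct a probe count table
#'
#' @param counts non-negative integer matrix, probes x lanes, with dimnames.
#' @param probe_class character vector per probe: `"endogenous"`,
#'   `"positive"` (spike-in) or `"negative"` (background control).
#' @param lanes sample sheet for the lanes (`sample`, `condition`).
#' @return list of class `probe_count_table` with `counts`, `probe_class`,
#'   `lanes`.
#' @export
probe_count_table <- function(counts, probe_class, lanes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry probe and lane names")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  probe_class <- match.arg(as.character(probe_class),
                           c("endogenous", "positive", "negative"),
                           several.ok = TRUE)
  if (length(probe_class) != nrow(counts)) {
    stop("probe_class must have one entry per probe")
  }
  if (!any(probe_class == "positive") || !any(probe_class == "negative")) {
    stop("at least one positive and one negative probe are required")
  }
  if (!all(colnames(counts) %in% lanes$sample)) {
    stop("every lane must appear in the sample sheet")
  }
  structure(list(counts = counts, probe_class = probe_class,
                 lanes = lanes[match(colnames(counts), lanes$sample), ,
                               drop = FALSE]),
            class = "probe_count_table")
}

#' nCounter-style two-step normalization
#'
#' Per-lane scaling in the manner of digital-counting (NanoString) pipelines:
#' first each lane is scaled so its positive-spike-in geometric mean matches
#' the grand geometric mean across lanes; then a content factor computed the
#' same way over endogenous probes (after step 1) equalises overall content.
#' Geometric means are taken over the probes of the relevant class detected
#' (count > 0) in *every* lane - a lane-invariant probe set, which makes the
#' normalization exactly scale-invariant per lane. A per-lane detection
#' threshold is recorded as mean + 2 sd of the normalized negative-control
#' probes.
#'
#' @param table a [probe_count_table()].
#' @return list of class `normalized_table`: `values` (real matrix, same
#'   shape as the counts), `probe_class`, `lanes`, `positive_factor`,
#'   `content_factor`, `background_threshold` (all per lane).
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "probe_count_table"))
  counts <- table$counts
  cls <- table$probe_class
  pos <- counts[cls == "positive", , drop = FALSE]
  if (any(colSums(pos) == 0)) {
    bad <- colnames(counts)[colSums(pos) == 0]
    stop("lane(s) with all-zero positive controls rejected: ",
         paste(bad, collapse = ", "))
  }
  lane_factor <- function(mat) {
    keep <- rowSums(mat == 0) == 0          # detected in every lane
    if (!any(keep)) stop("no probe of the class is detected in every lane")
    lane_gm <- apply(mat[keep, , drop = FALSE], 2, geometric_mean)
    geometric_mean(lane_gm) / lane_gm
  }
  positive_factor <- lane_factor(pos)
  step1 <- sweep(counts, 2, positive_factor, `*`)
  endo1 <- step1[cls == "endogenous", , drop = FALSE]
  content_factor <- lane_factor(endo1)
  values <- sweep(step1, 2, content_factor, `*`)
  neg <- values[cls == "negative", , drop = FALSE]
  background_threshold <- apply(neg, 2, function(v) mean(v) + 2 * stats::sd(v))
  structure(list(values = values, probe_class = cls, lanes = table$lanes,
                 positive_factor = positive_factor,
                 content_factor = content_factor,
                 background_threshold = background_threshold),
            class = "normalized_table")
}

lane_cols <- function(norm, lanes) {
  if (length(lanes) == 1 && lanes %in% norm$lanes$condition ||
      all(lanes %in% norm$lanes$condition)) {
    norm$lanes$sample[norm$lanes$condition %in% lanes]
  } else {
    stopifnot(all(lanes %in% colnames(norm$values)))
    lanes
  }
}

#' Presence filter for endogenous probes
#'
#' A probe is *detected* in a lane when its normalized value strictly exceeds
#' that lane's background threshold. It is kept when detected in at least
#' `min_a` lanes of group A **or** at least `min_b` lanes of group B - the
#' study-style "expressed in either 6/7 controls or 3/4 knockdowns" rule.
#'
#' @param norm a `normalized_table`.
#' @param group_a,group_b lane names, or condition labels resolved against
#'   the sample sheet.
#' @param min_a,min_b minimum detected-lane counts per group.
#' @return character vector of kept endogenous probe IDs.
#' @export
presence_filter <- function(norm, group_a, group_b, min_a, min_b) {
  stopifnot(inherits(norm, "normalized_table"))
  a <- lane_cols(norm, group_a); b <- lane_cols(norm, group_b)
  if (min_a > length(a) || min_b > length(b)) {
    stop("minimum detected-lane counts exceed the group sizes")
  }
  endo <- norm$probe_class == "endogenous"
  detected <- sweep(norm$values, 2, norm$background_threshold, `>`)
  da <- rowSums(detected[endo, a, drop = FALSE])
  db <- rowSums(detected[endo, b, drop = FALSE])
  rownames(norm$values)[endo][da >= min_a | db >= min_b]
}

#' Differential miRNA expression
#'
#' Welch t-test per probe on `log2(normalized + 1)` between two lane groups,
#' with a nominal significance list at `p < p_threshold` and BH-FDR flags at
#' `q < q_threshold`.
#'
#' @param norm a `normalized_table`.
#' @param contrast character pair `c(group, reference)` of condition labels
#'   (or two vectors of lane names via `group_a`/`group_b` semantics).
#' @param probes probe IDs to test (typically the [presence_filter()] output);
#'   defaults to all endogenous probes.
#' @param p_threshold,q_threshold nominal and FDR cutoffs.
#' @return data.frame of class `de_table`: `feature_id`, `log2fc`, `p`, `q`,
#'   `significant` (nominal, `p < p_threshold`), `fdr_significant`
#'   (`q < q_threshold`), `direction`.
#' @export
differential_mirna <- function(norm, contrast, probes = NULL,
                               p_threshold = 0.05, q_threshold = 0.10) {
  stopifnot(inherits(norm, "normalized_table"), length(contrast) == 2)
  if (is.null(probes)) probes <- rownames(norm$values)[norm$probe_class == "endogenous"]
  a <- lane_cols(norm, contrast[1]); b <- lane_cols(norm, contrast[2])
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 lanes")
  x <- log2(norm$values[probes, , drop = FALSE] + 1)
  tw <- row_welch(x, a, b)
  q <- bh_fdr(tw$p)
  out <- data.frame(feature_id = probes, log2fc = tw$delta, p = tw$p, q = q,
                    significant = tw$p < p_threshold,
                    fdr_significant = q < q_threshold,
                    direction = sign(tw$delta),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pool") <- probes
  class(out) <- c("de_table", "data.frame")
  out
}

#' Concordance of knockdown miRNA changes with the cell-state contrast
#'
#' For every probe significant in the knockdown contrast, the cell-state
#' log2 fold change is computed from the normalized table with *no*
#' significance requirement on the state side; the result reports the
#' fraction of probes changing in the same direction and the Pearson
#' correlation of the log2 fold changes.
#'
#' @param de_kd directional set (or `de_table`) of knockdown-significant
#'   probes.
#' @param norm the `normalized_table` carrying the cell-state lanes.
#' @param contrast character pair `c(state_group, reference)` of condition
#'   labels.
#' @return a [directional_concordance()] result, plus the per-probe state
#'   log2 fold changes in `$state_log2fc`.
#' @export
mirna_state_concordance <- function(de_kd, norm, contrast = c("nt_diff", "nt_prolif")) {
  stopifnot(inherits(norm, "normalized_table"), length(contrast) == 2)
  if (inherits(de_kd, "de_table")) {
    de_kd <- as_directional_set(de_kd, which = "significant")
  }
  missing_probes <- setdiff(de_kd$feature_id, rownames(norm$values))
  if (length(missing_probes)) {
    stop("probes absent from the state table: ",
         paste(missing_probes, collapse = ", "))
  }
  a <- lane_cols(norm, contrast[1]); b <- lane_cols(norm, contrast[2])
  x <- log2(norm$values[de_kd$feature_id, , drop = FALSE] + 1)
  state_fc <- rowMeans(x[, a, drop = FALSE]) - rowMeans(x[, b, drop = FALSE])
  state_set <- directional_set(de_kd$feature_id, state_fc)
  res <- directional_concordance(de_kd, state_set)
  res$state_log2fc <- state_fc
  res
}
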