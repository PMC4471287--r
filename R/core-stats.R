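#' Upper-tail hypergeometric probability
#'
#' Exact probability of drawing at least `k` marked features when `n` features
#' are drawn without replacement from a pool of `N` features of which `K` are
#' marked. This is the convergence statistic used throughout: the chance that
#' two significant-feature lists of sizes `K` and `n`, drawn from a common
#' detectable pool of size `N`, share `k` or more members.
#'
#' The sum is carried out term-by-term in log space (`lchoose`), which is
#' numerically stable for pools up to at least 1e5 features.
#'
#' @param N pool (universe) size.
#' @param K size of the first (marked) set; must satisfy `K <= N`.
#' @param n number of draws (size of the second set); `n <= N`.
#' @param k observed intersection size; `0 <= k <= min(K, n)`.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, a value in `(0, 1]`
#'   (exactly 1 when `k = 0`).
#' @examples
#' hypergeometric_tail(10, 4, 3, 2)  # 1/3
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  N <- as.numeric(N); K <- as.numeric(K); n <- as.numeric(n); k <- as.numeric(k)
  if (anyNA(c(N, K, n, k)) || any(c(N, K, n, k) < 0) ||
      any(c(N, K, n, k) != floor(c(N, K, n, k)))) {
    stop("N, K, n, k must be non-negative integers")
  }
  if (k > n || n > N || K > N) {
    stop("invalid ordering of counts: require k <= n <= N and K <= N")
  }
  if (k > K) {
    stop("k exceeds K: an intersection cannot contain more features than the smaller set")
  }
  if (k == 0) return(1)
  j <- seq.int(k, min(K, n))
  p <- sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  min(max(p, 0), 1)
}

#' Construct a directional feature set
#'
#' A directional feature set is the unit of every overlap/concordance analysis:
#' a set of feature identifiers each carrying a sign (direction of change), a
#' log2 fold change and (optionally) nominal and FDR-adjusted p-values.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param log2fc numeric log2 fold changes (contrast over reference).
#' @param direction optional integer vector in `{-1, 0, 1}`; defaults to
#'   `sign(log2fc)`. Must equal `sign(log2fc)` wherever `log2fc != 0`.
#' @param p,q optional probabilities in `[0, 1]`.
#' @return a `data.frame` of class `directional_set` with columns
#'   `feature_id`, `log2fc`, `direction`, `p`, `q`.
#' @export
directional_set <- function(feature_id, log2fc,
                            direction = sign(log2fc),
                            p = NA_real_, q = NA_real_) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) stop("feature IDs must be unique")
  n <- length(feature_id)
  log2fc <- as.numeric(rep_len(log2fc, n))
  direction <- as.numeric(rep_len(direction, n))
  p <- as.numeric(rep_len(p, n))
  q <- as.numeric(rep_len(q, n))
  nz <- !is.na(log2fc) & log2fc != 0
  if (any(direction[nz] != sign(log2fc[nz]))) {
    stop("direction must equal sign(log2fc) wherever log2fc != 0")
  }
  for (v in list(p = p, q = q)) {
    if (any(!is.na(v) & (v < 0 | v > 1))) stop("p and q must lie in [0, 1]")
  }
  out <- data.frame(feature_id = feature_id, log2fc = log2fc,
                    direction = direction, p = p, q = q,
                    stringsAsFactors = FALSE)
  class(out) <- c("directional_set", "data.frame")
  out
}

feature_ids <- function(x) {
  if (is.character(x)) unique(x)
  else if (is.data.frame(x) && "feature_id" %in% names(x)) x$feature_id
  else stop("expected a character vector or a directional_set")
}

#' Hypergeometric overlap test between two feature sets
#'
#' Restricts both sets to a common pool (features outside the pool are dropped
#' with a warning), counts the intersection, and computes the upper-tail
#' hypergeometric probability of an intersection at least that large arising
#' by chance from the pool.
#'
#' @param set_a,set_b `directional_set` objects or character vectors of
#'   feature IDs.
#' @param pool character vector: the common detectable feature universe.
#' @return a list of class `overlap_result` with elements `pool_size`,
#'   `set_a_size`, `set_b_size`, `intersection_size`, `p_hyper`,
#'   `intersection_ids`.
#' @export
overlap_test <- function(set_a, set_b, pool) {
  pool <- unique(as.character(pool))
  if (length(pool) == 0) stop("pool must be non-empty")
  a <- feature_ids(set_a)
  b <- feature_ids(set_b)
  a_out <- setdiff(a, pool); b_out <- setdiff(b, pool)
  if (length(a_out) || length(b_out)) {
    warning(sprintf("dropping %d set-A and %d set-B features outside the pool",
                    length(a_out), length(b_out)))
  }
  a <- intersect(a, pool); b <- intersect(b, pool)
  ids <- intersect(a, b)
  res <- list(pool_size = length(pool),
              set_a_size = length(a),
              set_b_size = length(b),
              intersection_size = length(ids),
              p_hyper = hypergeometric_tail(length(pool), length(a),
                                            length(b), length(ids)),
              intersection_ids = ids)
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d / (%d x %d) in pool %d; hypergeometric P(X >= k) = %.4g\n",
              x$intersection_size, x$set_a_size, x$set_b_size, x$pool_size,
              x$p_hyper))
  invisible(x)
}

#' Pearson correlation with a t-transform p-value
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`, and `defined` (FALSE when fewer than 3
#'   pairs or either vector has zero variance; `r`/`p` are then `NA`, never
#'   propagated NaNs).
#' @export
pearson_with_p <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, defined = TRUE)
}

#' Directional concordance between two directional feature sets
#'
#' Computes how much of set A recurs in set B, how often the shared features
#' agree in sign, and the Pearson correlation of their log2 fold changes
#' (defined when at least 3 shared features with nonzero variance exist).
#'
#' @param set_a,set_b `directional_set` objects.
#' @return list of class `concordance_result`: `shared_ids`, `frac_a_in_b`
#'   (0 with `a_empty = TRUE` when A is empty), `frac_directionally_identical`
#'   (NA when no shared features), `pearson_r`, `pearson_p`, `pearson_defined`,
#'   `n_shared`.
#' @export
directional_concordance <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "directional_set"), inherits(set_b, "directional_set"))
  shared <- intersect(set_a$feature_id, set_b$feature_id)
  a_empty <- nrow(set_a) == 0
  frac_a_in_b <- if (a_empty) 0 else length(shared) / nrow(set_a)
  ia <- match(shared, set_a$feature_id)
  ib <- match(shared, set_b$feature_id)
  frac_ident <- if (length(shared) == 0) NA_real_ else
    mean(set_a$direction[ia] == set_b$direction[ib])
  pr <- pearson_with_p(set_a$log2fc[ia], set_b$log2fc[ib])
  res <- list(shared_ids = shared,
              n_shared = length(shared),
              frac_a_in_b = frac_a_in_b,
              a_empty = a_empty,
              frac_directionally_identical = frac_ident,
              pearson_r = pr$r, pearson_p = pr$p, pearson_defined = pr$defined)
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d shared; frac(A in B) = %.3f; directionally identical = %s; Pearson r = %s\n",
              x$n_shared, x$frac_a_in_b,
              ifelse(is.na(x$frac_directionally_identical), "NA",
                     sprintf("%.3f", x$frac_directionally_identical)),
              ifelse(x$pearson_defined, sprintf("%.3f (p = %.3g)", x$pearson_r, x$pearson_p), "undefined")))
  invisible(x)
}

#' Welch two-sample t-test (closed form)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value. Degenerate inputs resolve deterministically: two
#' zero-variance groups with equal means give `t = 0, p = 1`; with unequal
#' means they give `p = 0` and a degenerate flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student form instead of Welch.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (delta == 0) return(list(t = 0, df = na + nb - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(delta) * Inf, df = na + nb - 2, p = 0, degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- delta / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df),
       degenerate = FALSE)
}

#' Row-wise Welch t-tests on a matrix
#'
#' Vectorised version of [welch_t()] used by the differential-expression and
#' differential-methylation engines: each row of `x` is a feature, `cols_a`
#' and `cols_b` index the two sample groups. Degenerate rows follow the same
#' rules as [welch_t()].
#'
#' @param x numeric matrix (features x samples).
#' @param cols_a,cols_b column indices (or names) of the two groups.
#' @return data.frame with `delta` (mean A - mean B), `t`, `df`, `p`.
#' @export
row_welch <- function(x, cols_a, cols_b) {
  xa <- x[, cols_a, drop = FALSE]
  xb <- x[, cols_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  delta <- ma - mb
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tstat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  deg <- se2 == 0
  if (any(deg)) {
    zero_d <- deg & delta == 0
    tstat[zero_d] <- 0; p[zero_d] <- 1
    inf_d <- deg & delta != 0
    tstat[inf_d] <- sign(delta[inf_d]) * Inf; p[inf_d] <- 0
    df[deg] <- na + nb - 2
  }
  data.frame(delta = delta, t = tstat, df = df, p = p,
             row.names = rownames(x))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (a thin wrapper over
#' `stats::p.adjust(method = "BH")`), order-preserving by original index.
#'
#' @param p_values numeric vector of probabilities in `[0, 1]`.
#' @return q-values of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Geometric mean of strictly positive values
#'
#' @param x numeric vector, all elements > 0. Count callers that need a zero
#'   guard apply their own offset before calling.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("x must be non-empty")
  if (any(is.na(x)) || any(x <= 0)) stop("all values must be strictly positive")
  exp(mean(log(x)))
}
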