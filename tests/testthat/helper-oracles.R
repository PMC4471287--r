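# Independent oracles the implementation is checked against.

# Exhaustive enumeration of all C(N, n) draws from an urn whose first K
# elements are marked: P(at least k marked in the draw).
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Naive O(n^2) pairwise-linkage clustering: positions are nodes, any pair
# within max_gap is an edge, clusters are connected components with at least
# min_sites members. Returns a list of sorted position vectors.
cluster_oracle <- function(pos, max_gap = 50, min_sites = 2) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & comp == 0L)
      comp[nb] <- cid
      frontier <- c(frontier[-1], nb)
    }
  }
  out <- lapply(split(pos, comp), sort)
  out <- out[vapply(out, length, 1L) >= min_sites]
  out <- out[order(vapply(out, min, numeric(1)))]
  names(out) <- NULL
  out
}

# Small-scale config used across tests.
tiny_config <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 500, n_mirna = 100, n_cpg_sites = 250,
               frac_de = 0.1, effect_log2fc = 2, rho_shared = 0.8)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# call_clusters output as a list of member-position vectors (single chrom)
clusters_as_list <- function(clustering) {
  sp <- split(clustering$sites$pos, clustering$sites$cluster_id)
  sp <- sp[order(vapply(sp, min, numeric(1)))]
  names(sp) <- NULL
  lapply(sp, sort)
}
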