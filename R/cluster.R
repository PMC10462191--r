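#' Channel adjacency from montage geometry
#'
#' Two channels are adjacent iff their great-circle distance is below
#' `max_angle` radians. The default threshold makes Fz adjacent to F3 and F4
#' and leaves the default 32+2-channel graph connected.
#'
#' @param montage an `mmn_montage`.
#' @param max_angle adjacency threshold in radians.
#' @return symmetric logical matrix (diagonal FALSE).
#' @export
channel_adjacency <- function(montage, max_angle = 0.7) {
  d <- channel_distances(montage)
  adj <- d < max_angle
  diag(adj) <- FALSE
  adj
}

## Connected components of suprathreshold channel-time points sharing a sign.
## Grid index p = ch + (t - 1) * nch. Spatial neighbours: adjacent channels at
## the same time point; temporal neighbours: same channel at t +- 1.
## Plain union-find with path halving.
find_clusters <- function(tvec, t_crit, adj_list, nch, nt) {
  supra <- which(abs(tvec) > t_crit)
  if (length(supra) == 0) return(list())
  sgn <- sign(tvec)
  member <- integer(nch * nt)
  member[supra] <- seq_along(supra)
  parent <- seq_along(supra)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (k in seq_along(supra)) {
    p <- supra[k]
    ch <- (p - 1) %% nch + 1
    t <- (p - 1) %/% nch + 1
    if (t < nt) {
      q <- p + nch
      if (member[q] && sgn[q] == sgn[p]) union_(k, member[q])
    }
    for (nb in adj_list[[ch]]) {
      q <- (t - 1) * nch + nb
      if (member[q] && sgn[q] == sgn[p]) union_(k, member[q])
    }
  }
  roots <- vapply(seq_along(supra), find, integer(1))
  split(supra, roots)
}

## Extremal (most extreme by absolute value, sign kept) cluster maxsum of a
## t-map; 0 when no suprathreshold point exists.
extremal_maxsum <- function(tvec, t_crit, adj_list, nch, nt) {
  cl <- find_clusters(tvec, t_crit, adj_list, nch, nt)
  if (length(cl) == 0) return(0)
  sums <- vapply(cl, function(idx) sum(tvec[idx]), numeric(1))
  sums[which.max(abs(sums))]
}

#' Spatio-temporal cluster-based permutation test (maxsum)
#'
#' Paired comparison of deviant vs standard subject ERPs across all
#' channel-time pairs. A paired t map is thresholded at the two-tailed
#' critical t for `cluster_alpha` with n-1 df; suprathreshold points are
#' clustered by spatial adjacency plus temporal contiguity within a common
#' sign, and each cluster is scored by the sum of its t values (maxsum). The
#' null distribution of the single most extreme cluster maxsum is built from
#' `n_perm` random within-subject condition-label flips (sign flips of the
#' paired differences); an observed cluster is significant when its maxsum
#' lies below the 2.5th or above the 97.5th percentile of that distribution
#' (at the default `alpha` of 0.05). Monte-Carlo cluster p-values use the
#' (b+1)/(n_perm+1) estimator.
#'
#' @param dev,std arrays subjects x channels x time on the same grid.
#' @param adjacency logical channel adjacency matrix.
#' @param n_perm number of permutations (default 2000).
#' @param alpha significance level of the percentile decision.
#' @param cluster_alpha cluster-forming (a priori) alpha for the t threshold.
#' @param seed integer seed for the label flips.
#' @return object of class `cluster_result`: list with `clusters`
#'   (data.frame: id, polarity, maxsum, p, n_members, t_min_ms..t_max_ms via
#'   indices, channels), `members` (list of index vectors), `t_map`
#'   (channels x time), `t_threshold`, `null_extremes`, `n_perm`, `alpha`.
#' @export
cluster_permutation_test <- function(dev, std, adjacency, n_perm = 2000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = 1) {
  stopifnot(length(dim(dev)) == 3, all(dim(dev) == dim(std)))
  n <- dim(dev)[1]; nch <- dim(dev)[2]; nt <- dim(dev)[3]
  if (n < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("n_perm < 100: Monte-Carlo p-values will be coarse")
  stopifnot(nrow(adjacency) == nch)
  D <- matrix(dev - std, nrow = n)      # subjects x (nch*nt), ch fastest
  adj_list <- apply(adjacency, 1, which, simplify = FALSE)

  ss <- colSums(D^2)                     # invariant under sign flips
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  mean_obs <- colMeans(D)
  var_obs <- (ss - n * mean_obs^2) / (n - 1)
  t_obs <- mean_obs / sqrt(var_obs / n)
  t_obs[!is.finite(t_obs)] <- 0

  clusters <- find_clusters(t_obs, t_crit, adj_list, nch, nt)

  null_ex <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (signs %*% D) / n
    V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    extremal_maxsums_cpp(Tm, t_crit, adj_list, nch, nt)
  })
  lo <- stats::quantile(null_ex, alpha / 2, names = FALSE)
  hi <- stats::quantile(null_ex, 1 - alpha / 2, names = FALSE)

  if (length(clusters)) {
    sums <- vapply(clusters, function(idx) sum(t_obs[idx]), numeric(1))
    p <- vapply(sums, function(s) {
      ## tolerance so permutations reproducing the observed labelling (exact
      ## ties up to floating-point path differences) are counted as extreme
      thr <- abs(s) * (1 - 1e-9) - 1e-12
      (1 + sum(abs(null_ex) >= thr)) / (n_perm + 1)
    }, numeric(1))
    chans <- vapply(clusters, function(idx) {
      paste(sort(unique((idx - 1) %% nch + 1)), collapse = ",")
    }, character(1))
    tidx <- lapply(clusters, function(idx) (idx - 1) %/% nch + 1)
    df <- data.frame(
      id = seq_along(clusters),
      polarity = ifelse(sums > 0, "positive", "negative"),
      maxsum = sums,
      p = p,
      significant = sums < lo | sums > hi,
      n_members = lengths(clusters),
      t_idx_min = vapply(tidx, min, numeric(1)),
      t_idx_max = vapply(tidx, max, numeric(1)),
      channels = chans)
    ord <- order(-abs(df$maxsum))
    df <- df[ord, ]; clusters <- clusters[ord]
    df$id <- seq_along(clusters)
    rownames(df) <- NULL
  } else {
    df <- data.frame(id = integer(0), polarity = character(0),
                     maxsum = numeric(0), p = numeric(0),
                     significant = logical(0), n_members = integer(0),
                     t_idx_min = numeric(0), t_idx_max = numeric(0),
                     channels = character(0))
  }
  structure(list(clusters = df, members = clusters,
                 t_map = matrix(t_obs, nch, nt), t_threshold = t_crit,
                 null_extremes = null_ex, percentiles = c(lo, hi),
                 n_perm = n_perm, alpha = alpha, n_subjects = n),
            class = "cluster_result")
}

#' Any significant cluster of a given polarity?
#'
#' Convenience accessor used by the headline-pattern analyses.
#'
#' @param result a `cluster_result`.
#' @param polarity "negative", "positive" or "any".
#' @return logical scalar.
#' @export
has_significant_cluster <- function(result, polarity = "any") {
  cl <- result$clusters
  if (nrow(cl) == 0) return(FALSE)
  sel <- cl$significant
  if (polarity != "any") sel <- sel & cl$polarity == polarity
  any(sel)
}
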