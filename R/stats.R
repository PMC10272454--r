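# Electrode-wise paired permutation statistics, spatial clustering of
# significant electrodes, and follow-up t-tests.

#' Paired sign-flip permutation test across electrodes
#'
#' For each electrode the observed statistic is the paired t on
#' within-participant differences `a - b`. The null is built by randomly
#' flipping the sign of each participant's difference (equivalently,
#' swapping the two condition values within participants), `n_perm` times.
#' The two-sided p-value uses the add-one estimator
#' `p = (#{|t*| >= |t|} + 1) / (n_perm + 1)`, which can never be exactly
#' zero. All electrodes share the same resampled sign patterns, computed in
#' one matrix product, so the test is fast for thousands of electrodes.
#'
#' @param a,b numeric matrices, participant x electrode, for the two paired
#'   conditions (same dimensions, aligned rows).
#' @param n_perm number of random sign patterns.
#' @param seed integer seed for reproducibility.
#' @return data.frame with one row per electrode: `electrode`, `t_obs`,
#'   `p_perm` (`NA` where the differences have zero variance).
#' @export
permutation_paired <- function(a, b, n_perm = 5000, seed = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a)
  if (n < 2) stop_tex("need at least 2 participants", "parameter_error")
  d <- a - b
  m_obs <- colMeans(d)
  v_obs <- apply(d, 2, stats::var)
  t_obs <- m_obs / sqrt(v_obs / n)
  ssq <- colSums(d^2)
  S <- with_seed(seed,
                 matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                        n_perm, n))
  M <- S %*% d / n                                   # n_perm x E means
  # sign flips leave sum(d^2) unchanged, so the permuted variance follows
  # from the permuted mean alone
  Vp <- (rep(ssq, each = n_perm) - n * M^2) / (n - 1)
  Tp <- M / sqrt(Vp / n)
  # count ties as exceedances with a relative tolerance: resampled sign
  # patterns equal to +-identity must reproduce |t_obs| exactly, and
  # floating-point noise in the vectorised path must not drop them
  exceed <- colSums(abs(Tp) >= rep(abs(t_obs) * (1 - 1e-9), each = n_perm))
  p <- (exceed + 1) / (n_perm + 1)
  p[v_obs == 0] <- NA_real_
  data.frame(electrode = colnames(a) %||% sprintf("E%d", seq_len(ncol(a))),
             t_obs = t_obs, p_perm = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Spatial adjacency of electrodes
#'
#' Two electrodes are neighbours when the angle between their unit-sphere
#' positions falls below a threshold. When `max_angle` is `NULL` a
#' deterministic threshold is derived from the layout itself: the median
#' over electrodes of the angular distance to their 6th-nearest neighbour
#' (plus a small slack), giving a median neighbour count near 6 as is
#' typical for dense geodesic nets.
#'
#' @param layout layout data.frame with unit positions (`x`, `y`, `z`).
#' @param max_angle neighbour threshold in radians, or `NULL` to derive.
#' @return symmetric logical adjacency matrix (no self-loops) with
#'   electrode labels as dimnames and the threshold in
#'   `attr(, "max_angle")`.
#' @export
adjacency_graph <- function(layout, max_angle = NULL) {
  pos <- as.matrix(layout[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  cp <- tcrossprod(pos)
  ang <- matrix(acos(pmin(1, pmax(-1, as.vector(cp)))), nrow(cp), ncol(cp))
  diag(ang) <- Inf
  if (is.null(max_angle)) {
    kth <- apply(ang, 1, function(r) sort(r)[6])
    max_angle <- stats::median(kth) * 1.001
  }
  adj <- ang <= max_angle
  diag(adj) <- FALSE
  dimnames(adj) <- list(layout$label, layout$label)
  structure(adj, max_angle = max_angle)
}

#' Group significant electrodes into spatial clusters
#'
#' Connected components of the adjacency subgraph induced by the electrodes
#' with `p < alpha`. Isolated significant electrodes form singleton
#' clusters.
#'
#' @param p named numeric vector of per-electrode p-values (names matching
#'   the adjacency dimnames), or the data.frame from
#'   [permutation_paired()].
#' @param alpha significance level.
#' @param graph adjacency matrix from [adjacency_graph()].
#' @return list of character vectors (electrode labels), largest first;
#'   empty list when nothing is significant.
#' @export
cluster_significant <- function(p, alpha = 0.05, graph) {
  if (is.data.frame(p)) p <- stats::setNames(p$p_perm, p$electrode)
  sig <- names(p)[!is.na(p) & p < alpha]
  if (length(sig) == 0) return(list())
  sub <- graph[sig, sig, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)
  cl <- split(sig, comp$membership)
  cl[order(-vapply(cl, length, 1L))]
}

#' Follow-up paired t-tests on electrode clusters
#'
#' Per cluster, the condition values are averaged over member electrodes
#' and compared across participants with a two-sided paired t-test
#' (`df = n - 1`). Bonferroni correction is applied over the clusters
#' tested (one family per contrast).
#'
#' @param a,b participant x electrode matrices (as in
#'   [permutation_paired()]).
#' @param clusters list of electrode-label vectors from
#'   [cluster_significant()].
#' @return data.frame with `cluster`, `electrodes`, `n_electrodes`, `t`,
#'   `df`, `p`, `p_bonferroni`. Degenerate clusters (zero-variance
#'   differences) get `t = Inf`-signed and `p = NA`.
#' @export
followup_t <- function(a, b, clusters) {
  if (length(clusters) == 0)
    return(data.frame(cluster = integer(0), electrodes = character(0),
                      n_electrodes = integer(0), t = numeric(0),
                      df = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0)))
  m <- length(clusters)
  rows <- lapply(seq_len(m), function(i) {
    el <- clusters[[i]]
    av <- rowMeans(a[, el, drop = FALSE])
    bv <- rowMeans(b[, el, drop = FALSE])
    dd <- av - bv
    if (stats::sd(dd) == 0) {
      t <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
      p <- NA_real_
    } else {
      tt <- stats::t.test(av, bv, paired = TRUE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(cluster = i, electrodes = paste(el, collapse = "+"),
               n_electrodes = length(el), t = t, df = length(av) - 1,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

#' Paired comparison of contact load between analysis windows
#'
#' @param pre,trans per-participant mean loads (gram-force) for the
#'   pre-transition and transition windows, aligned by participant.
#' @return list with `t`, `df`, `p`, `mean_pre`, `mean_trans`.
#' @export
load_compare <- function(pre, trans) {
  if (length(pre) != length(trans))
    stop_tex("load vectors must be paired (equal length)", "pairing_error")
  d <- pre - trans
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(pre) - 1, p = 1,
                mean_pre = mean(pre), mean_trans = mean(trans)))
  }
  tt <- stats::t.test(pre, trans, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_pre = mean(pre), mean_trans = mean(trans))
}
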