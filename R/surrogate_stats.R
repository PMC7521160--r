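#' One-sided P value for a z-score
#'
#' Upper-tail standard-normal probability, the mapping used to read
#' surrogate-normalized z maps as significance levels (z = 2, 3, 5
#' correspond to one-sided P of about 0.02, 0.001, and 1e-7).
#'
#' @param z Numeric vector of z-scores (finite).
#' @return Upper-tail probabilities, same length as `z`.
#' @export
#' @examples
#' z_to_p_one_sided(c(0, 2, 3, 5))
z_to_p_one_sided <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' z-score an observed statistic against a surrogate distribution
#'
#' @param observed Observed statistic (scalar).
#' @param surrogates Numeric vector of the same statistic under the null
#'   (at least 2 values with nonzero spread).
#' @return `(observed - mean(surrogates)) / sd(surrogates)`, with the
#'   sample (n-1) standard deviation.
#' @export
surrogate_zscore <- function(observed, surrogates) {
  if (length(surrogates) < 2) stop("need at least 2 surrogate values")
  s <- stats::sd(surrogates)
  if (!is.finite(s) || s == 0) stop("degenerate surrogate null: zero spread")
  (observed - mean(surrogates)) / s
}

#' Empirical (permutation) P value against surrogate values
#'
#' Proportion of surrogate values at least as extreme as the observed one;
#' ties count as extreme. A result of 0 means the observed statistic beat
#' every surrogate and should be reported as P < 1/n (see
#' [format_empirical_p()]).
#'
#' @param observed Observed statistic.
#' @param surrogates Numeric vector of surrogate statistics (length >= 1).
#' @param direction `"ge"` (default) counts surrogates >= observed,
#'   `"le"` counts surrogates <= observed.
#' @return Proportion in `[0, 1]`.
#' @export
empirical_p <- function(observed, surrogates, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(surrogates) < 1) stop("need at least 1 surrogate value")
  k <- if (direction == "ge") sum(surrogates >= observed) else sum(surrogates <= observed)
  k / length(surrogates)
}

#' Format an empirical P value for reporting
#'
#' @param p Proportion from [empirical_p()].
#' @param n Number of surrogate iterations.
#' @return `"P < 1/n"` when no surrogate reached the observed value,
#'   otherwise the proportion formatted as text.
#' @export
format_empirical_p <- function(p, n) {
  if (p == 0) sprintf("P < %.3g", 1 / n) else sprintf("P = %.3g", p)
}

#' Find sign-homogeneous suprathreshold clusters in a z map
#'
#' 4-connected components of bins with `|z| >= level` (positive and negative
#' bins clustered separately), retained only if their bounding extent spans
#' at least `min_freq_bins` rows and `min_time_bins` columns. Rows are
#' frequencies and columns time (or a second frequency axis).
#'
#' @param z_map Numeric matrix of z values (NA bins never belong to clusters).
#' @param level Positive threshold on `|z|`.
#' @param min_freq_bins Minimum row extent (default 2).
#' @param min_time_bins Minimum column extent (default 10, i.e. 36 ms at a
#'   250-Hz effective rate).
#' @return List of clusters; each has `bins` (two-column index matrix),
#'   `sign`, `level`, `mass` (sum of z), `row_range`, `col_range`, `n_bins`.
#' @export
find_clusters <- function(z_map, level, min_freq_bins = 2, min_time_bins = 10) {
  stopifnot(is.matrix(z_map), level > 0)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) z_map >= level else z_map <= -level
    mask[is.na(mask)] <- FALSE
    comps <- connected_components4(mask)
    for (comp in comps) {
      rr <- range(comp[, 1])
      cc <- range(comp[, 2])
      if (diff(rr) + 1 >= min_freq_bins && diff(cc) + 1 >= min_time_bins) {
        out[[length(out) + 1]] <- list(
          bins = comp, sign = sgn, level = level,
          mass = sum(z_map[comp]),
          row_range = rr, col_range = cc, n_bins = nrow(comp)
        )
      }
    }
  }
  out
}

# 4-connected components of a logical matrix; returns a list of two-column
# (row, col) index matrices. Iterative flood fill.
connected_components4 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comps <- list()
  idx <- which(mask)
  if (length(idx) == 0) return(comps)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    members <- integer(0)
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, p)
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, p - 1L)
      if (r < nr) nb <- c(nb, p + 1L)
      if (cl > 1L) nb <- c(nb, p - nr)
      if (cl < nc) nb <- c(nb, p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
    comps[[cur]] <- cbind(row = ((members - 1L) %% nr) + 1L,
                          col = ((members - 1L) %/% nr) + 1L)
  }
  comps
}

#' Choose integer z levels for multi-level cluster outlines
#'
#' Picks up to 5 integer z levels between the lowest Z >= 3 at which no
#' retained cluster spans all frequency rows, and the highest Z <= 25 that
#' still yields at least one retained cluster, evenly spaced over that range.
#'
#' @inheritParams find_clusters
#' @return Integer vector of at most 5 levels (possibly empty).
#' @export
choose_outline_levels <- function(z_map, min_freq_bins = 2, min_time_bins = 10) {
  candidates <- 3:25
  has_cluster <- logical(length(candidates))
  spans_all <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cl <- find_clusters(z_map, candidates[i], min_freq_bins, min_time_bins)
    has_cluster[i] <- length(cl) > 0
    spans_all[i] <- any(vapply(cl, function(x) {
      diff(x$row_range) + 1 == nrow(z_map)
    }, logical(1)))
  }
  ok_min <- which(!spans_all)
  ok_max <- which(has_cluster)
  if (length(ok_min) == 0 || length(ok_max) == 0) return(integer(0))
  zmin <- candidates[min(ok_min)]
  zmax <- candidates[max(ok_max)]
  if (zmax < zmin) return(integer(0))
  span <- zmax - zmin
  n_levels <- min(5L, span + 1L)
  # even spacing, ties rounded down: Zmin=3, Zmax=25 -> 3, 8, 14, 19, 25
  unique(as.integer(ceiling(seq(zmin, zmax, length.out = n_levels) - 0.5)))
}

#' One-sample cluster-based permutation test across segments
#'
#' Bin-wise one-tailed (positive) one-sample t tests against zero across data
#' segments; bins with p below `clusteralpha` form 4-connected clusters that
#' must span at least `min_extent` bins on each axis; cluster mass is the sum
#' of t values. The null distribution of the maximum cluster mass is built by
#' random sign flips of whole segments; a cluster is significant when its mass
#' exceeds the `1 - alpha` quantile of that null.
#'
#' @param x 3-d array `segments x rows x cols` (NA bins allowed, e.g.
#'   inadmissible frequency pairs; they never join clusters).
#' @param clusteralpha Bin-level inclusion threshold (default 0.1).
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param min_extent Length-2 integer: minimum row and column extent
#'   (default `c(2, 2)`).
#' @param alpha Cluster-level significance level, one-tailed (default 0.05).
#' @param seed Optional integer seed for the permutations.
#' @return List with `clusters` (each with `mass`, `p`, `significant`,
#'   `bins`, ranges), `t_map`, and `null_max_mass`.
#' @export
cluster_permutation_onesample <- function(x, clusteralpha = 0.1, n_perm = 1000,
                                          min_extent = c(2, 2), alpha = 0.05,
                                          seed = NULL) {
  stopifnot(length(dim(x)) == 3)
  n_seg <- dim(x)[1]
  if (n_seg < 3) stop("insufficient data: need at least 3 segments")
  nr <- dim(x)[2]
  nc <- dim(x)[3]
  xm <- matrix(x, nrow = n_seg)  # segments x (nr*nc)
  ssq <- colSums(xm^2)

  t_from_means <- function(m) {
    v <- (ssq - n_seg * m^2) / (n_seg - 1)
    tt <- m / sqrt(v / n_seg)
    tt[v <= 0] <- NA
    tt
  }
  clusters_of <- function(tvec) {
    p <- stats::pt(tvec, df = n_seg - 1, lower.tail = FALSE)
    mask <- matrix(!is.na(p) & p < clusteralpha & tvec > 0, nr, nc)
    tm <- matrix(tvec, nr, nc)
    comps <- connected_components4(mask)
    keep <- list()
    for (comp in comps) {
      if (diff(range(comp[, 1])) + 1 >= min_extent[1] &&
          diff(range(comp[, 2])) + 1 >= min_extent[2]) {
        keep[[length(keep) + 1]] <- list(bins = comp, mass = sum(tm[comp]))
      }
    }
    keep
  }

  t_obs <- t_from_means(colMeans(xm))
  obs_clusters <- clusters_of(t_obs)

  if (!is.null(seed)) set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * n_seg, replace = TRUE), n_perm, n_seg)
  perm_means <- (flips %*% xm) / n_seg
  null_max <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    cl <- clusters_of(t_from_means(perm_means[k, ]))
    null_max[k] <- if (length(cl) > 0) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
  }
  crit <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  t_map <- matrix(t_obs, nr, nc)
  clusters <- lapply(obs_clusters, function(cl) {
    list(bins = cl$bins, mass = cl$mass,
         p = mean(null_max >= cl$mass),
         significant = cl$mass > crit,
         row_range = range(cl$bins[, 1]), col_range = range(cl$bins[, 2]))
  })
  list(clusters = clusters, t_map = t_map, null_max_mass = null_max)
}
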