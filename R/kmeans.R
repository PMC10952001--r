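as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2L)
    return(unname(points))
  }
  cbind(points$x, points$y)
}

sq_dist_to_centers <- function(xy, centers) {
  # n x k matrix of squared Euclidean distances
  outer(rowSums(xy^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(xy)), rowSums(centers^2)) -
    2 * xy %*% t(centers)
}

lloyd <- function(xy, centers, max_iter, tol) {
  k <- nrow(centers)
  sse_trace <- numeric(0)
  assign_vec <- rep(1L, nrow(xy))
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centers(xy, centers)
    assign_vec <- max.col(-d2, ties.method = "first")
    sse_trace <- c(sse_trace, sum(d2[cbind(seq_len(nrow(xy)), assign_vec)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- xy[assign_vec == j, , drop = FALSE]
      # an emptied cluster keeps its previous center
      if (nrow(members) > 0L) new_centers[j, ] <- colMeans(members)
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- sq_dist_to_centers(xy, centers)
  assign_vec <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(nrow(xy)), assign_vec)])
  list(assignment = assign_vec, centers = centers, sse = sse,
       iterations = iter, sse_trace = c(sse_trace, sse))
}

# Best contiguous split of the points ordered along one direction,
# evaluated in O(n) with prefix sums; returns the two group centroids.
best_split_centers <- function(xy, direction) {
  n <- nrow(xy)
  ord <- order(xy %*% direction)
  sx <- cumsum(xy[ord, 1]); sy <- cumsum(xy[ord, 2])
  sq <- cumsum(rowSums(xy[ord, , drop = FALSE]^2))
  s <- seq_len(n - 1L)
  sse <- (sq[s] - (sx[s]^2 + sy[s]^2) / s) +
    (sq[n] - sq[s] - ((sx[n] - sx[s])^2 + (sy[n] - sy[s])^2) / (n - s))
  b <- which.min(sse)
  rbind(c(sx[b], sy[b]) / b, c(sx[n] - sx[b], sy[n] - sy[b]) / (n - b))
}

kmeans_init_candidates <- function(xy) {
  cands <- list()
  # seed one center in each homozygote arm: the most FAM-dominant and the
  # most HEX-dominant members
  diff_fh <- xy[, 2] - xy[, 1]
  cands[[1]] <- xy[c(which.max(diff_fh), which.min(diff_fh)), , drop = FALSE]
  # diameter endpoints
  d2 <- sq_dist_to_centers(xy, xy)
  far <- arrayInd(which.max(d2), dim(d2))
  cands[[2]] <- xy[c(far[1], far[2]), , drop = FALSE]
  # the optimal 2-partition is linearly separable, i.e. contiguous along the
  # direction joining its two centroids: scan a fan of directions and keep
  # the best contiguous split of each as a further starting point
  for (theta in seq(0, pi, length.out = 61L)[-61L]) {
    cands[[length(cands) + 1L]] <-
      best_split_centers(xy, c(cos(theta), sin(theta)))
  }
  cands
}

#' K-means clustering with deterministic, geometry-aware initialization
#'
#' Lloyd's algorithm on 2-D fluorescence coordinates. Points are assigned to
#' the nearest center by Euclidean distance (ties to the lower-numbered
#' center), centers are recomputed as member means, and iteration stops when
#' the largest center displacement falls below `tol`. Because random seeding
#' can strand centers in a single genotype arm, the default `k = 2`
#' initialization is a deterministic candidate set -- the most FAM- and most
#' HEX-dominant members, the diameter endpoints, and every contiguous split
#' along the first principal axis -- and the run with the lowest sum of
#' squared errors is kept.
#'
#' @param points A two-column matrix or a tibble with `x`, `y` columns.
#' @param k Number of clusters (`1 <= k <= nrow(points)`).
#' @param init_centers Optional `k x 2` matrix of starting centers; when
#'   supplied, a single Lloyd run is performed from it.
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence threshold on the maximum center displacement
#'   (default 1e-6).
#' @return List with `assignment` (integer vector), `centers` (`k x 2`
#'   matrix), `sse`, `iterations`, and `sse_trace` (SSE after each
#'   assignment step of the winning run; non-increasing).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 5), 10))
#' fit <- kasp_kmeans(pts, k = 2)
#' fit$centers
kasp_kmeans <- function(points, k, init_centers = NULL,
                        max_iter = 100L, tol = 1e-6) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")",
                  call. = FALSE)
  if (k == 1L) {
    ctr <- matrix(colMeans(xy), 1L)
    sse <- sum(sweep(xy, 2, ctr)^2)
    return(list(assignment = rep(1L, n), centers = ctr, sse = sse,
                iterations = 1L, sse_trace = sse))
  }
  if (!is.null(init_centers)) {
    init_centers <- as_xy(init_centers)
    stopifnot(nrow(init_centers) == k)
    return(lloyd(xy, init_centers, max_iter, tol))
  }
  if (k == 2L) {
    fits <- lapply(kmeans_init_candidates(xy),
                   function(ini) lloyd(xy, ini, max_iter, tol))
    return(fits[[which.min(vapply(fits, `[[`, 0, "sse"))]])
  }
  # generic k: farthest-first traversal from the point nearest the centroid
  ctr <- colMeans(xy)
  seeds <- which.min(rowSums(sweep(xy, 2, ctr)^2))
  while (length(seeds) < k) {
    d2 <- sq_dist_to_centers(xy, xy[seeds, , drop = FALSE])
    seeds <- c(seeds, which.max(apply(d2, 1, min)))
  }
  lloyd(xy, xy[seeds, , drop = FALSE], max_iter, tol)
}

#' Radius of a cluster
#'
#' The maximum Euclidean distance from the cluster center to any member;
#' 0 for an empty or singleton cluster (a singleton's center is the member
#' itself). This max-distance definition makes the circle drawn on the
#' typing map enclose every member.
#'
#' @param members Cluster members (two-column matrix or tibble with
#'   `x`, `y`).
#' @param center Numeric length-2 center.
#' @return Non-negative scalar.
#' @export
cluster_radius <- function(members, center) {
  xy <- as_xy(members)
  if (nrow(xy) == 0L) return(0)
  stopifnot(length(center) == 2L, all(is.finite(center)))
  max(sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2))
}

cluster_colors <- c(NTC = "black", `1` = "red", `2` = "blue",
                    `3` = "pink", `4` = "green")

summarize_cluster <- function(label, members) {
  if (nrow(members) == 0L) {
    ctr <- c(0, 0); rad <- 0; sse <- 0
  } else {
    xy <- as_xy(members)
    ctr <- colMeans(xy)
    rad <- cluster_radius(members, ctr)
    sse <- sum(sweep(xy, 2, ctr)^2)
  }
  list(label = label, cx = ctr[1], cy = ctr[2], radius = rad,
       n = nrow(members), color = cluster_colors[[label]],
       members = members, sse = sse)
}

#' Cluster the four partitioned pools into the five labeled clusters
#'
#' Each class is clustered separately: the NTC pool, the heterozygous pool
#' (cluster 4) and the untyped pool (cluster 3) each with k = 1, and the
#' homozygote pool with k = 2. Of the two homozygote clusters, the one whose
#' center is more FAM-dominant (larger y - x; ties toward cluster 1) becomes
#' cluster 1 (FAM homozygote, red) and the other cluster 2 (HEX homozygote,
#' blue). Empty pools yield empty clusters with center (0, 0) and radius 0.
#'
#' @param partition A `kasp_partition` from [partition_group()].
#' @return A `kasp_clusters` object: a tibble with one row per cluster
#'   (`label`, `cx`, `cy`, `radius`, `n`, `color`), with the member tibbles
#'   in `attr(, "members")` and the summed within-cluster SSE in
#'   `attr(, "sse")`.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' cluster_pools(partition_group(read_plate_table(path)$Z001))
cluster_pools <- function(partition) {
  stopifnot(inherits(partition, "kasp_partition"))
  empty <- partition$ntc[0, , drop = FALSE]

  pool <- partition$homozygote_pool
  if (nrow(pool) == 0L) {
    warning("empty homozygote pool; clusters 1 and 2 are empty",
            call. = FALSE)
    m1 <- empty; m2 <- empty
  } else if (nrow(pool) == 1L) {
    warning("single-point homozygote pool; one homozygote cluster is empty",
            call. = FALSE)
    if (pool$y[1] - pool$x[1] >= 0) { m1 <- pool; m2 <- empty }
    else { m1 <- empty; m2 <- pool }
  } else {
    fit <- kasp_kmeans(pool, k = 2L)
    fam_dom <- fit$centers[, 2] - fit$centers[, 1]
    first <- which.max(fam_dom)  # ties break toward cluster 1
    m1 <- pool[fit$assignment == first, , drop = FALSE]
    m2 <- pool[fit$assignment != first, , drop = FALSE]
  }

  summaries <- list(summarize_cluster("NTC", partition$ntc),
                    summarize_cluster("1", m1),
                    summarize_cluster("2", m2),
                    summarize_cluster("3", partition$untyped),
                    summarize_cluster("4", partition$het))
  out <- tibble::tibble(
    label = vapply(summaries, `[[`, "", "label"),
    cx = vapply(summaries, `[[`, 0, "cx"),
    cy = vapply(summaries, `[[`, 0, "cy"),
    radius = vapply(summaries, `[[`, 0, "radius"),
    n = vapply(summaries, `[[`, 0L, "n"),
    color = vapply(summaries, `[[`, "", "color"))
  attr(out, "members") <- stats::setNames(lapply(summaries, `[[`, "members"),
                                          out$label)
  attr(out, "sse") <- sum(vapply(summaries, `[[`, 0, "sse"))
  class(out) <- c("kasp_clusters", class(out))
  out
}
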