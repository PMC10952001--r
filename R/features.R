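#' Extract the 24 position-and-morphology eigenvalues of a typing map
#'
#' Collects, for one SNP group, the numeric features the grade decision tree
#' consumes: the center coordinates of clusters 1-4 and of the NTC cloud,
#' the four cluster radii, the six pairwise distances between cluster
#' centers, and the HEX/FAM axis extrema over non-NTC wells. Distances
#' involving an empty cluster are reported as 0, matching the zero-fill
#' convention for empty clusters (center (0, 0), radius 0).
#'
#' @param clusters A `kasp_clusters` object from [cluster_pools()].
#' @param non_ntc_points Tibble of all non-NTC wells of the group (used for
#'   the axis extrema); must be non-empty.
#' @return A `kasp_eigen` named numeric vector of length 24 (names as in
#'   [kasp_feature_labels()]), with cluster sizes in `attr(, "sizes")`.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' grp <- read_plate_table(path)$Z001
#' part <- partition_group(grp)
#' ev <- compute_eigenvalues(cluster_pools(part), non_ntc(grp))
#' round(ev[c("d12", "hex_max")], 4)
compute_eigenvalues <- function(clusters, non_ntc_points) {
  stopifnot(inherits(clusters, "kasp_clusters"), nrow(non_ntc_points) >= 1L)
  row_of <- function(lab) clusters[clusters$label == lab, ]
  ctr <- function(lab) { r <- row_of(lab); c(r$cx, r$cy) }
  n_of <- function(lab) row_of(lab)$n
  pair_dist <- function(a, b) {
    if (n_of(a) == 0L || n_of(b) == 0L) return(0)
    sqrt(sum((ctr(a) - ctr(b))^2))
  }
  ev <- c(c1x = ctr("1")[1], c1y = ctr("1")[2],
          c2x = ctr("2")[1], c2y = ctr("2")[2],
          c3x = ctr("3")[1], c3y = ctr("3")[2],
          c4x = ctr("4")[1], c4y = ctr("4")[2],
          ntcx = ctr("NTC")[1], ntcy = ctr("NTC")[2],
          r1 = row_of("1")$radius, r2 = row_of("2")$radius,
          r3 = row_of("3")$radius, r4 = row_of("4")$radius,
          d12 = pair_dist("1", "2"), d13 = pair_dist("1", "3"),
          d14 = pair_dist("1", "4"), d23 = pair_dist("2", "3"),
          d24 = pair_dist("2", "4"), d34 = pair_dist("3", "4"),
          hex_max = max(non_ntc_points$x), hex_min = min(non_ntc_points$x),
          fam_max = max(non_ntc_points$y), fam_min = min(non_ntc_points$y))
  structure(ev,
            sizes = stats::setNames(clusters$n, clusters$label),
            class = c("kasp_eigen", "numeric"))
}

#' Derived geometry used by the grade decision tree
#'
#' Three scalar quantities computed from the eigenvalues: `d04`, the
#' distance from the cluster-4 (heterozygous) center to the origin (0 when
#' cluster 4 is empty); `d_d`, the diagonal of the non-NTC bounding box,
#' used as the scale normalizer for all separation criteria; and `d0_ntc`,
#' the distance from the NTC center to the origin.
#'
#' @param ev A `kasp_eigen` vector from [compute_eigenvalues()].
#' @return List with `d04`, `d_d`, `d0_ntc`. A degenerate group (all points
#'   identical) gives `d_d = 0`; grading guards against dividing by it.
#' @export
compute_derived_geometry <- function(ev) {
  stopifnot(inherits(ev, "kasp_eigen"))
  sizes <- attr(ev, "sizes")
  d04 <- if (sizes[["4"]] == 0L) 0 else
    sqrt(ev[["c4x"]]^2 + ev[["c4y"]]^2)
  d_d <- sqrt((ev[["hex_max"]] - ev[["hex_min"]])^2 +
              (ev[["fam_max"]] - ev[["fam_min"]])^2)
  d0_ntc <- if (sizes[["NTC"]] == 0L) 0 else
    sqrt(ev[["ntcx"]]^2 + ev[["ntcy"]]^2)
  list(d04 = d04, d_d = d_d, d0_ntc = d0_ntc)
}

#' Non-NTC wells of a plate group
#'
#' Convenience accessor returning the wells of a group whose sample label
#' does not match the NTC pattern.
#'
#' @param group A `kasp_plate` tibble.
#' @param ntc_label NTC sample label (default `"NTC"`).
#' @return Tibble of non-NTC wells.
#' @export
non_ntc <- function(group, ntc_label = "NTC") {
  suppressWarnings(identify_ntc(group, ntc_label))$rest
}

#' @export
print.kasp_eigen <- function(x, digits = 4, ...) {
  cat("KASP typing-map eigenvalues (24 features)\n")
  print(round(unclass(x), digits))
  invisible(x)
}
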