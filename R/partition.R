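#' Separate no-template-control wells from sample wells
#'
#' NTC wells carry no DNA; they are identified purely by their sample label
#' (exact match after whitespace trimming, case-insensitive) and are set
#' aside before any geometric reasoning, so that contamination signal cannot
#' distort the genotype regions.
#'
#' @param group A `kasp_plate` tibble (or any tibble with `x`, `y`,
#'   `sample_id` columns).
#' @param ntc_label Label marking NTC wells (default `"NTC"`).
#' @return A list with elements `ntc` and `rest`, both tibbles. Row counts
#'   always sum to `nrow(group)`.
#' @export
identify_ntc <- function(group, ntc_label = "NTC") {
  stopifnot(nrow(group) >= 1L)
  is_ntc <- toupper(trimws(group$sample_id)) == toupper(trimws(ntc_label))
  if (!any(is_ntc)) {
    warning("no wells matched the NTC label '", ntc_label, "'", call. = FALSE)
  }
  list(ntc = group[is_ntc, , drop = FALSE],
       rest = group[!is_ntc, , drop = FALSE])
}

region_bounds <- function(points, divisor) {
  xr <- range(points$x)
  yr <- range(points$y)
  list(x_min = xr[1], x_max = xr[2], y_min = yr[1], y_max = yr[2],
       x_d = (xr[2] - xr[1]) / divisor, y_d = (yr[2] - yr[1]) / divisor)
}

#' Extract the heterozygous-genotype region
#'
#' Heterozygous wells report both alleles and therefore land in the centre
#' of the typing map. The centre is delimited by interception distances of
#' `range/divisor` from each end of both axes, computed over all non-NTC
#' wells; points strictly inside the central rectangle on both axes are
#' taken as heterozygous candidates.
#'
#' @param rest Non-NTC wells (tibble with `x`, `y`).
#' @param divisor Positive scale factor for the interception distance
#'   (default 4.2).
#' @return List with `het` (the central points), `remainder`
#'   (`rest` minus `het`) and `bounds` (the region bounds used).
#'   With a single point (degenerate, zero-area region) `het` is empty.
#' @export
extract_heterozygous <- function(rest, divisor = 4.2) {
  stopifnot(nrow(rest) >= 1L, divisor > 0)
  b <- region_bounds(rest, divisor)
  inside <- rest$x > b$x_min + b$x_d & rest$x < b$x_max - b$x_d &
            rest$y > b$y_min + b$y_d & rest$y < b$y_max - b$y_d
  list(het = rest[inside, , drop = FALSE],
       remainder = rest[!inside, , drop = FALSE],
       bounds = b)
}

#' Extract the untyped-product region
#'
#' Wells where amplification failed cluster near the origin of the typing
#' map. After NTC and heterozygous wells are removed, the low corner is cut
#' at `min + range/divisor` on each axis; points strictly below both cuts
#' are taken as untyped, the rest form the homozygote pool.
#'
#' @param remainder Wells left after heterozygote extraction.
#' @param divisor Positive scale factor for the corner cut (default 3.2).
#' @return List with `untyped`, `homozygote_pool` and `bounds`. All points
#'   identical (zero range) yields an empty `untyped` set.
#' @export
extract_untyped <- function(remainder, divisor = 3.2) {
  stopifnot(nrow(remainder) >= 1L, divisor > 0)
  b <- region_bounds(remainder, divisor)
  corner <- remainder$x < b$x_min + b$x_d & remainder$y < b$y_min + b$y_d
  list(untyped = remainder[corner, , drop = FALSE],
       homozygote_pool = remainder[!corner, , drop = FALSE],
       bounds = b)
}

#' Partition one plate group into the four data classes
#'
#' Runs the class extraction chain on one SNP group: NTC wells are split
#' off by label, the heterozygous centre rectangle is carved out of the
#' non-NTC points, and the untyped corner is carved out of what remains;
#' everything else is the homozygote pool. The four sets are disjoint and
#' jointly exhaust the group, and every point retains its sample label.
#'
#' @param group A `kasp_plate` tibble.
#' @param ntc_label Label marking NTC wells.
#' @param het_divisor,untyped_divisor Interception-distance divisors for the
#'   central rectangle and the origin corner (defaults 4.2 and 3.2).
#' @return A `kasp_partition` list with tibbles `ntc`, `het`, `untyped`,
#'   `homozygote_pool`.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' part <- partition_group(read_plate_table(path)$Z001)
#' vapply(part, nrow, 0L)
partition_group <- function(group, ntc_label = "NTC",
                            het_divisor = 4.2, untyped_divisor = 3.2) {
  stopifnot(nrow(group) >= 1L)
  empty <- group[0, , drop = FALSE]
  split1 <- identify_ntc(group, ntc_label)
  het <- empty; untyped <- empty; pool <- empty
  if (nrow(split1$rest) > 0L) {
    split2 <- extract_heterozygous(split1$rest, het_divisor)
    het <- split2$het
    if (nrow(split2$remainder) > 0L) {
      split3 <- extract_untyped(split2$remainder, untyped_divisor)
      untyped <- split3$untyped
      pool <- split3$homozygote_pool
    }
  }
  structure(list(ntc = split1$ntc, het = het, untyped = untyped,
                 homozygote_pool = pool),
            class = "kasp_partition")
}

#' @export
print.kasp_partition <- function(x, ...) {
  n <- vapply(x, nrow, 0L)
  cat("KASP plate partition:", sum(n), "wells\n")
  cat(sprintf("  NTC: %d  heterozygous: %d  untyped: %d  homozygote pool: %d\n",
              n[["ntc"]], n[["het"]], n[["untyped"]], n[["homozygote_pool"]]))
  invisible(x)
}
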