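#' Specification of a synthetic KASP plate group
#'
#' Defines a plate group drawn from up to four isotropic bivariate normal
#' clusters (FAM homozygote, HEX homozygote, heterozygous, untyped) plus an
#' NTC cloud. Coordinates are truncated at 0, since relative fluorescence is
#' non-negative. The defaults emulate a typical 48-well group with all four
#' classes present, with centers patterned on a real well-typed marker and
#' mild within-cluster noise.
#'
#' @param n_fam,n_hex,n_het,n_untyped Member counts of the four classes
#'   (non-negative).
#' @param centers 4 x 2 matrix of class centers, rows in the order FAM
#'   homozygote, HEX homozygote, heterozygous, untyped.
#' @param spreads Length-4 non-negative isotropic standard deviations, same
#'   order.
#' @param ntc_center Length-2 NTC cloud center.
#' @param ntc_spread Non-negative NTC standard deviation.
#' @param n_ntc Number of NTC wells (default 2).
#' @param snp_id Marker identifier for the simulated group.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `kasp_plate_spec` list.
#' @export
plate_spec <- function(n_fam = 16L, n_hex = 16L, n_het = 8L, n_untyped = 6L,
                       centers = rbind(fam = c(0.29, 1.58),
                                       hex = c(1.59, 0.45),
                                       het = c(1.08, 1.16),
                                       untyped = c(0.43, 0.40)),
                       spreads = c(0.04, 0.04, 0.04, 0.04),
                       ntc_center = c(0.35, 0.30), ntc_spread = 0.03,
                       n_ntc = 2L, snp_id = "SIM001", seed = 1L) {
  counts <- c(n_fam, n_hex, n_het, n_untyped, n_ntc)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(spreads < 0) || ntc_spread < 0) {
    stop("spreads must be non-negative", call. = FALSE)
  }
  centers <- as_xy(centers)
  stopifnot(nrow(centers) == 4L, length(spreads) == 4L,
            length(ntc_center) == 2L)
  structure(list(n_fam = as.integer(n_fam), n_hex = as.integer(n_hex),
                 n_het = as.integer(n_het), n_untyped = as.integer(n_untyped),
                 centers = centers, spreads = spreads,
                 ntc_center = ntc_center, ntc_spread = ntc_spread,
                 n_ntc = as.integer(n_ntc), snp_id = snp_id,
                 seed = as.integer(seed)),
            class = "kasp_plate_spec")
}

#' Simulate a KASP plate group with known class structure
#'
#' Draws each class as an isotropic bivariate normal around its center,
#' truncates coordinates at 0, labels NTC wells `"NTC"`, and shuffles the
#' rows (with the same seed) so that downstream code cannot rely on class
#' order. The generating class of each row is kept in `attr(, "truth")`
#' (levels `"fam"`, `"hex"`, `"het"`, `"untyped"`, `"ntc"`), aligned with
#' the shuffled rows, so recovery of the class structure can be scored.
#'
#' @param spec A [plate_spec()].
#' @return A `kasp_plate` tibble with a `truth` attribute.
#' @export
#' @examples
#' plate <- simulate_plate(plate_spec(seed = 7))
#' table(attr(plate, "truth"))
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "kasp_plate_spec"))
  set.seed(spec$seed)
  counts <- c(fam = spec$n_fam, hex = spec$n_hex, het = spec$n_het,
              untyped = spec$n_untyped)
  xs <- numeric(0); ys <- numeric(0); cls <- character(0)
  for (i in seq_len(4L)) {
    n <- counts[[i]]
    if (n == 0L) next
    xs <- c(xs, stats::rnorm(n, spec$centers[i, 1], spec$spreads[i]))
    ys <- c(ys, stats::rnorm(n, spec$centers[i, 2], spec$spreads[i]))
    cls <- c(cls, rep(names(counts)[i], n))
  }
  n_dna <- length(xs)
  if (spec$n_ntc > 0L) {
    xs <- c(xs, stats::rnorm(spec$n_ntc, spec$ntc_center[1], spec$ntc_spread))
    ys <- c(ys, stats::rnorm(spec$n_ntc, spec$ntc_center[2], spec$ntc_spread))
    cls <- c(cls, rep("ntc", spec$n_ntc))
  }
  ids <- character(length(xs))
  ids[cls != "ntc"] <- sprintf("S%03d", seq_len(n_dna))
  ids[cls == "ntc"] <- "NTC"
  ord <- sample.int(length(xs))
  plate <- new_kasp_plate(pmax(xs[ord], 0), pmax(ys[ord], 0),
                          spec$snp_id, ids[ord])
  attr(plate, "truth") <- cls[ord]
  plate
}

# Canned geometries whose pipeline grade is known by construction. Counts
# sum to 48 wells (46 DNA + 2 NTC). See the vignette for the reasoning
# behind each layout.
ideal_geometries <- list(
  # well-separated near-axis arms, clean untyped corner, no heterozygotes
  `0` = list(n_fam = 18L, n_hex = 20L, n_het = 0L, n_untyped = 8L,
             centers = rbind(c(0.30, 1.40), c(1.50, 0.40),
                             c(0.90, 0.90), c(0.35, 0.35)),
             spreads = c(0.04, 0.04, 0.04, 0.04),
             ntc_center = c(0.32, 0.30), ntc_spread = 0.03),
  # as grade 0 plus a compact, well-separated heterozygous cluster
  `1` = list(n_fam = 16L, n_hex = 16L, n_het = 8L, n_untyped = 6L,
             centers = rbind(c(0.30, 1.40), c(1.50, 0.40),
                             c(0.90, 0.90), c(0.35, 0.35)),
             spreads = c(0.04, 0.04, 0.04, 0.04),
             ntc_center = c(0.32, 0.30), ntc_spread = 0.03),
  # FAM arm drifted off its axis: red specificity degrades to Weaker
  `2` = list(n_fam = 18L, n_hex = 20L, n_het = 0L, n_untyped = 8L,
             centers = rbind(c(0.76, 1.40), c(1.50, 0.40),
                             c(0.90, 0.90), c(0.35, 0.35)),
             spreads = c(0.04, 0.04, 0.04, 0.04),
             ntc_center = c(0.32, 0.30), ntc_spread = 0.03),
  # failed typing: both arms collapsed into one undifferentiated cloud
  `3` = list(n_fam = 23L, n_hex = 23L, n_het = 0L, n_untyped = 0L,
             centers = rbind(c(0.64, 0.42), c(0.64, 0.42),
                             c(0.90, 0.90), c(0.40, 0.40)),
             spreads = c(0.04, 0.04, 0.04, 0.04),
             ntc_center = c(0.56, 0.36), ntc_spread = 0.02))

#' Canned plate with a known expected grade
#'
#' Emits a simulated plate whose geometry is constructed so that, under the
#' default [grading_config()], the full pipeline assigns the requested
#' grade: 0 uses well-separated near-axis homozygote arms; 1 adds a
#' compact, well-separated heterozygous cluster; 2 drifts one homozygote
#' arm off its axis (degraded specificity); 3 collapses both arms into one
#' undifferentiated low-signal cloud (failed typing).
#'
#' @param grade_target Integer in 0..3.
#' @param seed Integer seed forwarded to the simulator.
#' @return List with `plate` (a `kasp_plate`) and `expected_grade`.
#' @export
#' @examples
#' sim <- ideal_plate(0, seed = 11)
#' evaluate_plate(sim$plate)$grade$grade
ideal_plate <- function(grade_target, seed = 1L) {
  key <- as.character(grade_target)
  if (!key %in% names(ideal_geometries)) {
    stop("grade_target must be 0, 1, 2 or 3", call. = FALSE)
  }
  geom <- ideal_geometries[[key]]
  spec <- do.call(plate_spec, c(geom, list(snp_id = sprintf("IDEAL%s", key),
                                           seed = seed)))
  list(plate = simulate_plate(spec), expected_grade = as.integer(grade_target))
}
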