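#' Column dialect for plate tables
#'
#' Describes how the columns of a delimited plate export map onto the four
#' fields the pipeline uses: the relative HEX signal (x axis of the typing
#' map), the relative FAM signal (y axis), the SNP marker identifier and the
#' per-well sample label. The defaults follow the common export header
#' `X, Y, SNPID, SubjectID`; other platforms can be accommodated by renaming.
#'
#' @param x,y Column names holding the relative HEX and FAM fluorescence
#'   magnitudes (dimensionless, non-negative).
#' @param snp_id Column name holding the SNP locus identifier; one plate
#'   group is the set of rows sharing this value.
#' @param sample_id Column name holding the well/sample label. Labels may
#'   repeat within a group.
#' @param ntc_label Sample label that marks no-template-control wells.
#'   Matching is case-insensitive after trimming whitespace.
#' @return A `kasp_dialect` list.
#' @export
#' @examples
#' plate_dialect()
plate_dialect <- function(x = "X", y = "Y", snp_id = "SNPID",
                          sample_id = "SubjectID", ntc_label = "NTC") {
  stopifnot(is.character(x), is.character(y), is.character(snp_id),
            is.character(sample_id), is.character(ntc_label))
  structure(list(x = x, y = y, snp_id = snp_id, sample_id = sample_id,
                 ntc_label = ntc_label),
            class = "kasp_dialect")
}

new_kasp_plate <- function(x, y, snp_id, sample_id) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        snp_id = as.character(snp_id),
                        sample_id = as.character(sample_id))
  class(out) <- c("kasp_plate", class(out))
  out
}

#' Read a table of endpoint fluorescence readings, grouped by SNP marker
#'
#' Reads a comma- or tab-delimited file (the delimiter is sniffed from the
#' header line) with one row per well and returns one plate group per SNP
#' identifier. Row order within a group follows file order; columns beyond
#' the four mapped ones are ignored.
#'
#' @param path Path to the delimited file.
#' @param dialect A [plate_dialect()] describing the column mapping.
#' @return A named list of `kasp_plate` tibbles (columns `x`, `y`, `snp_id`,
#'   `sample_id`), one per SNP, in order of first appearance. An empty file
#'   (header only) yields an empty list.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' groups <- read_plate_table(path)
#' nrow(groups$Z001)
read_plate_table <- function(path, dialect = plate_dialect()) {
  if (!file.exists(path)) {
    stop("plate table not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  needed <- c(dialect$x, dialect$y, dialect$snp_id, dialect$sample_id)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("plate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, label) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s value '%s' at data row %d",
                   label, raw[[col]][bad[1L]], bad[1L]), call. = FALSE)
    }
    v
  }
  x <- parse_num(dialect$x, "x (HEX)")
  y <- parse_num(dialect$y, "y (FAM)")
  pts <- new_kasp_plate(x, y, raw[[dialect$snp_id]], raw[[dialect$sample_id]])
  if (nrow(pts) == 0L) {
    return(structure(list(), names = character(0)))
  }
  ids <- unique(pts$snp_id)
  groups <- lapply(ids, function(id) {
    g <- pts[pts$snp_id == id, ]
    class(g) <- c("kasp_plate", setdiff(class(g), "kasp_plate"))
    g
  })
  names(groups) <- ids
  groups
}

#' Human-readable labels for the 24 eigenvalue features
#'
#' Maps the short internal feature names onto the descriptive labels used in
#' the results table: cluster-center coordinates for clusters 1-4 and the
#' NTC, the four cluster radii, the six pairwise center distances, and the
#' HEX/FAM axis extrema over non-NTC wells.
#'
#' @return A named character vector; names are the short feature names.
#' @export
kasp_feature_labels <- function() {
  c(c1x = "Transverse coordinates of the center of cluster 1",
    c1y = "Vertical coordinates of the center of cluster 1",
    c2x = "Transverse coordinates of the center of cluster 2",
    c2y = "Vertical coordinates of the center of cluster 2",
    c3x = "Transverse coordinates of the center of cluster 3",
    c3y = "Vertical coordinates of the center of cluster 3",
    c4x = "Transverse coordinates of the center of cluster 4",
    c4y = "Vertical coordinates of the center of cluster 4",
    ntcx = "Transverse coordinates of the center of the NTC",
    ntcy = "Vertical coordinates of the NTC center",
    r1 = "The radius of cluster 1",
    r2 = "The radius of cluster 2",
    r3 = "The radius of cluster 3",
    r4 = "The radius of cluster 4",
    d12 = "Distance between centers of cluster 1 and cluster 2",
    d13 = "Distance between centers of cluster 1 and cluster 3",
    d14 = "Distance between centers of cluster 1 and cluster 4",
    d23 = "Distance between centers of cluster 2 and cluster 3",
    d24 = "Distance between centers of cluster 2 and cluster 4",
    d34 = "Distance between centers of cluster 3 and cluster 4",
    hex_max = "Maximum relative value of HEX",
    hex_min = "Minimum relative value of HEX",
    fam_max = "Maximum relative value of FAM",
    fam_min = "Minimum relative value of FAM")
}

#' Write eigenvalues and grades for a batch of evaluated groups
#'
#' Writes one CSV row per evaluated group: the SNP identifier, the grade and
#' verbal rating, then the 24 eigenvalue columns under their descriptive
#' labels (see [kasp_feature_labels()]). Values are written at full double
#' precision.
#'
#' @param results A list of `kasp_eval` objects as returned by
#'   [evaluate_plate()], or a single such object.
#' @param path Output file path.
#' @return The written tibble, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "kasp_eval")) results <- list(results)
  labels <- kasp_feature_labels()
  rows <- lapply(results, function(res) {
    ev <- as.numeric(res$eigenvalues[names(labels)])
    row <- c(list(snp_id = res$snp_id,
                  grade = res$grade$grade,
                  rating = res$grade$rating),
             as.list(ev))
    names(row) <- c("snp_id", "grade", "rating", unname(labels))
    tibble::as_tibble(row)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::as_tibble(c(list(snp_id = character(0), grade = integer(0),
                             rating = character(0)),
                        stats::setNames(rep(list(numeric(0)), length(labels)),
                                        unname(labels))))
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}
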