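#' Evaluate one plate group end to end
#'
#' Runs the full chain on one SNP group: class partitioning, per-class
#' clustering, eigenvalue extraction and grading.
#'
#' @param group A `kasp_plate` tibble.
#' @param config A [grading_config()].
#' @return A `kasp_eval` list: `snp_id`, `partition`, `clusters`,
#'   `eigenvalues`, `geometry`, `grade`.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' res <- evaluate_plate(read_plate_table(path)$Z001)
#' res$grade$grade
evaluate_plate <- function(group, config = grading_config()) {
  stopifnot(nrow(group) >= 1L)
  part <- partition_group(group, ntc_label = config$ntc_label,
                          het_divisor = config$het_divisor,
                          untyped_divisor = config$untyped_divisor)
  clusters <- cluster_pools(part)
  rest <- non_ntc(group, config$ntc_label)
  if (nrow(rest) == 0L) {
    stop("group '", group$snp_id[1], "' contains only NTC wells",
         call. = FALSE)
  }
  ev <- compute_eigenvalues(clusters, rest)
  geo <- compute_derived_geometry(ev)
  structure(list(snp_id = group$snp_id[1], partition = part,
                 clusters = clusters, eigenvalues = ev, geometry = geo,
                 grade = grade_group(ev, geo, config)),
            class = "kasp_eval")
}

#' @export
print.kasp_eval <- function(x, ...) {
  cat("KASP typing evaluation for", x$snp_id, "\n")
  print(x$partition)
  print(x$grade)
  invisible(x)
}

#' Run the evaluation pipeline over a plate table
#'
#' Reads a delimited plate table, evaluates every SNP group, writes a
#' results CSV (`results.csv` under `out_dir`) and, optionally, one typing
#' map PNG per group (named by SNP id). A failure in one group is recorded
#' as a warning in the manifest and does not abort the batch; one summary
#' line per group is emitted on standard error.
#'
#' @param input Path to the plate table.
#' @param config A [grading_config()].
#' @param out_dir Output directory (created if absent).
#' @param plots Render a typing map per group (default `FALSE`).
#' @param dialect A [plate_dialect()].
#' @return A `kasp_manifest` tibble with one row per group: `snp_id`, the
#'   four class sizes, `grade`, `rating` and any warning text, with the
#'   evaluated `kasp_eval` objects in `attr(, "results")`.
#' @export
run_pipeline <- function(input, config = grading_config(), out_dir = ".",
                         plots = FALSE, dialect = plate_dialect()) {
  groups <- read_plate_table(input, dialect)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  results <- list()
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    id <- names(groups)[i]
    warnings_seen <- character(0)
    res <- withCallingHandlers(
      tryCatch(evaluate_plate(groups[[i]], config),
               error = function(e) conditionMessage(e)),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "kasp_eval")) {
      results[[id]] <- res
      n <- vapply(res$partition, nrow, 0L)
      rows[[i]] <- tibble::tibble(
        snp_id = id, n_wells = nrow(groups[[i]]),
        n_ntc = n[["ntc"]], n_het = n[["het"]], n_untyped = n[["untyped"]],
        n_homozygote = n[["homozygote_pool"]],
        grade = res$grade$grade, rating = res$grade$rating,
        warnings = paste(warnings_seen, collapse = "; "))
      message(sprintf("%s: %d wells -> grade %d (%s)%s", id,
                      nrow(groups[[i]]), res$grade$grade, res$grade$rating,
                      if (length(warnings_seen)) " [warnings]" else ""))
      if (plots) {
        render_typing_map(groups[[i]], res$clusters,
                          file.path(out_dir, paste0(id, ".png")))
      }
    } else {
      rows[[i]] <- tibble::tibble(
        snp_id = id, n_wells = nrow(groups[[i]]), n_ntc = NA_integer_,
        n_het = NA_integer_, n_untyped = NA_integer_,
        n_homozygote = NA_integer_, grade = NA_integer_,
        rating = NA_character_,
        warnings = paste(c(warnings_seen, res), collapse = "; "))
      message(sprintf("%s: FAILED (%s)", id, res))
    }
  }
  write_results_table(results, file.path(out_dir, "results.csv"))
  manifest <- do.call(rbind, rows)
  attr(manifest, "results") <- results
  class(manifest) <- c("kasp_manifest", class(manifest))
  manifest
}

circle_path <- function(cx, cy, r, n = 120L) {
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Render the typing map of one plate group
#'
#' Scatter plot of all wells in the HEX/FAM plane, colored by assigned
#' class (NTC black, FAM homozygote red, HEX homozygote blue, untyped pink,
#' heterozygous green), with a star at each non-empty cluster center, a
#' circle of the cluster radius around it, and the cluster numeral beside
#' non-NTC centers.
#'
#' @param group The `kasp_plate` that was clustered.
#' @param clusters Its `kasp_clusters` result.
#' @param out Optional PNG path; when `NULL` the ggplot object is returned
#'   without writing.
#' @return The ggplot object, invisibly.
#' @export
render_typing_map <- function(group, clusters, out = NULL) {
  stopifnot(inherits(clusters, "kasp_clusters"))
  members <- attr(clusters, "members")
  pts <- do.call(rbind, lapply(names(members), function(lab) {
    m <- members[[lab]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(x = m$x, y = m$y, label = lab)
  }))
  live <- clusters[clusters$n > 0L, ]
  circles <- do.call(rbind, lapply(seq_len(nrow(live)), function(i) {
    if (live$radius[i] <= 0) return(NULL)
    cbind(circle_path(live$cx[i], live$cy[i], live$radius[i]),
          label = live$label[i])
  }))
  pal <- cluster_colors[unique(pts$label)]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = as.data.frame(live),
                        ggplot2::aes(x = .data$cx, y = .data$cy,
                                     colour = .data$label),
                        shape = 8, size = 4, stroke = 1.2,
                        inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = pal, name = "cluster") +
    ggplot2::labs(title = paste("Typing map:", group$snp_id[1]),
                  x = "Relative HEX signal", y = "Relative FAM signal") +
    ggplot2::theme_bw()
  if (!is.null(circles)) {
    p <- p + ggplot2::geom_path(data = circles,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             group = .data$label,
                                             colour = .data$label),
                                linetype = 2, inherit.aes = FALSE)
  }
  ann <- live[live$label %in% c("1", "2", "3", "4"), ]
  if (nrow(ann) > 0L) {
    p <- p + ggplot2::annotate("text", x = ann$cx + 0.04, y = ann$cy + 0.04,
                               label = ann$label, fontface = "bold")
  }
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 5, dpi = 120)
  }
  invisible(p)
}
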