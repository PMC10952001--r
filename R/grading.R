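#' Grading configuration
#'
#' All thresholds of the typing-effect decision tree, plus the partitioning
#' knobs, in one validated object. Every separation criterion is a ratio
#' against the bounding-box diagonal `d_d`, so grading is invariant to
#' rescaling the fluorescence values.
#'
#' @param ntc_alpha Fraction of an axis range above which an NTC center
#'   coordinate counts as a significant fluorescence signal (default 0.4).
#' @param eff_thr Normalized separation (`d13/d_d`, resp. `d23/d_d`) at or
#'   above which a primer's amplification efficiency is Higher
#'   (default 0.45).
#' @param spec_bins Three strictly increasing cut points in (0, 1) binning
#'   the normalized axis offset of a homozygote center into the specificity
#'   levels Higher / Worse / Weaker / Lower (default 0.15, 0.30, 0.45).
#' @param comp_margin Normalized gap `(d14 - (r1 + r4))/d_d` (resp. with
#'   `d24`, `r2`) at or above which combination competitiveness is Stronger
#'   (default 0.05).
#' @param comp_d04_frac Minimum `d04/d_d` additionally required for Stronger
#'   competitiveness (default 0.5): the heterozygous cluster must sit well
#'   away from the origin, not on the untyped cloud.
#' @param overlap_factor The two homozygote clusters are considered
#'   indistinguishable (collapsed typing; both primers graded Lower on
#'   efficiency and specificity) when `d12 < overlap_factor * (r1 + r2)`
#'   (default 1: the member-enclosing circles intersect).
#' @param ntc_label Sample label of NTC wells.
#' @param het_divisor,untyped_divisor Partitioning divisors, see
#'   [partition_group()].
#' @return A `kasp_config` list.
#' @export
#' @examples
#' grading_config(ntc_alpha = 0.5)
grading_config <- function(ntc_alpha = 0.4, eff_thr = 0.45,
                           spec_bins = c(0.15, 0.30, 0.45),
                           comp_margin = 0.05, comp_d04_frac = 0.5,
                           overlap_factor = 1, ntc_label = "NTC",
                           het_divisor = 4.2, untyped_divisor = 3.2) {
  stopifnot(ntc_alpha > 0, ntc_alpha < 1,
            eff_thr > 0, eff_thr < 1,
            length(spec_bins) == 3L, all(diff(spec_bins) > 0),
            all(spec_bins > 0), all(spec_bins < 1),
            comp_margin >= 0, comp_d04_frac >= 0, overlap_factor >= 0,
            het_divisor > 0, untyped_divisor > 0)
  structure(list(ntc_alpha = ntc_alpha, eff_thr = eff_thr,
                 spec_bins = spec_bins, comp_margin = comp_margin,
                 comp_d04_frac = comp_d04_frac,
                 overlap_factor = overlap_factor, ntc_label = ntc_label,
                 het_divisor = het_divisor,
                 untyped_divisor = untyped_divisor),
            class = "kasp_config")
}

#' Read or write a grading configuration file
#'
#' Configurations serialize to a flat JSON or YAML mapping (chosen by file
#' extension); unknown keys are rejected by [grading_config()]'s validation.
#'
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @param config A `kasp_config` to write.
#' @return `read_grading_config()` returns a `kasp_config`;
#'   `write_grading_config()` returns `path` invisibly.
#' @export
read_grading_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(grading_config, vals)
}

#' @rdname read_grading_config
#' @export
write_grading_config <- function(config, path) {
  stopifnot(inherits(config, "kasp_config"))
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Is the NTC fluorescence signal significant?
#'
#' A clean no-template control sits near the origin of the typing map. The
#' NTC center is flagged as significant when either coordinate exceeds the
#' corresponding axis minimum by more than `ntc_alpha` of that axis range
#' (ranges over non-NTC wells). Groups without NTC wells, and degenerate
#' groups with a zero axis range, are never significant.
#'
#' @param ev A `kasp_eigen` vector.
#' @param config A `kasp_config`.
#' @return Logical scalar.
#' @export
ntc_significance <- function(ev, config = grading_config()) {
  stopifnot(inherits(ev, "kasp_eigen"))
  if (attr(ev, "sizes")[["NTC"]] == 0L) return(FALSE)
  hex_range <- ev[["hex_max"]] - ev[["hex_min"]]
  fam_range <- ev[["fam_max"]] - ev[["fam_min"]]
  if (hex_range <= 0 && fam_range <= 0) return(FALSE)
  (hex_range > 0 && ev[["ntcx"]] > ev[["hex_min"]] + config$ntc_alpha * hex_range) ||
    (fam_range > 0 && ev[["ntcy"]] > ev[["fam_min"]] + config$ntc_alpha * fam_range)
}

bin_specificity <- function(s, bins) {
  c("Higher", "Worse", "Weaker", "Lower")[findInterval(s, bins) + 1L]
}

#' Derive the per-primer combination status
#'
#' Turns the eigenvalues into the three status factors of each competitive
#' primer. The red (FAM) primer is judged from cluster 1, the blue (HEX)
#' primer from cluster 2:
#' \itemize{
#'   \item Collapse gate: the alleles were not resolved at all when the two
#'     homozygote clusters' member-enclosing circles intersect
#'     (`d12 < overlap_factor * (r1 + r2)`), or when a heterozygous cluster
#'     exists that intersects both homozygote clusters in the same sense.
#'     Both primers are then scored (Lower, Lower) directly -- on such
#'     plates the positions of the indistinguishable sub-clusters carry no
#'     information.
#'   \item Amplification efficiency is Higher when the homozygote cluster is
#'     present and separated from the untyped cluster by at least
#'     `eff_thr * d_d` (when cluster 3 is empty, the distance to the
#'     low-signal corner `(hex_min, fam_min)` is used instead); otherwise
#'     Lower.
#'   \item Amplification specificity bins the normalized axis offset of the
#'     homozygote center -- `(c1x - hex_min)/range` for red,
#'     `(c2y - fam_min)/range` for blue -- into
#'     Higher / Worse / Weaker / Lower: a specific homozygote hugs its axis.
#'   \item Combination competitiveness is None when no heterozygous cluster
#'     exists; otherwise Stronger when the heterozygous cluster clears the
#'     homozygote by `comp_margin * d_d` beyond the two radii and lies at
#'     least `comp_d04_frac * d_d` from the origin, else Weaker.
#' }
#' An empty homozygote cluster gives that primer (Lower, Lower); a
#' degenerate map (`d_d = 0`) gives both primers (Lower, Lower).
#'
#' @param ev A `kasp_eigen` vector.
#' @param geo Output of [compute_derived_geometry()].
#' @param config A `kasp_config`.
#' @return List with `red` and `blue`, each a list with elements
#'   `efficiency`, `specificity`, `competitiveness`.
#' @export
derive_primer_status <- function(ev, geo, config = grading_config()) {
  stopifnot(inherits(ev, "kasp_eigen"))
  sizes <- attr(ev, "sizes")
  d_d <- geo$d_d
  has4 <- sizes[["4"]] > 0L
  hex_range <- ev[["hex_max"]] - ev[["hex_min"]]
  fam_range <- ev[["fam_max"]] - ev[["fam_min"]]

  competitiveness <- function(d_het, r_homo) {
    if (!has4) return("None")
    if (d_d <= 0) return("Weaker")
    ok_sep <- (d_het - (r_homo + ev[["r4"]])) / d_d >= config$comp_margin
    ok_origin <- geo$d04 / d_d >= config$comp_d04_frac
    if (ok_sep && ok_origin) "Stronger" else "Weaker"
  }

  f <- config$overlap_factor
  collapsed <- sizes[["1"]] > 0L && sizes[["2"]] > 0L &&
    (ev[["d12"]] < f * (ev[["r1"]] + ev[["r2"]]) ||
       (sizes[["4"]] > 0L &&
          ev[["d14"]] < f * (ev[["r1"]] + ev[["r4"]]) &&
          ev[["d24"]] < f * (ev[["r2"]] + ev[["r4"]])))

  one_primer <- function(cl, d_unt, d_het, r_homo, offset, axis_range) {
    if (sizes[[cl]] == 0L || d_d <= 0 || collapsed) {
      return(list(efficiency = "Lower", specificity = "Lower",
                  competitiveness = competitiveness(d_het, r_homo)))
    }
    sep <- if (sizes[["3"]] > 0L) d_unt else {
      ctr <- if (cl == "1") c(ev[["c1x"]], ev[["c1y"]]) else
        c(ev[["c2x"]], ev[["c2y"]])
      sqrt((ctr[1] - ev[["hex_min"]])^2 + (ctr[2] - ev[["fam_min"]])^2)
    }
    eff <- if (sep / d_d >= config$eff_thr) "Higher" else "Lower"
    s <- if (axis_range > 0) offset / axis_range else 0
    list(efficiency = eff,
         specificity = bin_specificity(s, config$spec_bins),
         competitiveness = competitiveness(d_het, r_homo))
  }

  list(red = one_primer("1", ev[["d13"]], ev[["d14"]], ev[["r1"]],
                        ev[["c1x"]] - ev[["hex_min"]], hex_range),
       blue = one_primer("2", ev[["d23"]], ev[["d24"]], ev[["r2"]],
                         ev[["c2y"]] - ev[["fam_min"]], fam_range))
}

#' The encoded grade rule table
#'
#' One row per published combination-status rule: the red and blue primer
#' statuses and the grade they map to. `comp = "Any"` is a wildcard. Rules
#' are matched first to last; combinations matching no rule fall back to
#' grade 2 (Fair), recorded as `matched_rule = "fallback"`. The duplicated
#' all-Lower row is resolved to grade 3 (see the package vignette).
#'
#' @return A tibble with columns `rule`, `grade`, `r_eff`, `r_spec`,
#'   `r_comp`, `b_eff`, `b_spec`, `b_comp`.
#' @export
kasp_grade_rules <- function() {
  r <- function(rule, grade, re, rs, rc, be, bs, bc) {
    tibble::tibble(rule = rule, grade = grade, r_eff = re, r_spec = rs,
                   r_comp = rc, b_eff = be, b_spec = bs, b_comp = bc)
  }
  do.call(rbind, list(
    r("0a", 0L, "Higher", "Higher", "None",     "Higher", "Higher", "None"),
    r("1a", 1L, "Higher", "Worse",  "None",     "Higher", "Higher", "None"),
    r("1b", 1L, "Higher", "Higher", "Stronger", "Lower",  "Worse",  "None"),
    r("1c", 1L, "Lower",  "Worse",  "None",     "Higher", "Higher", "Stronger"),
    r("1d", 1L, "Higher", "Higher", "Stronger", "Higher", "Higher", "Stronger"),
    r("3a", 3L, "Lower",  "Lower",  "Any",      "Lower",  "Lower",  "Any"),
    r("2a", 2L, "Higher", "Weaker", "None",     "Higher", "Higher", "None"),
    r("2b", 2L, "Higher", "Higher", "None",     "Higher", "Worse",  "None"),
    r("2c", 2L, "Higher", "Higher", "None",     "Higher", "Weaker", "None"),
    r("2d", 2L, "Higher", "Higher", "Stronger", "Higher", "Higher", "None"),
    r("2e", 2L, "Higher", "Higher", "None",     "Higher", "Higher", "Stronger"),
    r("2f", 2L, "Higher", "Higher", "Weaker",   "Higher", "Higher", "Weaker"),
    r("2g", 2L, "Lower",  "Higher", "None",     "Lower",  "Higher", "None")))
}

grade_ratings <- c(`0` = "Excellent", `1` = "Good", `2` = "Fair",
                   `3` = "Poor")

#' Grade a red/blue status pair
#'
#' Looks a pair of primer statuses up in [kasp_grade_rules()] (first match
#' wins; no match falls back to grade 2) and applies the NTC override: a
#' significant no-template-control signal caps the grade at no better
#' than 2, while a grade-3 combination stays 3.
#'
#' @param red,blue Primer status lists with elements `efficiency`
#'   (`"Higher"`/`"Lower"`), `specificity` (`"Higher"`/`"Worse"`/
#'   `"Weaker"`/`"Lower"`) and `competitiveness` (`"None"`/`"Stronger"`/
#'   `"Weaker"`).
#' @param ntc_significant Logical; see [ntc_significance()].
#' @return List with `grade` (0-3), `rating` and `matched_rule`.
#' @export
#' @examples
#' hh <- list(efficiency = "Higher", specificity = "Higher",
#'            competitiveness = "None")
#' grade_from_status(hh, hh)$grade
grade_from_status <- function(red, blue, ntc_significant = FALSE) {
  rules <- kasp_grade_rules()
  match_comp <- function(rule_comp, comp) rule_comp == "Any" | rule_comp == comp
  hit <- rules$r_eff == red$efficiency & rules$r_spec == red$specificity &
    match_comp(rules$r_comp, red$competitiveness) &
    rules$b_eff == blue$efficiency & rules$b_spec == blue$specificity &
    match_comp(rules$b_comp, blue$competitiveness)
  if (any(hit)) {
    i <- which(hit)[1L]
    grade <- rules$grade[i]; rule <- rules$rule[i]
  } else {
    grade <- 2L; rule <- "fallback"
  }
  if (ntc_significant && grade != 3L) grade <- 2L
  list(grade = grade, rating = grade_ratings[[as.character(grade)]],
       matched_rule = rule)
}

#' Grade the typing effect of one plate group
#'
#' Derives the per-primer statuses, looks the status pair up in the encoded
#' rule table (fallback: grade 2), and applies the NTC override: a group
#' whose no-template control shows a significant fluorescence signal cannot
#' grade better than 2 (a group already at 3 stays 3).
#'
#' @param ev A `kasp_eigen` vector.
#' @param geo Output of [compute_derived_geometry()].
#' @param config A `kasp_config`.
#' @return A `kasp_grade` list: `grade` (0-3), `rating`
#'   (Excellent/Good/Fair/Poor), `red_status`, `blue_status`,
#'   `ntc_significant`, `matched_rule`.
#' @export
#' @examples
#' path <- system.file("extdata", "z001_plate.csv", package = "kaspqc")
#' grp <- read_plate_table(path)$Z001
#' ev <- compute_eigenvalues(cluster_pools(partition_group(grp)), non_ntc(grp))
#' grade_group(ev, compute_derived_geometry(ev))
grade_group <- function(ev, geo, config = grading_config()) {
  status <- derive_primer_status(ev, geo, config)
  sig <- ntc_significance(ev, config)
  hit <- grade_from_status(status$red, status$blue, sig)
  structure(list(grade = hit$grade, rating = hit$rating,
                 red_status = status$red, blue_status = status$blue,
                 ntc_significant = sig, matched_rule = hit$matched_rule),
            class = "kasp_grade")
}

#' @export
print.kasp_grade <- function(x, ...) {
  fmt <- function(s) sprintf("efficiency %s, specificity %s, competitiveness %s",
                             s$efficiency, s$specificity, s$competitiveness)
  cat(sprintf("Typing grade %d (%s)%s\n", x$grade, x$rating,
              if (x$ntc_significant) " [significant NTC signal]" else ""))
  cat("  red (FAM) primer: ", fmt(x$red_status), "\n", sep = "")
  cat("  blue (HEX) primer:", fmt(x$blue_status), "\n")
  cat("  matched rule:", x$matched_rule, "\n")
  invisible(x)
}
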