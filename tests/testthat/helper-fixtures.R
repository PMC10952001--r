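# Shared fixtures and independent oracles for the test suite.

z001_path <- function() {
  system.file("extdata", "z001_plate.csv", package = "kaspqc")
}

z001_group <- function() read_plate_table(z001_path())$Z001

# Published eigenvalue column for the Z001 reference group (4 dp).
z001_expected_eigenvalues <- c(
  c1x = 0.2813, c1y = 1.2938, c2x = 1.5193, c2y = 0.4139,
  c3x = 0.3489, c3y = 0.3672, c4x = 0.0000, c4y = 0.0000,
  ntcx = 0.5330, ntcy = 0.6002,
  r1 = 0.2543, r2 = 0.3373, r3 = 0.1051, r4 = 0.0000,
  d12 = 1.5188, d13 = 0.9291, d14 = 0.0000,
  d23 = 1.1713, d24 = 0.0000, d34 = 0.0000,
  hex_max = 1.7408, hex_min = 0.2399, fam_max = 1.5447, fam_min = 0.3193)

# Brute-force oracle for the minimum-SSE 2-partition of a small point set,
# by exhaustive enumeration of all bipartitions.
brute_force_best_sse2 <- function(xy) {
  n <- nrow(xy)
  stopifnot(n >= 2L, n <= 16L)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(mask))[1:n]
    a <- xy[grp == 1L, , drop = FALSE]
    b <- xy[grp == 0L, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    sse <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (sse < best) best <- sse
  }
  best
}

# Random plate group resembling no particular geometry (for property tests).
random_group <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(x = runif(n, 0, 2), y = runif(n, 0, 2),
                 snp_id = "RND", sample_id = c(rep("NTC", 2), paste0("s", seq_len(n - 2))))
}

# Map each well of a plate back to the cluster label it was assigned to.
assigned_classes <- function(plate, clusters) {
  members <- attr(clusters, "members")
  key <- paste(plate$x, plate$y, plate$sample_id)
  out <- rep(NA_character_, nrow(plate))
  for (lab in names(members)) {
    m <- members[[lab]]
    if (nrow(m) > 0L) out[match(paste(m$x, m$y, m$sample_id), key)] <- lab
  }
  out
}

status <- function(eff, spec, comp) {
  list(efficiency = eff, specificity = spec, competitiveness = comp)
}

# Every formally possible status combination.
all_status_combinations <- function() {
  lv <- expand.grid(eff = c("Higher", "Lower"),
                    spec = c("Higher", "Worse", "Weaker", "Lower"),
                    comp = c("None", "Stronger", "Weaker"),
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lv)), function(i) status(lv$eff[i], lv$spec[i], lv$comp[i]))
}
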