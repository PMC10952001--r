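test_that("k = 1 reduces to the coordinate-wise mean", {
  ntc <- partition_group(z001_group())$ntc
  fit <- kasp_kmeans(ntc, k = 1)
  expect_equal(fit$centers[1, ], c((0.26926 + 0.79678) / 2,
                                   (0.83101 + 0.36945) / 2))
  expect_equal(round(fit$centers[1, ], 4), c(0.5330, 0.6002))
  set.seed(5)
  xy <- matrix(runif(40), ncol = 2)
  fit <- kasp_kmeans(xy, k = 1)
  expect_identical(fit$centers[1, ], colMeans(xy))
  expect_equal(fit$sse, sum(sweep(xy, 2, colMeans(xy))^2))
})

test_that("two tight pairs split exactly under k = 2", {
  xy <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  fit <- kasp_kmeans(xy, k = 2)
  expect_equal(sort(table(fit$assignment)), sort(c(2L, 2L)),
               ignore_attr = TRUE)
  expect_equal(fit$assignment[1], fit$assignment[2])
  expect_equal(fit$assignment[3], fit$assignment[4])
  expect_equal(fit$sse, 2 * 2 * 0.05^2)
})

test_that("invalid cluster counts are rejected", {
  xy <- matrix(runif(10), ncol = 2)
  expect_error(kasp_kmeans(xy, k = 0), "at least 1")
  expect_error(kasp_kmeans(xy, k = 6), "fewer points")
})

test_that("SSE is non-increasing and the result is a fixed point", {
  for (seed in 1:8) {
    set.seed(seed)
    xy <- matrix(runif(60, 0, 2), ncol = 2)
    fit <- kasp_kmeans(xy, k = 2)
    expect_true(all(diff(fit$sse_trace) <= 1e-12))
    # every point sits with its nearest center (ties to lower index)
    d2 <- cbind(colSums((t(xy) - fit$centers[1, ])^2),
                colSums((t(xy) - fit$centers[2, ])^2))
    expect_equal(fit$assignment, max.col(-d2, ties.method = "first"))
    # centers are member means
    for (j in 1:2) {
      expect_equal(fit$centers[j, ],
                   colMeans(xy[fit$assignment == j, , drop = FALSE]))
    }
  }
})

test_that("explicit initial centers are honored", {
  xy <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  fit <- kasp_kmeans(xy, k = 2, init_centers = rbind(c(0, 0), c(11, 0)))
  expect_equal(fit$centers, rbind(c(0.5, 0), c(10.5, 0)))
})

test_that("cluster radius is the maximum member distance", {
  part <- partition_group(z001_group())
  cl <- cluster_pools(part)
  expect_equal(round(cl$radius[cl$label == "3"], 4), 0.1051)
  expect_equal(round(cl$radius[cl$label == "1"], 4), 0.2543)
  expect_equal(cluster_radius(tibble::tibble(x = 1, y = 2), c(1, 2)), 0)
  expect_equal(cluster_radius(tibble::tibble(x = numeric(0), y = numeric(0)),
                              c(0, 0)), 0)
  expect_equal(cluster_radius(rbind(c(0, 0), c(3, 4)), c(0, 0)), 5)
})

test_that("the reference group clusters into the published structure", {
  cl <- cluster_pools(partition_group(z001_group()))
  expect_equal(cl$label, c("NTC", "1", "2", "3", "4"))
  expect_equal(cl$n, c(2L, 7L, 33L, 6L, 0L))
  expect_equal(cl$color, c("black", "red", "blue", "pink", "green"))
  expect_equal(round(cl$cx[cl$label == "1"], 4), 0.2813)
  expect_equal(round(cl$cy[cl$label == "1"], 4), 1.2938)
  expect_equal(round(cl$cx[cl$label == "2"], 4), 1.5193)
  expect_equal(round(cl$cy[cl$label == "2"], 4), 0.4139)
  # empty heterozygous cluster zero-fills
  expect_equal(cl$cx[cl$label == "4"], 0)
  expect_equal(cl$radius[cl$label == "4"], 0)
})

test_that("homozygote labeling is deterministic and FAM-dominant first", {
  # cluster 1 must be the FAM-dominant (larger y - x) cluster regardless of
  # the order in which points arrive
  pool <- tibble::tibble(x = c(0.2, 0.25, 1.4, 1.5), y = c(1.5, 1.4, 0.3, 0.2),
                         snp_id = "T", sample_id = letters[1:4])
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    part <- structure(list(ntc = pool[0, ], het = pool[0, ],
                           untyped = pool[0, ],
                           homozygote_pool = pool[perm, ]),
                      class = "kasp_partition")
    cl <- cluster_pools(part)
    expect_setequal(attr(cl, "members")[["1"]]$sample_id, c("a", "b"))
    expect_setequal(attr(cl, "members")[["2"]]$sample_id, c("c", "d"))
  }
})

test_that("degenerate homozygote pools warn and zero-fill", {
  base <- tibble::tibble(x = c(0.2, 0.2), y = c(0.1, 0.1), snp_id = "T",
                         sample_id = c("NTC", "NTC"))
  one <- tibble::tibble(x = 0.5, y = 1.5, snp_id = "T", sample_id = "s")
  part <- structure(list(ntc = base, het = one[0, ], untyped = one[0, ],
                         homozygote_pool = one),
                    class = "kasp_partition")
  expect_warning(cl <- cluster_pools(part), "single-point")
  expect_equal(cl$n[cl$label == "1"], 1L)  # FAM-dominant singleton
  expect_equal(cl$n[cl$label == "2"], 0L)
  # duplicate points still produce a valid two-cluster structure
  dup <- tibble::tibble(x = c(1, 1), y = c(1, 1), snp_id = "T",
                        sample_id = c("s1", "s2"))
  part2 <- structure(list(ntc = base, het = dup[0, ], untyped = dup[0, ],
                          homozygote_pool = dup),
                     class = "kasp_partition")
  cl2 <- cluster_pools(part2)
  expect_equal(sum(cl2$n[cl2$label %in% c("1", "2")]), 2L)
  expect_equal(attr(cl2, "sse"), 0)
})
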