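# a scaled cohort whose cells are three well-separated Gaussian blobs
blob_cohort <- function(n_per_blob = 20, sep = 10, d = 4, seed = 5) {
  set.seed(seed)
  cents <- sep * diag(d)[1:3, ]
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(n_per_blob * d, sd = 1), ncol = d), 2, cents[i, ], "+")
  }))
  markers <- paste0("M", 1:d)
  colnames(x) <- markers
  cells <- dplyr::bind_cols(
    tibble::tibble(subject_id = rep(c("cg_1", "hd_1", "hd_2"), each = n_per_blob)),
    tibble::as_tibble(x))
  subjects <- tibble::tibble(
    subject_id = c("cg_1", "hd_1", "hd_2"),
    group = c("cGVHD", "HD", "HD"), stratum = NA, batch = "B1",
    outcome = NA_character_, truth_freq = NA_real_)
  co <- new_cohort(cells, subjects, markers, transformed = TRUE, scaled = TRUE)
  list(cohort = co, truth = rep(1:3, each = n_per_blob), centroids = cents)
}

test_that("well-separated blobs are recovered exactly, matching the nearest-centroid oracle", {
  b <- blob_cohort()
  cl <- cluster_cells(b$cohort, k_neighbors = 10, seed = 1)
  got <- cl$labels$cluster
  expect_equal(length(unique(got)), 3)
  oracle <- oracle_nearest_centroid(
    as.matrix(b$cohort$cells[, b$cohort$markers]), b$centroids)
  # same partition up to label names
  expect_equal(length(unique(paste(got, oracle))), 3)
})

test_that("clustering is deterministic under a fixed seed", {
  b <- blob_cohort(seed = 8)
  c1 <- cluster_cells(b$cohort, k_neighbors = 10, seed = 3)
  c2 <- cluster_cells(b$cohort, k_neighbors = 10, seed = 3)
  expect_identical(c1$labels, c2$labels)
})

test_that("a single blob collapses to one cluster as resolution tends to zero", {
  b <- blob_cohort(n_per_blob = 60, sep = 0)
  cl <- cluster_cells(b$cohort, k_neighbors = 15, resolution = 0.01, seed = 2)
  expect_equal(length(unique(cl$labels$cluster)), 1)
})

test_that("precondition failures are informative", {
  b <- blob_cohort(n_per_blob = 5)
  expect_error(cluster_cells(b$cohort, k_neighbors = 15), "k_neighbors")
  raw <- b$cohort; raw$scaled <- FALSE
  expect_error(cluster_cells(raw, k_neighbors = 2), "scaled")
})

test_that("composition fractions sum to one per cluster and counts are conserved", {
  b <- blob_cohort()
  cl <- cluster_cells(b$cohort, k_neighbors = 10, seed = 1)
  sums <- tapply(cl$composition$fraction, cl$composition$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  by_group <- tapply(cl$composition$n, cl$composition$group, sum)
  expect_equal(as.vector(by_group[c("cGVHD", "HD")]), c(20L, 40L))
})

fake_clusters <- function(comp) {
  structure(list(composition = comp,
                 labels = tibble::tibble(.cell = integer(), subject_id = character(),
                                         cluster = integer())),
            class = "cgps_clusters")
}

test_that("the disease cluster is the one dominated by disease-group cells", {
  comp <- tibble::tibble(
    cluster = rep(0:2, each = 2),
    group = rep(c("cGVHD", "HD"), 3),
    n = c(500, 500, 400, 600, 1748, 383),
    fraction = c(0.50, 0.50, 0.40, 0.60, 0.820, 0.180))
  expect_equal(identify_disease_cluster(fake_clusters(comp), min_fraction = 0.75), 2)
  # permutation invariance: relabelling clusters moves the id, not the set
  comp2 <- comp; comp2$cluster <- c(2L, 2L, 1L, 1L, 0L, 0L)
  expect_equal(identify_disease_cluster(fake_clusters(comp2), min_fraction = 0.75), 0)
})

test_that("no qualifying cluster raises the stated error; ties break on count", {
  comp <- tibble::tibble(
    cluster = rep(0:1, each = 2), group = rep(c("cGVHD", "HD"), 2),
    n = c(30, 70, 60, 140), fraction = c(0.30, 0.70, 0.30, 0.70))
  expect_error(identify_disease_cluster(fake_clusters(comp), min_fraction = 0.75),
               "no disease-associated cluster")
  tie <- tibble::tibble(
    cluster = rep(0:1, each = 2), group = rep(c("cGVHD", "HD"), 2),
    n = c(100, 25, 500, 125), fraction = c(0.80, 0.20, 0.80, 0.20))
  expect_equal(identify_disease_cluster(fake_clusters(tie), min_fraction = 0.75), 1)
})

test_that("marker ranking flags planted markers and ignores flat ones", {
  set.seed(4)
  n_in <- 40; n_out <- 160
  cells <- tibble::tibble(
    subject_id = rep(c("cg_1", "hd_1"), c(n_in, n_out)),
    up = c(rnorm(n_in, 3), rnorm(n_out, 0)),
    flat = rnorm(n_in + n_out),
    down = c(rnorm(n_in, -2), rnorm(n_out, 0)))
  subjects <- tibble::tibble(subject_id = c("cg_1", "hd_1"),
                             group = c("cGVHD", "HD"), stratum = NA,
                             batch = "B1", outcome = NA, truth_freq = NA)
  co <- new_cohort(cells, subjects, c("up", "flat", "down"),
                   transformed = TRUE, scaled = TRUE)
  cl <- structure(list(labels = tibble::tibble(
    .cell = seq_len(n_in + n_out),
    subject_id = cells$subject_id,
    cluster = rep(c(1L, 0L), c(n_in, n_out)))), class = "cgps_clusters")
  rk <- rank_cluster_markers(co, cl, 1, alpha = 1e-4, effect_floor = 0.5)
  expect_setequal(rk$marker[rk$selected], c("up", "down"))
  expect_equal(rk$direction[rk$marker == "down"], "down")
  flat_row <- rk[rk$marker == "flat", ]
  expect_gt(flat_row$p_value, 0.05)
  expect_error(rank_cluster_markers(co, cl, 99), "no such cluster")
})
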