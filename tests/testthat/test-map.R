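test_that("classical MDS reproduces exactly-Euclidean configurations", {
  # equilateral triangle, side 1
  tri <- matrix(1, 3, 3) - diag(3)
  fit <- classical_mds(tri)
  expect_equal(as.matrix(stats::dist(fit$coords)), as.matrix(tri),
               ignore_attr = TRUE, tolerance = 1e-9)
  # collinear points embed on one axis
  lin <- abs(outer(0:3, 0:3, "-"))
  fit <- suppressWarnings(classical_mds(lin))
  expect_lt(max(abs(fit$coords[, 2L])), 1e-8)
  # random Euclidean clouds: distances recovered entrywise
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(20), 10, 2)
    D <- as.matrix(stats::dist(X))
    fit <- classical_mds(D)
    expect_lt(max(abs(as.matrix(stats::dist(fit$coords)) - D)), 1e-8)
    expect_equal(fit$negative_mass, 0, tolerance = 1e-6)
  }
})

test_that("MDS handles degenerate and rank-deficient inputs", {
  Z <- matrix(0, 4, 4)
  expect_warning(fit <- classical_mds(Z), "all-zero")
  expect_true(all(fit$coords == 0))
  lin <- abs(outer(0:3, 0:3, "-"))
  expect_warning(fit2 <- classical_mds(lin, dims = 3L), "rank")
  expect_identical(ncol(fit2$coords), 3L)
})

test_that("semantic (non-Euclidean) distances embed with reported negative mass", {
  dm <- build_distance_matrix(small_kb(seed = 5), "phenotype")
  fit <- classical_mds(dm)
  expect_true(all(is.finite(fit$coords)))
  expect_gte(fit$negative_mass, 0)
  expect_lt(fit$negative_mass, 1)
})

test_that("k-means labels blobs correctly and is deterministic under seed", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 8, 0.3), ncol = 2))
  truth <- rep(1:2, each = 20)
  l1 <- kmeans_cluster(X, 2L, seed = 11)
  expect_equal(label_agreement(truth, as.integer(l1)), 1)
  l2 <- kmeans_cluster(X, 2L, seed = 11)
  expect_identical(as.integer(l1), as.integer(l2))
  expect_identical(unique(as.integer(kmeans_cluster(X, 1L))), 1L)
  expect_error(kmeans_cluster(X[1:3, ], 5L), "exceeds")
})

test_that("bootstrap stability selects the planted blob count", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
             matrix(rnorm(40, 10, 0.5), ncol = 2),
             cbind(rnorm(20, 5, 0.5), rnorm(20, 8, 0.5)))
  sel <- select_k_bootstrap(X, 2:6, B = 20, seed = 2)
  expect_identical(sel$k, 3L)
  expect_identical(sel$selected_by, "threshold")
  expect_true(all(sel$stability$stability[sel$stability$k == 3L] > 0.9))
  # determinism given the seed
  sel2 <- select_k_bootstrap(X, 2:6, B = 2, seed = 5)
  sel3 <- select_k_bootstrap(X, 2:6, B = 2, seed = 5)
  expect_identical(sel2$stability, sel3$stability)
  expect_error(select_k_bootstrap(X, integer()), "empty k_range")
})

test_that("a single diffuse blob exercises the fallback path", {
  set.seed(1)
  X <- matrix(rnorm(120), ncol = 2)
  sel <- select_k_bootstrap(X, 2:4, B = 20, seed = 1)
  expect_identical(sel$selected_by, "fallback")
})

test_that("cluster overlap cross-tabulates shared diseases", {
  mp <- list(ids = c("a", "b", "c", "d"), cluster = c(1L, 1L, 2L, 2L))
  mg <- list(ids = c("b", "c", "d", "e"), cluster = c(1L, 1L, 2L, 2L))
  ov <- cluster_overlap(mp, mg)
  expect_identical(attr(ov, "n_shared"), 3L)
  expect_identical(sum(ov$count), 3L)
  # hand-counted flows: b (1->1), c (2->1), d (2->2)
  expect_identical(ov$count[ov$cluster_p == 1L & ov$cluster_g == 1L], 1L)
  expect_identical(ov$count[ov$cluster_p == 2L & ov$cluster_g == 1L], 1L)
  # identical maps give diagonal flows only
  self <- cluster_overlap(mp, mp)
  expect_true(all(self$cluster_p == self$cluster_g))
  expect_identical(sum(self$count), 4L)
  # label permutation only permutes the table
  mg2 <- mg; mg2$cluster <- c(2L, 1L)[mg$cluster]
  ov2 <- cluster_overlap(mp, mg2)
  expect_identical(sort(ov2$count), sort(ov$count))
  expect_error(cluster_overlap(mp, list(ids = "z", cluster = 1L)), "share no")
})

test_that("the fitted map object carries coherent labels, methods, and JSON", {
  fx <- generate_knowledge_base(n_diseases = 24L, n_clusters = 2L,
                                dag_terms = 120L, n_genes = 10L, seed = 3)
  m <- rdmap(fx$kb, "phenotype", k_range = 2:4, B = 5, seed = 2)
  expect_s3_class(m, "rdmap")
  expect_length(m$cluster, length(m$ids))
  expect_setequal(unique(m$cluster), seq_len(m$k))
  expect_identical(nrow(m$stability), m$k)
  df <- as.data.frame(m)
  expect_identical(nrow(df), length(m$ids))
  out <- utils::capture.output(print(summary(m)))
  expect_true(any(grepl("bootstrap stability", out)))
  path <- withr::local_tempfile(fileext = ".json")
  write_map_json(m, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(js$k, m$k)
  expect_identical(nrow(js$diseases), length(m$ids))
  expect_identical(js$metadata$d_max_mode, "exact")
  # predict locates an exact-annotation query at rank 1 on the map
  target <- m$ids[1L]
  hits <- predict(m, fx$kb$diseases[[target]]$terms)
  expect_identical(rank_of_target(hits, target), 1L)
  expect_false(anyNA(hits$x[hits$disease_id == target]))
})
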