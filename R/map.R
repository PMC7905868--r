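#' Classical multidimensional scaling of a disease distance matrix
#'
#' Torgerson scaling: double-centering of squared distances followed by
#' eigendecomposition, keeping the top `dims` non-negative eigenpairs
#' (via [stats::cmdscale()]). Semantic disease distances are generally
#' non-Euclidean, so negative eigenvalues are expected; they are clamped
#' to zero and their relative mass is reported as a map-quality metric.
#' Coordinates are deterministic up to rotation/reflection.
#'
#' @param dm An `rd_dist`, or a symmetric numeric matrix with zero
#'   diagonal.
#' @param dims Number of embedding dimensions (default 2).
#' @return List with `coords` (n x dims matrix, disease ids as
#'   rownames), `eigenvalues` (all n), and `negative_mass` (sum of
#'   absolute negative eigenvalues over total absolute mass).
#' @export
classical_mds <- function(dm, dims = 2L) {
  V <- if (inherits(dm, "rd_dist")) dm$values else as.matrix(dm)
  stopifnot(isSymmetric(unname(V)), all(abs(diag(V)) < 1e-12))
  n <- nrow(V)
  if (dims < 1L || dims > n - 1L) stop("dims must be in [1, n-1]")
  if (all(V == 0)) {
    warning("all-zero distance matrix: degenerate embedding at the origin")
    coords <- matrix(0, n, dims, dimnames = list(rownames(V), NULL))
    return(list(coords = coords, eigenvalues = rep(0, n), negative_mass = 0))
  }
  fit <- stats::cmdscale(V, k = dims, eig = TRUE)
  coords <- fit$points
  eig <- fit$eig
  # effective rank: eigenvalues at numerical noise level carry no geometry
  rank_eff <- sum(eig > max(eig) * 1e-8)
  if (ncol(coords) < dims || rank_eff < dims) {
    warning("requested dims exceed the configuration rank; padding with zeros")
    if (ncol(coords) < dims)
      coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
    if (rank_eff < dims) coords[, (rank_eff + 1L):dims] <- 0
  }
  rownames(coords) <- rownames(V)
  neg_mass <- sum(abs(eig[eig < 0])) / sum(abs(eig))
  list(coords = coords, eigenvalues = eig, negative_mass = neg_mass)
}

#' Seeded k-means clustering of map coordinates
#'
#' Best of `restarts` random starts by total within-cluster sum of
#' squares; deterministic given `seed`.
#'
#' @param coords Numeric matrix of point coordinates.
#' @param k Number of clusters (`1 <= k <= nrow(coords)`).
#' @param seed Integer RNG seed.
#' @param restarts Number of random starts.
#' @return Integer vector of cluster labels in `1..k`, with the fitted
#'   centers in attribute `"centers"`.
#' @export
kmeans_cluster <- function(coords, k, seed = 1L, restarts = 10L) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop("k exceeds the number of points")
  if (k == 1L) {
    labels <- rep(1L, nrow(coords))
    attr(labels, "centers") <- matrix(colMeans(coords), 1L)
    return(labels)
  }
  key <- apply(coords, 1L, paste, collapse = "\r")
  if (length(unique(key)) <= k) {
    # fewer distinct points than requested clusters (common in bootstrap
    # resamples of small maps): every distinct location is its own cluster
    labels <- match(key, unique(key))
    attr(labels, "centers") <- coords[!duplicated(key), , drop = FALSE]
    return(labels)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = restarts, iter.max = 100L)
  labels <- as.integer(km$cluster)
  attr(labels, "centers") <- km$centers
  labels
}

# Jaccard overlap between two label vectors' clusters: for each cluster of
# `ref`, the max Jaccard with any cluster of `other`.
cluster_jaccard <- function(ref, other) {
  vapply(sort(unique(ref)), function(c1) {
    in1 <- ref == c1
    max(vapply(unique(other), function(c2) {
      in2 <- other == c2
      sum(in1 & in2) / sum(in1 | in2)
    }, 0))
  }, 0)
}

#' Select the number of clusters by bootstrap stability
#'
#' For each candidate k the full data set is clustered, then `B`
#' bootstrap resamples are re-clustered; every original point is
#' assigned to its nearest bootstrap centroid and each original
#' cluster's stability is the mean (over resamples) of its maximal
#' Jaccard overlap with the induced clusters. The selected k is the
#' largest candidate whose minimum per-cluster stability reaches
#' `threshold`; if none does, the k with the highest mean stability is
#' returned and flagged (`selected_by = "fallback"`).
#'
#' @param coords Numeric matrix of point coordinates.
#' @param k_range Integer vector of candidate k (within `[2, n-1]`).
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Master seed; per-(k, replicate) seeds are derived from it.
#' @param threshold Minimum per-cluster stability required (default 0.8:
#'   clusters whose bootstrap max-Jaccard falls below ~0.75 are
#'   conventionally regarded as dissolved, and arbitrary k-means splits
#'   of a single homogeneous cloud typically retain 0.6-0.7).
#' @param restarts k-means restarts per fit.
#' @return List with `k`, `selected_by`, `stability` (data frame with
#'   columns `k`, `cluster`, `size`, `stability`), and `mean_stability`
#'   (named by k).
#' @export
select_k_bootstrap <- function(coords, k_range, B = 20L, seed = 1L,
                               threshold = 0.8, restarts = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k_range")
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within [2, n-1]")
  if (B < 2L) stop("B must be >= 2")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  rows <- list()
  for (k in k_range) {
    base <- kmeans_cluster(coords, k, seed = seed + 1000L * k, restarts = restarts)
    jac <- matrix(0, B, k)
    for (b in seq_len(B)) {
      set.seed(seed + 1000L * k + b)
      idx <- sample.int(n, n, replace = TRUE)
      boot <- kmeans_cluster(coords[idx, , drop = FALSE], k,
                             seed = seed + 1000L * k + b, restarts = restarts)
      centers <- attr(boot, "centers")
      # assign every original point to its nearest bootstrap centroid (the
      # resample may have yielded fewer than k distinct clusters)
      d2 <- vapply(seq_len(nrow(centers)), function(c2)
        rowSums(sweep(coords, 2L, centers[c2, ])^2), numeric(n))
      d2 <- as.matrix(d2)
      induced <- max.col(-d2, ties.method = "first")
      jac[b, ] <- cluster_jaccard(base, induced)
    }
    rows[[as.character(k)]] <- data.frame(
      k = k, cluster = seq_len(k),
      size = as.integer(table(factor(base, levels = seq_len(k)))),
      stability = colMeans(jac))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  min_stab <- tapply(tab$stability, tab$k, min)
  mean_stab <- tapply(tab$stability, tab$k, mean)
  passing <- as.integer(names(min_stab))[min_stab >= threshold]
  if (length(passing)) {
    list(k = max(passing), selected_by = "threshold", stability = tab,
         mean_stability = mean_stab)
  } else {
    list(k = as.integer(names(which.max(mean_stab))), selected_by = "fallback",
         stability = tab, mean_stability = mean_stab)
  }
}

#' Cross-map cluster overlap
#'
#' Cross-tabulates cluster labels of two map embeddings over the
#' diseases they share — the flows of the alluvial view connecting a
#' phenotype-based and a gene-based map.
#'
#' @param map_p,map_g `rdmap` objects (or lists with `ids` and
#'   `cluster`).
#' @return Object of class `rd_overlap`: data frame with columns
#'   `cluster_p`, `cluster_g`, `count` (only non-zero flows), with the
#'   shared-disease count in attribute `"n_shared"`.
#' @export
cluster_overlap <- function(map_p, map_g) {
  shared <- intersect(map_p$ids, map_g$ids)
  if (!length(shared)) stop("maps share no disease ids")
  lp <- map_p$cluster[match(shared, map_p$ids)]
  lg <- map_g$cluster[match(shared, map_g$ids)]
  tab <- as.data.frame(table(cluster_p = lp, cluster_g = lg),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  out <- data.frame(cluster_p = as.integer(tab$cluster_p),
                    cluster_g = as.integer(tab$cluster_g),
                    count = as.integer(tab$Freq))
  out <- out[order(out$cluster_p, out$cluster_g), ]
  rownames(out) <- NULL
  attr(out, "n_shared") <- length(shared)
  class(out) <- c("rd_overlap", "data.frame")
  out
}
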