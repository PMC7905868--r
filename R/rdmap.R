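#' Fit a rare-disease map
#'
#' The top-level model fit: builds the all-pairs disease distance matrix
#' of the requested kind (weighted phenotype semantics or gene-GO
#' semantics), embeds it in `dims` dimensions by classical
#' multidimensional scaling, selects the number of clusters by bootstrap
#' stability, and clusters the embedding with seeded k-means.
#'
#' @param kb An `rd_kb` knowledge base (see
#'   [assemble_knowledge_base()]).
#' @param kind `"phenotype"` or `"gene"`.
#' @param dims Embedding dimensionality (default 2).
#' @param k_range Candidate cluster counts (default `2:8`, truncated to
#'   `[2, n-1]`).
#' @param B Bootstrap replicates for k selection.
#' @param threshold Minimum per-cluster bootstrap stability.
#' @param seed Master seed; all stochastic stages derive their seeds
#'   from it and record them.
#' @param restarts k-means restarts.
#' @param distance_matrix Optional precomputed `rd_dist` to skip the
#'   matrix stage (e.g. read back from [read_distance_matrix()]).
#' @return An object of class `rdmap`: list with `ids`, `coords`,
#'   `cluster`, `k`, `stability` (per-cluster table for the selected k),
#'   `selection` (full stability table and selection mode),
#'   `eigenvalues`, `negative_mass`, `kind`, `distance` (the `rd_dist`),
#'   `kb`, `seed`, `call`.
#' @examples
#' fx <- generate_knowledge_base(n_diseases = 20, n_clusters = 2, seed = 1)
#' m <- rdmap(fx$kb, "phenotype", k_range = 2:4, B = 5, seed = 1)
#' print(m)
#' @export
rdmap <- function(kb, kind = c("phenotype", "gene"), dims = 2L,
                  k_range = 2:8, B = 20L, threshold = 0.8, seed = 1L,
                  restarts = 10L, distance_matrix = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(kb, "rd_kb"))
  dm <- if (is.null(distance_matrix)) build_distance_matrix(kb, kind)
        else distance_matrix
  emb <- classical_mds(dm, dims = dims)
  n <- length(dm$ids)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("no feasible k in k_range for ", n, " diseases")
  sel <- select_k_bootstrap(emb$coords, k_range, B = B, seed = seed,
                            threshold = threshold, restarts = restarts)
  labels <- kmeans_cluster(emb$coords, sel$k, seed = seed + 1000L * sel$k,
                           restarts = restarts)
  stab <- sel$stability[sel$stability$k == sel$k,
                        c("cluster", "size", "stability")]
  rownames(stab) <- NULL
  structure(list(ids = dm$ids, coords = emb$coords,
                 cluster = as.integer(labels), k = sel$k,
                 stability = stab, selection = sel,
                 eigenvalues = emb$eigenvalues,
                 negative_mass = emb$negative_mass,
                 kind = kind, distance = dm, kb = kb, seed = seed,
                 call = match.call()),
            class = "rdmap")
}

#' @export
print.rdmap <- function(x, ...) {
  cat(sprintf("Rare-disease map (%s): %d diseases, %d clusters (%s selection)\n",
              x$kind, length(x$ids), x$k, x$selection$selected_by))
  cat(sprintf("  negative eigenvalue mass: %.3f; min cluster stability: %.3f\n",
              x$negative_mass, min(x$stability$stability)))
  invisible(x)
}

#' @export
summary.rdmap <- function(object, ...) {
  pos <- object$eigenvalues[object$eigenvalues > 0]
  explained <- sum(sort(pos, decreasing = TRUE)[seq_len(min(2L, length(pos)))]) / sum(pos)
  out <- list(kind = object$kind, n = length(object$ids), k = object$k,
              selected_by = object$selection$selected_by,
              stability = object$stability,
              variance_explained_2d = explained,
              negative_mass = object$negative_mass,
              census = object$kb$census, seed = object$seed)
  class(out) <- "summary.rdmap"
  out
}

#' @export
print.summary.rdmap <- function(x, ...) {
  cat(sprintf("Rare-disease map (%s)\n", x$kind))
  cat(sprintf("  diseases: %d   clusters: %d (%s)\n", x$n, x$k, x$selected_by))
  cat(sprintf("  leading-2-eigenvalue share of positive mass: %.3f\n",
              x$variance_explained_2d))
  cat(sprintf("  negative eigenvalue mass: %.3f\n", x$negative_mass))
  cat("  per-cluster bootstrap stability:\n")
  print(x$stability, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.rdmap <- function(x, ...) {
  data.frame(disease_id = x$ids,
             name = vapply(x$kb$diseases[x$ids], `[[`, "", "name"),
             x = x$coords[, 1L], y = x$coords[, 2L],
             cluster = x$cluster,
             prevalence_class = vapply(x$kb$diseases[x$ids], `[[`, "",
                                       "prevalence_class"),
             row.names = NULL)
}

#' Plot a rare-disease map
#'
#' Scatter of the 2-D embedding, colored by cluster.
#'
#' @param x An `rdmap`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rdmap <- function(x, ...) {
  pal <- grDevices::hcl.colors(max(x$cluster), "Dark 3")
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = pal[x$cluster],
                 pch = 19, xlab = "MDS 1", ylab = "MDS 2",
                 main = sprintf("%s disease map (k = %d)", x$kind, x$k), ...)
  invisible(x)
}

#' Locate diseases on a map for a query phenotype set
#'
#' `predict` on a fitted map runs the phenotype search against the
#' map's knowledge base and attaches each hit's map coordinates and
#' cluster, mirroring the "locate by phenotypes" interaction.
#'
#' @param object An `rdmap`.
#' @param terms Character vector of query phenotype term ids.
#' @param ... Passed to [search_diseases()] (`method`, `threshold`,
#'   `prevalence`, `weighted`, `max_hits`).
#' @return The [search_diseases()] hit data frame with added `x`, `y`,
#'   `cluster` columns (NA for diseases absent from this map).
#' @export
predict.rdmap <- function(object, terms, ...) {
  hits <- search_diseases(object$kb, terms, ...)
  idx <- match(hits$disease_id, object$ids)
  hits$x <- object$coords[idx, 1L]
  hits$y <- object$coords[idx, 2L]
  hits$cluster <- object$cluster[idx]
  hits
}

#' Serialize a map embedding as JSON
#'
#' Writes the per-disease records (id, name, coordinates, cluster,
#' prevalence class) together with the per-cluster stability table and
#' provenance metadata (seed, d_max mode, selection mode).
#'
#' @param x An `rdmap`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_map_json <- function(x, path) {
  stopifnot(inherits(x, "rdmap"))
  payload <- list(
    kind = x$kind,
    diseases = as.data.frame(x),
    clusters = x$stability,
    k = x$k,
    selection = x$selection$selected_by,
    negative_eigenvalue_mass = x$negative_mass,
    metadata = list(seed = x$seed,
                    d_max_mode = x$distance$metadata$d_max_mode,
                    census = as.list(x$kb$census)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
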