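#' Semantic distance between two genes
#'
#' Averages the per-aspect best-match distance over the three GO aspects:
#' `(Dist_cc + Dist_mf + Dist_bp) / 3`. The per-aspect distance between
#' two genes' term sets is the minimum normalized common-ancestor-path
#' distance over all cross-pairs (best match); `"bma"` replaces the
#' minimum by the symmetric best-match average. An aspect with no terms
#' on either gene contributes 1 (maximal dissimilarity) so the mean stays
#' defined.
#'
#' @param go_dags Named list of `rd_ontology` objects `cc`, `mf`, `bp`.
#' @param g1,g2 Gene annotations: lists with term-id vectors `cc`, `mf`,
#'   `bp`.
#' @param aspect_method `"best_match"` (default) or `"bma"`.
#' @return A number in `[0, 1]`; 0 for identical annotations.
#' @export
gene_distance <- function(go_dags, g1, g2,
                          aspect_method = c("best_match", "bma")) {
  aspect_method <- match.arg(aspect_method)
  if (all(vapply(g1[c("cc", "mf", "bp")], length, 0L) == 0L))
    stop("gene with all GO aspects empty")
  if (all(vapply(g2[c("cc", "mf", "bp")], length, 0L) == 0L))
    stop("gene with all GO aspects empty")
  per_aspect <- vapply(c("cc", "mf", "bp"), function(a) {
    t1 <- g1[[a]]; t2 <- g2[[a]]
    if (!length(t1) || !length(t2)) return(1)
    D <- term_distance_matrix(go_dags[[a]], t1, t2)
    if (aspect_method == "best_match") min(D)
    else (mean(apply(D, 1L, min)) + mean(apply(D, 2L, min))) / 2
  }, 0)
  mean(per_aspect)
}

# Weighted one-way best-match sum used by Eq. 3 and the search scores:
# for each row term i, min_j D[i, j] * (w1[i] * w2[j*]) where j* attains
# the min; ties in the min break toward the larger weight.
one_way_weighted <- function(D, w1, w2) {
  total <- 0
  for (i in seq_len(nrow(D))) {
    row <- D[i, ]
    mn <- min(row)
    wj <- max(w2[row == mn])
    total <- total + mn * w1[i] * wj
  }
  total / nrow(D)
}

#' Weighted phenotype distance between two diseases
#'
#' Symmetric two-way weighted best-match average over the diseases'
#' phenotype term sets: each of d1's terms is matched to its nearest term
#' in d2 (and vice versa), each matched distance is multiplied by the
#' product of the two terms' frequency weights, the per-direction sums
#' are averaged over the direction's term count, and the two directions
#' are averaged. The weight on the matched side is that of the term
#' attaining the minimum distance; ties break toward the larger weight.
#'
#' @param dag Phenotype `rd_ontology`.
#' @param d1,d2 Disease records (lists with `terms` and `weights`), e.g.
#'   entries of `kb$diseases`.
#' @param D Optional precomputed normalized term-distance matrix with
#'   dimnames covering both diseases' terms (lookup fast path).
#' @return A number in `[0, 1]`; 0 for identical term sets with unit
#'   weights.
#' @export
disease_phenotype_distance <- function(dag, d1, d2, D = NULL) {
  if (!length(d1$terms)) stop("disease without phenotypes: ", d1$disease_id)
  if (!length(d2$terms)) stop("disease without phenotypes: ", d2$disease_id)
  t1 <- resolve_terms(dag, d1$terms); t2 <- resolve_terms(dag, d2$terms)
  if (is.null(D)) {
    D12 <- term_distance_matrix(dag, t1, t2)
  } else {
    D12 <- D[t1, t2, drop = FALSE]
  }
  (one_way_weighted(D12, d1$weights, d2$weights) +
     one_way_weighted(t(D12), d2$weights, d1$weights)) / 2
}

#' Gene-based distance between two diseases
#'
#' Unweighted symmetric two-way best-match average of [gene_distance()]
#' over the diseases' pathogenic gene lists.
#'
#' @param go_dags Named list of GO aspect ontologies.
#' @param d1,d2 Disease records with non-empty `genes`.
#' @param gene_annotations Named list of per-gene GO annotations.
#' @param G Optional precomputed gene-gene distance matrix (dimnames =
#'   gene symbols) for the fast path.
#' @return A number in `[0, 1]`.
#' @export
disease_gene_distance <- function(go_dags, d1, d2, gene_annotations, G = NULL) {
  g1 <- intersect(d1$genes, names(gene_annotations))
  g2 <- intersect(d2$genes, names(gene_annotations))
  if (!length(g1)) stop("disease without annotated genes: ", d1$disease_id)
  if (!length(g2)) stop("disease without annotated genes: ", d2$disease_id)
  if (is.null(G)) {
    G <- matrix(0, length(g1), length(g2), dimnames = list(g1, g2))
    for (a in g1) for (b in g2)
      G[a, b] <- gene_distance(go_dags, gene_annotations[[a]], gene_annotations[[b]])
    Gsub <- G
  } else {
    Gsub <- G[g1, g2, drop = FALSE]
  }
  (mean(apply(Gsub, 1L, min)) + mean(apply(Gsub, 2L, min))) / 2
}

#' Jaccard similarity between two term sets
#'
#' `|q intersect t| / |q union t|`; the direct term-matching baseline.
#' Reported as a similarity (higher = more similar). Alias resolution is
#' the caller's responsibility (see [search_diseases()]).
#'
#' @param q,t Non-empty character vectors of term ids.
#' @return A number in `[0, 1]`.
#' @export
jaccard_similarity <- function(q, t) {
  if (!length(q) || !length(t)) stop("Jaccard similarity of an empty set")
  q <- unique(q); t <- unique(t)
  length(intersect(q, t)) / length(union(q, t))
}

#' All-pairs disease distance matrix
#'
#' Computes the symmetric disease-disease distance matrix over all
#' eligible diseases of the requested kind, ordered by disease id.
#' Phenotype matrices use the weighted phenotype distance; gene matrices
#' the gene-based distance (gene-gene distances are computed once and
#' reused).
#'
#' @param kb An `rd_kb`.
#' @param kind `"phenotype"` or `"gene"`.
#' @param verbose Log progress to stderr.
#' @return An object of class `rd_dist`: list with `ids`, `values`
#'   (symmetric matrix, zero diagonal, entries in `[0, 1]`), `kind`,
#'   `metadata`.
#' @export
build_distance_matrix <- function(kb, kind = c("phenotype", "gene"),
                                  verbose = FALSE) {
  kind <- match.arg(kind)
  ids <- eligible_diseases(kb, kind)
  if (length(ids) < 2L)
    stop("fewer than 2 diseases eligible for a ", kind, " matrix")
  n <- length(ids)
  V <- matrix(0, n, n, dimnames = list(ids, ids))

  if (kind == "phenotype") {
    all_terms <- sort(unique(unlist(lapply(kb$diseases[ids], `[[`, "terms"),
                                    use.names = FALSE)))
    D <- term_distance_matrix(kb$phenotype_dag, all_terms, all_terms)
    for (i in seq_len(n - 1L)) {
      if (verbose && i %% 50L == 0L)
        message("phenotype matrix row ", i, "/", n)
      di <- kb$diseases[[ids[i]]]
      for (j in (i + 1L):n) {
        V[i, j] <- V[j, i] <-
          disease_phenotype_distance(kb$phenotype_dag, di, kb$diseases[[ids[j]]], D = D)
      }
    }
  } else {
    syms <- sort(unique(intersect(
      unlist(lapply(kb$diseases[ids], `[[`, "genes"), use.names = FALSE),
      names(kb$genes))))
    G <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
    if (length(syms) > 1L)
      for (a in seq_len(length(syms) - 1L)) for (b in (a + 1L):length(syms))
        G[a, b] <- G[b, a] <- gene_distance(kb$go_dags, kb$genes[[syms[a]]],
                                            kb$genes[[syms[b]]])
    for (i in seq_len(n - 1L)) {
      if (verbose && i %% 50L == 0L) message("gene matrix row ", i, "/", n)
      di <- kb$diseases[[ids[i]]]
      for (j in (i + 1L):n) {
        V[i, j] <- V[j, i] <-
          disease_gene_distance(kb$go_dags, di, kb$diseases[[ids[j]]],
                                kb$genes, G = G)
      }
    }
  }

  structure(list(ids = ids, values = V, kind = kind,
                 metadata = list(
                   d_max_mode = if (kind == "phenotype") kb$phenotype_dag$d_max_mode
                                else kb$go_dags$cc$d_max_mode,
                   weights_table = kb$weights_table,
                   census = kb$census)),
            class = "rd_dist")
}

#' @export
print.rd_dist <- function(x, ...) {
  cat(sprintf("%s disease distance matrix: %d x %d, mean off-diagonal %.3f\n",
              x$kind, length(x$ids), length(x$ids),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Write / read a distance matrix cache
#'
#' Serializes an `rd_dist` as a plain-text rectangular matrix (TSV) with
#' an id sidecar and JSON metadata, and reads it back.
#'
#' @param dm An `rd_dist`.
#' @param prefix Path prefix; writes `<prefix>.tsv`, `<prefix>.ids`,
#'   `<prefix>.meta.json`.
#' @return `write_distance_matrix`: `prefix`, invisibly.
#'   `read_distance_matrix`: an `rd_dist`.
#' @export
write_distance_matrix <- function(dm, prefix) {
  stopifnot(inherits(dm, "rd_dist"))
  utils::write.table(format(dm$values, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dm$ids, paste0(prefix, ".ids"))
  jsonlite::write_json(c(dm$metadata, list(kind = dm$kind)),
                       paste0(prefix, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(prefix) {
  ids <- readLines(paste0(prefix, ".ids"))
  V <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(V) <- list(ids, ids)
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"), simplifyVector = TRUE)
  structure(list(ids = ids, values = V, kind = meta$kind,
                 metadata = meta[setdiff(names(meta), "kind")]),
            class = "rd_dist")
}
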