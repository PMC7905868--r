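# Shared fixtures and independent brute-force oracles.
# The oracles deliberately avoid the package's min-plus matrix machinery:
# ancestor sets are found by exhaustive recursive climbing, distances by
# direct enumeration over common ancestors.

# 7-node toy DAG: root R; A, B children of R; A1, A2 children of A;
# B1 child of B; B2 child of B1. Exact d_max = 5 (A-leaves vs B2).
toy_dag <- function() {
  ontology(c("R", "A", "B", "A1", "A2", "B1", "B2"),
           parents = list(A = "R", B = "R", A1 = "A", A2 = "A",
                          B1 = "B", B2 = "B1"),
           d_max_mode = "exact")
}

# All ancestors of `id` with the minimum climb length to each, by
# exhaustive recursion over every parent chain.
bf_ancestors <- function(dag, id) {
  best <- new.env(parent = emptyenv())
  climb <- function(node, len) {
    prev <- get0(node, best, ifnotfound = Inf)
    if (len >= prev) return(invisible())
    assign(node, len, best)
    for (p in dag$parents[[node]]) climb(p, len + 1L)
  }
  climb(id, 0L)
  unlist(as.list(best))
}

# Unnormalized common-ancestor-path distance; Inf when no common ancestor.
bf_term_distance_raw <- function(dag, t1, t2) {
  a1 <- bf_ancestors(dag, t1)
  a2 <- bf_ancestors(dag, t2)
  common <- intersect(names(a1), names(a2))
  if (!length(common)) return(Inf)
  min(a1[common] + a2[common])
}

# Weighted two-way best-match disease distance, naive loops.
bf_disease_phenotype_distance <- function(dag, d1, d2) {
  dmax <- dag$d_max
  dist1 <- function(ta, tb) min(bf_term_distance_raw(dag, ta, tb) / dmax, 1)
  one_way <- function(ta, wa, tb, wb) {
    total <- 0
    for (i in seq_along(ta)) {
      ds <- vapply(tb, function(t) dist1(ta[i], t), 0)
      mn <- min(ds)
      wj <- max(wb[ds == mn])
      total <- total + mn * wa[i] * wj
    }
    total / length(ta)
  }
  (one_way(d1$terms, d1$weights, d2$terms, d2$weights) +
     one_way(d2$terms, d2$weights, d1$terms, d1$weights)) / 2
}

bf_gene_distance <- function(go_dags, g1, g2) {
  per <- vapply(c("cc", "mf", "bp"), function(a) {
    t1 <- g1[[a]]; t2 <- g2[[a]]
    if (!length(t1) || !length(t2)) return(1)
    min(vapply(t1, function(x) min(vapply(t2, function(y)
      min(bf_term_distance_raw(go_dags[[a]], x, y) / go_dags[[a]]$d_max, 1),
      0)), 0))
  }, 0)
  mean(per)
}

bf_disease_gene_distance <- function(go_dags, d1, d2, annos) {
  g1 <- intersect(d1$genes, names(annos))
  g2 <- intersect(d2$genes, names(annos))
  G <- outer(g1, g2, Vectorize(function(a, b)
    bf_gene_distance(go_dags, annos[[a]], annos[[b]])))
  (mean(apply(G, 1L, min)) + mean(apply(G, 2L, min))) / 2
}

# Small planted/non-planted knowledge bases reused across test files.
small_kb <- function(seed = 1L, n = 20L, clusters = 1L) {
  generate_knowledge_base(n_diseases = n, n_clusters = clusters,
                          dag_terms = 120L, n_genes = 12L, seed = seed)$kb
}
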