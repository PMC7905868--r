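go_toy <- function() {
  list(cc = toy_dag(), mf = toy_dag(), bp = toy_dag())
}

test_that("gene distance averages the three aspect distances", {
  gos <- go_toy()
  g <- list(cc = "A1", mf = "B1", bp = "A2")
  expect_equal(gene_distance(gos, g, g), 0)
  g2 <- list(cc = "A2", mf = "B2", bp = "A1")
  # aspect distances: cc d(A1,A2)=0.4, mf d(B1,B2)=0.2, bp d(A2,A1)=0.4
  expect_equal(gene_distance(gos, g, g2), mean(c(0.4, 0.2, 0.4)))
  expect_equal(gene_distance(gos, g, g2), gene_distance(gos, g2, g))
  # missing aspect contributes maximal dissimilarity
  g3 <- list(cc = "A2", mf = "B2", bp = character())
  expect_equal(gene_distance(gos, g, g3), mean(c(0.4, 0.2, 1)))
  g4 <- list(cc = character(), mf = character(), bp = character())
  expect_error(gene_distance(gos, g, g4), "all GO aspects empty")
})

test_that("disease phenotype distance matches hand-worked cases", {
  dag <- toy_dag()
  mk <- function(id, terms, w) list(disease_id = id, terms = terms, weights = w)
  same <- mk("x", c("A1", "B1"), c(1, 1))
  expect_equal(disease_phenotype_distance(dag, same, same), 0)
  expect_equal(disease_phenotype_distance(dag, mk("a", "A1", 1), mk("b", "A2", 1)),
               0.4)
  # weights deflate the matched distance in both directions
  expect_equal(disease_phenotype_distance(dag, mk("a", "A1", 0.5),
                                          mk("b", "A2", 0.5)),
               0.5 * (0.4 * 0.25 + 0.4 * 0.25))
  expect_error(disease_phenotype_distance(dag, mk("a", character(), numeric()),
                                          same), "without phenotypes")
})

test_that("argmin ties in the weighted matching break toward the larger weight", {
  dag <- toy_dag()
  # query side term A: both A1 and A2 are at distance 1/5; weights differ
  d1 <- list(disease_id = "q", terms = "A", weights = 1)
  d2 <- list(disease_id = "t", terms = c("A1", "A2"), weights = c(0.2, 0.9))
  # one-way q->t: 0.2 * 1 * 0.9 (larger weight wins the tie)
  # one-way t->q: (0.2*0.2*1 + 0.2*0.9*1)/2
  expect_equal(disease_phenotype_distance(dag, d1, d2),
               0.5 * (0.2 * 0.9 + (0.2 * 0.2 + 0.2 * 0.9) / 2))
})

test_that("disease distances agree with naive brute-force enumeration", {
  fx <- generate_knowledge_base(n_diseases = 20L, dag_terms = 80L,
                                n_genes = 10L, terms_per_disease = 5L,
                                go_terms_per_aspect = 2L, seed = 6)
  kb <- fx$kb
  ids <- eligible_diseases(kb, "phenotype")
  pick <- utils::combn(ids[1:8], 2L)
  for (p in seq_len(ncol(pick))) {
    d1 <- kb$diseases[[pick[1L, p]]]; d2 <- kb$diseases[[pick[2L, p]]]
    expect_equal(disease_phenotype_distance(kb$phenotype_dag, d1, d2),
                 bf_disease_phenotype_distance(kb$phenotype_dag, d1, d2))
    expect_equal(disease_gene_distance(kb$go_dags, d1, d2, kb$genes),
                 bf_disease_gene_distance(kb$go_dags, d1, d2, kb$genes))
  }
})

test_that("with unit weights the phenotype distance reduces to the unweighted two-way best-match", {
  fx <- generate_knowledge_base(n_diseases = 10L, dag_terms = 80L, seed = 8)
  kb <- fx$kb
  ids <- eligible_diseases(kb, "phenotype")[1:6]
  for (p in seq_len(ncol(utils::combn(ids, 2L)))) {
    pair <- utils::combn(ids, 2L)[, p]
    d1 <- kb$diseases[[pair[1L]]]; d2 <- kb$diseases[[pair[2L]]]
    d1$weights <- rep(1, length(d1$terms)); d2$weights <- rep(1, length(d2$terms))
    D <- term_distance_matrix(kb$phenotype_dag, d1$terms, d2$terms)
    unweighted <- (mean(apply(D, 1L, min)) + mean(apply(D, 2L, min))) / 2
    expect_equal(disease_phenotype_distance(kb$phenotype_dag, d1, d2), unweighted)
  }
})

test_that("the weighted best-match distance is not a metric (triangle violation pinned)", {
  dag <- toy_dag()
  a <- list(disease_id = "a", terms = "A1", weights = 1)
  c_ <- list(disease_id = "c", terms = "B2", weights = 1)
  hub <- list(disease_id = "b", terms = c("A1", "B2"), weights = c(1, 1))
  d_ab <- disease_phenotype_distance(dag, a, hub)
  d_bc <- disease_phenotype_distance(dag, hub, c_)
  d_ac <- disease_phenotype_distance(dag, a, c_)
  expect_equal(d_ab, 0.25)
  expect_equal(d_bc, 0.25)
  expect_equal(d_ac, 1)
  expect_gt(d_ac, d_ab + d_bc)
})

test_that("Jaccard similarity counts shared terms", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c", "d"), c("a", "b", "e")), 0.4)
  expect_error(jaccard_similarity(character(), "a"), "empty")
})

test_that("distance matrices are symmetric, bounded, and consistent with pairwise calls", {
  fx <- generate_knowledge_base(n_diseases = 12L, dag_terms = 80L,
                                n_genes = 8L, seed = 10)
  kb <- fx$kb
  for (kind in c("phenotype", "gene")) {
    dm <- build_distance_matrix(kb, kind)
    expect_identical(dm$ids, sort(dm$ids))
    expect_equal(dm$values, t(dm$values))
    expect_true(all(diag(dm$values) == 0))
    expect_true(all(dm$values >= 0 & dm$values <= 1))
  }
  dm <- build_distance_matrix(kb, "phenotype")
  i <- dm$ids[2L]; j <- dm$ids[7L]
  expect_equal(dm$values[i, j],
               disease_phenotype_distance(kb$phenotype_dag,
                                          kb$diseases[[i]], kb$diseases[[j]]))
  gm <- build_distance_matrix(kb, "gene")
  expect_equal(gm$values[i, j],
               disease_gene_distance(kb$go_dags, kb$diseases[[i]],
                                     kb$diseases[[j]], kb$genes))
})

test_that("distance matrices survive the text cache round-trip", {
  fx <- generate_knowledge_base(n_diseases = 8L, dag_terms = 60L, seed = 12)
  dm <- build_distance_matrix(fx$kb, "phenotype")
  prefix <- file.path(withr::local_tempdir(), "phen")
  write_distance_matrix(dm, prefix)
  back <- read_distance_matrix(prefix)
  expect_identical(back$ids, dm$ids)
  expect_equal(back$values, dm$values)
  expect_identical(back$kind, "phenotype")
})
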