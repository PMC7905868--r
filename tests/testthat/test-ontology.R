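test_that("minimal OBO files load into validated DAGs", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: HP:0000001", "name: root", "",
           "[Term]", "id: HP:0000002", "name: child one",
           "is_a: HP:0000001 ! root", "",
           "[Term]", "id: HP:0000003", "name: child two",
           "alt_id: HP:0009999",
           "is_a: HP:0000001", "")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  dag <- load_obo(path, d_max_mode = "exact")
  expect_length(dag$ids, 3L)
  expect_identical(dag$roots, "HP:0000001")
  expect_identical(unname(dag$depth[c("HP:0000001", "HP:0000002")]), c(0L, 1L))
  expect_identical(resolve_terms(dag, "HP:0009999"), "HP:0000003")
})

test_that("obsolete terms are skipped and structural errors are caught", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "",
               "[Term]", "id: B", "name: b", "is_a: A", "is_obsolete: true", ""),
             path)
  expect_warning(dag <- load_obo(path), "single-term")
  expect_length(dag$ids, 1L)

  writeLines(c("[Term]", "id: A", "name: a", "is_a: B", "",
               "[Term]", "id: B", "name: b", "is_a: A", ""), path)
  expect_error(load_obo(path), "cycle")

  writeLines(c("[Term]", "id: A", "name: a", "is_a: NOPE", ""), path)
  expect_error(load_obo(path), "unknown term")

  expect_error(load_obo(file.path(tempdir(), "absent.obo")), "cannot read")
})

test_that("toy-DAG distances match hand-derived values", {
  dag <- toy_dag()
  expect_identical(dag$d_max, 5L)
  expect_equal(term_distance(dag, "A1", "A1"), 0)
  expect_equal(term_distance(dag, "A1", "A2"), 0.4)   # 2 edges via A, /5
  expect_equal(term_distance(dag, "A1", "B1"), 0.8)   # 4 edges via R, /5
  expect_equal(term_distance(dag, "A1", "B2"), 1)     # 5 edges via R = d_max
  expect_equal(term_distance(dag, "B1", "A1"), term_distance(dag, "A1", "B1"))
  expect_error(term_distance(dag, "A1", "NOPE"), "NOPE")
})

test_that("d_max: chain case, exactness, and the depth bound", {
  chain <- ontology(c("R", "A", "A1"), parents = list(A = "R", A1 = "A"),
                    d_max_mode = "exact")
  expect_identical(chain$d_max, 2L)
  expect_identical(compute_d_max(toy_dag(), "exact"), 5L)
  for (s in 1:5) {
    dag <- generate_dag(40, seed = s, d_max_mode = "exact")
    expect_gte(compute_d_max(dag, "depth_bound"), dag$d_max)
  }
  single <- suppressWarnings(ontology("R"))
  expect_identical(single$d_max, 0L)
  expect_equal(term_distance(single, "R", "R"), 0)
})

test_that("normalized distance agrees with exhaustive common-ancestor search", {
  for (s in 1:8) {
    dag <- generate_dag(30, seed = s, d_max_mode = "exact")
    D <- term_distance_matrix(dag)
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    ids <- dag$ids
    pairs <- utils::combn(length(ids), 2L)
    for (p in seq_len(ncol(pairs))) {
      t1 <- ids[pairs[1L, p]]; t2 <- ids[pairs[2L, p]]
      expect_equal(D[t1, t2] * dag$d_max, bf_term_distance_raw(dag, t1, t2),
                   info = sprintf("seed %d pair %s-%s", s, t1, t2))
    }
  }
})

test_that("terms in different connected components are maximally distant", {
  dag <- ontology(c("R1", "R2", "C1", "C2"),
                  parents = list(C1 = "R1", C2 = "R2"), d_max_mode = "exact")
  expect_equal(term_distance(dag, "C1", "C2"), 1)
  expect_equal(term_distance(dag, "R1", "R2"), 1)
  expect_equal(term_distance(dag, "C1", "R1"), 1 / dag$d_max)
})

test_that("imprecision neighborhoods are exactly the adjacent terms", {
  dag <- toy_dag()
  expect_setequal(neighbors_for_imprecision(dag, "R"), c("A", "B"))
  expect_setequal(neighbors_for_imprecision(dag, "A1"), "A")
  expect_setequal(neighbors_for_imprecision(dag, "B"), c("R", "B1"))
  # replacing a term by an adjacent one moves its unnormalized distance to
  # any fixed target by at most 1 in the constrained direction: a parent
  # keeps every common-ancestor route of the child (so the distance cannot
  # drop by more than 1), a child extends each of them by one edge (so it
  # cannot rise by more than 1). The opposite direction is unbounded on
  # multi-parent DAGs, where an alternate parent can open a shortcut.
  for (s in 1:3) {
    rdag <- generate_dag(25, seed = s, d_max_mode = "exact")
    for (t in sample(rdag$ids, 5L)) {
      for (target in sample(rdag$ids, 3L)) {
        d0 <- bf_term_distance_raw(rdag, t, target)
        for (nb in rdag$parents[[t]])
          expect_gte(bf_term_distance_raw(rdag, nb, target), d0 - 1)
        for (nb in rdag$children[[t]])
          expect_lte(bf_term_distance_raw(rdag, nb, target), d0 + 1)
      }
    }
  }
})

test_that("OBO write/load round-trips preserve the DAG", {
  dag <- generate_dag(50, seed = 9, d_max_mode = "exact")
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- load_obo(path, d_max_mode = "exact")
  expect_setequal(back$ids, dag$ids)
  expect_identical(back$parents[order(names(back$parents))],
                   dag$parents[order(names(dag$parents))])
  expect_identical(back$d_max, dag$d_max)
  expect_identical(back$depth[dag$ids], dag$depth[dag$ids])
})
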