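test_that("frequency weights anchor, order, and pass numerics through", {
  expect_equal(frequency_weight("Obligate (100%)"), 1.0)
  expect_equal(frequency_weight("Excluded (0%)"), 0.0)
  expect_equal(frequency_weight("Frequent (79-30%)"), 0.545)
  expect_equal(frequency_weight("frequent"), 0.545)        # bare class name
  expect_equal(frequency_weight("0.37"), 0.37)
  ladder <- c("Obligate (100%)", "Very frequent (99-80%)", "Frequent (79-30%)",
              "Occasional (29-5%)", "Very rare (<4-1%)", "Excluded (0%)")
  w <- frequency_weight(ladder)
  expect_true(all(diff(w) < 0))                            # strictly decreasing
  expect_error(frequency_weight("Sometimes"), "Sometimes")
})

test_that("phenotype TSVs load into per-disease records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease_id\tdisease_name\thpo_id\tfrequency_label",
               "ORPHA:1\tone\tHP:0000001\tObligate (100%)",
               "ORPHA:1\tone\tHP:0000002\tFrequent (79-30%)",
               "ORPHA:2\ttwo\tHP:0000002\tOccasional (29-5%)",
               "ORPHA:2\ttwo\tHP:0000003\tExcluded (0%)"), path)
  recs <- load_disease_phenotypes(path)
  expect_length(recs, 2L)
  expect_length(recs[["ORPHA:1"]]$terms, 2L)
  expect_identical(recs[["ORPHA:2"]]$freq_labels[2L], "Excluded (0%)")

  writeLines(c("disease_id\tdisease_name\thpo_id\tfrequency_label",
               "ORPHA:1\tone\tHP:0000001\tWhenever"), path)
  expect_error(load_disease_phenotypes(path), "Whenever")
})

test_that("gene TSVs load and empty gene rows drop the disease with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease_id\tgene_symbol",
               "ORPHA:1\tBRCA1", "ORPHA:1\tBRCA2", "ORPHA:2\t"), path)
  expect_warning(gm <- load_disease_genes(path), "empty gene lists")
  expect_length(gm, 1L)
  expect_identical(gm[["ORPHA:1"]], c("BRCA1", "BRCA2"))
})

test_that("knowledge-base assembly reports the annotation census", {
  dag <- toy_dag()
  recs <- list(
    d1 = list(disease_id = "d1", name = "one", terms = c("A1", "B1"),
              freq_labels = rep("Obligate (100%)", 2), xrefs = character()),
    d2 = list(disease_id = "d2", name = "two", terms = "A2",
              freq_labels = "Frequent (79-30%)", xrefs = character()))
  genes <- list(d2 = "G1", d3 = "G2")
  kb <- assemble_knowledge_base(recs, genes, NULL, dag)
  expect_identical(unname(kb$census), c(2L, 2L, 1L))
  # census identity: |union| = phen + gene - overlap
  expect_identical(length(kb$diseases),
                   sum(kb$census[c("phenotype", "gene")]) - kb$census[["overlap"]])
})

test_that("unresolvable terms are dropped with a warning, census unchanged", {
  dag <- toy_dag()
  recs <- list(d1 = list(disease_id = "d1", name = "one",
                         terms = c("A1", "HP:BOGUS"),
                         freq_labels = rep("Obligate (100%)", 2),
                         xrefs = character()))
  expect_warning(kb <- assemble_knowledge_base(recs, NULL, NULL, dag),
                 "did not resolve")
  expect_identical(kb$diseases$d1$terms, "A1")
  expect_identical(kb$census[["phenotype"]], 1L)
  expect_identical(kb$dropped_terms, 1L)
})

test_that("diseases with only Excluded phenotypes are flagged off the map", {
  dag <- toy_dag()
  recs <- list(
    d1 = list(disease_id = "d1", name = "one", terms = "A1",
              freq_labels = "Excluded (0%)", xrefs = character()),
    d2 = list(disease_id = "d2", name = "two", terms = "A2",
              freq_labels = "Obligate (100%)", xrefs = character()),
    d3 = list(disease_id = "d3", name = "three", terms = "B1",
              freq_labels = "Obligate (100%)", xrefs = character()))
  kb <- assemble_knowledge_base(recs, NULL, NULL, dag)
  expect_true(kb$diseases$d1$all_excluded)
  expect_setequal(eligible_diseases(kb, "phenotype"), c("d2", "d3"))
})

test_that("loading is idempotent and XML matches the generator manifest", {
  dir <- withr::local_tempdir()
  fx <- generate_knowledge_base(n_diseases = 20L, dag_terms = 100L,
                                n_genes = 10L, seed = 4, dir = dir)
  x1 <- load_disease_phenotypes(fx$files[["phenotypes_xml"]], "orphanet_xml")
  x2 <- load_disease_phenotypes(fx$files[["phenotypes_xml"]], "orphanet_xml")
  expect_identical(x1, x2)
  expect_length(x1, 20L)
  for (id in names(fx$manifest$diseases))
    expect_setequal(x1[[id]]$terms, fx$manifest$diseases[[id]]$terms)
  gm <- load_disease_genes(fx$files[["genes_xml"]], "orphanet_xml")
  for (id in names(fx$manifest$genes))
    expect_setequal(gm[[id]], fx$manifest$genes[[id]])
})

test_that("census comparison against the published release is reported", {
  kb <- small_kb(seed = 2)
  cen <- kb_census(kb)
  expect_identical(rownames(cen), c("phenotype", "gene", "overlap"))
  expect_identical(cen$reference, c(3287L, 3789L, 1718L))
  expect_true(all(cen$count >= 0L))
})
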