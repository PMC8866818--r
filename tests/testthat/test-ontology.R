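triple_in <- function(g, super) {
  k <- function(x) paste(x$s, x$p, x$o, x$lit)
  k(g) %in% k(super)
}

test_that("registry holds the core vocabulary with unique absolute IRIs", {
  reg <- term_registry()
  core13 <- c("NCBITaxon_9606", "IAO_0000219", "BFO_0000057", "NPT_0020000",
              "OBI_0000070", "OBI_0000299", "OBI_0001933", "IAO_0000109",
              "OBI_0001938", "OBI_0002135", "OBI_0000097", "RO_0000052",
              "OBI_0000011")
  for (id in core13)
    expect_identical(resolve_term(id, reg), OBO(id))
  vals <- unname(unclass(reg))
  expect_true(all(grepl("^https?://", vals)))
  # label and CURIE keys resolve to the same IRI
  expect_identical(resolve_term("planned process", reg),
                   resolve_term("OBI_0000011", reg))
  expect_error(resolve_term("no such term", reg), "resolution error")
  expect_error(resolve_term("http://unknown.example/x", reg), "resolution error")
})

test_that("define_term yields one subclass axiom per parent and one restriction axiom per entry", {
  reg <- term_registry()
  td <- define_term(
    "right hippocampal volume feature extraction using the FIRST segmentation utility from FSL on a T1 MRI image",
    parents = c("planned process",
                "https://kg.cohortkg.org/onto/RightHippocampalVolumeFeatureExtraction"),
    restrictions = list(
      c("has specified input", "some", "image"),
      c("has specified output", "some",
        "https://kg.cohortkg.org/onto/RightHippocampalVolumeMeasurementDatum"),
      c("achieves planned objective", "some", "feature extraction objective")),
    registry = reg)
  expect_equal(unname(axiom_counts(td)), c(2L, 3L))
  g <- as_graph(td)
  expect_equal(sum(g$p == SCO & !startsWith(g$o, "_:")), 2L)
  restr <- g$o[g$p == SCO & startsWith(g$o, "_:")]
  expect_equal(length(restr), 3L)
  for (b in restr) {
    expect_equal(sum(g$s == b & g$p == "http://www.w3.org/2002/07/owl#onProperty"), 1L)
    expect_equal(sum(g$s == b & g$p == "http://www.w3.org/2002/07/owl#someValuesFrom"), 1L)
  }
})

test_that("define_term minimal and error contracts", {
  td <- define_term("x", parents = "planned process")
  expect_equal(unname(axiom_counts(td)), c(1L, 0L))
  g <- as_graph(td)
  expect_equal(sum(g$p == SCO), 1L)
  expect_error(define_term("x", parents = character(0)), "definition error")
  expect_error(define_term("", parents = "planned process"), "definition error")
  expect_error(
    define_term("x", parents = "planned process",
                restrictions = list(c("has specified input", "some",
                                      "http://unregistered.example/Filler"))),
    "resolution error.*unregistered.example")
  expect_error(
    define_term("x", parents = "planned process",
                restrictions = list(c("has specified input", "only", "image"))),
    "quantifier")
})

test_that("module extraction follows the recursive reference closure", {
  onto <- toy_ontology()
  m <- extract_module(onto, "http://t/A")
  expect_setequal(graph_members(m), c("http://t/A", "http://t/B", "http://t/C"))
  expect_equal(graph_size(m), 2L)  # A<B and B<C only
  m2 <- extract_module(onto, "http://t/D")
  expect_setequal(graph_members(m2), c("http://t/D", "http://t/E"))
  # identity: all classes as seeds returns the ontology
  all_seeds <- graph_members(onto)
  expect_true(graph_equal(extract_module(onto, all_seeds), onto))
})

test_that("module extraction is monotone and idempotent, and crosses restriction blanks", {
  onto <- merge_graphs(core_ontology(), app_ontology())
  seeds1 <- OBO("NPT_0020000")
  seeds2 <- c(seeds1, "https://kg.cohortkg.org/onto/LeftHippocampalVolumeFeatureExtractionFIRST")
  m1 <- extract_module(onto, seeds1)
  m2 <- extract_module(onto, seeds2)
  expect_true(all(graph_members(m1) %in% graph_members(m2)))
  expect_true(all(triple_in(m1, m2)))
  # closure pulls the restriction filler (the measurement datum class) in
  expect_true("https://kg.cohortkg.org/onto/LeftHippocampalVolumeMeasurementDatum" %in%
                graph_members(m2))
  # idempotent
  m1b <- extract_module(m1, seeds1)
  expect_true(graph_equal(m1, m1b))
  # missing seed warns and is declared
  expect_warning(m3 <- extract_module(onto, "http://t/NotThere"), "not present")
  expect_true("http://t/NotThere" %in% graph_members(m3))
})

test_that("modules merged with instance data round-trip through serialization", {
  fix <- toy_score_graph()
  module <- extract_module(core_ontology(), OBO("NPT_0020000"))
  merged <- merge_graphs(module, fix$graph, app_ontology())
  path <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(merged, path)
  expect_true(graph_isomorphic(read_turtle(path), merged))
})
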