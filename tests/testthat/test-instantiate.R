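test_that("subject fragments follow the human/role/identifier/anatomy pattern", {
  pol <- pseudonym_policy("s")
  iri <- mint_subject_iri("d1", "A1", pol)
  frag <- instantiate_subject(iri, subject_label(iri), "PD")
  expect_true(any(frag$s == iri & frag$p == RT & frag$o == HUMAN))
  expect_equal(sum(frag$p == OBO("RO_0000052")), 1L)   # one role inheres
  expect_equal(sum(frag$p == OBO("IAO_0000219")), 1L)  # one identifier denotes
  # anatomy skeleton present
  expect_true(any(frag$o == "https://kg.cohortkg.org/onto/LeftHippocampus"))
  expect_true(any(frag$o == "https://kg.cohortkg.org/onto/RightHippocampus"))
  # two subjects share no instance nodes
  iri2 <- mint_subject_iri("d1", "A2", pol)
  frag2 <- instantiate_subject(iri2, subject_label(iri2), "HC")
  shared <- intersect(unique(frag$s), unique(frag2$s))
  expect_length(shared, 0L)
  expect_error(instantiate_subject(iri, "x", "XX"), "instantiation error")
})

test_that("assessment fragments carry the output -> value-spec -> value path", {
  pol <- pseudonym_policy("s")
  iri <- mint_subject_iri("d1", "A1", pol)
  frag <- instantiate_assessment(iri, "NPT_0020000", 24)
  assay <- frag$s[frag$p == RT & frag$o == MOCA]
  expect_length(assay, 1L)
  datum <- frag$o[frag$s == assay & frag$p == OBO("OBI_0000299")]
  expect_length(datum, 1L)
  vs <- frag$o[frag$s == datum & frag$p == OBO("OBI_0001938")]
  expect_length(vs, 1L)
  val <- frag$o[frag$s == vs & frag$p == OBO("OBI_0002135")]
  expect_identical(val, "24")
  expect_identical(frag$dt[frag$s == vs & frag$p == OBO("OBI_0002135")], "integer")
  # missing score: no fragment, one logged skip
  expect_message(empty <- instantiate_assessment(iri, "NPT_0020000", NA),
                 "skip")
  expect_equal(graph_size(empty), 0L)
})

test_that("feature extraction links datum to the correct hippocampus via aboutness", {
  pol <- pseudonym_policy("s")
  iri <- mint_subject_iri("d1", "A1", pol)
  anat <- instantiate_subject(iri, subject_label(iri), "PD")
  for (side in c("left", "right")) {
    frag <- instantiate_feature_extraction(iri, 3700.5, side, anat)
    proc <- frag$s[frag$p == RT & grepl("FeatureExtractionFIRST", frag$o)]
    expect_length(frag$o[frag$s == proc & frag$p == OBO("OBI_0000293")], 1L)
    expect_length(frag$o[frag$s == proc & frag$p == OBO("OBI_0000299")], 1L)
    datum <- frag$o[frag$s == proc & frag$p == OBO("OBI_0000299")]
    about <- frag$o[frag$s == datum & frag$p == OBO("IAO_0000136")]
    expect_identical(about, paste0(iri, "/hippocampus-", side))
  }
  ldat <- instantiate_feature_extraction(iri, 3000, "left", anat)
  rdat <- instantiate_feature_extraction(iri, 3100, "right", anat)
  lmd <- ldat$s[ldat$p == RT & ldat$o == OBO("IAO_0000109")]
  rmd <- rdat$s[rdat$p == RT & rdat$o == OBO("IAO_0000109")]
  expect_false(lmd == rmd)
  expect_error(instantiate_feature_extraction(iri, 3000, "up", anat),
               "instantiation error")
  expect_error(instantiate_feature_extraction(iri, 3000, graph = anat),
               "instantiation error")
  # no anatomy -> error naming the subject
  expect_error(instantiate_feature_extraction("http://x/nobody", 3000, "left",
                                              rdf_graph()),
               "nobody")
})

test_that("one assay instance per scored subject, with row conservation by source", {
  fix <- make_cohort(small_config(seed = 11, n = c(40, 30, 20, 10)))
  g <- fix$graph
  n_assays <- sum(g$p == RT & g$o == MOCA)
  n_scored <- sum(!is.na(fix$harmonized$data$moca_total))
  expect_equal(n_assays, n_scored)
  # provenance-based conservation per source
  for (sn in unique(fix$harmonized$data$source)) {
    assay_rows <- g$s[g$p == RT & g$o == MOCA & g$src == sn & !is.na(g$src)]
    expected <- sum(fix$harmonized$data$source == sn &
                      !is.na(fix$harmonized$data$moca_total))
    expect_equal(length(assay_rows), expected)
  }
})

test_that("every instance triple carries provenance; ontology triples do not", {
  fix <- make_cohort(small_config(seed = 12, n = c(4, 3, 4, 3)))
  inst <- suppressMessages(build_instance_graph(fix$harmonized))
  expect_true(all(!is.na(inst$src)))
  expect_true(all(!is.na(inst$row)))
  onto <- core_ontology()
  expect_true(all(is.na(onto$src)))
})

test_that("validation passes on conformant graphs and pinpoints seeded violations", {
  fix <- toy_score_graph()
  rep0 <- validate_patterns(fix$graph)
  expect_equal(nrow(rep0$violations), 0L)
  expect_true(all(rep0$counts == 0L))

  # remove one identifier
  g1 <- fix$graph[!(fix$graph$p == OBO("IAO_0000219") &
                      fix$graph$o == fix$subject_iris[[1]]), ]
  class(g1) <- class(fix$graph)
  rep1 <- validate_patterns(g1)
  expect_equal(unname(rep1$counts[["subject-has-identifier"]]), 1L)
  expect_equal(nrow(rep1$violations), 1L)
  expect_equal(rep1$violations$focus, fix$subject_iris[[1]])

  # duplicate a value specification on one datum
  d <- sort(unique(fix$graph$s[fix$graph$p == OBO("OBI_0001938")]))[[1]]
  extra <- rdf_graph(d, OBO("OBI_0001938"), paste0(d, "/vs2"))
  rep2 <- validate_patterns(merge_graphs(fix$graph, extra))
  expect_equal(unname(rep2$counts[["single-value-spec"]]), 1L)
  expect_equal(rep2$violations$focus[rep2$violations$rule == "single-value-spec"], d)
  # report ordering is deterministic
  rep2b <- validate_patterns(merge_graphs(extra, fix$graph))
  expect_identical(rep2$violations, rep2b$violations)
})

test_that("instance graphs serialize and re-parse isomorphically", {
  fix <- make_cohort(small_config(seed = 13, n = c(3, 2, 3, 2)))
  path <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(fix$graph, path)
  expect_true(graph_isomorphic(read_turtle(path), fix$graph))
})

test_that("SHACL export produces parseable shapes for each rule", {
  path <- withr::local_tempfile(fileext = ".ttl")
  write_shacl_shapes(path)
  shapes <- read_turtle(path)
  n_shapes <- sum(shapes$p == RT &
                    shapes$o == "http://www.w3.org/ns/shacl#NodeShape")
  expect_equal(n_shapes, 6L)
})
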