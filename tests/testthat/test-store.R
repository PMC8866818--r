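test_that("SELECT matches basic graph patterns with deterministic results", {
  expect_equal(nrow(run_sparql(rdf_graph(),
                               "SELECT ?s WHERE { ?s rdf:type ?t . }")$bindings), 0L)
  g <- rdf_graph(c("http://x/a", "http://x/b", "http://x/c"), RT,
                 c(HUMAN, HUMAN, "http://x/Other"))
  q <- sprintf("PREFIX human: <%s> SELECT ?s WHERE { ?s rdf:type human: . }", HUMAN)
  res <- run_sparql(g, q)
  expect_equal(res$bindings$s, c("http://x/a", "http://x/b"))
  expect_true(run_sparql(g, "ASK { ?s rdf:type <http://x/Other> . }"))
  expect_false(run_sparql(g, "ASK { ?s rdf:type <http://x/Missing> . }"))
  expect_error(run_sparql(g, "SELECT ?s WHERE { ?s rdf:type . }"),
               "query error at position")
})

test_that("cohort query selects strictly-below-threshold scorers on the toy graph", {
  fix <- toy_score_graph(c(24L, 26L, 30L))
  sel <- select_cohort_by_score(fix$graph, "NPT_0020000", "lt", 26)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$score, 24)
  expect_equal(sel$subject_iri, fix$subject_iris[[1]])
  sel_ge <- select_cohort_by_score(fix$graph, "NPT_0020000", "ge", 26)
  expect_setequal(sel_ge$score, c(26, 30))
  # lt/ge partition all scored subjects disjointly
  expect_length(intersect(sel$subject_iri, sel_ge$subject_iri), 0L)
  expect_setequal(c(sel$subject_iri, sel_ge$subject_iri), fix$subject_iris)
})

test_that("a filter on an unbound variable keeps no solutions (erratum semantics)", {
  fix <- toy_score_graph(c(24L, 26L, 30L))
  verbatim <- sub("FILTER \\(\\?score", "FILTER (?val",
                  cohort_query("NPT_0020000", "lt", 26))
  expect_warning(res <- run_sparql(fix$graph, verbatim), "unbound")
  expect_equal(nrow(res$bindings), 0L)
  corrected <- cohort_query("NPT_0020000", "lt", 26)
  expect_equal(nrow(run_sparql(fix$graph, corrected)$bindings), 1L)
})

test_that("direct typing excludes strict-subclass matches but plain typing does not", {
  fix <- toy_score_graph(c(20L))
  # also type the assay with the assay superclass
  assay <- fix$graph$s[fix$graph$p == RT & fix$graph$o == MOCA]
  g <- merge_graphs(fix$graph, rdf_graph(assay, RT, OBO("OBI_0000070")))
  direct <- select_cohort_by_score(g, "NPT_0020000", "lt", 26)
  expect_equal(nrow(direct), 1L)
  # the superclass is not the direct type, so it selects nothing
  expect_no_warning(
    none <- select_cohort_by_score(g, "OBI_0000070", "lt", 26))
  expect_equal(nrow(none), 0L)
  # with plain rdf:type the superclass query would match
  q <- cohort_query("OBI_0000070", "lt", 26, direct_type = FALSE)
  expect_equal(nrow(run_sparql(g, q)$bindings), 1L)
})

test_that("query results equal a brute-force filter over the harmonized table", {
  fix <- make_cohort(small_config(seed = 21, n = c(12, 9, 14, 8)))
  d <- fix$harmonized$data
  for (cmp in c("lt", "ge")) {
    for (th in c(20, 26, 30)) {
      sel <- select_cohort_by_score(fix$graph, "NPT_0020000", cmp, th)
      oracle <- if (cmp == "lt") d$id_label[!is.na(d$moca_total) & d$moca_total < th]
                else d$id_label[!is.na(d$moca_total) & d$moca_total >= th]
      expect_setequal(sel$id_label, oracle)
    }
  }
})

test_that("threshold monotonicity and lt/ge complementarity hold", {
  fix <- make_cohort(small_config(seed = 22, n = c(10, 8, 10, 8)))
  m24 <- select_cohort_by_score(fix$graph, "NPT_0020000", "lt", 24)
  m26 <- select_cohort_by_score(fix$graph, "NPT_0020000", "lt", 26)
  expect_true(all(m24$subject_iri %in% m26$subject_iri))
  ge26 <- select_cohort_by_score(fix$graph, "NPT_0020000", "ge", 26)
  scored <- fix$harmonized$data$subject_iri[!is.na(fix$harmonized$data$moca_total)]
  expect_setequal(c(m26$subject_iri, ge26$subject_iri), scored)
  expect_length(intersect(m26$subject_iri, ge26$subject_iri), 0L)
})

test_that("defined-class materialization equals the query result and is idempotent", {
  fix <- make_cohort(small_config(seed = 23, n = c(10, 6, 10, 6)))
  rule <- defined_class_rule(comparator = "lt", threshold = 26)
  inferred <- materialize_defined_class(fix$graph, rule)
  sel <- select_cohort_by_score(fix$graph, "NPT_0020000", "lt", 26)
  expect_setequal(inferred$s, unique(sel$subject_iri))
  g2 <- merge_graphs(fix$graph, inferred)
  expect_setequal(class_members(g2, rule$class_iri), sort(unique(sel$subject_iri)))
  again <- materialize_defined_class(g2, rule)
  expect_equal(graph_size(again), 0L)
  expect_equal(graph_size(materialize_defined_class(rdf_graph(), rule)), 0L)
  expect_error(defined_class_rule(threshold = 99), "valid range")
})

test_that("unknown assay classes yield an empty result with a warning", {
  fix <- toy_score_graph(c(24L))
  expect_warning(
    res <- select_cohort_by_score(fix$graph,
                                  "https://kg.cohortkg.org/onto/NoSuchAssay",
                                  "lt", 26),
    "does not occur")
  expect_equal(nrow(res), 0L)
})

test_that("bindings export to CSV and SPARQL-JSON", {
  fix <- toy_score_graph(c(24L, 25L))
  res <- run_sparql(fix$graph, cohort_query("NPT_0020000", "lt", 26))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_bindings(res, csv)
  expect_equal(nrow(utils::read.csv(csv)), 2L)
  write_bindings(res, jsn)
  parsed <- jsonlite::read_json(jsn)
  expect_equal(unlist(parsed$head$vars), res$variables)
  expect_length(parsed$results$bindings, 2L)
})
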