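# Shared fixtures: IRIs, toy ontologies, and small generated cohorts.

RT  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
SCO <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
LBL <- "http://www.w3.org/2000/01/rdf-schema#label"
OBO <- function(id) paste0("http://purl.obolibrary.org/obo/", id)
HUMAN <- OBO("NCBITaxon_9606")
MOCA  <- OBO("NPT_0020000")

# A subClassOf B, B subClassOf C, D subClassOf E
toy_ontology <- function() {
  rdf_graph(c("http://t/A", "http://t/B", "http://t/D"), SCO,
            c("http://t/B", "http://t/C", "http://t/E"))
}

# small config: overrides per-group n (pd1, hc1, pd2, hc2), keeps defaults
small_config <- function(seed, n = c(8, 6, 10, 7), delta = 0.8, ...) {
  s <- cohort_config(seed = seed)$sources
  s$dataset1$pd$n <- n[[1]]; s$dataset1$hc$n <- n[[2]]
  s$dataset2$pd$n <- n[[3]]; s$dataset2$hc$n <- n[[4]]
  cohort_config(sources = s, planted_effect_delta = delta, seed = seed, ...)
}

# generate -> write -> load -> harmonize; optionally build the merged graph
make_cohort <- function(config, graph = TRUE, salt = "test-salt") {
  coh <- generate_cohorts(config)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_source_files(coh, dir)
  src_names <- names(coh$tables)
  tabs <- list(
    load_source_table(paths[[src_names[[1]]]], src_names[[1]],
                      subject_id_column(src_names[[1]], config)),
    load_source_table(paths[[src_names[[2]]]], src_names[[2]],
                      subject_id_column(src_names[[2]], config)))
  h <- harmonize_sources(tabs, default_field_mapping(), pseudonym_policy(salt))
  g <- NULL
  if (graph) {
    inst <- suppressMessages(build_instance_graph(h))
    g <- merge_graphs(inst, core_ontology(), app_ontology())
  }
  list(cohort = coh, paths = paths, tables = tabs, harmonized = h, graph = g,
       dir = dir)
}

# hand-built instance graph with three subjects scoring 24, 26, 30
toy_score_graph <- function(scores = c(24L, 26L, 30L)) {
  pol <- pseudonym_policy("toy")
  frags <- lapply(seq_along(scores), function(i) {
    iri <- mint_subject_iri("toy", paste0("S", i), pol)
    merge_graphs(
      instantiate_subject(iri, subject_label(iri), "PD"),
      instantiate_assessment(iri, "NPT_0020000", scores[[i]]))
  })
  list(graph = merge_graphs(c(frags, list(core_ontology(), app_ontology()))),
       subject_iris = vapply(seq_along(scores), function(i)
         mint_subject_iri("toy", paste0("S", i), pol), character(1)))
}
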