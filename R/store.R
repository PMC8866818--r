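# Cohort selection over the knowledge graph: the parameterized cohort-query
# template, score-threshold selection, and rule-based materialization of
# defined cohort classes.

CMP_SPARQL <- c(lt = "<", le = "<=", ge = ">=", gt = ">")

#' Build the cohort-selection SPARQL query
#'
#' The standard template: a human subject with a study-subject role inhering
#' in it and an identifier denoting it participates in an assay of the given
#' class whose specified-output measurement datum carries a score through
#' its value specification; a FILTER keeps scores satisfying
#' `comparator threshold`. The filter is applied to the bound score
#' variable (`?score`).
#'
#' @param assay_class Assay class IRI or registry key (default: the MoCA
#'   assay class).
#' @param comparator One of `"lt"`, `"le"`, `"ge"`, `"gt"`.
#' @param threshold Numeric threshold on the score.
#' @param direct_type Use direct typing for the assay class (`TRUE`, the
#'   default, via the store's virtual direct-type predicate) or plain
#'   `rdf:type`.
#' @param select Variables to project (default subject, identifier label,
#'   score).
#' @param registry A `term_registry`.
#' @return SPARQL query text (character scalar).
#' @export
cohort_query <- function(assay_class = "NPT_0020000",
                         comparator = c("lt", "le", "ge", "gt"),
                         threshold = 26,
                         direct_type = TRUE,
                         select = c("s", "idl", "score"),
                         registry = term_registry()) {
  comparator <- match.arg(comparator)
  assay_iri <- resolve_term(assay_class, registry)
  type_line <- if (direct_type) "  ?assay sesame:directType assayclass: ."
               else "  ?assay rdf:type assayclass: ."
  paste0(
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>\n",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>\n",
    "PREFIX sesame: <http://www.openrdf.org/schema/sesame#>\n",
    "PREFIX human: <", resolve_term("NCBITaxon_9606", registry), ">\n",
    "PREFIX denotes: <", resolve_term("IAO_0000219", registry), ">\n",
    "PREFIX has_participant: <", resolve_term("BFO_0000057", registry), ">\n",
    "PREFIX assayclass: <", assay_iri, ">\n",
    "PREFIX has_specified_output: <", resolve_term("OBI_0000299", registry), ">\n",
    "PREFIX measurement_datum: <", resolve_term("IAO_0000109", registry), ">\n",
    "PREFIX has_value_specification: <", resolve_term("OBI_0001938", registry), ">\n",
    "PREFIX has_specified_value: <", resolve_term("OBI_0002135", registry), ">\n",
    "PREFIX subject_role: <", resolve_term("OBI_0000097", registry), ">\n",
    "PREFIX inheres_in: <", resolve_term("RO_0000052", registry), ">\n",
    "select ", paste0("?", select, collapse = " "), " where {\n",
    "  ?s rdf:type human: .            # the individual subject\n",
    "  ?srole rdf:type subject_role: . # a study-subject role\n",
    "  ?srole inheres_in: ?s .\n",
    "  ?id denotes: ?s .               # the subject identifier\n",
    "  ?id rdfs:label ?idl .\n",
    "  ?assay has_participant: ?s .\n",
    type_line, "\n",
    "  ?assay has_specified_output: ?output .\n",
    "  ?output rdf:type measurement_datum: .\n",
    "  ?output has_value_specification: ?vs .\n",
    "  ?vs has_specified_value: ?score .\n",
    "  FILTER (?score ", CMP_SPARQL[[comparator]], " ", format(threshold), ")\n",
    "}\n")
}

#' Select a cohort by assessment score
#'
#' Runs the [cohort_query()] template over the graph and returns one row per
#' qualifying (subject, assay) pair.
#'
#' @param graph The knowledge graph (`rdf_graph`).
#' @param assay_class Assay class IRI or registry key.
#' @param comparator One of `"lt"`, `"le"`, `"ge"`, `"gt"`.
#' @param threshold Numeric score threshold.
#' @param registry A `term_registry`.
#' @return data.frame of class `cohort_selection` with columns
#'   `subject_iri`, `id_label`, `score` (numeric), sorted by `id_label`.
#'   Unknown assay classes yield an empty result with a warning.
#' @export
select_cohort_by_score <- function(graph, assay_class = "NPT_0020000",
                                   comparator = c("lt", "le", "ge", "gt"),
                                   threshold = 26,
                                   registry = term_registry()) {
  comparator <- match.arg(comparator)
  assay_iri <- resolve_term(assay_class, registry)
  known <- any(graph$p == RDF_TYPE & graph$o == assay_iri) ||
    any(graph$s == assay_iri | (!graph$lit & graph$o == assay_iri))
  if (!known)
    warning("select_cohort_by_score: assay class <", assay_iri,
            "> does not occur in the graph; empty result", call. = FALSE)
  q <- cohort_query(assay_iri, comparator, threshold, registry = registry)
  res <- run_sparql(graph, q)
  out <- data.frame(subject_iri = res$bindings$s,
                    id_label = res$bindings$idl,
                    score = as.numeric(res$bindings$score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_selection", "data.frame")
  out
}

#' Defined-class rule
#'
#' A rule that assigns subjects to a defined cohort class when their score
#' on the given assay satisfies `comparator threshold` (e.g. "study subject
#' with mild cognitive impairment": MoCA total `lt 26`).
#'
#' @param class_iri IRI of the defined class.
#' @param assay_class Assay class IRI or registry key.
#' @param comparator One of `"lt"`, `"le"`, `"ge"`, `"gt"`.
#' @param threshold Numeric threshold; must lie within the instrument's
#'   valid range when the assay maps to a catalogued pattern key.
#' @param valid_range Optional length-2 numeric range to enforce.
#' @return Object of class `defined_class_rule`.
#' @export
defined_class_rule <- function(class_iri = app_iri("StudySubjectWithMildCognitiveImpairment"),
                               assay_class = "NPT_0020000",
                               comparator = c("lt", "le", "ge", "gt"),
                               threshold = 26,
                               valid_range = c(0, 30)) {
  comparator <- match.arg(comparator)
  if (!is.null(valid_range) &&
      (threshold < valid_range[[1]] || threshold > valid_range[[2]]))
    stop(sprintf("rule error: threshold %s outside the instrument's valid range [%s, %s]",
                 format(threshold), format(valid_range[[1]]),
                 format(valid_range[[2]])), call. = FALSE)
  structure(list(class_iri = class_iri, assay_class = assay_class,
                 comparator = comparator, threshold = threshold),
            class = "defined_class_rule")
}

#' Materialize a defined cohort class
#'
#' Adds `rdf:type` assertions typing every subject selected by the rule's
#' comparator/threshold with the rule's class IRI. Idempotent: assertions
#' already present in `graph` are not produced again.
#'
#' @param graph The knowledge graph.
#' @param rule A [defined_class_rule()].
#' @param registry A `term_registry`.
#' @return An `rdf_graph` with the inferred type assertions (possibly empty).
#'   Merge it into the store with [merge_graphs()].
#' @export
materialize_defined_class <- function(graph, rule, registry = term_registry()) {
  stopifnot(inherits(rule, "defined_class_rule"))
  sel <- suppressWarnings(select_cohort_by_score(
    graph, rule$assay_class, rule$comparator, rule$threshold, registry))
  subjects <- unique(sel$subject_iri)
  already <- graph$s[graph$p == RDF_TYPE & graph$o == rule$class_iri]
  new_subjects <- setdiff(subjects, already)
  if (length(new_subjects) == 0L) return(rdf_graph())
  rdf_graph(new_subjects, RDF_TYPE, rule$class_iri)
}

#' Members of a defined class in a graph
#' @param graph An `rdf_graph`.
#' @param class_iri The class IRI.
#' @return Sorted character vector of instance IRIs typed with the class.
#' @export
class_members <- function(graph, class_iri) {
  sort(unique(graph$s[graph$p == RDF_TYPE & graph$o == class_iri]))
}
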