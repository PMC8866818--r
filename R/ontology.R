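# Ontology vocabulary, application-ontology term definitions, and
# ROBOT-style minimal module extraction.

#' The shared term registry
#'
#' Maps OBO CURIEs and human-readable labels to absolute IRIs. Contains the
#' core vocabulary the instance pattern uses: human subjects (NCBITaxon),
#' identifier denotation and measurement datum/value-specification terms
#' (IAO/OBI), assay and participation terms (OBI/BFO/RO/NPT), plus the
#' standard input/output/objective relations and the local application
#' namespace classes (anatomy, feature-extraction processes, cohort classes).
#'
#' @param extra Optional named character vector of additional
#'   key -> IRI entries.
#' @return A named character vector of class `term_registry`; names are keys
#'   (CURIE and label forms), values are absolute IRIs.
#' @export
term_registry <- function(extra = NULL) {
  obo <- function(id) paste0(OBO_NS, id)
  core <- c(
    NCBITaxon_9606 = obo("NCBITaxon_9606"),
    IAO_0000219    = obo("IAO_0000219"),
    BFO_0000057    = obo("BFO_0000057"),
    NPT_0020000    = obo("NPT_0020000"),
    OBI_0000070    = obo("OBI_0000070"),
    OBI_0000299    = obo("OBI_0000299"),
    OBI_0001933    = obo("OBI_0001933"),
    IAO_0000109    = obo("IAO_0000109"),
    OBI_0001938    = obo("OBI_0001938"),
    OBI_0002135    = obo("OBI_0002135"),
    OBI_0000097    = obo("OBI_0000097"),
    RO_0000052     = obo("RO_0000052"),
    OBI_0000011    = obo("OBI_0000011"),
    # standard companion relations/classes (not part of the core 13)
    OBI_0000293    = obo("OBI_0000293"),
    OBI_0000417    = obo("OBI_0000417"),
    IAO_0000101    = obo("IAO_0000101"),
    IAO_0000136    = obo("IAO_0000136"),
    BFO_0000051    = obo("BFO_0000051")
  )
  labels <- c(
    "Homo sapiens"              = core[["NCBITaxon_9606"]],
    "denotes"                   = core[["IAO_0000219"]],
    "has participant"           = core[["BFO_0000057"]],
    "Montreal cognitive assessment assay" = core[["NPT_0020000"]],
    "assay"                     = core[["OBI_0000070"]],
    "has specified output"      = core[["OBI_0000299"]],
    "value specification"       = core[["OBI_0001933"]],
    "measurement datum"         = core[["IAO_0000109"]],
    "has value specification"   = core[["OBI_0001938"]],
    "has specified value"       = core[["OBI_0002135"]],
    "study subject role"        = core[["OBI_0000097"]],
    "inheres in"                = core[["RO_0000052"]],
    "planned process"           = core[["OBI_0000011"]],
    "has specified input"       = core[["OBI_0000293"]],
    "achieves planned objective" = core[["OBI_0000417"]],
    "image"                     = core[["IAO_0000101"]],
    "is about"                  = core[["IAO_0000136"]],
    "has part"                  = core[["BFO_0000051"]]
  )
  app <- c(
    "brain"                     = app_iri("Brain"),
    "left hippocampus"          = app_iri("LeftHippocampus"),
    "right hippocampus"         = app_iri("RightHippocampus"),
    "subject identifier"        = app_iri("SubjectIdentifier"),
    "feature extraction objective" = app_iri("FeatureExtractionObjective"),
    "MoCA category fluency test" = app_iri("MocaCategoryFluencyTest")
  )
  reg <- c(core, labels, app, extra)
  if (anyNA(reg) || any(!nzchar(reg)))
    stop("registry error: empty IRI entry", call. = FALSE)
  dup_key <- duplicated(names(reg))
  if (any(dup_key))
    stop("registry error: duplicate keys: ",
         paste(unique(names(reg)[dup_key]), collapse = ", "), call. = FALSE)
  if (!all(grepl("^[a-z][a-z0-9+.-]*://", reg)))
    stop("registry error: non-absolute IRI in registry", call. = FALSE)
  class(reg) <- "term_registry"
  reg
}

app_iri <- function(local) paste0(APP_NS, local)

#' Resolve a term key to an absolute IRI
#'
#' Accepts a registry key (CURIE like `"OBI_0000011"` or label like
#' `"planned process"`), an `obo:`-style CURIE, or an already-absolute IRI.
#'
#' @param key Character scalar to resolve.
#' @param registry A `term_registry`.
#' @return Absolute IRI (character scalar).
#' @export
resolve_term <- function(key, registry = term_registry()) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  if (grepl("^[a-z][a-z0-9+.-]*://", key)) {
    std_ns <- c("http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                "http://www.w3.org/2000/01/rdf-schema#",
                "http://www.w3.org/2002/07/owl#")
    known <- key %in% unname(unclass(registry)) || startsWith(key, APP_NS) ||
      startsWith(key, SUBJ_NS) || any(startsWith(key, std_ns))
    if (!known)
      stop(sprintf("resolution error: IRI <%s> is not in the term registry or the application namespace", key),
           call. = FALSE)
    return(key)
  }
  if (startsWith(key, "obo:")) key <- sub("^obo:", "", key)
  idx <- match(key, names(registry))
  if (is.na(idx))
    stop(sprintf("resolution error: term '%s' not found in the registry", key),
         call. = FALSE)
  unname(unclass(registry)[[idx]])
}

#' @export
print.term_registry <- function(x, ...) {
  cat(sprintf("<term_registry> %d keys, %d distinct IRIs\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

# ---- application-ontology term definitions ------------------------------

#' Define an application-ontology term
#'
#' Builds a class definition following the application-ontology axiom
#' pattern: one `rdfs:subClassOf` axiom per parent and one existential
#' (`owl:someValuesFrom`) restriction axiom per `(property, "some", filler)`
#' entry. All referenced terms must resolve in the registry or the local
#' application namespace.
#'
#' @param label Non-empty class label.
#' @param parents Character vector (length >= 1) of parent keys/IRIs.
#' @param restrictions List of length-3 character vectors
#'   `c(property, "some", filler)` (or a list of lists with named fields
#'   `property`, `quantifier`, `filler`).
#' @param annotations Named character vector of extra annotation literals.
#' @param registry A `term_registry` used to resolve references.
#' @param iri Optional explicit class IRI; by default minted in the
#'   application namespace from the label.
#' @return Object of class `term_definition`.
#' @export
define_term <- function(label, parents, restrictions = list(),
                        annotations = character(0),
                        registry = term_registry(), iri = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("definition error: label must be a non-empty string", call. = FALSE)
  if (length(parents) == 0L)
    stop("definition error: at least one parent IRI is required", call. = FALSE)
  parent_iris <- vapply(parents, resolve_term, character(1), registry = registry)
  norm_restr <- lapply(restrictions, function(r) {
    if (is.list(r)) r <- c(r$property, r$quantifier, r$filler)
    if (length(r) != 3L)
      stop("definition error: each restriction needs (property, quantifier, filler)",
           call. = FALSE)
    if (!identical(r[[2]], "some"))
      stop(sprintf("definition error: unsupported quantifier '%s' (only 'some')",
                   r[[2]]), call. = FALSE)
    list(property = resolve_term(r[[1]], registry),
         quantifier = "some",
         filler = resolve_term(r[[3]], registry))
  })
  if (is.null(iri)) {
    local <- gsub("[^A-Za-z0-9]+", "-", label)
    local <- gsub("(^-)|(-$)", "", local)
    iri <- app_iri(local)
  }
  structure(list(iri = iri, label = label,
                 parent_iris = unname(parent_iris),
                 restrictions = norm_restr,
                 annotations = annotations),
            class = "term_definition")
}

#' Serialize a term definition to RDF triples
#'
#' Each parent contributes one `rdfs:subClassOf` axiom; each restriction
#' contributes one `owl:Restriction` blank node with `owl:onProperty` and
#' `owl:someValuesFrom`, attached via `rdfs:subClassOf`. Blank-node labels
#' are deterministic in the class IRI and restriction index.
#'
#' @param x A `term_definition`.
#' @param ... Unused.
#' @return An `rdf_graph`.
#' @export
as_graph <- function(x, ...) UseMethod("as_graph")

#' @rdname as_graph
#' @export
as_graph.term_definition <- function(x, ...) {
  s <- c(x$iri, x$iri)
  p <- c(RDF_TYPE, RDFS_LABEL)
  o <- c(OWL_CLASS, x$label)
  lit <- c(FALSE, TRUE)
  dt <- c(NA, "string")
  for (parent in x$parent_iris) {
    s <- c(s, x$iri); p <- c(p, RDFS_SUBCLASS); o <- c(o, parent)
    lit <- c(lit, FALSE); dt <- c(dt, NA)
  }
  local <- gsub("[^A-Za-z0-9]+", "_", sub(".*/", "", x$iri))
  for (i in seq_along(x$restrictions)) {
    r <- x$restrictions[[i]]
    b <- sprintf("_:restr_%s_%d", local, i)
    s <- c(s, x$iri, b, b, b)
    p <- c(p, RDFS_SUBCLASS, RDF_TYPE, OWL_ON_PROPERTY, OWL_SOME_VALUES)
    o <- c(o, b, OWL_RESTRICTION, r$property, r$filler)
    lit <- c(lit, FALSE, FALSE, FALSE, FALSE)
    dt <- c(dt, NA, NA, NA, NA)
  }
  for (an in names(x$annotations)) {
    s <- c(s, x$iri); p <- c(p, an); o <- c(o, x$annotations[[an]])
    lit <- c(lit, TRUE); dt <- c(dt, "string")
  }
  rdf_graph(s, p, o, lit, dt)
}

#' Count axioms in a term definition
#' @param x A `term_definition`.
#' @return Named integer vector with `parent` and `restriction` axiom counts.
#' @export
axiom_counts <- function(x) {
  stopifnot(inherits(x, "term_definition"))
  c(parent = length(x$parent_iris), restriction = length(x$restrictions))
}

#' @export
print.term_definition <- function(x, ...) {
  cat(sprintf("<term_definition> %s  <%s>\n", x$label, x$iri))
  cat(sprintf("  parents: %d, existential restrictions: %d\n",
              length(x$parent_iris), length(x$restrictions)))
  invisible(x)
}

#' Built-in application ontology
#'
#' Term definitions for the volumetric feature-extraction processes and
#' measurement data, the anatomy skeleton, the assessment subtest classes,
#' and the defined cohort class used for rule materialization.
#'
#' @param registry A `term_registry`.
#' @return An `rdf_graph` with the application-ontology axioms.
#' @export
app_ontology <- function(registry = term_registry()) {
  defs <- list()
  defs$brain <- define_term("brain", parents = app_iri("AnatomicalStructure"),
                            registry = registry,
                            iri = app_iri("Brain"))
  defs$anat <- define_term("anatomical structure",
                           parents = app_iri("MaterialEntity"),
                           registry = registry,
                           iri = app_iri("AnatomicalStructure"))
  defs$mat <- define_term("material entity", parents = app_iri("Entity"),
                          registry = registry, iri = app_iri("MaterialEntity"))
  defs$ent <- define_term("entity",
                          parents = "http://www.w3.org/2002/07/owl#Thing",
                          registry = registry, iri = app_iri("Entity"))
  defs$hip <- define_term("hippocampus", parents = app_iri("AnatomicalStructure"),
                          registry = registry, iri = app_iri("Hippocampus"))
  defs$hipL <- define_term("left hippocampus", parents = app_iri("Hippocampus"),
                           registry = registry, iri = app_iri("LeftHippocampus"))
  defs$hipR <- define_term("right hippocampus", parents = app_iri("Hippocampus"),
                           registry = registry, iri = app_iri("RightHippocampus"))
  defs$sid <- define_term("subject identifier",
                          parents = resolve_term("IAO_0000109", registry),
                          registry = registry, iri = app_iri("SubjectIdentifier"))
  defs$feo <- define_term("feature extraction objective",
                          parents = app_iri("Entity"),
                          registry = registry,
                          iri = app_iri("FeatureExtractionObjective"))
  defs$fluency <- define_term("MoCA category fluency test",
                              parents = resolve_term("OBI_0000070", registry),
                              registry = registry,
                              iri = app_iri("MocaCategoryFluencyTest"))
  for (side in c("Left", "Right")) {
    datum_iri <- app_iri(sprintf("%sHippocampalVolumeMeasurementDatum", side))
    defs[[paste0("datum", side)]] <- define_term(
      sprintf("%s hippocampal volume measurement datum", tolower(side)),
      parents = resolve_term("IAO_0000109", registry),
      registry = registry, iri = datum_iri)
    defs[[paste0("fx", side)]] <- define_term(
      sprintf("%s hippocampal volume feature extraction", tolower(side)),
      parents = resolve_term("OBI_0000011", registry),
      registry = registry,
      iri = app_iri(sprintf("%sHippocampalVolumeFeatureExtraction", side)))
    defs[[paste0("fxFirst", side)]] <- define_term(
      sprintf("%s hippocampal volume feature extraction using the FIRST segmentation utility from FSL on a T1 MRI image", tolower(side)),
      parents = c(resolve_term("OBI_0000011", registry),
                  app_iri(sprintf("%sHippocampalVolumeFeatureExtraction", side))),
      restrictions = list(
        c("has specified input", "some", "image"),
        list(property = "has specified output", quantifier = "some", filler = datum_iri),
        c("achieves planned objective", "some", app_iri("FeatureExtractionObjective"))),
      registry = registry,
      iri = app_iri(sprintf("%sHippocampalVolumeFeatureExtractionFIRST", side)))
  }
  defs$icvDatum <- define_term("intracranial volume measurement datum",
                               parents = resolve_term("IAO_0000109", registry),
                               registry = registry,
                               iri = app_iri("IntracranialVolumeMeasurementDatum"))
  defs$icvFx <- define_term(
    "intracranial volume feature extraction",
    parents = resolve_term("OBI_0000011", registry),
    restrictions = list(
      c("has specified input", "some", "image"),
      c("has specified output", "some", app_iri("IntracranialVolumeMeasurementDatum")),
      c("achieves planned objective", "some", app_iri("FeatureExtractionObjective"))),
    registry = registry, iri = app_iri("IntracranialVolumeFeatureExtraction"))
  defs$pd <- define_term("Parkinson disease study subject",
                         parents = resolve_term("NCBITaxon_9606", registry),
                         registry = registry,
                         iri = app_iri("ParkinsonDiseaseSubject"))
  defs$hc <- define_term("healthy control study subject",
                         parents = resolve_term("NCBITaxon_9606", registry),
                         registry = registry,
                         iri = app_iri("HealthyControlSubject"))
  defs$mci <- define_term("study subject with mild cognitive impairment",
                          parents = resolve_term("NCBITaxon_9606", registry),
                          registry = registry,
                          iri = app_iri("StudySubjectWithMildCognitiveImpairment"))
  defs$gcf <- define_term("global cognitive function",
                          parents = app_iri("Entity"),
                          registry = registry,
                          iri = app_iri("GlobalCognitiveFunction"))
  defs$smf <- define_term("semantic fluency function",
                          parents = app_iri("Entity"),
                          registry = registry,
                          iri = app_iri("SemanticFluencyFunction"))
  merge_graphs(lapply(defs, as_graph))
}

#' Load the vendored core-ontology module
#'
#' A minimal hand-built Turtle module containing the core OBO vocabulary
#' (labels plus a shallow subclass skeleton) so the pipeline runs without
#' downloading full ontologies. Loading real OBI/NPT modules instead is
#' supported via [read_turtle()].
#'
#' @return An `rdf_graph`.
#' @export
core_ontology <- function() {
  path <- system.file("extdata", "core_ontology.ttl", package = "cohortkg")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "core_ontology.ttl")
  read_turtle(path)
}

# ---- module extraction ---------------------------------------------------

#' Extract a minimal ontology module
#'
#' Recursive reference closure: the module contains the seed terms, every
#' axiom (triple subtree, including restriction blank nodes) of a member
#' term, and, recursively, every term referenced by those axioms
#' (superclasses, restriction properties and fillers, asserted types).
#'
#' @param ontology An `rdf_graph` of ontology axioms.
#' @param seeds Character vector of seed IRIs (or registry keys).
#' @param registry Optional `term_registry` used to resolve non-IRI seeds.
#' @return An `rdf_graph` subset of `ontology` with attribute `seeds`;
#'   seeds missing from the ontology are retained as bare
#'   `owl:Class` declarations, with a warning.
#' @export
extract_module <- function(ontology, seeds, registry = NULL) {
  if (length(seeds) == 0L) stop("extract_module: seeds must be non-empty", call. = FALSE)
  seeds <- vapply(seeds, function(k) {
    if (grepl("^[a-z][a-z0-9+.-]*://", k) || startsWith(k, "_:")) k
    else if (!is.null(registry)) resolve_term(k, registry)
    else k
  }, character(1))
  seeds <- unique(unname(seeds))

  mentioned <- unique(c(ontology$s, ontology$o[!ontology$lit]))
  missing <- setdiff(seeds, mentioned)
  if (length(missing) > 0)
    warning("extract_module: seed(s) not present in ontology, retained as bare declarations: ",
            paste(missing, collapse = ", "), call. = FALSE)

  ref_preds <- c(RDFS_SUBCLASS, OWL_SOME_VALUES, OWL_ON_PROPERTY, RDF_TYPE,
                 "http://www.w3.org/2002/07/owl#equivalentClass")
  builtin <- c(OWL_CLASS, OWL_RESTRICTION,
               "http://www.w3.org/2002/07/owl#ObjectProperty")

  members <- character(0)
  rows <- logical(nrow(ontology))
  queue <- seeds
  while (length(queue) > 0) {
    m <- queue[[1]]; queue <- queue[-1]
    if (m %in% members) next
    members <- c(members, m)
    # axiom subtree: triples with subject m, following blank-node objects
    subtree_subjects <- m
    frontier <- m
    while (length(frontier) > 0) {
      hit <- ontology$s %in% frontier
      rows <- rows | hit
      blanks <- unique(ontology$o[hit & !ontology$lit & startsWith(ontology$o, "_:")])
      frontier <- setdiff(blanks, subtree_subjects)
      subtree_subjects <- c(subtree_subjects, frontier)
    }
    ax <- ontology[ontology$s %in% subtree_subjects, , drop = FALSE]
    refs <- unique(ax$o[!ax$lit & ax$p %in% ref_preds & !startsWith(ax$o, "_:")])
    refs <- setdiff(refs, c(builtin, members))
    queue <- unique(c(queue, refs))
  }
  module <- ontology[rows, , drop = FALSE]
  bare <- setdiff(seeds, unique(c(module$s, module$o[!module$lit])))
  if (length(bare) > 0)
    module <- merge_graphs(module, rdf_graph(bare, RDF_TYPE, OWL_CLASS))
  module <- dedupe_graph(as_rdf_graph(as.data.frame(module)))
  attr(module, "seeds") <- seeds
  module
}

#' Classes and properties mentioned in a graph
#'
#' @param g An `rdf_graph`.
#' @return Character vector of non-blank IRIs appearing as subject or object.
#' @export
graph_members <- function(g) {
  iris <- unique(c(g$s, g$o[!g$lit]))
  sort(iris[!startsWith(iris, "_:")])
}
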