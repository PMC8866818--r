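# Translation of harmonized records into the subject/assay/feature
# knowledge-graph instance pattern, and pattern-conformance validation.
#
# Instance IRIs are deterministic suffixes of the subject IRI (role, id,
# anatomy, assay, datum, value specification), so re-ingestion is idempotent
# and canonical serializations are reproducible.

inst_iri <- function(subject_iri, ...) paste(subject_iri, ..., sep = "/")

#' Default subtest-to-cognitive-function table
#'
#' Which cognitive-function instance an assessment's measurement is about.
#' Configurable: pass your own table with the same columns to
#' [build_instance_graph()].
#'
#' @return data.frame with columns `pattern_key`, `function_class`
#'   (class IRI), `function_name` (instance suffix).
#' @export
default_subtest_functions <- function() {
  data.frame(
    pattern_key = c("moca_total", "moca_category_fluency"),
    function_class = c(app_iri("GlobalCognitiveFunction"),
                       app_iri("SemanticFluencyFunction")),
    function_name = c("global-cognition", "semantic-fluency"),
    stringsAsFactors = FALSE)
}

#' Instantiate a study subject
#'
#' Emits the subject node (typed Homo sapiens), a study-subject role
#' inhering in the subject, an identifier instance denoting the subject
#' with the pseudonymous label, the group class assertion, and the anatomy
#' skeleton (brain with left and right hippocampus parts).
#'
#' @param subject_iri Minted subject IRI.
#' @param id_label Pseudonymous identifier label.
#' @param group `"PD"` or `"HC"`.
#' @param registry A `term_registry`.
#' @param src,row Provenance (source name, row index).
#' @return An `rdf_graph` fragment.
#' @export
instantiate_subject <- function(subject_iri, id_label, group,
                                registry = term_registry(),
                                src = NA_character_, row = NA_integer_) {
  if (!group %in% c("PD", "HC"))
    stop("instantiation error: group must be 'PD' or 'HC', got: ", group,
         call. = FALSE)
  r <- function(k) resolve_term(k, registry)
  role <- inst_iri(subject_iri, "role")
  id <- inst_iri(subject_iri, "id")
  brain <- inst_iri(subject_iri, "brain")
  hipL <- inst_iri(subject_iri, "hippocampus-left")
  hipR <- inst_iri(subject_iri, "hippocampus-right")
  group_class <- if (group == "PD") app_iri("ParkinsonDiseaseSubject")
                 else app_iri("HealthyControlSubject")
  rdf_graph(
    s = c(subject_iri, subject_iri,
          role, role,
          id, id, id,
          subject_iri, brain, brain, brain, hipL, hipR),
    p = c(RDF_TYPE, RDF_TYPE,
          RDF_TYPE, r("RO_0000052"),
          RDF_TYPE, r("IAO_0000219"), RDFS_LABEL,
          r("BFO_0000051"), RDF_TYPE, r("BFO_0000051"), r("BFO_0000051"),
          RDF_TYPE, RDF_TYPE),
    o = c(r("NCBITaxon_9606"), group_class,
          r("OBI_0000097"), subject_iri,
          app_iri("SubjectIdentifier"), subject_iri, id_label,
          brain, app_iri("Brain"), hipL, hipR,
          app_iri("LeftHippocampus"), app_iri("RightHippocampus")),
    lit = c(rep(FALSE, 6), TRUE, rep(FALSE, 6)),
    dt = c(rep(NA, 6), "string", rep(NA, 6)),
    src = src, row = row)
}

#' Instantiate a completed assessment with its score
#'
#' Emits the assay instance (participating subject), its specified-output
#' measurement datum, the value specification carrying the literal score,
#' and optional subtest parts with their own output chains. Measurement
#' data are linked by aboutness to the cognitive-function instance given in
#' `functions_table`.
#'
#' @param subject_iri Subject the assay has as participant.
#' @param assay_class Assay class IRI or registry key (e.g. `NPT_0020000`).
#' @param score Numeric total score (integer-valued).
#' @param part_scores Optional named numeric vector of subtest scores; names
#'   are pattern keys with entries in `functions_table` and `part_classes`.
#' @param part_classes Named character vector mapping subtest pattern keys to
#'   class IRIs.
#' @param functions_table See [default_subtest_functions()].
#' @param assay_key Pattern key of the main score (for function lookup and
#'   instance naming).
#' @param registry A `term_registry`.
#' @param src,row Provenance.
#' @return An `rdf_graph` fragment, or an empty graph (with a message) when
#'   `score` is missing.
#' @export
instantiate_assessment <- function(subject_iri, assay_class, score,
                                   part_scores = NULL,
                                   part_classes = c(
                                     moca_category_fluency = app_iri("MocaCategoryFluencyTest")),
                                   functions_table = default_subtest_functions(),
                                   assay_key = "moca_total",
                                   registry = term_registry(),
                                   src = NA_character_, row = NA_integer_) {
  if (is.null(score) || is.na(score)) {
    message(sprintf("skip: no %s score for <%s>", assay_key, subject_iri))
    return(rdf_graph())
  }
  r <- function(k) resolve_term(k, registry)
  assay_class <- resolve_term(assay_class, registry)
  assay <- inst_iri(subject_iri, "assay", sub(".*_", "", assay_key))
  g <- score_chain(assay, assay_class, subject_iri, score, assay_key,
                   functions_table, registry, src, row, participant = TRUE)
  if (!is.null(part_scores)) {
    for (k in names(part_scores)) {
      if (is.na(part_scores[[k]])) {
        message(sprintf("skip: no %s score for <%s>", k, subject_iri))
        next
      }
      part <- inst_iri(assay, "part", k)
      pg <- score_chain(part, part_classes[[k]], subject_iri, part_scores[[k]],
                        k, functions_table, registry, src, row,
                        participant = TRUE)
      pg <- merge_graphs(pg, rdf_graph(assay, r("BFO_0000051"), part,
                                       src = src, row = row))
      g <- merge_graphs(g, pg)
    }
  }
  g
}

# assay/subtest instance with its output -> value specification -> value path
score_chain <- function(proc_iri, proc_class, subject_iri, score, key,
                        functions_table, registry, src, row, participant) {
  r <- function(k) resolve_term(k, registry)
  datum <- inst_iri(proc_iri, "datum")
  vs <- inst_iri(datum, "vs")
  s <- c(proc_iri, proc_iri, datum, proc_iri, datum, vs, vs)
  p <- c(RDF_TYPE, r("OBI_0000299"), RDF_TYPE, r("BFO_0000057"),
         r("OBI_0001938"), RDF_TYPE, r("OBI_0002135"))
  o <- c(proc_class, datum, r("IAO_0000109"), subject_iri,
         vs, r("OBI_0001933"), format(as.integer(round(score))))
  lit <- c(rep(FALSE, 6), TRUE)
  dt <- c(rep(NA, 6), "integer")
  fn <- functions_table[functions_table$pattern_key == key, , drop = FALSE]
  if (nrow(fn) == 1L) {
    fn_inst <- inst_iri(subject_iri, "function", fn$function_name)
    s <- c(s, fn_inst, fn_inst, datum)
    p <- c(p, RDF_TYPE, r("RO_0000052"), r("IAO_0000136"))
    o <- c(o, fn$function_class, inst_iri(subject_iri, "brain"), fn_inst)
    lit <- c(lit, FALSE, FALSE, FALSE)
    dt <- c(dt, NA, NA, NA)
  }
  rdf_graph(s, p, o, lit, dt, src = src, row = row)
}

#' Instantiate an image-derived volume feature extraction
#'
#' Emits a feature-extraction process instance with a T1 image as specified
#' input and a volume measurement datum as specified output; the datum is
#' about the subject's hippocampus instance (which must already exist in
#' `graph`) and carries the volume in cubic millimetres through its value
#' specification.
#'
#' @param subject_iri Subject whose hippocampus was measured.
#' @param volume_mm3 Positive volume in cubic millimetres.
#' @param side `"left"` or `"right"`.
#' @param graph Existing `rdf_graph` holding the subject's anatomy skeleton.
#' @param registry A `term_registry`.
#' @param src,row Provenance.
#' @return An `rdf_graph` fragment.
#' @export
instantiate_feature_extraction <- function(subject_iri, volume_mm3, side,
                                           graph,
                                           registry = term_registry(),
                                           src = NA_character_,
                                           row = NA_integer_) {
  if (missing(side) || length(side) != 1L || !side %in% c("left", "right"))
    stop("instantiation error: side must be 'left' or 'right'", call. = FALSE)
  if (is.null(volume_mm3) || is.na(volume_mm3)) {
    message(sprintf("skip: no %s hippocampal volume for <%s>", side, subject_iri))
    return(rdf_graph())
  }
  r <- function(k) resolve_term(k, registry)
  hip <- inst_iri(subject_iri, paste0("hippocampus-", side))
  if (!any(graph$s == hip & graph$p == RDF_TYPE))
    stop(sprintf("instantiation error: no %s hippocampus instance for subject <%s>",
                 side, subject_iri), call. = FALSE)
  cap <- if (side == "left") "Left" else "Right"
  proc <- inst_iri(subject_iri, "fx", side)
  img <- inst_iri(subject_iri, "image", "t1")
  datum <- inst_iri(proc, "datum")
  vs <- inst_iri(datum, "vs")
  rdf_graph(
    s = c(proc, img, proc, proc,
          datum, datum, datum,
          datum, vs, vs),
    p = c(RDF_TYPE, RDF_TYPE, r("has specified input"), r("OBI_0000299"),
          RDF_TYPE, RDF_TYPE, r("IAO_0000136"),
          r("OBI_0001938"), RDF_TYPE, r("OBI_0002135")),
    o = c(app_iri(sprintf("%sHippocampalVolumeFeatureExtractionFIRST", cap)),
          r("image"), img, datum,
          r("IAO_0000109"),
          app_iri(sprintf("%sHippocampalVolumeMeasurementDatum", cap)), hip,
          vs, r("OBI_0001933"), format(volume_mm3, scientific = FALSE, trim = TRUE)),
    lit = c(rep(FALSE, 9), TRUE),
    dt = c(rep(NA, 9), "decimal"),
    src = src, row = row)
}

# ICV measurement about the subject's brain, same output pattern
instantiate_icv <- function(subject_iri, icv_mm3, graph,
                            registry = term_registry(),
                            src = NA_character_, row = NA_integer_) {
  if (is.null(icv_mm3) || is.na(icv_mm3)) {
    message(sprintf("skip: no intracranial volume for <%s>", subject_iri))
    return(rdf_graph())
  }
  r <- function(k) resolve_term(k, registry)
  brain <- inst_iri(subject_iri, "brain")
  proc <- inst_iri(subject_iri, "fx", "icv")
  img <- inst_iri(subject_iri, "image", "t1")
  datum <- inst_iri(proc, "datum")
  vs <- inst_iri(datum, "vs")
  rdf_graph(
    s = c(proc, proc, proc, datum, datum, datum, datum, vs, vs),
    p = c(RDF_TYPE, r("has specified input"), r("OBI_0000299"),
          RDF_TYPE, RDF_TYPE, r("IAO_0000136"), r("OBI_0001938"),
          RDF_TYPE, r("OBI_0002135")),
    o = c(app_iri("IntracranialVolumeFeatureExtraction"), img, datum,
          r("IAO_0000109"), app_iri("IntracranialVolumeMeasurementDatum"),
          brain, vs, r("OBI_0001933"),
          format(icv_mm3, scientific = FALSE, trim = TRUE)),
    lit = c(rep(FALSE, 8), TRUE),
    dt = c(rep(NA, 8), "decimal"),
    src = src, row = row)
}

#' Build the full instance graph for a harmonized cohort
#'
#' Instantiates every subject, their completed assessments (MoCA total with
#' category-fluency subtest) and their volumetric feature extractions.
#' Records with a missing score simply emit no assay triples (logged skips);
#' out-of-range values were already quarantined during harmonization.
#'
#' @param harmonized A `harmonized_cohort` from [harmonize_sources()].
#' @param registry A `term_registry`.
#' @param functions_table Subtest-to-function table; see
#'   [default_subtest_functions()].
#' @return An `rdf_graph` with per-triple provenance (`src`, `row`).
#' @export
build_instance_graph <- function(harmonized, registry = term_registry(),
                                 functions_table = default_subtest_functions()) {
  stopifnot(inherits(harmonized, "harmonized_cohort"))
  d <- harmonized$data
  if (anyDuplicated(d$subject_iri))
    stop("instantiation error: duplicate subject IRI in cohort", call. = FALSE)
  frags <- vector("list", nrow(d) * 4L)
  k <- 0L
  for (i in seq_len(nrow(d))) {
    k <- k + 1L
    frags[[k]] <- instantiate_subject(d$subject_iri[[i]], d$id_label[[i]],
                                      d$group_label[[i]], registry,
                                      src = d$source[[i]], row = i)
    k <- k + 1L
    frags[[k]] <- instantiate_assessment(
      d$subject_iri[[i]], "NPT_0020000", d$moca_total[[i]],
      part_scores = c(moca_category_fluency = d$moca_category_fluency[[i]]),
      functions_table = functions_table, registry = registry,
      src = d$source[[i]], row = i)
    anat <- frags[[k - 1L]]
    for (side in c("left", "right")) {
      vol <- d[[paste0("volume_", side, "_hippocampus")]][[i]]
      k <- k + 1L
      frags[[k]] <- instantiate_feature_extraction(
        d$subject_iri[[i]], vol, side, anat, registry,
        src = d$source[[i]], row = i)
    }
    k <- k + 1L
    frags[[k]] <- instantiate_icv(d$subject_iri[[i]], d$icv[[i]], anat,
                                  registry, src = d$source[[i]], row = i)
  }
  merge_graphs(frags[seq_len(k)])
}

# ---- pattern conformance -------------------------------------------------

count_edges <- function(g, nodes, p, direction = c("out", "in"), o = NULL) {
  direction <- match.arg(direction)
  rows <- g[g$p == p & !g$lit, , drop = FALSE]
  if (!is.null(o)) rows <- rows[rows$o == o, , drop = FALSE]
  key <- if (direction == "out") rows$s else rows$o
  tab <- table(factor(key, levels = nodes))
  as.integer(tab)
}

#' Validate instance-pattern conformance
#'
#' Evaluates the instance-graph invariants as named rules:
#' \describe{
#'   \item{subject-has-identifier}{every subject has exactly one identifier
#'     instance denoting it}
#'   \item{subject-has-role}{every subject has exactly one study-subject role
#'     inhering in it}
#'   \item{assay-has-participant}{every assay instance has at least one
#'     participant}
#'   \item{assay-has-output}{every assay instance has exactly one specified
#'     output}
#'   \item{single-value-spec}{every measurement datum has exactly one value
#'     specification}
#'   \item{single-value}{every value specification has exactly one specified
#'     value}
#' }
#'
#' @param graph An `rdf_graph`.
#' @param registry A `term_registry`.
#' @return Object of class `pattern_report`: list with `violations`
#'   (data.frame `rule`, `focus`, `message`, deterministically ordered) and
#'   `counts` (named integer vector per rule).
#' @export
validate_patterns <- function(graph, registry = term_registry()) {
  r <- function(k) resolve_term(k, registry)
  typed <- function(class_iri)
    sort(unique(graph$s[graph$p == RDF_TYPE & graph$o == class_iri]))
  subjects <- typed(r("NCBITaxon_9606"))
  assay_classes <- unique(c(r("NPT_0020000"), r("OBI_0000070"),
                            app_iri("MocaCategoryFluencyTest")))
  assays <- sort(unique(unlist(lapply(assay_classes, typed))))
  datums <- typed(r("IAO_0000109"))
  vss <- typed(r("OBI_0001933"))

  rules <- list(
    list(id = "subject-has-identifier", nodes = subjects,
         n = count_edges(graph, subjects, r("IAO_0000219"), "in"),
         want = "exactly one identifier denoting the subject", exact = 1L),
    list(id = "subject-has-role", nodes = subjects,
         n = count_edges(graph, subjects, r("RO_0000052"), "in"),
         want = "exactly one role inhering in the subject", exact = 1L),
    list(id = "assay-has-participant", nodes = assays,
         n = count_edges(graph, assays, r("BFO_0000057"), "out"),
         want = "at least one participant", exact = NA_integer_),
    list(id = "assay-has-output", nodes = assays,
         n = count_edges(graph, assays, r("OBI_0000299"), "out"),
         want = "exactly one specified output", exact = 1L),
    list(id = "single-value-spec", nodes = datums,
         n = count_edges(graph, datums, r("OBI_0001938"), "out"),
         want = "exactly one value specification", exact = 1L),
    list(id = "single-value", nodes = vss,
         n = count_edges(graph, vss, r("OBI_0002135"), "out", o = NULL),
         want = "exactly one specified value", exact = 1L))
  # specified value is a literal edge; count separately
  lit_counts <- function(nodes, p) {
    rows <- graph[graph$p == p & graph$lit, , drop = FALSE]
    as.integer(table(factor(rows$s, levels = nodes)))
  }
  rules[[6]]$n <- lit_counts(vss, r("OBI_0002135"))

  viols <- list()
  for (rule in rules) {
    bad <- if (is.na(rule$exact)) rule$n < 1L else rule$n != rule$exact
    if (any(bad)) {
      viols[[rule$id]] <- data.frame(
        rule = rule$id, focus = rule$nodes[bad],
        message = sprintf("%s: expected %s, found %d",
                          rule$id, rule$want, rule$n[bad]),
        stringsAsFactors = FALSE)
    }
  }
  violations <- if (length(viols) > 0) do.call(rbind, c(viols, list(make.row.names = FALSE)))
    else data.frame(rule = character(0), focus = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  violations <- violations[order(violations$rule, violations$focus), , drop = FALSE]
  rownames(violations) <- NULL
  counts <- vapply(rules, function(rule) sum(violations$rule == rule$id), integer(1))
  names(counts) <- vapply(rules, `[[`, character(1), "id")
  structure(list(violations = violations, counts = counts),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  total <- nrow(x$violations)
  cat(sprintf("<pattern_report> %d violation(s)\n", total))
  for (id in names(x$counts)) cat(sprintf("  %-24s %d\n", id, x$counts[[id]]))
  invisible(x)
}

#' Export conformance rules as SHACL shapes
#'
#' Serializes the pattern rules of [validate_patterns()] as SHACL node
#' shapes (Turtle) for interoperability with external validators.
#'
#' @param path Output `.ttl` path.
#' @param registry A `term_registry`.
#' @return `path`, invisibly.
#' @export
write_shacl_shapes <- function(path, registry = term_registry()) {
  sh <- "http://www.w3.org/ns/shacl#"
  r <- function(k) resolve_term(k, registry)
  shape <- function(name, target, p, min, max, inverse = FALSE) {
    s <- app_iri(paste0("shape/", name))
    prop <- paste0("_:p_", name)
    base <- rdf_graph(
      s = c(s, s, s),
      p = c(RDF_TYPE, paste0(sh, "targetClass"), paste0(sh, "property")),
      o = c(paste0(sh, "NodeShape"), target, prop))
    path <- if (inverse) {
      pb <- paste0("_:path_", name)
      rdf_graph(c(prop, pb), c(paste0(sh, "path"), paste0(sh, "inversePath")),
                c(pb, p))
    } else {
      rdf_graph(prop, paste0(sh, "path"), p)
    }
    cnt <- rdf_graph(
      s = c(prop, if (!is.na(max)) prop),
      p = c(paste0(sh, "minCount"), if (!is.na(max)) paste0(sh, "maxCount")),
      o = c(format(min), if (!is.na(max)) format(max)),
      lit = TRUE, dt = "integer")
    merge_graphs(base, path, cnt)
  }
  g <- merge_graphs(
    shape("subject-has-identifier", r("NCBITaxon_9606"), r("IAO_0000219"),
          1L, 1L, inverse = TRUE),
    shape("subject-has-role", r("NCBITaxon_9606"), r("RO_0000052"),
          1L, 1L, inverse = TRUE),
    shape("assay-has-participant", r("NPT_0020000"), r("BFO_0000057"), 1L, NA),
    shape("assay-has-output", r("NPT_0020000"), r("OBI_0000299"), 1L, 1L),
    shape("single-value-spec", r("IAO_0000109"), r("OBI_0001938"), 1L, 1L),
    shape("single-value", r("OBI_0001933"), r("OBI_0002135"), 1L, 1L))
  write_turtle(g, path, c(default_prefixes(), sh = sh))
  invisible(path)
}
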