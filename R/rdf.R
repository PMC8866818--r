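# Lightweight RDF triple container.
#
# A graph is a data.frame with columns:
#   s, p  : character, absolute IRIs or blank-node labels ("_:name")
#   o     : character, IRI / blank label / literal lexical form
#   lit   : logical, TRUE when `o` is a literal
#   dt    : character, literal datatype key ("string", "integer", "decimal"),
#           NA for IRIs
#   src,row : optional per-triple provenance (source name, source row index);
#           NA for ontology background triples
# Triple identity is (s, p, o, lit, dt); provenance is carried along but
# ignored by set operations and comparisons.

RDF_TYPE     <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL   <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASS<- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
OWL_CLASS    <- "http://www.w3.org/2002/07/owl#Class"
OWL_RESTRICTION <- "http://www.w3.org/2002/07/owl#Restriction"
OWL_ON_PROPERTY <- "http://www.w3.org/2002/07/owl#onProperty"
OWL_SOME_VALUES <- "http://www.w3.org/2002/07/owl#someValuesFrom"
XSD_NS       <- "http://www.w3.org/2001/XMLSchema#"
SESAME_DIRECT_TYPE <- "http://www.openrdf.org/schema/sesame#directType"

APP_NS  <- "https://kg.cohortkg.org/onto/"
SUBJ_NS <- "https://kg.cohortkg.org/subject/"
OBO_NS  <- "http://purl.obolibrary.org/obo/"

#' Default namespace prefixes
#'
#' Prefix map used when reading and writing Turtle and when expanding
#' prefixed names in SPARQL queries.
#'
#' @return Named character vector mapping prefix labels to namespace IRIs.
#' @export
default_prefixes <- function() {
  c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl  = "http://www.w3.org/2002/07/owl#",
    xsd  = XSD_NS,
    obo  = OBO_NS,
    app  = APP_NS,
    subj = SUBJ_NS,
    sesame = "http://www.openrdf.org/schema/sesame#")
}

#' Construct an RDF graph
#'
#' @param s,p,o Character vectors (recycled to a common length). `s` and `p`
#'   must be absolute IRIs or blank-node labels (`"_:name"`).
#' @param lit Logical; `TRUE` where `o` is a literal lexical form.
#' @param dt Literal datatype key (`"string"`, `"integer"`, `"decimal"`);
#'   ignored (set to `NA`) for IRI objects.
#' @param src,row Optional provenance: source name and row index.
#' @return An object of class `rdf_graph` (a data.frame of triples, with
#'   duplicates removed).
#' @export
rdf_graph <- function(s = character(), p = character(), o = character(),
                      lit = FALSE, dt = NA_character_,
                      src = NA_character_, row = NA_integer_) {
  n <- max(length(s), length(p), length(o), 0L)
  g <- data.frame(s = rep_len(as.character(s), n),
                  p = rep_len(as.character(p), n),
                  o = rep_len(as.character(o), n),
                  lit = rep_len(as.logical(lit), n),
                  dt = rep_len(as.character(dt), n),
                  src = rep_len(as.character(src), n),
                  row = rep_len(as.integer(row), n),
                  stringsAsFactors = FALSE)
  g$dt[!g$lit] <- NA_character_
  g$dt[g$lit & is.na(g$dt)] <- "string"
  class(g) <- c("rdf_graph", "data.frame")
  dedupe_graph(g)
}

as_rdf_graph <- function(df) {
  for (col in c("lit")) if (is.null(df[[col]])) df[[col]] <- FALSE
  for (col in c("dt", "src")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$row)) df$row <- NA_integer_
  df <- df[, c("s", "p", "o", "lit", "dt", "src", "row")]
  class(df) <- c("rdf_graph", "data.frame")
  df
}

triple_keys <- function(g) {
  paste(g$s, g$p, g$o, g$lit, ifelse(is.na(g$dt), "", g$dt), sep = "\x1f")
}

dedupe_graph <- function(g) {
  keep <- !duplicated(triple_keys(g))
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph> %d triples, %d subjects\n",
              nrow(x), length(unique(x$s))))
  if (nrow(x) > 0) {
    show <- utils::head(as_ntriples(x), 8L)
    cat(paste0("  ", show, collapse = "\n"), "\n")
    if (nrow(x) > 8) cat(sprintf("  ... (%d more)\n", nrow(x) - 8L))
  }
  invisible(x)
}

#' Number of triples in a graph
#' @param g An `rdf_graph`.
#' @return Integer triple count.
#' @export
graph_size <- function(g) nrow(g)

#' Merge RDF graphs
#'
#' Set union of the input triple sets. Every input triple is present in the
#' result; duplicates collapse (first provenance wins), so merging is
#' idempotent, commutative and associative up to set equality.
#'
#' @param ... `rdf_graph` objects, or a single list of them.
#' @return A merged `rdf_graph`.
#' @export
merge_graphs <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "data.frame"))
    gs <- gs[[1]]
  if (length(gs) == 0L) return(rdf_graph())
  g <- do.call(rbind, lapply(gs, function(x) as.data.frame(x)))
  dedupe_graph(as_rdf_graph(g))
}

#' Test set equality of two graphs
#'
#' Compares the two triple sets exactly (blank-node labels included,
#' provenance ignored).
#'
#' @param g1,g2 `rdf_graph` objects.
#' @return Logical.
#' @export
graph_equal <- function(g1, g2) {
  setequal(triple_keys(g1), triple_keys(g2))
}

#' Test graph isomorphism
#'
#' Graphs are isomorphic when some relabelling of blank nodes makes the
#' triple sets equal. Ground triples (no blank nodes) are compared exactly;
#' blank nodes are matched by iterative signature refinement, with a
#' backtracking search over signature-equivalent candidates to resolve ties.
#'
#' @param g1,g2 `rdf_graph` objects.
#' @return Logical.
#' @export
graph_isomorphic <- function(g1, g2) {
  if (nrow(g1) != nrow(g2)) return(FALSE)
  is_blank <- function(x) startsWith(x, "_:")
  b1 <- unique(c(g1$s[is_blank(g1$s)], g1$o[!g1$lit & is_blank(g1$o)]))
  b2 <- unique(c(g2$s[is_blank(g2$s)], g2$o[!g2$lit & is_blank(g2$o)]))
  if (length(b1) != length(b2)) return(FALSE)
  if (length(b1) == 0L) return(graph_equal(g1, g2))

  ground_keys <- function(g) {
    grd <- !(is_blank(g$s) | (!g$lit & is_blank(g$o)))
    triple_keys(g[grd, , drop = FALSE])
  }
  if (!setequal(ground_keys(g1), ground_keys(g2))) return(FALSE)

  # signature: multiset of incident triple shapes with blanks wildcarded
  signatures <- function(g, blanks) {
    sig1 <- function(b) {
      as_s <- g[g$s == b, , drop = FALSE]
      as_o <- g[!g$lit & g$o == b, , drop = FALSE]
      parts <- c(paste("S", as_s$p,
                       ifelse(!as_s$lit & is_blank(as_s$o), "_", as_s$o),
                       as_s$lit, sep = "|"),
                 paste("O", as_o$p,
                       ifelse(is_blank(as_o$s), "_", as_o$s), sep = "|"))
      paste(sort(parts), collapse = ";")
    }
    vapply(blanks, sig1, character(1))
  }
  s1 <- signatures(g1, b1); s2 <- signatures(g2, b2)
  if (!identical(sort(unname(s1)), sort(unname(s2)))) return(FALSE)

  rename <- function(g, map) {
    g$s <- ifelse(g$s %in% names(map), map[g$s], g$s)
    hit <- !g$lit & g$o %in% names(map)
    g$o[hit] <- map[g$o[hit]]
    g
  }
  target <- sort(triple_keys(g2))
  # backtracking over signature-compatible assignments
  assign_next <- function(map) {
    if (length(map) == length(b1)) {
      return(identical(sort(triple_keys(rename(g1, map))), target))
    }
    b <- b1[length(map) + 1L]
    cands <- setdiff(b2[s2 == s1[[b]]], unname(map))
    for (cand in cands) {
      m2 <- c(map, stats::setNames(cand, b))
      if (assign_next(m2)) return(TRUE)
    }
    FALSE
  }
  names(s1) <- b1
  assign_next(stats::setNames(character(0), character(0)))
}

# ---- serialization -----------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

dt_iri <- function(dt) {
  ifelse(dt == "integer", paste0(XSD_NS, "integer"),
         ifelse(dt == "decimal", paste0(XSD_NS, "decimal"), NA_character_))
}

format_term_nt <- function(x, lit, dt) {
  out <- ifelse(startsWith(x, "_:"), x, paste0("<", x, ">"))
  if (any(lit)) {
    lex <- paste0("\"", escape_literal(x[lit]), "\"")
    d <- dt_iri(dt[lit])
    out[lit] <- ifelse(is.na(d), lex, paste0(lex, "^^<", d, ">"))
  }
  out
}

#' Serialize a graph to canonical N-Triples lines
#'
#' One triple per line, lexicographically sorted, so that two equal graphs
#' always produce byte-identical output.
#'
#' @param g An `rdf_graph`.
#' @return Character vector of N-Triples lines.
#' @export
as_ntriples <- function(g) {
  if (nrow(g) == 0) return(character(0))
  lines <- paste(format_term_nt(g$s, FALSE, NA), format_term_nt(g$p, FALSE, NA),
                 format_term_nt(g$o, g$lit, g$dt), ".")
  sort(lines, method = "radix")
}

#' Write a graph as canonical N-Triples
#' @param g An `rdf_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(g, path) {
  writeLines(as_ntriples(g), path, useBytes = TRUE)
  invisible(path)
}

shorten_iri <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    hit <- startsWith(iri, ns)
    if (any(hit)) {
      local <- substring(iri[hit], nchar(ns) + 1L)
      ok <- grepl("^[A-Za-z_][A-Za-z0-9_-]*$|^$", local)
      out[hit][ok] <- paste0(pfx, ":", local[ok])
    }
  }
  out[startsWith(iri, "_:")] <- iri[startsWith(iri, "_:")]
  out
}

#' Write a graph as Turtle
#'
#' Emits a `@prefix` block followed by one triple per line (sorted), using
#' prefixed names where a default prefix applies.
#'
#' @param g An `rdf_graph`.
#' @param path Output file path.
#' @param prefixes Named character vector of prefixes to use.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(g, path, prefixes = default_prefixes()) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  body <- character(0)
  if (nrow(g) > 0) {
    s <- shorten_iri(g$s, prefixes)
    p <- shorten_iri(g$p, prefixes)
    p[g$p == RDF_TYPE] <- "a"
    o <- shorten_iri(g$o, prefixes)
    if (any(g$lit)) {
      lex <- paste0("\"", escape_literal(g$o[g$lit]), "\"")
      dsh <- ifelse(g$dt[g$lit] == "integer", "^^xsd:integer",
             ifelse(g$dt[g$lit] == "decimal", "^^xsd:decimal", ""))
      o[g$lit] <- paste0(lex, dsh)
    }
    body <- sort(paste(s, p, o, "."), method = "radix")
  }
  writeLines(c(header, "", body), path, useBytes = TRUE)
  invisible(path)
}

# ---- tokenizer shared by the Turtle reader and the SPARQL engine -------

TOKEN_PATTERN <- paste0(
  "#[^\n]*",                                        # comment
  "|<[^<>\"{}|^`\\\\ \t\r\n]*>",                    # IRIREF
  "|\"(?:[^\"\\\\]|\\\\.)*\"",                      # string literal
  "|_:[A-Za-z][A-Za-z0-9_-]*",                      # blank node
  "|\\?[A-Za-z][A-Za-z0-9_]*",                      # variable
  "|@prefix|@base",
  "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z_]?[A-Za-z0-9_.-]*", # prefixed name
  "|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?", # number
  "|[A-Za-z_][A-Za-z0-9_]*",                        # bare word / keyword
  "|\\^\\^|<=|>=|!=|&&|\\|\\||[{}().;,*=<>!]"       # punctuation/operators
)

tokenize_rdf <- function(text) {
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    if (grepl("^[[:space:]]*$", text)) return(data.frame(tok = character(0), pos = integer(0)))
    stop("parse error at position 1: no tokens found", call. = FALSE)
  }
  toks <- regmatches(text, list(m))[[1]]
  pos <- as.integer(m)
  len <- attr(m, "match.length")
  # verify gaps are whitespace only
  gaps_start <- c(1L, pos + len)
  gaps_end <- c(pos - 1L, nchar(text))
  for (i in seq_along(gaps_start)) {
    if (gaps_start[i] <= gaps_end[i]) {
      gap <- substr(text, gaps_start[i], gaps_end[i])
      if (!grepl("^[[:space:]]*$", gap))
        stop(sprintf("parse error at position %d: unexpected '%s'",
                     gaps_start[i], trimws(gap)), call. = FALSE)
    }
  }
  keep <- !startsWith(toks, "#")
  data.frame(tok = toks[keep], pos = pos[keep], stringsAsFactors = FALSE)
}

is_pname <- function(tok) {
  grepl("^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z_]?[A-Za-z0-9_.-]*$", tok) &&
    !startsWith(tok, "_:")
}

expand_pname <- function(tok, prefixes, pos = NA) {
  i <- regexpr(":", tok, fixed = TRUE)
  pfx <- substr(tok, 1L, i - 1L)
  local <- substring(tok, i + 1L)
  ns <- prefixes[[pfx]]
  if (is.null(ns))
    stop(sprintf("parse error%s: undefined prefix '%s:'",
                 if (is.na(pos)) "" else sprintf(" at position %d", pos), pfx),
         call. = FALSE)
  paste0(ns, local)
}

# ---- Turtle reader -----------------------------------------------------

#' Read a Turtle or N-Triples file into a graph
#'
#' Supports the Turtle subset this package emits plus predicate (`;`) and
#' object (`,`) lists, `@prefix`/`PREFIX` declarations, `a`, blank-node
#' labels, and typed or plain string and numeric literals.
#'
#' @param path Path to a `.ttl` or `.nt` file (or a character vector of
#'   lines via `text`).
#' @param text Optional character scalar/vector of Turtle source, used
#'   instead of `path`.
#' @return An `rdf_graph`.
#' @export
read_turtle <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  }
  toks <- tokenize_rdf(paste(text, collapse = "\n"))
  prefixes <- list()
  out_s <- character(0); out_p <- character(0); out_o <- character(0)
  out_lit <- logical(0); out_dt <- character(0)
  i <- 1L; n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  advance <- function() { t <- toks$tok[i]; i <<- i + 1L; t }
  fail <- function(msg) {
    p <- if (i <= n) toks$pos[i] else nchar(paste(text, collapse = "\n"))
    stop(sprintf("parse error at position %d: %s", p, msg), call. = FALSE)
  }
  term <- function() {
    if (i > n) fail("unexpected end of input")
    t <- advance()
    if (startsWith(t, "<")) return(list(v = substr(t, 2L, nchar(t) - 1L), lit = FALSE, dt = NA))
    if (startsWith(t, "_:")) return(list(v = t, lit = FALSE, dt = NA))
    if (t == "a") return(list(v = RDF_TYPE, lit = FALSE, dt = NA))
    if (startsWith(t, "\"")) {
      lex <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      dt <- "string"
      if (identical(peek(), "^^")) {
        advance()
        d <- advance()
        d <- if (startsWith(d, "<")) substr(d, 2L, nchar(d) - 1L)
             else expand_pname(d, prefixes)
        dt <- if (d == paste0(XSD_NS, "integer")) "integer"
              else if (d %in% paste0(XSD_NS, c("decimal", "double", "float"))) "decimal"
              else "string"
      }
      return(list(v = lex, lit = TRUE, dt = dt))
    }
    if (grepl("^[+-]?[0-9]", t)) {
      dt <- if (grepl("[.eE]", t)) "decimal" else "integer"
      return(list(v = t, lit = TRUE, dt = dt))
    }
    if (is_pname(t)) return(list(v = expand_pname(t, prefixes, toks$pos[i - 1L]), lit = FALSE, dt = NA))
    fail(sprintf("unexpected token '%s'", t))
  }
  while (i <= n) {
    t <- peek()
    if (t == "@prefix" || toupper(t) == "PREFIX") {
      advance()
      pname <- advance()
      if (!grepl(":$", pname)) fail("expected prefix declaration ending in ':'")
      iri <- advance()
      if (!startsWith(iri, "<")) fail("expected IRI in prefix declaration")
      prefixes[[sub(":$", "", pname)]] <- substr(iri, 2L, nchar(iri) - 1L)
      if (identical(peek(), ".")) advance()
      next
    }
    subj <- term()
    repeat {
      pred <- term()
      repeat {
        obj <- term()
        out_s <- c(out_s, subj$v); out_p <- c(out_p, pred$v)
        out_o <- c(out_o, obj$v); out_lit <- c(out_lit, obj$lit)
        out_dt <- c(out_dt, if (is.na(obj$dt)) NA_character_ else obj$dt)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      if (identical(peek(), ";")) {
        advance()
        if (identical(peek(), ".")) break  # trailing ;
        next
      }
      break
    }
    if (!identical(peek(), ".")) fail("expected '.' at end of statement")
    advance()
  }
  rdf_graph(out_s, out_p, out_o, out_lit, out_dt)
}

#' @rdname read_turtle
#' @export
read_ntriples <- function(path = NULL, text = NULL) read_turtle(path, text)
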