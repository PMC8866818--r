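# SPARQL 1.1 subset engine over rdf_graph triple sets.
#
# Supported: PREFIX declarations; SELECT [DISTINCT] (?vars | *), ASK,
# CONSTRUCT { template }; basic graph patterns with IRIs, prefixed names,
# `a`, blank nodes, typed/plain literals and numbers; FILTER with
# comparison operators on numbers, strings and IRIs; ORDER BY [ASC|DESC];
# comments. The store-specific `sesame:directType` predicate is evaluated
# virtually as rdf:type minus strict-subclass matches.

# encode terms so IRIs and literals join correctly in one character column
enc_iri <- function(x) {
  if (length(x) == 0L) return(character(0))
  paste0("I", x)
}
enc_lit <- function(lex, dt) {
  if (length(lex) == 0L) return(character(0))
  paste0("L", ifelse(is.na(dt), "string", dt), "\x1f", lex)
}
enc_col <- function(x, lit, dt) ifelse(lit, enc_lit(x, dt), enc_iri(x))
dec_value <- function(enc) ifelse(startsWith(enc, "I"), substring(enc, 2L),
                                  sub("^L[^\x1f]*\x1f", "", enc))
dec_is_lit <- function(enc) startsWith(enc, "L")
dec_numeric <- function(enc) suppressWarnings(as.numeric(dec_value(enc)))

encoded_triples <- function(g) {
  data.frame(es = enc_iri(g$s), ep = enc_iri(g$p),
             eo = enc_col(g$o, g$lit, g$dt), stringsAsFactors = FALSE)
}

# transitive subclass closure: named list class -> all strict superclasses
subclass_closure <- function(g) {
  sub <- g[g$p == RDFS_SUBCLASS & !g$lit & !startsWith(g$o, "_:") &
           !startsWith(g$s, "_:"), c("s", "o")]
  classes <- unique(c(sub$s, sub$o))
  up <- split(sub$o, factor(sub$s, levels = classes))
  closure <- list()
  for (cl in classes) {
    seen <- character(0); frontier <- up[[cl]]
    while (length(frontier) > 0) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unique(unlist(up[frontier], use.names = FALSE))
    }
    closure[[cl]] <- setdiff(seen, cl)
  }
  closure
}

# rdf:type assertions that are direct: no asserted strict subclass of the
# class also types the instance
direct_type_triples <- function(g) {
  ty <- g[g$p == RDF_TYPE & !g$lit, c("s", "o")]
  if (nrow(ty) == 0) return(ty)
  closure <- subclass_closure(g)
  keep <- vapply(seq_len(nrow(ty)), function(i) {
    others <- ty$o[ty$s == ty$s[[i]] & ty$o != ty$o[[i]]]
    !any(vapply(others, function(oc) ty$o[[i]] %in% (closure[[oc]] %||% character(0)),
                logical(1)))
  }, logical(1))
  ty[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- query parsing -------------------------------------------------------

parse_sparql <- function(query) {
  toks <- tokenize_rdf(query)
  n <- nrow(toks); i <- 1L
  prefixes <- as.list(default_prefixes())
  fail <- function(msg) {
    p <- if (i <= n) toks$pos[i] else nchar(query)
    stop(sprintf("query error at position %d: %s", p, msg), call. = FALSE)
  }
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  advance <- function() { t <- toks$tok[i]; i <<- i + 1L; t }
  kw <- function(t, word) !is.na(t) && toupper(t) == word

  while (kw(peek(), "PREFIX") || identical(peek(), "@prefix")) {
    advance()
    pname <- advance()
    if (!grepl(":$", pname)) fail("expected prefix name ending in ':'")
    iri <- advance()
    if (!startsWith(iri, "<")) fail("expected IRI in PREFIX declaration")
    prefixes[[sub(":$", "", pname)]] <- substr(iri, 2L, nchar(iri) - 1L)
  }

  form <- toupper(peek())
  if (!form %in% c("SELECT", "ASK", "CONSTRUCT"))
    fail(sprintf("expected SELECT, ASK or CONSTRUCT, got '%s'", peek()))
  advance()

  term <- function(allow_var = TRUE) {
    if (i > n) fail("unexpected end of query")
    t <- advance()
    if (startsWith(t, "?")) {
      if (!allow_var) fail("variable not allowed here")
      return(list(kind = "var", v = substring(t, 2L)))
    }
    if (startsWith(t, "<")) return(list(kind = "const", v = enc_iri(substr(t, 2L, nchar(t) - 1L))))
    if (startsWith(t, "_:")) return(list(kind = "var", v = paste0(".blank.", substring(t, 3L))))
    if (t == "a") return(list(kind = "const", v = enc_iri(RDF_TYPE)))
    if (startsWith(t, "\"")) {
      lex <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      dt <- "string"
      if (identical(peek(), "^^")) {
        advance(); d <- advance()
        d <- if (startsWith(d, "<")) substr(d, 2L, nchar(d) - 1L)
             else expand_pname(d, prefixes)
        dt <- if (d == paste0(XSD_NS, "integer")) "integer"
              else if (d %in% paste0(XSD_NS, c("decimal", "double", "float"))) "decimal"
              else "string"
      }
      return(list(kind = "const", v = enc_lit(lex, dt), num = suppressWarnings(as.numeric(lex))))
    }
    if (grepl("^[+-]?[0-9]", t))
      return(list(kind = "num", v = as.numeric(t)))
    if (is_pname(t))
      return(list(kind = "const", v = enc_iri(expand_pname(t, prefixes, toks$pos[i - 1L]))))
    fail(sprintf("unexpected token '%s'", t))
  }

  parse_group <- function() {
    if (!identical(peek(), "{")) fail("expected '{'")
    advance()
    patterns <- list(); filters <- list()
    while (!identical(peek(), "}")) {
      if (is.na(peek())) fail("unterminated group pattern")
      if (kw(peek(), "FILTER")) {
        advance()
        if (!identical(peek(), "(")) fail("expected '(' after FILTER")
        advance()
        lhs <- term()
        op <- advance()
        if (!op %in% c("<", "<=", ">", ">=", "=", "!="))
          fail(sprintf("unsupported FILTER operator '%s'", op))
        rhs <- term()
        if (!identical(peek(), ")")) fail("expected ')' closing FILTER")
        advance()
        filters[[length(filters) + 1L]] <- list(lhs = lhs, op = op, rhs = rhs)
        if (identical(peek(), ".")) advance()
        next
      }
      s <- term(); p <- term(); o <- term()
      patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
      if (identical(peek(), ".")) advance()
      else if (!identical(peek(), "}")) fail("expected '.' or '}' after triple pattern")
    }
    advance()
    list(patterns = patterns, filters = filters)
  }

  res <- list(form = form, prefixes = prefixes)
  if (form == "SELECT") {
    res$distinct <- FALSE
    if (kw(peek(), "DISTINCT")) { advance(); res$distinct <- TRUE }
    vars <- character(0)
    if (identical(peek(), "*")) { advance(); vars <- "*" }
    else {
      while (!is.na(peek()) && startsWith(peek(), "?"))
        vars <- c(vars, substring(advance(), 2L))
      if (length(vars) == 0L) fail("SELECT needs projection variables or *")
    }
    res$vars <- vars
    if (!kw(peek(), "WHERE") && !identical(peek(), "{")) fail("expected WHERE")
    if (kw(peek(), "WHERE")) advance()
    res$group <- parse_group()
    res$order <- list()
    if (kw(peek(), "ORDER")) {
      advance()
      if (!kw(peek(), "BY")) fail("expected BY after ORDER")
      advance()
      while (!is.na(peek())) {
        dir <- "ASC"
        t <- peek()
        if (kw(t, "ASC") || kw(t, "DESC")) {
          dir <- toupper(advance())
          if (!identical(peek(), "(")) fail("expected '(' after ASC/DESC")
          advance()
          v <- advance()
          if (!startsWith(v, "?")) fail("expected variable in ORDER BY")
          if (!identical(peek(), ")")) fail("expected ')'")
          advance()
        } else if (startsWith(t, "?")) {
          v <- advance()
        } else break
        res$order[[length(res$order) + 1L]] <- list(var = substring(v, 2L), dir = dir)
      }
    }
  } else if (form == "ASK") {
    res$group <- parse_group()
  } else { # CONSTRUCT
    res$template <- parse_group()
    if (length(res$template$filters) > 0) fail("FILTER not allowed in CONSTRUCT template")
    if (!kw(peek(), "WHERE")) fail("expected WHERE after CONSTRUCT template")
    advance()
    res$group <- parse_group()
  }
  if (i <= n) fail(sprintf("trailing input near '%s'", peek()))
  res
}

# ---- evaluation ----------------------------------------------------------

eval_bgp <- function(g, group) {
  enc <- encoded_triples(g)
  direct <- NULL
  bindings <- NULL  # NULL = universal single solution

  for (pat in group$patterns) {
    cand <- enc
    if (pat$p$kind == "const" && pat$p$v == enc_iri(SESAME_DIRECT_TYPE)) {
      if (is.null(direct)) {
        dt <- direct_type_triples(g)
        direct <- data.frame(es = enc_iri(dt$s), ep = enc_iri(SESAME_DIRECT_TYPE),
                             eo = enc_iri(dt$o), stringsAsFactors = FALSE)
      }
      cand <- direct
    }
    cols <- character(0)
    for (pos in c("s", "p", "o")) {
      t <- pat[[pos]]
      col <- paste0("e", pos)
      if (t$kind == "const") {
        cand <- cand[cand[[col]] == t$v, , drop = FALSE]
      } else if (t$kind == "num") {
        vals <- dec_numeric(cand[[col]])
        cand <- cand[!is.na(vals) & vals == t$v & dec_is_lit(cand[[col]]), , drop = FALSE]
      } else {
        if (t$v %in% names(cols)) {
          cand <- cand[cand[[col]] == cand[[cols[[t$v]]]], , drop = FALSE]
        } else {
          cols[[t$v]] <- col
        }
      }
    }
    sel <- cand[, unname(cols), drop = FALSE]
    names(sel) <- names(cols)
    sel <- unique(sel)
    if (is.null(bindings)) {
      bindings <- sel
    } else {
      shared <- intersect(names(bindings), names(sel))
      if (length(shared) > 0) {
        bindings <- merge(bindings, sel, by = shared, stringsAsFactors = FALSE)
      } else {
        bindings <- merge(bindings, sel, by = NULL)
      }
    }
    if (nrow(bindings) == 0L) break
  }
  if (is.null(bindings)) bindings <- data.frame(row.names = 1L)

  for (f in group$filters) {
    if (nrow(bindings) == 0L) break
    side <- function(t) {
      if (t$kind == "var") {
        if (!t$v %in% names(bindings)) {
          warning(sprintf("FILTER references unbound variable ?%s; no solutions retained",
                          t$v), call. = FALSE)
          return(NULL)
        }
        list(enc = bindings[[t$v]], num = dec_numeric(bindings[[t$v]]))
      } else if (t$kind == "num") {
        list(enc = NULL, num = rep(t$v, nrow(bindings)))
      } else {
        list(enc = rep(t$v, nrow(bindings)),
             num = rep(t$num %||% NA_real_, nrow(bindings)))
      }
    }
    l <- side(f$lhs); r <- side(f$rhs)
    if (is.null(l) || is.null(r)) {
      bindings <- bindings[0L, , drop = FALSE]
      break
    }
    numeric_cmp <- !anyNA(l$num) && !anyNA(r$num)
    if (numeric_cmp) {
      lv <- l$num; rv <- r$num
    } else {
      lv <- if (is.null(l$enc)) as.character(l$num) else dec_value(l$enc)
      rv <- if (is.null(r$enc)) as.character(r$num) else dec_value(r$enc)
    }
    keep <- switch(f$op,
                   "<" = lv < rv, "<=" = lv <= rv, ">" = lv > rv,
                   ">=" = lv >= rv, "=" = lv == rv, "!=" = lv != rv)
    keep[is.na(keep)] <- FALSE
    bindings <- bindings[keep, , drop = FALSE]
  }
  bindings
}

#' Run a SPARQL query over a graph
#'
#' @param graph An `rdf_graph`.
#' @param query SPARQL text (SELECT, ASK or CONSTRUCT; see the engine notes
#'   in the package vignette for the supported subset).
#' @return For SELECT, an object of class `sparql_bindings`: list with
#'   `variables` and `bindings` (a data.frame of decoded values; IRIs and
#'   literal lexical forms as character). Rows follow `ORDER BY` when given
#'   and are otherwise sorted canonically so results are deterministic.
#'   For ASK, a logical scalar. For CONSTRUCT, an `rdf_graph`.
#' @export
run_sparql <- function(graph, query) {
  q <- parse_sparql(query)
  b <- eval_bgp(graph, q$group)
  drop_blanks <- function(df) df[, !startsWith(names(df), ".blank."), drop = FALSE]
  if (q$form == "ASK") return(nrow(b) > 0L)
  if (q$form == "CONSTRUCT") {
    out <- list()
    for (pat in q$template$patterns) {
      inst <- function(t) {
        if (t$kind == "var") b[[t$v]] %||% stop(
          "query error: CONSTRUCT template variable ?", t$v, " unbound", call. = FALSE)
        else if (t$kind == "num") enc_lit(format(t$v), if (t$v %% 1 == 0) "integer" else "decimal")
        else t$v
      }
      s <- dec_value(inst(pat$s)); p <- dec_value(inst(pat$p))
      oenc <- inst(pat$o)
      out[[length(out) + 1L]] <- rdf_graph(
        s, p, dec_value(oenc), lit = dec_is_lit(oenc),
        dt = ifelse(dec_is_lit(oenc), sub("^L([^\x1f]*)\x1f.*$", "\\1", oenc), NA))
    }
    return(merge_graphs(out))
  }
  b <- drop_blanks(b)
  vars <- if (identical(q$vars, "*")) names(b) else q$vars
  missing_vars <- setdiff(vars, names(b))
  for (v in missing_vars) b[[v]] <- rep(NA_character_, nrow(b))
  proj <- b[, vars, drop = FALSE]
  if (isTRUE(q$distinct)) proj <- unique(proj)
  decoded <- as.data.frame(lapply(proj, dec_value), stringsAsFactors = FALSE,
                           optional = TRUE)
  names(decoded) <- vars
  if (nrow(proj) == 0L) decoded <- proj[, vars, drop = FALSE]
  if (length(q$order) > 0) {
    keys <- lapply(q$order, function(o) {
      v <- decoded[[o$var]]
      nv <- suppressWarnings(as.numeric(v))
      k <- if (!anyNA(nv)) nv else v
      if (o$dir == "DESC") k <- if (is.numeric(k)) -k else -xtfrm(k)
      k
    })
    decoded <- decoded[do.call(order, keys), , drop = FALSE]
  } else if (nrow(decoded) > 1L) {
    decoded <- decoded[do.call(order, unname(as.list(decoded))), , drop = FALSE]
  }
  rownames(decoded) <- NULL
  structure(list(variables = vars, bindings = decoded),
            class = "sparql_bindings")
}

#' @export
print.sparql_bindings <- function(x, ...) {
  cat(sprintf("<sparql_bindings> %d row(s): %s\n", nrow(x$bindings),
              paste0("?", x$variables, collapse = " ")))
  if (nrow(x$bindings) > 0) print(utils::head(x$bindings, 10L))
  invisible(x)
}

#' Export SPARQL bindings
#'
#' @param x A `sparql_bindings`.
#' @param path Output path; `.csv` or `.json` (SPARQL-JSON results format).
#' @return `path`, invisibly.
#' @export
write_bindings <- function(x, path) {
  stopifnot(inherits(x, "sparql_bindings"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_len(nrow(x$bindings)), function(i) {
      row <- lapply(x$variables, function(v) {
        val <- x$bindings[[v]][[i]]
        list(type = if (grepl("^[a-z][a-z0-9+.-]*://", val)) "uri" else "literal",
             value = val)
      })
      stats::setNames(row, x$variables)
    })
    jsonlite::write_json(list(head = list(vars = x$variables),
                              results = list(bindings = rows)),
                         path, auto_unbox = TRUE)
  } else {
    utils::write.csv(x$bindings, path, row.names = FALSE)
  }
  invisible(path)
}
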