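# The TripleGraph container and its four serializations (Turtle, RDF/XML,
# N-Triples, JSON-LD), each with a parser, for the constrained profile the
# package emits: absolute IRIs, no blank nodes, plain or XSD-typed literals.

.RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.RDF_TYPE <- paste0(.RDF_NS, "type")
.XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
.SALON_NS <- "https://w3id.org/salon#"

.RDF_FORMATS <- c("turtle", "rdfxml", "ntriples", "jsonld")

.emptyTriples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), objectType = character(),
             datatype = character(), stringsAsFactors = FALSE)
}

.tripleRow <- function(s, p, o, type = "iri", datatype = NA_character_) {
  data.frame(subject = s, predicate = p, object = as.character(o),
             objectType = type, datatype = datatype, stringsAsFactors = FALSE)
}

#' @rdname TripleGraph-class
#' @param triples a data.frame of statements (see the class slots); duplicates
#'   are removed, keeping first occurrence order.
#' @param baseNamespace the vocabulary/instance namespace.
#' @return a [TripleGraph-class]
#' @export
TripleGraph <- function(triples = .emptyTriples(), baseNamespace = .SALON_NS) {
  keep <- !duplicated(triples[c("subject", "predicate", "object", "objectType")])
  rows <- triples[keep, , drop = FALSE]
  rownames(rows) <- NULL
  new("TripleGraph", triples = rows, baseNamespace = baseNamespace)
}

#' @rdname TripleGraph-class
setMethod("triples", "TripleGraph", function(x) x@triples)
#' @rdname TripleGraph-class
setMethod("baseNamespace", "TripleGraph", function(x) x@baseNamespace)

setMethod("show", "TripleGraph", function(object) {
  cat("TripleGraph:", nrow(object@triples), "triple(s), base <",
      object@baseNamespace, ">\n")
})

#' Add statements to a graph
#'
#' @param graph a [TripleGraph-class]
#' @param triples data.frame of statements in the [TripleGraph-class] column
#'   layout.
#' @return a new deduplicated [TripleGraph-class]
#' @export
addTriples <- function(graph, triples) {
  TripleGraph(rbind(graph@triples, triples), graph@baseNamespace)
}

#' Compare two graphs as triple sets
#'
#' Order-insensitive equality of the statement sets.
#'
#' @param a,b [TripleGraph-class] objects
#' @return `TRUE` or `FALSE`
#' @export
sameTripleSet <- function(a, b) {
  canon <- function(g) {
    tr <- g@triples
    tr$datatype[is.na(tr$datatype)] <- ""
    tr <- tr[do.call(order, tr), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  }
  isTRUE(all.equal(canon(a), canon(b)))
}

# ---- IRI minting -----------------------------------------------------------

#' @rdname IriPolicy-class
#' @param base absolute namespace IRI (default the SALON namespace).
#' @return an [IriPolicy-class]
#' @export
iriPolicy <- function(base = .SALON_NS) new("IriPolicy", base = base)

.sanitizeLocal <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Mint a deterministic instance IRI
#'
#' Instance IRIs follow the `alignmentId + "_" + localId` pattern (e.g. the
#' sequence `1aab_` of alignment `BB11001` becomes `...#BB11001_1aab_`), with
#' characters outside `[A-Za-z0-9_]` replaced by `_`.
#'
#' @param policy an [IriPolicy-class]
#' @param alignmentId alignment identifier; non-empty.
#' @param localId local entity identifier; non-empty.
#' @return an absolute IRI string
#' @examples
#' mintIri(iriPolicy(), "BB11001", "1aab_")
#' @export
mintIri <- function(policy, alignmentId, localId) {
  if (!length(alignmentId) || is.na(alignmentId) || !nzchar(alignmentId))
    stop("alignmentId must be non-empty")
  if (!length(localId) || is.na(localId) || !nzchar(localId))
    stop("localId must be non-empty")
  paste0(policy@base, .sanitizeLocal(alignmentId), "_", .sanitizeLocal(localId))
}

# ---- literal escaping ------------------------------------------------------

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescapeLiteral <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[k], "", fixed = TRUE)[[1]]
    res <- character(0); i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        i <- i + 2L
      } else { res <- c(res, chars[i]); i <- i + 1L }
    }
    out[k] <- paste(res, collapse = "")
  }
  out
}

# ---- N-Triples -------------------------------------------------------------

.ntObject <- function(o, type, dt) {
  if (type == "iri") return(paste0("<", o, ">"))
  lit <- paste0("\"", .escapeLiteral(o), "\"")
  if (!is.na(dt)) paste0(lit, "^^<", dt, ">") else lit
}

.serializeNTriples <- function(graph) {
  tr <- graph@triples
  if (!nrow(tr)) return("")
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    paste0("<", tr$subject[i], "> <", tr$predicate[i], "> ",
           .ntObject(tr$object[i], tr$objectType[i], tr$datatype[i]), " .")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

.parseLiteralToken <- function(tok) {
  m <- regmatches(tok, regexec(
    '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>)?$', tok, perl = TRUE))[[1]]
  if (!length(m)) stop("cannot parse literal token: ", tok)
  list(value = .unescapeLiteral(m[2]),
       datatype = if (nzchar(m[3])) m[3] else NA_character_)
}

.parseNTriples <- function(text, base = .SALON_NS) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(line) {
    m <- regmatches(line, regexec(
      "^<([^>]*)>\\s+<([^>]*)>\\s+(.*?)\\s*\\.$", line, perl = TRUE))[[1]]
    if (!length(m)) stop("N-Triples parse error in line: ", line)
    obj <- m[4]
    if (startsWith(obj, "<")) {
      .tripleRow(m[2], m[3], sub("^<(.*)>$", "\\1", obj))
    } else {
      lit <- .parseLiteralToken(obj)
      .tripleRow(m[2], m[3], lit$value, "literal", lit$datatype)
    }
  })
  TripleGraph(do.call(rbind, c(list(.emptyTriples()), rows)), base)
}

# ---- Turtle ----------------------------------------------------------------

.pnLocalOk <- function(x) grepl("^[A-Za-z0-9_]+$", x)

.ttlName <- function(iri, base) {
  if (startsWith(iri, base)) {
    local <- substring(iri, nchar(base) + 1L)
    if (.pnLocalOk(local)) return(paste0("salon:", local))
  }
  if (startsWith(iri, .XSD_NS)) {
    local <- substring(iri, nchar(.XSD_NS) + 1L)
    if (.pnLocalOk(local)) return(paste0("xsd:", local))
  }
  paste0("<", iri, ">")
}

.ttlObject <- function(o, type, dt, base) {
  if (type == "iri") return(.ttlName(o, base))
  lit <- paste0("\"", .escapeLiteral(o), "\"")
  if (!is.na(dt)) paste0(lit, "^^", .ttlName(dt, base)) else lit
}

.serializeTurtle <- function(graph) {
  base <- graph@baseNamespace
  tr <- graph@triples
  head <- c(paste0("@prefix salon: <", base, "> ."),
            paste0("@prefix xsd: <", .XSD_NS, "> ."),
            paste0("@prefix rdf: <", .RDF_NS, "> ."), "")
  if (!nrow(tr)) return(paste0(paste(head, collapse = "\n"), "\n"))
  blocks <- character()
  for (s in unique(tr$subject)) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    po <- vapply(seq_len(nrow(rows)), function(i) {
      pred <- if (rows$predicate[i] == .RDF_TYPE) "a"
              else .ttlName(rows$predicate[i], base)
      paste(pred, .ttlObject(rows$object[i], rows$objectType[i],
                             rows$datatype[i], base))
    }, character(1))
    blocks <- c(blocks, paste0(.ttlName(s, base), " ",
                               paste(po, collapse = " ;\n    "), " ."))
  }
  paste0(paste(head, collapse = "\n"), "\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

.TTL_TOKEN <- paste0(
  "@prefix\\s+[A-Za-z][A-Za-z0-9_.-]*:\\s*<[^>]*>\\s*\\.",    # prefix decl
  "|<[^>]*>",                                                  # IRIREF
  "|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^(?:<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_]+))?",
  "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_]+",                    # prefixed name
  "|\\ba\\b",
  "|[;,.]")

.parseTurtle <- function(text, base = .SALON_NS) {
  m <- gregexpr(.TTL_TOKEN, text, perl = TRUE)[[1]]
  toks <- if (m[1] == -1L) character() else regmatches(text, list(m))[[1]]
  prefixes <- character()
  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
    parts <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", tok))[[1]]
    if (!parts[2] %in% names(prefixes))
      stop("undeclared Turtle prefix: ", parts[2])
    paste0(prefixes[[parts[2]]], parts[3])
  }
  objectRow <- function(s, p, tok) {
    if (startsWith(tok, "\"")) {
      # split literal body and optional datatype suffix
      m2 <- regmatches(tok, regexec(
        '^("(?:[^"\\\\]|\\\\.)*")(?:\\^\\^(.+))?$', tok, perl = TRUE))[[1]]
      lit <- .parseLiteralToken(m2[2])
      dt <- if (nzchar(m2[3])) resolve(m2[3]) else NA_character_
      .tripleRow(s, p, lit$value, "literal", dt)
    } else {
      .tripleRow(s, p, resolve(tok))
    }
  }
  rows <- list()
  i <- 1L
  subject <- NULL; predicate <- NULL
  state <- "subject"
  while (i <= length(toks)) {
    tok <- toks[i]
    if (startsWith(tok, "@prefix")) {
      pm <- regmatches(tok, regexec(
        "^@prefix\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>", tok))[[1]]
      prefixes[pm[2]] <- pm[3]
      i <- i + 1L; next
    }
    switch(state,
      subject = { subject <- resolve(tok); state <- "predicate" },
      predicate = {
        predicate <- if (tok == "a") .RDF_TYPE else resolve(tok)
        state <- "object"
      },
      object = {
        rows[[length(rows) + 1L]] <- objectRow(subject, predicate, tok)
        state <- "punct"
      },
      punct = {
        if (tok == ";") state <- "predicate"
        else if (tok == ",") state <- "object"
        else if (tok == ".") state <- "subject"
        else stop("Turtle parse error near token: ", tok)
      })
    i <- i + 1L
  }
  TripleGraph(do.call(rbind, c(list(.emptyTriples()), rows)), base)
}

# ---- RDF/XML ---------------------------------------------------------------

.ncNameOk <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)

.rdfxmlQName <- function(pred, base) {
  if (pred == .RDF_TYPE) return("rdf:type")
  if (startsWith(pred, base)) {
    local <- substring(pred, nchar(base) + 1L)
    if (.ncNameOk(local)) return(paste0("salon:", local))
  }
  stop("cannot express predicate as RDF/XML element: ", pred)
}

.serializeRdfXml <- function(graph) {
  base <- graph@baseNamespace
  root <- xml2::xml_new_root("rdf:RDF",
                             "xmlns:rdf" = .RDF_NS, "xmlns:salon" = base)
  tr <- graph@triples
  for (s in unique(tr$subject)) {
    desc <- xml2::xml_add_child(root, "rdf:Description", "rdf:about" = s)
    rows <- tr[tr$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      qn <- .rdfxmlQName(rows$predicate[i], base)
      if (rows$objectType[i] == "iri") {
        xml2::xml_add_child(desc, qn, "rdf:resource" = rows$object[i])
      } else if (!is.na(rows$datatype[i])) {
        xml2::xml_add_child(desc, qn, rows$object[i],
                            "rdf:datatype" = rows$datatype[i])
      } else {
        xml2::xml_add_child(desc, qn, rows$object[i])
      }
    }
  }
  as.character(root)
}

.parseRdfXml <- function(text, base = .SALON_NS) {
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns(doc)
  expand <- function(node) {
    qn <- xml2::xml_name(node, ns)
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) stop("unqualified RDF/XML element: ", qn)
    paste0(ns[[parts[1]]], parts[2])
  }
  rows <- list()
  for (desc in xml2::xml_find_all(doc, "./*")) {
    s <- xml2::xml_attr(desc, "about")
    for (child in xml2::xml_children(desc)) {
      pred <- expand(child)
      res <- xml2::xml_attr(child, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- .tripleRow(s, pred, res)
      } else {
        dt <- xml2::xml_attr(child, "datatype")
        rows[[length(rows) + 1L]] <-
          .tripleRow(s, pred, xml2::xml_text(child), "literal", dt)
      }
    }
  }
  TripleGraph(do.call(rbind, c(list(.emptyTriples()), rows)), base)
}

# ---- JSON-LD ---------------------------------------------------------------

.serializeJsonLd <- function(graph) {
  tr <- graph@triples
  nodes <- lapply(unique(tr$subject), function(s) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    node <- list("@id" = s)
    types <- rows$object[rows$predicate == .RDF_TYPE & rows$objectType == "iri"]
    if (length(types)) node[["@type"]] <- as.list(types)
    rest <- rows[rows$predicate != .RDF_TYPE, , drop = FALSE]
    for (p in unique(rest$predicate)) {
      sub <- rest[rest$predicate == p, , drop = FALSE]
      node[[p]] <- lapply(seq_len(nrow(sub)), function(i) {
        if (sub$objectType[i] == "iri") list("@id" = sub$object[i])
        else if (!is.na(sub$datatype[i]))
          list("@value" = sub$object[i], "@type" = sub$datatype[i])
        else list("@value" = sub$object[i])
      })
    }
    node
  })
  as.character(jsonlite::toJSON(nodes, auto_unbox = TRUE, pretty = TRUE))
}

.parseJsonLd <- function(text, base = .SALON_NS) {
  nodes <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  rows <- list()
  for (node in nodes) {
    s <- node[["@id"]]
    for (t in node[["@type"]])
      rows[[length(rows) + 1L]] <- .tripleRow(s, .RDF_TYPE, t)
    for (p in setdiff(names(node), c("@id", "@type"))) {
      vals <- node[[p]]
      if (!is.null(names(vals))) vals <- list(vals)   # single object, unboxed
      for (v in vals) {
        rows[[length(rows) + 1L]] <- if (!is.null(v[["@id"]])) {
          .tripleRow(s, p, v[["@id"]])
        } else {
          .tripleRow(s, p, as.character(v[["@value"]]), "literal",
                     if (is.null(v[["@type"]])) NA_character_ else v[["@type"]])
        }
      }
    }
  }
  TripleGraph(do.call(rbind, c(list(.emptyTriples()), rows)), base)
}

# ---- dispatch --------------------------------------------------------------

#' Serialize a graph
#'
#' @param graph a [TripleGraph-class]
#' @param format one of `"turtle"`, `"rdfxml"`, `"ntriples"`, `"jsonld"`.
#' @param file optional path; when `NULL` the serialization is returned as a
#'   string.
#' @return serialization text, invisibly when `file` is given.
#' @export
serializeRdf <- function(graph, format, file = NULL) {
  if (!length(format) || !format %in% .RDF_FORMATS)
    stop("unsupported RDF format '", format, "'; supported: ",
         paste(.RDF_FORMATS, collapse = ", "))
  text <- switch(format,
    turtle   = .serializeTurtle(graph),
    rdfxml   = .serializeRdfXml(graph),
    ntriples = .serializeNTriples(graph),
    jsonld   = .serializeJsonLd(graph))
  if (is.null(file)) text else { writeLines(text, file); invisible(text) }
}

#' Parse an RDF serialization into a graph
#'
#' Supports the profile emitted by [serializeRdf()] for each of the four
#' formats; `parseRdf(serializeRdf(g, f), f)` reproduces `g`'s triple set
#' exactly.
#'
#' @param text serialization text.
#' @inheritParams serializeRdf
#' @param base the base namespace to record on the parsed graph.
#' @return a [TripleGraph-class]
#' @export
parseRdf <- function(text, format, base = .SALON_NS) {
  if (!length(format) || !format %in% .RDF_FORMATS)
    stop("unsupported RDF format '", format, "'; supported: ",
         paste(.RDF_FORMATS, collapse = ", "))
  switch(format,
    turtle   = .parseTurtle(text, base),
    rdfxml   = .parseRdfXml(text, base),
    ntriples = .parseNTriples(text, base),
    jsonld   = .parseJsonLd(text, base))
}

#' Export a graph as a SPARQL update
#'
#' Produces an `INSERT DATA` update suitable for populating a triple store
#' over the SPARQL protocol.
#'
#' @param graph a [TripleGraph-class]
#' @return SPARQL update text
#' @export
sparqlUpdate <- function(graph) {
  body <- .serializeNTriples(graph)
  paste0("INSERT DATA {\n", body, "}\n")
}
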