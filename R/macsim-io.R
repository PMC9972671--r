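# MACSIM XML (BAliBASE dialect) reader/writer. Exactly the elements of the
# MACSIM-to-SALON mapping are modeled (<aln-name>, <sequence seq-type>,
# <seq-name>, <accession>, inner <sequence>, <fitem>/<ftype>/<fstart>/
# <fstop>/<fnote>); any other element is carried through a pass-through bag
# and re-emitted verbatim, so files with richer MACSIM content survive
# round-trips.

.MACSIM_SEQ_CHILDREN <- c("seq-name", "accession", "sequence", "fitem")
.MACSIM_ALN_CHILDREN <- c("aln-name", "sequence")

.xmlChildText <- function(node, name) {
  child <- xml2::xml_find_first(node, paste0("./", name))
  if (inherits(child, "xml_missing")) NA_character_ else xml2::xml_text(child)
}

.parseFitem <- function(node) {
  fstart <- .xmlChildText(node, "fstart")
  fstop  <- .xmlChildText(node, "fstop")
  if (is.na(fstart) || is.na(fstop))
    stop("MACSIM error: <fitem> without <fstart>/<fstop>")
  fscore <- .xmlChildText(node, "fscore")
  Feature(ftype = .xmlChildText(node, "ftype") %||% NA_character_,
          fstart = as.integer(fstart), fstop = as.integer(fstop),
          fnote = .xmlChildText(node, "fnote"),
          fscore = if (is.na(fscore)) NA_real_ else as.numeric(fscore))
}

.parseMacsimSequence <- function(node, index) {
  name <- .xmlChildText(node, "seq-name")
  if (is.na(name) || !nzchar(name))
    stop(sprintf("MACSIM error: sequence %d has no <seq-name>", index))
  res <- .xmlChildText(node, "sequence")
  if (is.na(res))
    stop(sprintf("MACSIM error: sequence %d ('%s') has no inner <sequence>",
                 index, name))
  res <- toupper(gsub("\\s", "", res))
  seqType <- xml2::xml_attr(node, "seq-type")
  molecule <- if (!is.na(seqType) && toupper(seqType) == "DNA") "DNA" else "Protein"
  kids <- xml2::xml_children(node)
  unknown <- kids[!xml2::xml_name(kids) %in% .MACSIM_SEQ_CHILDREN]
  feats <- lapply(xml2::xml_find_all(node, "./fitem"), .parseFitem)
  AlignmentSequence(
    identifier = name, residues = res,
    accessionNumber = .xmlChildText(node, "accession"),
    molecule = molecule, features = feats,
    passthrough = vapply(unknown, function(k) as.character(k), character(1)))
}

.parseMacsimAlignment <- function(node) {
  seqNodes <- xml2::xml_find_all(node, "./sequence")
  seqs <- lapply(seq_along(seqNodes),
                 function(i) .parseMacsimSequence(seqNodes[[i]], i))
  kids <- xml2::xml_children(node)
  unknown <- kids[!xml2::xml_name(kids) %in% .MACSIM_ALN_CHILDREN]
  name <- .xmlChildText(node, "aln-name")
  SubAlignment(sequences = seqs,
               name = if (is.na(name)) "" else name,
               passthrough = vapply(unknown, function(k) as.character(k),
                                    character(1)))
}

#' Parse MACSIM XML into an alignment
#'
#' Accepts a `<macsim>` document with one or more `<alignment>` elements (each
#' becoming one sub-alignment), or a bare `<alignment>` root. The gap
#' character is derived from the residues.
#'
#' @param xmlText MACSIM XML as a single string.
#' @param alignmentId identifier for the resulting [Alignment-class]; defaults
#'   to the first non-empty `<aln-name>`, then `"alignment"`.
#' @return an [Alignment-class].
#' @examples
#' aln <- parseMacsim(writeMacsim(generateAlignment(nSequences = 3,
#'                                                  nColumns = 12, seed = 1)))
#' alignmentId(aln)
#' @export
parseMacsim <- function(xmlText, alignmentId = NULL) {
  doc <- tryCatch(xml2::read_xml(xmlText),
                  error = function(e) stop("MACSIM XML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  alnNodes <- if (xml2::xml_name(root) == "alignment") list(root)
              else xml2::xml_find_all(root, ".//alignment")
  if (!length(alnNodes))
    stop("MACSIM error: no <alignment> element found")
  subs <- lapply(alnNodes, .parseMacsimAlignment)
  if (is.null(alignmentId)) {
    names <- vapply(subs, function(s) s@name, character(1))
    alignmentId <- c(names[nzchar(names)], "alignment")[1L]
  }
  Alignment(alignmentId = alignmentId, subAlignments = subs)
}

#' Read a MACSIM XML file
#'
#' @param file path to a MACSIM XML file.
#' @param alignmentId identifier; defaults to the file name without extension.
#' @return an [Alignment-class].
#' @export
readMacsim <- function(file, alignmentId = NULL) {
  if (is.null(alignmentId))
    alignmentId <- tools::file_path_sans_ext(basename(file))
  parseMacsim(paste(readLines(file), collapse = "\n"), alignmentId)
}

.appendPassthrough <- function(node, snippets) {
  for (snippet in snippets)
    xml2::xml_add_child(node, xml2::read_xml(snippet))
}

.emitMacsimSequence <- function(parent, seq) {
  node <- xml2::xml_add_child(parent, "sequence", "seq-type" = seq@molecule)
  xml2::xml_add_child(node, "seq-name", seq@identifier)
  if (!is.na(seq@accessionNumber))
    xml2::xml_add_child(node, "accession", seq@accessionNumber)
  for (f in seq@features) {
    fn <- xml2::xml_add_child(node, "fitem")
    if (!is.na(f@ftype)) xml2::xml_add_child(fn, "ftype", f@ftype)
    xml2::xml_add_child(fn, "fstart", as.character(f@fstart))
    xml2::xml_add_child(fn, "fstop", as.character(f@fstop))
    if (!is.na(f@fnote)) xml2::xml_add_child(fn, "fnote", f@fnote)
    if (!is.na(f@fscore)) xml2::xml_add_child(fn, "fscore",
                                              format(f@fscore, digits = 15))
  }
  xml2::xml_add_child(node, "sequence", seq@residues)
  .appendPassthrough(node, seq@passthrough)
}

#' Write an alignment as MACSIM XML
#'
#' Inverse of [parseMacsim()]: `parseMacsim(writeMacsim(a))` reproduces `a`
#' field-for-field on every mapped element, including pass-through content.
#'
#' @param alignment an [Alignment-class].
#' @param file optional path; when `NULL` the XML text is returned.
#' @return the XML text, invisibly when `file` is given.
#' @export
writeMacsim <- function(alignment, file = NULL) {
  stopifnot(is(alignment, "Alignment"))
  doc <- xml2::xml_new_root("macsim")
  for (sub in alignment@subAlignments) {
    alnNode <- xml2::xml_add_child(doc, "alignment")
    xml2::xml_add_child(alnNode, "aln-name", sub@name)
    for (seq in sub@sequences) .emitMacsimSequence(alnNode, seq)
    .appendPassthrough(alnNode, sub@passthrough)
  }
  text <- as.character(doc)
  if (is.null(file)) text else { writeLines(text, file); invisible(text) }
}
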