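# Seeded synthetic alignment generator, emulating BAliBASE-style reference
# alignments: a controllable fraction of totally conserved columns, a
# per-cell gap rate in the remaining columns, and annotated features.

.PROTEIN_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.DNA_ALPHABET <- strsplit("ACGT", "")[[1]]

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a seeded synthetic alignment
#'
#' Produces one sub-alignment of `nSequences` aligned strings of length
#' `nColumns`. Exactly `round(conservation * nColumns)` columns are totally
#' conserved (one residue across all rows, no gaps); every other column is
#' guaranteed non-conserved, with each cell gapped at probability `gapRate`.
#' No column is ever all-gap. Features are placed with
#' `1 <= fstart <= fstop <= nColumns`. Output is a pure function of the
#' arguments: the same spec and seed give byte-identical MACSIM XML.
#'
#' The generator emulates the shape of curated reference alignments
#' (conservation structure, gaps, annotated regions); it does not simulate
#' an evolutionary substitution or indel process.
#'
#' @param nSequences number of sequences (>= 1; a 1-sequence sub-alignment
#'   is generated but fails validation's cardinality rule, by design).
#' @param nColumns number of columns (>= 1).
#' @param molecule `"Protein"` (20-letter alphabet) or `"DNA"` (ACGT).
#' @param conservation fraction of columns forced totally conserved, in
#'   `[0, 1]`.
#' @param gapRate per-cell gap probability in non-conserved columns, in
#'   `[0, 1]`.
#' @param nFeatures total number of features placed on random sequences.
#' @param seed integer RNG seed; the generator uses its own RNG stream and
#'   leaves the global RNG state untouched.
#' @param alignmentId identifier; default `SYN<seed>`.
#' @return an [Alignment-class] whose single sub-alignment is named like the
#'   alignment itself.
#' @examples
#' aln <- generateAlignment(nSequences = 3, nColumns = 10,
#'                          conservation = 1, gapRate = 0, seed = 7)
#' scoreAlignment(aln, "percent_totally_conserved")$alignmentScore@value
#' @export
generateAlignment <- function(nSequences = 4L, nColumns = 60L,
                              molecule = c("Protein", "DNA"),
                              conservation = 0.3, gapRate = 0.1,
                              nFeatures = 1L, seed, alignmentId = NULL) {
  molecule <- match.arg(molecule)
  if (missing(seed)) stop("seed must be given explicitly")
  if (nSequences < 1L) stop("nSequences must be >= 1")
  if (nColumns < 1L) stop("nColumns must be >= 1")
  if (conservation < 0 || conservation > 1)
    stop("conservation must be within [0, 1]")
  if (gapRate < 0 || gapRate > 1) stop("gapRate must be within [0, 1]")
  if (nFeatures < 0L) stop("nFeatures must be >= 0")
  if (is.null(alignmentId)) alignmentId <- paste0("SYN", as.integer(seed))
  alphabet <- if (molecule == "Protein") .PROTEIN_ALPHABET else .DNA_ALPHABET
  .withSeed(seed, {
    nCons <- round(conservation * nColumns)
    consPos <- if (nCons > 0L) sort(sample.int(nColumns, nCons)) else integer()
    mat <- matrix("", nrow = nSequences, ncol = nColumns)
    for (j in seq_len(nColumns)) {
      if (j %in% consPos) {
        mat[, j] <- sample(alphabet, 1L)
      } else {
        cell <- sample(alphabet, nSequences, replace = TRUE)
        gapped <- stats::runif(nSequences) < gapRate
        cell[gapped] <- "-"
        if (all(cell == "-"))
          cell[sample.int(nSequences, 1L)] <- sample(alphabet, 1L)
        if (nSequences > 1L && !any(cell == "-") &&
            length(unique(cell)) == 1L) {
          i <- sample.int(nSequences, 1L)
          cell[i] <- sample(setdiff(alphabet, cell[i]), 1L)
        }
        mat[, j] <- cell
      }
    }
    seqs <- lapply(seq_len(nSequences), function(i)
      AlignmentSequence(
        identifier = sprintf("seq%d", i),
        residues = paste(mat[i, ], collapse = ""),
        accessionNumber = sprintf("P%05d", i),
        molecule = molecule))
    for (k in seq_len(nFeatures)) {
      i <- sample.int(nSequences, 1L)
      fstart <- sample.int(nColumns, 1L)
      fstop <- fstart + sample.int(nColumns - fstart + 1L, 1L) - 1L
      feat <- Feature(
        ftype = sample(c("DOMAIN", "CHAIN", "HELIX", "STRAND"), 1L),
        fstart = fstart, fstop = fstop,
        fnote = sprintf("synthetic feature %d", k),
        fscore = round(stats::runif(1), 3))
      seqs[[i]]@features <- c(seqs[[i]]@features, feat)
      validObject(seqs[[i]])
    }
    Alignment(alignmentId = alignmentId,
              subAlignments = list(
                SubAlignment(sequences = seqs, name = alignmentId,
                             gapCharacter = "-")))
  })
}
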