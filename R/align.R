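#' Read a substitution matrix in NCBI text layout
#'
#' @param path Matrix file; defaults to the shipped BLOSUM62.
#' @return Numeric matrix with residue row/column names.
#' @export
readSubMatrix <- function(path = system.file("extdata", "EBLOSUM62",
                                             package = "pilyprofiler")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  letters <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(letters))))
  rownames(m) <- vapply(rows, `[`, "", 1L)
  colnames(m) <- letters
  m[letters, letters, drop = FALSE]
}

#' Alignment parameters (EMBOSS-needle-style defaults)
#'
#' Affine gap model: a gap of length L costs `gapOpen + L * gapExtend`.
#' With `endGapsPenalized = FALSE` (the needle default) terminal gaps are
#' free but still counted as alignment columns.
#'
#' @param matrix Substitution matrix name or numeric matrix; the shipped
#'   `EBLOSUM62` by default.
#' @param gapOpen Gap opening penalty (default 10).
#' @param gapExtend Gap extension penalty per position (default 0.5).
#' @param endGapsPenalized Penalize terminal gaps? Default FALSE.
#' @return A list of validated parameters.
#' @export
alignParams <- function(matrix = "EBLOSUM62", gapOpen = 10,
                        gapExtend = 0.5, endGapsPenalized = FALSE) {
  if (is.character(matrix)) {
    path <- system.file("extdata", matrix, package = "pilyprofiler")
    if (!nzchar(path)) path <- matrix
    matrix <- readSubMatrix(path)
  }
  stopifnot(is.matrix(matrix), gapOpen >= gapExtend, gapExtend >= 0)
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
       endGapsPenalized = endGapsPenalized)
}

#' Global pairwise alignment with percent identity and similarity
#'
#' Optimal affine-gap global alignment (Gotoh) under the given parameters,
#' reproducing EMBOSS-needle conventions: terminal gaps free by default but
#' included in the alignment length, percent identity =
#' 100 * identical columns / alignment length, percent similarity counting
#' columns whose residue pair scores > 0 in the substitution matrix (gap
#' columns are never similar). Traceback ties prefer a residue pair over a
#' gap in `a` over a gap in `b`, making the reported alignment
#' deterministic.
#'
#' @param a,b Protein sequences (character, `AAString`, or single-protein
#'   [ProteinSet]).
#' @param params Parameters from [alignParams()].
#' @param rangeA,rangeB Optional 1-based inclusive `c(start, end)` slices
#'   aligning only a region (e.g. a beta-propeller domain).
#' @return list: `aligned_a`, `aligned_b` (equal-length gapped strings),
#'   `score`, `align_len`, `n_identical`, `n_similar`, `pct_identity`,
#'   `pct_similarity`.
#' @examples
#' globalAlign("AAAA", "AAA")$pct_identity
#' @export
globalAlign <- function(a, b, params = alignParams(), rangeA = NULL,
                        rangeB = NULL) {
  sa <- .as_seq_char(a)
  sb <- .as_seq_char(b)
  if (!is.null(rangeA)) sa <- substring(sa, rangeA[1], rangeA[2])
  if (!is.null(rangeB)) sb <- substring(sb, rangeB[1], rangeB[2])
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  res <- .gotoh_align_cpp(sa, sb, params$matrix, rownames(params$matrix),
                          params$gapOpen, params$gapExtend,
                          !params$endGapsPenalized)
  res$pct_identity <- 100 * res$n_identical / res$align_len
  res$pct_similarity <- 100 * res$n_similar / res$align_len
  res
}

#' Pairwise percent-identity matrix and identity-derived distances
#'
#' Aligns every unordered pair of proteins and returns the symmetric
#' percent-identity matrix (diagonal 100). The companion distance is
#' `d = 100 - identity` (diagonal 0), the input to [njTree()].
#'
#' @param proteins A [ProteinSet] (at least 2 proteins).
#' @param params Parameters from [alignParams()].
#' @param similarity Also return the percent-similarity matrix?
#' @return list: `identity` (matrix), `distance` (matrix), and `similarity`
#'   when requested; dimnames are the protein ids.
#' @export
identityMatrix <- function(proteins, params = alignParams(),
                           similarity = FALSE) {
  stopifnot(methods::is(proteins, "ProteinSet"), length(proteins) >= 2L)
  ids <- proteinIds(proteins)
  seqs <- as.character(proteins@sequences)
  n <- length(ids)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  simm <- if (similarity) matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- globalAlign(seqs[[i]], seqs[[j]], params)
      idm[i, j] <- idm[j, i] <- r$pct_identity
      if (similarity) simm[i, j] <- simm[j, i] <- r$pct_similarity
    }
  }
  out <- list(identity = idm, distance = 100 - idm)
  if (similarity) out$similarity <- simm
  out
}
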