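#' @include pilyprofiler-package.R
NULL

.AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")
.AA_WITH_X <- c(.AA_LETTERS, "X")
.CLADE_LEVELS <- c("1.1","1.2","1.3","1.4a","1.4b","1.4c","1.5","1.6","1.7")
.ROLE_LEVELS <- c("pilY1","pilX","pilW","pilV","fimU","tfcP","pilA","pilB",
                  "pilT","pilC","pilM","pilN","pilO","pilP","pilQ","other")
.MINOR_ROLES <- c("pilX","pilW","pilV","fimU")
.CORE_ROLES <- c("pilQ","pilP","pilO","pilN","pilM","pilB","pilT","pilC","pilA")

#' ProteinSet: a collection of candidate PilY1 / minor-pilin proteins
#'
#' Wraps a [Biostrings::AAStringSet] (names are the unique protein ids;
#' `mcols()` carries `organism` and the optional reference clade label
#' `ref_clade`) together with a domain-annotation table (one row per domain
#' call: `protein_id`, `name`, `start`, `end`, 1-based inclusive), standing
#' in for CDD/SMART output.
#'
#' @slot sequences An `AAStringSet`; uppercase sequences over the 20 amino
#'   acids plus `X`.
#' @slot domains A `DataFrame` with columns `protein_id`, `name`, `start`,
#'   `end`.
#' @export
setClass("ProteinSet",
         slots = c(sequences = "AAStringSet", domains = "DataFrame"))

setValidity("ProteinSet", function(object) {
  seqs <- object@sequences
  ids <- names(seqs)
  msgs <- character()
  if (length(seqs)) {
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "every protein must have a non-empty id")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, paste0("duplicate protein id: ",
                             ids[duplicated(ids)][1L]))
    w <- Biostrings::width(seqs)
    if (any(w == 0)) msgs <- c(msgs, "empty sequence")
    ltrs <- Biostrings::uniqueLetters(seqs)
    if (length(setdiff(ltrs, .AA_WITH_X)))
      msgs <- c(msgs, paste0("invalid residue letter(s): ",
                             paste(setdiff(ltrs, .AA_WITH_X), collapse = ",")))
  }
  dom <- object@domains
  req <- c("protein_id", "name", "start", "end")
  if (!all(req %in% colnames(dom))) {
    msgs <- c(msgs, "domains must have columns protein_id, name, start, end")
  } else if (nrow(dom)) {
    if (length(setdiff(dom$protein_id, ids)))
      msgs <- c(msgs, "domain rows refer to unknown protein ids")
    else {
      len <- setNames(Biostrings::width(seqs), ids)
      ok <- dom$start >= 1L & dom$start <= dom$end &
            dom$end <= len[dom$protein_id]
      if (!all(ok)) msgs <- c(msgs, "domain coordinates out of bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences An `AAStringSet`, or a named character vector of
#'   sequences.
#' @param organism Character vector of organism names, recycled.
#' @param refClade Optional reference clade labels (`1.1` ... `1.7` or `NA`).
#' @param domains Optional data.frame/DataFrame of domain calls
#'   (`protein_id`, `name`, `start`, `end`).
#' @return A `ProteinSet`.
#' @examples
#' ps <- ProteinSet(c(p1 = "ACDEF", p2 = "MKLYC"), organism = "toy")
#' proteinIds(ps)
#' @export
ProteinSet <- function(sequences, organism = NA_character_,
                       refClade = NA_character_, domains = NULL) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  n <- length(sequences)
  S4Vectors::mcols(sequences) <- S4Vectors::DataFrame(
    organism = rep_len(as.character(organism), n),
    ref_clade = rep_len(as.character(refClade), n))
  if (is.null(domains))
    domains <- S4Vectors::DataFrame(protein_id = character(),
                                    name = character(),
                                    start = integer(), end = integer())
  else {
    domains <- S4Vectors::DataFrame(protein_id = as.character(domains$protein_id),
                                    name = as.character(domains$name),
                                    start = as.integer(domains$start),
                                    end = as.integer(domains$end))
  }
  methods::new("ProteinSet", sequences = sequences, domains = domains)
}

#' Accessors for ProteinSet
#'
#' @param x A `ProteinSet`.
#' @param i Index (id, logical or integer) for subsetting.
#' @name ProteinSet-accessors
#' @return `proteinIds`: character ids; `sequences`: the `AAStringSet`;
#'   `organisms`, `refClades`: per-protein character vectors; `domains`:
#'   the domain `DataFrame`.
NULL

#' @rdname ProteinSet-accessors
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-accessors
#' @export
proteinIds <- function(x) names(x@sequences)

#' @rdname ProteinSet-accessors
#' @export
sequences <- function(x) x@sequences

#' @rdname ProteinSet-accessors
#' @export
organisms <- function(x) S4Vectors::mcols(x@sequences)$organism

#' @rdname ProteinSet-accessors
#' @export
refClades <- function(x) setNames(S4Vectors::mcols(x@sequences)$ref_clade,
                                  names(x@sequences))

#' @rdname ProteinSet-accessors
#' @export
domains <- function(x) x@domains

#' @rdname ProteinSet-accessors
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  seqs <- x@sequences[i]
  dom <- x@domains[x@domains$protein_id %in% names(seqs), , drop = FALSE]
  methods::new("ProteinSet", sequences = seqs, domains = dom)
})

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object), "proteins\n")
  if (length(object)) {
    w <- Biostrings::width(object@sequences)
    cat("  length range:", min(w), "-", max(w), "aa\n")
    rc <- refClades(object)
    if (any(!is.na(rc)))
      cat("  reference-labeled:", sum(!is.na(rc)), "\n")
  }
  cat("  domain annotations:", nrow(object@domains), "rows\n")
})

#' MotifPattern: a compiled degenerate sequence motif
#'
#' Tokens are character vectors of allowed residues; a zero-length token is
#' the wildcard `x` (matches any residue, including `X`). An optional
#' discontinuous tail lists residues required/annotated downstream of the
#' contiguous core (offsets relative to the core start, 1-based).
#'
#' @slot name Motif name.
#' @slot tokens List of character vectors (allowed residue sets; `character(0)`
#'   = wildcard).
#' @slot tail A data.frame with columns `residue`, `from`, `to` (offset window
#'   relative to core start) and `required` (logical).
#' @export
setClass("MotifPattern",
         slots = c(name = "character", tokens = "list", tail = "data.frame"))

setValidity("MotifPattern", function(object) {
  if (!length(object@tokens)) return("pattern needs at least one token")
  ok <- vapply(object@tokens, function(t)
    length(t) == 0 || all(t %in% .AA_LETTERS), TRUE)
  if (!all(ok)) return("fixed token sets must be subsets of the 20 residues")
  TRUE
})

setMethod("show", "MotifPattern", function(object) {
  tok <- vapply(object@tokens, function(t) {
    if (!length(t)) "x"
    else if (length(t) == 1L) t
    else paste0("(", paste(t, collapse = "/"), ")")
  }, "")
  cat("MotifPattern", object@name, ":", paste(tok, collapse = ""), "\n")
  if (nrow(object@tail))
    cat("  discontinuous tail:",
        paste(sprintf("%s@+%d..+%d%s", object@tail$residue, object@tail$from,
                      object@tail$to,
                      ifelse(object@tail$required, "", " (annotated)")),
              collapse = ", "), "\n")
})

#' StructureModel: ordered atomic coordinates of one model
#'
#' @slot modelId Model identifier.
#' @slot atoms A data.frame with columns `res_index` (integer), `res_name`
#'   (3-letter code), `atom_name`, `x`, `y`, `z` (Angstrom), in file order.
#' @export
setClass("StructureModel",
         slots = c(modelId = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  at <- object@atoms
  req <- c("res_index", "res_name", "atom_name", "x", "y", "z")
  if (!all(req %in% colnames(at)))
    return("atoms must have columns res_index, res_name, atom_name, x, y, z")
  if (nrow(at) && !all(is.finite(c(at$x, at$y, at$z))))
    return("coordinates must be finite")
  TRUE
})

#' Construct a StructureModel
#' @param modelId Model identifier.
#' @param atoms data.frame of atoms (`res_index`, `res_name`, `atom_name`,
#'   `x`, `y`, `z`).
#' @return A `StructureModel`.
#' @export
StructureModel <- function(modelId, atoms) {
  atoms$res_index <- as.integer(atoms$res_index)
  methods::new("StructureModel", modelId = as.character(modelId),
               atoms = as.data.frame(atoms))
}

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel", object@modelId, "with", nrow(object@atoms),
      "atoms,", length(unique(object@atoms$res_index)), "residues\n")
})

#' Superposition: result of a Kabsch rigid-body fit
#'
#' The stored transform maps model B coordinates onto model A:
#' `fitted = B %*% t(rotation) + translation`.
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation Length-3 numeric, Angstrom.
#' @slot rmsd Root-mean-square deviation after the fit, Angstrom.
#' @slot nPairs Number of paired atoms used.
#' @export
setClass("Superposition",
         slots = c(rotation = "matrix", translation = "numeric",
                   rmsd = "numeric", nPairs = "integer"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: %d atom pairs, RMSD %.4f Angstrom\n",
              object@nPairs, object@rmsd))
})
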