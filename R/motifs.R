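#' Compile a degenerate motif specification
#'
#' Pattern strings use residue letters, `x` for a wildcard position, and
#' `(A/B)` (or bare `A/B`) for alternation, the notation used for the
#' PilY1 calcium-binding motifs: motif 1 `Dx(D/N)xDGxxD`, motif 2
#' `DxDxNxxxD`, motif 3 `DxD/NxDxxxxxxD/E`. A wildcard matches any residue
#' including `X`; a fixed position is never satisfied by `X`.
#'
#' The discontinuous MIDAS tail (`T` then `D` at variable spacing after the
#' `DxSxS` core) is expressed with `tail`, e.g.
#' `"T:+6..+40;D:+7..+80"`; append `!` to a tail element to make it
#' required rather than annotated.
#'
#' @param spec Pattern string.
#' @param name Motif name (defaults to `spec`).
#' @param tail Optional discontinuous-tail specification (see Details).
#' @return A [MotifPattern].
#' @examples
#' compilePattern("Dx(D/N)xDGxxD", name = "motif1")
#' @export
compilePattern <- function(spec, name = spec, tail = NULL) {
  chars <- strsplit(spec, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("malformed alternation: unclosed '(' in ", spec)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      alt <- strsplit(inner, "/", fixed = TRUE)[[1]]
      if (length(alt) < 2L || !all(alt %in% .AA_LETTERS))
        stop("malformed alternation '(", inner, ")' in ", spec)
      tokens[[length(tokens) + 1L]] <- alt
      i <- j + 1L
    } else if (ch == "/") {
      if (!length(tokens) || i == n)
        stop("malformed alternation: dangling '/' in ", spec)
      prev <- tokens[[length(tokens)]]
      nxt <- chars[i + 1L]
      if (!length(prev) || !nxt %in% .AA_LETTERS)
        stop("malformed alternation around '/' in ", spec)
      tokens[[length(tokens)]] <- c(prev, nxt)
      i <- i + 2L
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- character(0)  # wildcard
      i <- i + 1L
    } else if (ch %in% .AA_LETTERS) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in motif spec ", spec)
    }
  }
  taildf <- data.frame(residue = character(), from = integer(),
                       to = integer(), required = logical())
  if (!is.null(tail) && nzchar(tail)) {
    parts <- strsplit(tail, ";", fixed = TRUE)[[1]]
    for (p in parts) {
      required <- grepl("!$", p)
      p <- sub("!$", "", p)
      m <- regmatches(p, regexec("^([A-Z]):\\+?(\\d+)\\.\\.\\+?(\\d+)$", p))[[1]]
      if (length(m) != 4L) stop("malformed tail element '", p, "'")
      taildf <- rbind(taildf, data.frame(
        residue = m[2], from = as.integer(m[3]), to = as.integer(m[4]),
        required = required))
    }
  }
  methods::new("MotifPattern", name = name, tokens = tokens, tail = taildf)
}

#' The shipped motif catalog
#'
#' Reads the plain-text motif catalog (TSV: name, pattern, optional tail)
#' and compiles every entry. The default catalog holds the three
#' calcium-binding motifs, the MIDAS core (`DxSxS` with the annotated
#' discontinuous T/D tail) and RGD.
#'
#' @param path Catalog path; defaults to the catalog shipped with the
#'   package.
#' @return Named list of [MotifPattern] objects.
#' @export
defaultMotifs <- function(path = system.file("extdata", "motifs.tsv",
                                             package = "pilyprofiler")) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  pats <- lapply(seq_len(nrow(cat)), function(i)
    compilePattern(cat$pattern[i], name = cat$name[i],
                   tail = if ("tail" %in% colnames(cat) &&
                              nzchar(cat$tail[i])) cat$tail[i] else NULL))
  setNames(pats, cat$name)
}

.as_seq_char <- function(x) {
  if (methods::is(x, "ProteinSet")) {
    stopifnot(length(x) == 1L)
    as.character(x@sequences)[[1]]
  } else if (methods::is(x, "AAString") || methods::is(x, "AAStringSet")) {
    as.character(x)[[1]]
  } else as.character(x)[[1]]
}

#' Scan one sequence with a compiled motif pattern
#'
#' Every (possibly overlapping) match of the contiguous core is reported,
#' ascending by start. `X` never satisfies a fixed residue position. If the
#' pattern carries a required discontinuous tail element, a core match
#' without it is dropped; annotated (non-required) tail residues are
#' reported in `tail_pos` when present.
#'
#' @param x A single-protein [ProteinSet], `AAString`, or character
#'   sequence.
#' @param pattern A [MotifPattern].
#' @param protein_id Id used in the output (taken from `x` when possible).
#' @return data.frame with columns `protein_id`, `motif_name`, `start`,
#'   `end` (1-based inclusive core span), `matched`, `tail_pos`.
#' @examples
#' scanMotif("AARGDKK", compilePattern("RGD"))
#' @export
scanMotif <- function(x, pattern, protein_id = NULL) {
  seq <- .as_seq_char(x)
  if (is.null(protein_id))
    protein_id <- if (methods::is(x, "ProteinSet")) proteinIds(x)[1]
                  else NA_character_
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- length(pattern@tokens)
  empty <- data.frame(protein_id = character(), motif_name = character(),
                      start = integer(), end = integer(),
                      matched = character(), tail_pos = character())
  if (L < k) return(empty)
  n_off <- L - k + 1L
  ok <- rep(TRUE, n_off)
  for (t in seq_len(k)) {
    set <- pattern@tokens[[t]]
    if (!length(set)) next  # wildcard
    ok <- ok & (chars[seq.int(t, t + n_off - 1L)] %in% set)
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  tail_pos <- rep("", length(starts))
  if (nrow(pattern@tail)) {
    keep <- rep(TRUE, length(starts))
    for (h in seq_along(starts)) {
      p <- starts[h]
      ann <- character()
      for (r in seq_len(nrow(pattern@tail))) {
        lo <- max(p + pattern@tail$from[r], 1L)
        hi <- min(p + pattern@tail$to[r], L)
        win <- if (lo > hi) integer(0) else seq.int(lo, hi)
        found <- win[chars[win] == pattern@tail$residue[r]]
        if (length(found)) {
          ann <- c(ann, paste0(pattern@tail$residue[r], found[1]))
        } else if (pattern@tail$required[r]) {
          keep[h] <- FALSE
        }
      }
      tail_pos[h] <- paste(ann, collapse = ",")
    }
    starts <- starts[keep]
    tail_pos <- tail_pos[keep]
    if (!length(starts)) return(empty)
  }
  data.frame(protein_id = protein_id, motif_name = pattern@name,
             start = starts, end = starts + k - 1L,
             matched = substring(seq, starts, starts + k - 1L),
             tail_pos = tail_pos, stringsAsFactors = FALSE)
}

#' Cysteine census of a protein sequence
#'
#' @param x A single-protein [ProteinSet], `AAString`, or character
#'   sequence.
#' @return list with `length`, `n_cys` (exact count of `C` over the full
#'   annotated sequence) and `cys_positions` (1-based).
#' @examples
#' cysteineCensus("CACC")
#' @export
cysteineCensus <- function(x) {
  seq <- .as_seq_char(x)
  pos <- as.integer(gregexpr("C", seq, fixed = TRUE)[[1]])
  if (length(pos) == 1L && pos[1] == -1L) pos <- integer(0)
  list(length = nchar(seq), n_cys = length(pos), cys_positions = pos)
}

.DOMAIN_ALIASES <- list(
  vWFA = c("vwfa", "vwa", "vwf_a"),
  DUF4114 = c("duf4114"),
  beta_propeller = c("beta_propeller", "pily1_beta_propeller", "pily1",
                     "beta-propeller", "pf05567"))

.domain_flags <- function(dom, id) {
  nm <- tolower(dom$name[dom$protein_id == id])
  vapply(.DOMAIN_ALIASES, function(al) any(nm %in% al), TRUE)
}

#' Per-protein feature profiles
#'
#' Aggregates, for every protein, the scan results of the five repertoire
#' motifs (calcium-binding motifs 1-3, MIDAS, RGD), the cysteine census and
#' the domain flags from the annotation table (vWFA, DUF4114,
#' beta-propeller). `all_three_ca` is true iff motifs 1, 2 and 3 all have
#' at least one hit.
#'
#' @param proteins A [ProteinSet].
#' @param patterns Named list of [MotifPattern] (default [defaultMotifs()]);
#'   names `motif1`, `motif2`, `motif3`, `MIDAS`, `RGD` drive the flag
#'   columns.
#' @return data.frame, one row per protein: `protein_id`, `organism`,
#'   `length`, `n_cys`, per-motif flag (`has_<name>`) and start-position
#'   columns (`<name>_starts`, comma-joined), `vWFA`, `DUF4114`,
#'   `beta_propeller`, `all_three_ca`.
#' @export
profileFeatures <- function(proteins, patterns = defaultMotifs()) {
  stopifnot(methods::is(proteins, "ProteinSet"))
  ids <- proteinIds(proteins)
  seqs <- as.character(proteins@sequences)
  dom <- as.data.frame(proteins@domains)
  rows <- lapply(seq_along(ids), function(i) {
    cen <- cysteineCensus(seqs[[i]])
    row <- data.frame(protein_id = ids[i],
                      organism = organisms(proteins)[i],
                      length = cen$length, n_cys = cen$n_cys,
                      stringsAsFactors = FALSE)
    for (nm in names(patterns)) {
      hits <- scanMotif(seqs[[i]], patterns[[nm]], protein_id = ids[i])
      row[[paste0("has_", nm)]] <- as.integer(nrow(hits) > 0L)
      row[[paste0(nm, "_starts")]] <- paste(hits$start, collapse = ",")
    }
    fl <- .domain_flags(dom, ids[i])
    row$vWFA <- as.integer(fl[["vWFA"]])
    row$DUF4114 <- as.integer(fl[["DUF4114"]])
    row$beta_propeller <- as.integer(fl[["beta_propeller"]])
    row
  })
  out <- do.call(rbind, rows)
  ca <- c("has_motif1", "has_motif2", "has_motif3")
  out$all_three_ca <- if (all(ca %in% colnames(out)))
    as.integer(rowSums(out[, ca, drop = FALSE]) == 3L) else NA_integer_
  out
}
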