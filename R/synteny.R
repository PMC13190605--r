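.check_features <- function(features) {
  stopifnot(methods::is(features, "GRanges"))
  mc <- S4Vectors::mcols(features)
  if (!all(c("locus_tag", "role") %in% colnames(mc)))
    stop("features need locus_tag and role metadata columns (see readGff3)")
  invisible(features)
}

.per_contig_sorted <- function(features, require_sorted = FALSE) {
  .check_features(features)
  contigs <- as.character(GenomicRanges::seqnames(features))
  idx <- split(seq_along(features), contigs)
  if (require_sorted) {
    for (ii in idx)
      if (is.unsorted(GenomicRanges::start(features)[ii]))
        stop("features must be sorted by start within each contig")
  }
  lapply(idx, function(ii) ii[order(GenomicRanges::start(features)[ii])])
}

#' Detect T4aP gene clusters by greedy chaining
#'
#' Two role-bearing genes (role != `other`) on one contig join the same
#' cluster when at most `maxGapGenes` non-role genes intervene and their
#' intergenic span is at most `maxGapBp`. Cluster types: `major_cluster`
#' when at least 5 distinct core roles (pilQ/P/O/N/M, pilB, pilT, pilC,
#' pilA) are present; `minor_cluster` when a pilY1 plus at least two of
#' pilX/pilW/pilV/fimU are present; `major_embedded_pilY1` when both hold;
#' a pilY1 that joins no other role gene is `solitary_pilY1`; anything else
#' is `other`.
#'
#' @param features GRanges from [readGff3()], sorted by start per contig.
#' @param maxGapGenes Maximum intervening non-role genes (default 2).
#' @param maxGapBp Maximum intergenic span in bp (default 3000).
#' @param couplingGap Passed to [detectTranslationalCoupling()] for the
#'   per-cluster coupling pairs.
#' @return data.frame, one row per cluster: `contig`, `start`, `end`,
#'   `cluster_type`, `members` (comma-joined locus_tags in genomic order),
#'   `roles`, `pilY1_tags`, `coupling_pairs`
#'   (`upstream>downstream` semicolon-joined).
#' @export
detectClusters <- function(features, maxGapGenes = 2, maxGapBp = 3000,
                           couplingGap = 4) {
  ord <- .per_contig_sorted(features, require_sorted = TRUE)
  coupling <- detectTranslationalCoupling(features,
                                          maxOverlapGap = couplingGap)
  rows <- list()
  for (contig in names(ord)) {
    ii <- ord[[contig]]
    roles <- as.character(features$role[ii])
    tags <- as.character(features$locus_tag[ii])
    starts <- GenomicRanges::start(features)[ii]
    ends <- GenomicRanges::end(features)[ii]
    rpos <- which(roles != "other")
    if (!length(rpos)) next
    chains <- list()
    cur <- rpos[1]
    if (length(rpos) > 1L) for (k in seq.int(2L, length(rpos))) {
      prev <- cur[length(cur)]
      nxt <- rpos[k]
      n_between <- nxt - prev - 1L
      span <- starts[nxt] - ends[prev] - 1L
      if (n_between <= maxGapGenes && span <= maxGapBp) {
        cur <- c(cur, nxt)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- nxt
      }
    }
    chains[[length(chains) + 1L]] <- cur
    for (ch in chains) {
      mroles <- roles[ch]
      mtags <- tags[ch]
      n_core <- length(intersect(unique(mroles), .CORE_ROLES))
      has_pily1 <- "pilY1" %in% mroles
      n_minor <- length(intersect(unique(mroles), .MINOR_ROLES))
      is_major <- n_core >= 5L
      is_minor <- has_pily1 && n_minor >= 2L
      type <- if (is_major && is_minor && has_pily1) "major_embedded_pilY1"
              else if (is_major) "major_cluster"
              else if (is_minor) "minor_cluster"
              else if (has_pily1 && length(ch) == 1L) "solitary_pilY1"
              else "other"
      cpl <- coupling[coupling$upstream_tag %in% mtags &
                      coupling$downstream_tag %in% mtags, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = min(starts[ch]), end = max(ends[ch]),
        cluster_type = type,
        members = paste(mtags, collapse = ","),
        roles = paste(mroles, collapse = ","),
        pilY1_tags = paste(mtags[mroles == "pilY1"], collapse = ","),
        coupling_pairs = if (nrow(cpl))
          paste(paste0(cpl$upstream_tag, ">", cpl$downstream_tag),
                collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), cluster_type = character(),
                      members = character(), roles = character(),
                      pilY1_tags = character(), coupling_pairs = character()))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Classify each pilY1 gene as linked or unlinked
#'
#' A pilY1 is `linked` iff at least one minor-pilin gene (pilX, pilW, pilV
#' or fimU) lies within `windowGenes` genes of it on the same contig
#' (strand ignored); otherwise `unlinked`. Evidence lists every minor-pilin
#' role found in the window with its signed gene distance (negative =
#' upstream in coordinate order).
#'
#' @param features GRanges from [readGff3()].
#' @param windowGenes Gene-distance window (default 5).
#' @return data.frame, one row per pilY1: `pilY1_tag`, `contig`, `status`,
#'   `evidence` (e.g. `"pilX:-1,pilW:-2"`).
#' @export
classifyLinkage <- function(features, windowGenes = 5) {
  ord <- .per_contig_sorted(features)
  rows <- list()
  for (contig in names(ord)) {
    ii <- ord[[contig]]
    roles <- as.character(features$role[ii])
    tags <- as.character(features$locus_tag[ii])
    for (p in which(roles == "pilY1")) {
      win <- seq.int(max(1L, p - windowGenes),
                     min(length(ii), p + windowGenes))
      win <- setdiff(win, p)
      hits <- win[roles[win] %in% .MINOR_ROLES]
      ev <- paste(sprintf("%s:%+d", roles[hits], hits - p), collapse = ",")
      rows[[length(rows) + 1L]] <- data.frame(
        pilY1_tag = tags[p], contig = contig,
        status = if (length(hits)) "linked" else "unlinked",
        evidence = ev, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pilY1_tag = character(), contig = character(),
                      status = character(), evidence = character()))
  do.call(rbind, rows)
}

#' Detect translational coupling between consecutive CDS
#'
#' For every pair of consecutive same-strand CDS on one contig the
#' intergenic distance is `g = next_start - prev_end - 1`; the pair is
#' reported as coupled when `g <= maxOverlapGap` (covering the canonical
#' 1-bp and 4-bp stop/start overlaps, where `g` is negative).
#'
#' @param features GRanges from [readGff3()].
#' @param maxOverlapGap Maximum intergenic distance in bp (default 4).
#' @return data.frame: `contig`, `upstream_tag`, `downstream_tag`, `gap_bp`.
#' @export
detectTranslationalCoupling <- function(features, maxOverlapGap = 4) {
  ord <- .per_contig_sorted(features)
  rows <- list()
  for (contig in names(ord)) {
    ii <- ord[[contig]]
    if (length(ii) < 2L) next
    strands <- as.character(GenomicRanges::strand(features)[ii])
    starts <- GenomicRanges::start(features)[ii]
    ends <- GenomicRanges::end(features)[ii]
    tags <- as.character(features$locus_tag[ii])
    for (k in seq_len(length(ii) - 1L)) {
      if (strands[k] != strands[k + 1L]) next
      g <- starts[k + 1L] - ends[k] - 1L
      if (g <= maxOverlapGap)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, upstream_tag = tags[k],
          downstream_tag = tags[k + 1L], gap_bp = g,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), upstream_tag = character(),
                      downstream_tag = character(), gap_bp = integer()))
  do.call(rbind, rows)
}

#' Flag a pilY1 gene near a contig edge
#'
#' Assembly-artifact caveat: TRUE when the pilY1 CDS starts or ends within
#' `marginBp` of a contig boundary. Contig lengths come from the
#' `##sequence-region` pragmas captured by [readGff3()]; when absent the
#' flag is `NA` with a warning.
#'
#' @param features GRanges from [readGff3()].
#' @param pilY1Tag locus_tag of the pilY1 gene.
#' @param marginBp Edge margin in bp (default 2000).
#' @return TRUE, FALSE, or NA (unknown contig length).
#' @export
edgeFlag <- function(features, pilY1Tag, marginBp = 2000) {
  .check_features(features)
  i <- which(features$locus_tag == pilY1Tag)
  if (!length(i)) stop("no feature with locus_tag ", pilY1Tag)
  i <- i[1]
  contig <- as.character(GenomicRanges::seqnames(features)[i])
  clen <- GenomeInfoDb::seqlengths(features)[contig]
  if (is.na(clen)) {
    warning("contig length unknown for ", contig,
            " (no ##sequence-region pragma); edge flag unknown")
    return(NA)
  }
  s <- GenomicRanges::start(features)[i]
  e <- GenomicRanges::end(features)[i]
  (s - 1L) < marginBp || (clen - e) < marginBp
}
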