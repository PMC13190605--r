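# Independent oracles and fixture builders used across the suite.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
          "R","S","T","V","W","Y")

# ---- brute-force motif oracle: test every offset independently ----------
# patterns given as list of allowed-letter vectors (character(0) = wildcard)
oracle_scan_starts <- function(seq, tokens) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- length(tokens)
  if (L < k) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(L - k + 1L)) {
    ok <- TRUE
    for (t in seq_len(k)) {
      set <- tokens[[t]]
      if (length(set) && !(chars[s + t - 1L] %in% set)) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

oracle_tokens <- list(
  motif1 = list("D", character(0), c("D","N"), character(0), "D", "G",
                character(0), character(0), "D"),
  motif2 = list("D", character(0), "D", character(0), "N", character(0),
                character(0), character(0), "D"),
  motif3 = list("D", character(0), c("D","N"), character(0), "D",
                character(0), character(0), character(0), character(0),
                character(0), character(0), c("D","E")),
  MIDAS = list("D", character(0), "S", character(0), "S"),
  RGD = list("R", "G", "D"))

# ---- exhaustive global-alignment oracle ---------------------------------
# enumerates every global alignment (no gap-gap columns) and scores it
# under the documented affine model: gap of length L costs open + L*ext,
# terminal gap runs free when free_ends.
oracle_best_score <- function(a, b, submat, open = 10, ext = 0.5,
                              free_ends = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  score_cols <- function(cols) {
    sa <- vapply(cols, `[`, "", 1L)
    sb <- vapply(cols, `[`, "", 2L)
    s <- 0
    run_cost <- function(gapped) {
      r <- rle(gapped == "-")
      cost <- 0
      pos <- cumsum(r$lengths)
      start <- c(1L, head(pos, -1L) + 1L)
      for (q in seq_along(r$values)) {
        if (!r$values[q]) next
        terminal <- start[q] == 1L || pos[q] == length(gapped)
        if (free_ends && terminal) next
        cost <- cost + open + ext * r$lengths[q]
      }
      cost
    }
    for (k in seq_along(sa))
      if (sa[k] != "-" && sb[k] != "-") s <- s + submat[sa[k], sb[k]]
    s - run_cost(sa) - run_cost(sb)
  }
  rec <- function(i, j, cols) {
    if (i > length(ca) && j > length(cb)) {
      sc <- score_cols(cols)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, c(cols, list(c(ca[i], cb[j]))))
    if (i <= length(ca))
      rec(i + 1L, j, c(cols, list(c(ca[i], "-"))))
    if (j <= length(cb))
      rec(i, j + 1L, c(cols, list(c("-", cb[j]))))
  }
  rec(1L, 1L, list())
  best
}

# ---- GRanges fixture builder for synteny tests --------------------------
make_features <- function(roles, contig = "ctg1", start0 = 1000,
                          gene_len = 900, gap = 150, strand = "+",
                          seqlen = NA) {
  n <- length(roles)
  starts <- start0 + (seq_len(n) - 1L) * (gene_len + gap)
  ends <- starts + gene_len - 1L
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = rep_len(strand, n),
    locus_tag = sprintf("g%02d", seq_len(n)), role = roles)
  if (!is.na(seqlen)) GenomeInfoDb::seqlengths(gr) <- setNames(seqlen, contig)
  gr
}

# mirror a contig coordinate system (reversal-invariance property)
mirror_features <- function(gr, L) {
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  ns <- L - e + 1L; ne <- L - s + 1L
  o <- order(ns)
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr))[o],
    ranges = IRanges::IRanges(start = ns[o], end = ne[o]),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                    "-", "+")[o],
    locus_tag = gr$locus_tag[o], role = gr$role[o])
  out
}

# ---- random proper rotation (for Kabsch oracles) ------------------------
random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rmsd of B onto A under a fixed rotation with the optimal translation
rmsd_given_rotation <- function(A, B, R) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B)) %*% t(R)
  sqrt(mean(rowSums((A0 - B0)^2)))
}

# random additive tree and its exact leaf distance matrix
random_additive_matrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.5, 3))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[sort(rownames(D)), sort(rownames(D))])
}

# tiny PDB text fixture (altloc optional; blank when absent)
write_toy_pdb <- function(path, atoms) {
  altloc <- if (is.null(atoms$altloc)) rep(" ", nrow(atoms))
            else ifelse(atoms$altloc == "", " ", atoms$altloc)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom_name) < 4L, paste0(" ", atoms$atom_name),
           atoms$atom_name),
    altloc, atoms$res_name, atoms$res_index, atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  path
}
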