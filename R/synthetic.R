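.BG_ALPHABET <- setdiff(.AA_LETTERS, "C")  # cysteines are planted exactly

#' Clade templates for the synthetic proteome generator
#'
#' One row per PilY1 clade with the study conditions the generator plants:
#' the per-clade cysteine-count medians (23/22 for 1.1/1.2, 35 for 1.3,
#' 21/25/17 for 1.4a/b/c, 30/36/41 for 1.5/1.6/1.7), protein-length
#' medians following the reported ordering (clade 1.4a shortest, 1.6/1.7
#' longest), the N-terminal domain to emit (DUF4114 for 1.1/1.2, vWFA for
#' 1.3/1.4b/1.5/1.6/1.7, none for 1.4a/1.4c; a C-terminal beta-propeller
#' always), and the motif-repertoire probabilities (motif 1 predominant in
#' 1.1/1.2; 1.4c/1.4a/1.7 mostly lacking all three calcium-binding motifs;
#' MIDAS spread across lineages; RGD in roughly a fifth of proteins).
#'
#' @return data.frame of templates, one row per clade.
#' @export
cladeTemplates <- function() {
  data.frame(
    clade = .CLADE_LEVELS,
    median_len = c(1250L, 1200L, 1450L, 900L, 1100L, 1000L, 1500L,
                   1700L, 1650L),
    median_cys = c(23L, 22L, 35L, 21L, 25L, 17L, 30L, 36L, 41L),
    domain = c("DUF4114", "DUF4114", "vWFA", "none", "vWFA", "none",
               "vWFA", "vWFA", "vWFA"),
    p_motif1 = c(0.90, 0.90, 0.50, 0.10, 0.50, 0.10, 0.50, 0.50, 0.10),
    p_motif2 = c(0.10, 0.10, 0.35, 0.05, 0.35, 0.05, 0.35, 0.35, 0.05),
    p_motif3 = c(0.10, 0.10, 0.30, 0.05, 0.30, 0.05, 0.30, 0.30, 0.05),
    p_MIDAS = c(0.25, 0.25, 0.60, 0.25, 0.60, 0.25, 0.60, 0.60, 0.60),
    p_RGD = rep(0.19, 9L),
    stringsAsFactors = FALSE)
}

# symmetric delta multiset with exact median 0 (even n: central pair is 0,0)
.balanced_deltas <- function(n, max_abs) {
  if (n <= 2L || max_abs == 0) return(rep(0L, n))
  m <- min(floor((n - 2L) / 2), max_abs)
  mags <- unique(round(seq_len(m) / m * max_abs))
  mags <- mags[mags > 0]
  d <- c(-rev(mags), rep(0L, n - 2L * length(mags)), mags)
  as.integer(d)
}

.random_bg <- function(n) paste(sample(.BG_ALPHABET, n, replace = TRUE),
                                collapse = "")

# concrete instance of a motif pattern (wildcards filled from the
# cysteine-free background; fixed sets take a random allowed letter)
.motif_instance <- function(pattern) {
  vapply(pattern@tokens, function(t) {
    if (!length(t)) sample(.BG_ALPHABET, 1L)
    else if (length(t) == 1L) t
    else sample(t, 1L)
  }, "")
}

.scan_all <- function(seq, patterns) {
  hits <- lapply(patterns, function(p) scanMotif(seq, p)$start)
  names(hits) <- names(patterns)
  hits
}

#' Generate a clade-structured synthetic proteome with ground truth
#'
#' Each protein is built from its clade's conserved core (mutated per
#' protein at `subRate`, keeping within-clade identity high and
#' between-clade identity low), a protein-specific random N-terminal
#' flank, planted motif instances at recorded positions, and cysteines
#' injected at exactly the planted count (the background alphabet excludes
#' C). Per-clade cysteine counts and lengths are the clade median plus a
#' balanced delta multiset whose median is zero, so the planted clade
#' medians are exact. Every generated protein is re-scanned; a protein
#' whose background produces chance motif hits beyond the planted set is
#' regenerated (logged, at most `maxRetry` attempts) so that the manifest
#' exactly equals the scanner output.
#'
#' @param templates Templates from [cladeTemplates()] (or a subset).
#' @param nPerClade Proteins per clade (default 12).
#' @param seed Integer seed; output is byte-deterministic given the seed.
#' @param exemplarsPerClade How many proteins per clade carry a reference
#'   clade label (default 2).
#' @param subRate Per-site substitution rate applied to the clade core
#'   (default 0.04, tuned so within-clade identity stays at or above 70
#'   percent while between-clade identity stays far below 40 percent).
#' @param maxRetry Regeneration attempts per protein (default 100).
#' @return list: `proteins` (a [ProteinSet] with domain annotations and
#'   exemplar `refClade` labels) and `manifest` (per-protein data.frame:
#'   `protein_id`, `clade`, `length`, `n_cys`, one `<motif>_starts` column
#'   per motif with the planted, comma-joined 1-based positions).
#' @export
generateProteome <- function(templates = cladeTemplates(), nPerClade = 12,
                             seed = 1, exemplarsPerClade = 2,
                             subRate = 0.04, maxRetry = 100) {
  set.seed(seed)
  patterns <- defaultMotifs()
  ids <- character(); seqs <- character()
  man_rows <- list(); dom_rows <- list(); ref <- character()
  for (ci in seq_len(nrow(templates))) {
    tp <- templates[ci, ]
    core_len <- as.integer(round(0.9 * tp$median_len))
    # clade core free of chance motif hits
    core <- NULL
    for (try in seq_len(maxRetry)) {
      cand <- .random_bg(core_len)
      if (sum(lengths(.scan_all(cand, patterns))) == 0L) { core <- cand; break }
    }
    if (is.null(core)) stop("could not build a motif-free clade core")
    core_chars <- strsplit(core, "")[[1]]
    len_deltas <- sample(.balanced_deltas(nPerClade,
                          max_abs = round(0.04 * tp$median_len)))
    cys_deltas <- sample(.balanced_deltas(nPerClade, max_abs = 4L))
    for (k in seq_len(nPerClade)) {
      id <- sprintf("%s_p%02d", gsub("\\.", "_", paste0("c", tp$clade)), k)
      L <- as.integer(tp$median_len + len_deltas[k])
      n_cys <- as.integer(tp$median_cys + cys_deltas[k])
      flank_len <- L - core_len
      # planted-motif plan, fixed across retries
      plan <- names(patterns)[stats::runif(length(patterns)) <
        unlist(tp[paste0("p_", names(patterns))])]
      done <- FALSE
      for (attempt in seq_len(maxRetry)) {
        chars <- c(strsplit(.random_bg(flank_len), "")[[1]], core_chars)
        # per-protein substitutions on the core
        mut <- flank_len + which(stats::runif(core_len) < subRate)
        chars[mut] <- sample(.BG_ALPHABET, length(mut), replace = TRUE)
        # plant motifs at non-overlapping positions inside the core
        occupied <- integer(0)
        planted <- list()
        ok <- TRUE
        for (nm in plan) {
          inst <- .motif_instance(patterns[[nm]])
          klen <- length(inst)
          extra <- if (nm == "MIDAS") 25L else 0L  # room for the T/D tail
          placed <- FALSE
          for (ptry in seq_len(50L)) {
            s <- sample.int(L - klen - extra - 1L, 1L)
            span <- seq.int(s, s + klen + extra - 1L)
            if (!length(intersect(span, occupied))) {
              chars[seq.int(s, s + klen - 1L)] <- inst
              if (nm == "MIDAS") {  # annotated discontinuous tail
                chars[s + 10L] <- "T"
                chars[s + 20L] <- "D"
              }
              occupied <- c(occupied, span)
              planted[[nm]] <- s
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) next
        # exact cysteine planting outside motif spans
        free <- setdiff(seq_len(L), occupied)
        if (length(free) < n_cys) next
        cys_pos <- sort(sample(free, n_cys))
        chars[cys_pos] <- "C"
        seqstr <- paste(chars, collapse = "")
        # manifest must equal the scan exactly: no chance hits allowed
        hits <- .scan_all(seqstr, patterns)
        want <- lapply(setNames(names(patterns), names(patterns)),
                       function(nm) unname(unlist(planted[nm])))
        if (identical(lapply(hits, as.integer),
                      lapply(want, function(w)
                        if (is.null(w)) integer(0) else as.integer(w)))) {
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("motif planting failed after ", maxRetry, " retries for ", id)
      if (attempt > 1L)
        message(id, ": regenerated ", attempt - 1L,
                " time(s) to clear chance motif hits")
      ids <- c(ids, id); seqs <- c(seqs, seqstr)
      ref <- c(ref, if (k <= exemplarsPerClade) tp$clade else NA_character_)
      row <- data.frame(protein_id = id, clade = tp$clade, length = L,
                        n_cys = n_cys, stringsAsFactors = FALSE)
      for (nm in names(patterns))
        row[[paste0(nm, "_starts")]] <-
          if (!is.null(planted[[nm]])) as.character(planted[[nm]]) else ""
      man_rows[[length(man_rows) + 1L]] <- row
      # domain annotations: beta-propeller always; clade N-terminal domain
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = id, name = "beta_propeller",
        start = L - 360L, end = L - 20L, stringsAsFactors = FALSE)
      if (tp$domain != "none")
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = id, name = tp$domain, start = 40L, end = 220L,
          stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man_rows)
  proteins <- ProteinSet(setNames(seqs, ids), organism = "synthetic",
                         refClade = ref, domains = do.call(rbind, dom_rows))
  list(proteins = proteins, manifest = manifest)
}

.GENOME_LAYOUTS <- list(
  mx_cluster1 = list(
    genes = c("fimU", "pilV", "pilW", "pilX", "tfcP", "pilY1"),
    coupling_after = c("tfcP"), overlap_bp = 4L,
    cluster_type = "minor_cluster", linkage = "linked"),
  mx_cluster2 = list(
    genes = c("fimU", "pilV", "pilW", "pilX", "pilY1"),
    coupling_after = character(0), overlap_bp = 4L,
    cluster_type = "minor_cluster", linkage = "linked"),
  mx_cluster3 = list(
    genes = c("fimU", "pilV", "pilW", "pilX", "pilY1", "other"),
    coupling_after = c("pilY1"), overlap_bp = 1L,
    cluster_type = "minor_cluster", linkage = "linked"),
  anaeromyxobacter_embedded = list(
    genes = c("pilQ", "pilP", "pilO", "pilN", "pilM", "fimU", "pilV",
              "pilW", "pilX", "pilY1", "pilB", "pilT", "pilC", "pilA"),
    coupling_after = character(0), overlap_bp = 4L,
    cluster_type = "major_embedded_pilY1", linkage = "linked"),
  solitary_unlinked = list(
    genes = c("other", "other", "pilY1", "other", "other"),
    coupling_after = character(0), overlap_bp = 4L,
    cluster_type = "solitary_pilY1", linkage = "unlinked"),
  pilX_adjacent_partial = list(
    genes = c("other", "pilY1", "pilX", "other"),
    coupling_after = character(0), overlap_bp = 4L,
    cluster_type = "other", linkage = "linked"))

.GENE_LEN <- c(pilY1 = 4200L, tfcP = 1200L, fimU = 550L, pilV = 600L,
               pilW = 800L, pilX = 650L, pilA = 600L, pilB = 1700L,
               pilT = 1100L, pilC = 1300L, pilM = 1100L, pilN = 600L,
               pilO = 650L, pilP = 550L, pilQ = 2400L, other = 900L)

#' Generate annotated synthetic genomes with planted pilY1 arrangements
#'
#' Each requested layout becomes one genome (one contig) with CDS
#' coordinates honoring the layout's gene order, random intergenic gaps,
#' and planted 1-bp/4-bp stop/start overlaps where the layout specifies
#' translational coupling. Available layouts: `mx_cluster1` (minor-pilin
#' cluster with a tfcP-pilY1 coupling overlap), `mx_cluster2`,
#' `mx_cluster3` (trailing non-role gene, coupled to pilY1),
#' `anaeromyxobacter_embedded` (pilY1 and minor pilins inside the major
#' cluster), `solitary_unlinked`, `pilX_adjacent_partial`.
#'
#' @param layouts Character vector of layout names (default: all six).
#' @param seed Integer seed.
#' @param outdir Optional directory; when given, one GFF3 file per layout
#'   is written (`<layout>.gff3`).
#' @return list: `genomes` (named list of GRanges with `locus_tag`/`role`,
#'   contig lengths set), `gff_paths` (when written) and `manifest`
#'   (per-layout expected cluster type, linkage status and coupling pairs).
#' @export
generateGenome <- function(layouts = names(.GENOME_LAYOUTS), seed = 1,
                           outdir = NULL) {
  unknown <- setdiff(layouts, names(.GENOME_LAYOUTS))
  if (length(unknown)) stop("unknown layout(s): ", paste(unknown, collapse = ","))
  set.seed(seed)
  genomes <- list(); man_rows <- list(); paths <- character()
  for (ly in layouts) {
    lay <- .GENOME_LAYOUTS[[ly]]
    contig <- paste0("ctg_", ly)
    pos <- 2500L + sample.int(500L, 1L)
    starts <- integer(); ends <- integer(); tags <- character()
    roles <- character()
    expected_pairs <- character()
    for (gi in seq_along(lay$genes)) {
      role <- lay$genes[gi]
      glen <- .GENE_LEN[[role]] + sample.int(60L, 1L)
      tag <- sprintf("%s_g%02d", ly, gi)
      starts <- c(starts, pos); ends <- c(ends, pos + glen - 1L)
      tags <- c(tags, tag); roles <- c(roles, role)
      # next start: coupled -> overlap; else a 50-250 bp gap
      if (gi < length(lay$genes) && role %in% lay$coupling_after) {
        pos <- pos + glen - lay$overlap_bp
        expected_pairs <- c(expected_pairs,
                            paste0(tag, ">", sprintf("%s_g%02d", ly, gi + 1L)))
      } else {
        pos <- pos + glen - 1L + 50L + sample.int(200L, 1L)
      }
    }
    clen <- max(ends) + 2500L + sample.int(500L, 1L)
    gr <- GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(start = starts, end = ends),
      strand = "+", locus_tag = tags, role = roles)
    GenomeInfoDb::seqlengths(gr) <- setNames(clen, contig)
    genomes[[ly]] <- gr
    pily <- tags[roles == "pilY1"]
    man_rows[[length(man_rows) + 1L]] <- data.frame(
      layout = ly, contig = contig, pilY1_tag = pily,
      expected_cluster_type = lay$cluster_type,
      expected_linkage = lay$linkage,
      expected_coupling = paste(expected_pairs, collapse = ";"),
      stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(outdir, paste0(ly, ".gff3"))
      attrs <- sprintf("ID=%s;locus_tag=%s%s", tags, tags,
                       ifelse(roles == "other", "",
                              paste0(";gene=", roles)))
      writeLines(c("##gff-version 3",
                   sprintf("##sequence-region %s 1 %d", contig, clen),
                   sprintf("%s\tpilyprofiler\tCDS\t%d\t%d\t.\t+\t0\t%s",
                           contig, starts, ends, attrs)), p)
      paths <- c(paths, p)
    }
  }
  out <- list(genomes = genomes, manifest = do.call(rbind, man_rows))
  if (!is.null(outdir)) out$gff_paths <- paths
  out
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a pair of coordinate models with a known rigid transform
#'
#' Model A is a self-avoiding random CA trace (3.8 A steps) with
#' `nDisulfides` planted cysteine bridges: bridge residues become CYS and
#' receive SG atoms exactly 2.05 A apart. Model B applies a seeded random
#' rotation and translation to A plus isotropic Gaussian noise of standard
#' deviation `noiseSigma` per coordinate.
#'
#' @param nRes Number of residues (at least 4).
#' @param noiseSigma Per-coordinate noise in Angstrom (default 0).
#' @param seed Integer seed (drives trace, transform and noise).
#' @param nDisulfides Planted bridges (default 3).
#' @return list: `modelA`, `modelB` ([StructureModel]), `manifest`
#'   (rotation, translation, sigma, disulfide pair data.frame).
#' @export
generateStructurePair <- function(nRes, noiseSigma = 0, seed = 1,
                                  nDisulfides = 3) {
  stopifnot(nRes >= 4, nDisulfides >= 0, 2 * nDisulfides <= nRes)
  set.seed(seed)
  step <- 3.8
  xyz <- matrix(0, nRes, 3)
  for (i in seq.int(2L, nRes)) {
    for (try in seq_len(200L)) {
      d <- stats::rnorm(3)
      cand <- xyz[i - 1L, ] + step * d / sqrt(sum(d^2))
      clash <- if (i > 2L)
        min(sqrt(rowSums(sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2,
                               cand)^2))) < 3.0 else FALSE
      if (!clash) { xyz[i, ] <- cand; break }
      if (try == 200L) stop("self-avoiding trace failed")
    }
  }
  res_name <- rep("ALA", nRes)
  atoms <- data.frame(res_index = seq_len(nRes), res_name = res_name,
                      atom_name = "CA", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  bridges <- data.frame(res_i = integer(), res_j = integer())
  if (nDisulfides > 0) {
    picks <- sample(nRes, 2L * nDisulfides)
    sg_rows <- list()
    for (b in seq_len(nDisulfides)) {
      i <- picks[2L * b - 1L]; j <- picks[2L * b]
      atoms$res_name[c(i, j)] <- "CYS"
      mid <- (xyz[i, ] + xyz[j, ]) / 2
      dir <- xyz[j, ] - xyz[i, ]
      dir <- dir / sqrt(sum(dir^2))
      # planted SG-SG distance: canonical 2.05 A, well clear of other pairs
      mid <- mid + 8 * b * c(1, 0, 0)  # separate bridges in space
      sg_rows[[length(sg_rows) + 1L]] <- data.frame(
        res_index = c(i, j), res_name = "CYS", atom_name = "SG",
        x = mid[1] + c(-1, 1) * 1.025 * dir[1],
        y = mid[2] + c(-1, 1) * 1.025 * dir[2],
        z = mid[3] + c(-1, 1) * 1.025 * dir[3],
        stringsAsFactors = FALSE)
      bridges <- rbind(bridges, data.frame(res_i = min(i, j),
                                           res_j = max(i, j)))
    }
    atoms <- rbind(atoms, do.call(rbind, sg_rows))
    atoms <- atoms[order(atoms$res_index,
                         atoms$atom_name != "CA"), , drop = FALSE]
  }
  R <- .random_rotation()
  tr <- stats::runif(3, -20, 20)
  co <- as.matrix(atoms[, c("x", "y", "z")])
  cb <- co %*% t(R) + matrix(tr, nrow(co), 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * nrow(co), sd = noiseSigma), ncol = 3)
  atomsB <- atoms
  atomsB[, c("x", "y", "z")] <- cb
  bridges <- bridges[order(bridges$res_i), , drop = FALSE]
  rownames(bridges) <- NULL
  list(modelA = StructureModel("synthA", atoms),
       modelB = StructureModel("synthB", atomsB),
       manifest = list(rotation = R, translation = tr,
                       sigma = noiseSigma, disulfides = bridges))
}
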