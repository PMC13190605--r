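.input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pilyInputError", "error")))
}

#' Pipeline configuration
#'
#' Collects input paths and the documented thresholds in one validated
#' list, echoed verbatim into `report.json`.
#'
#' @param fasta Protein FASTA path (required for profiling).
#' @param gff3 Character vector of GFF3 paths (optional; synteny stage).
#' @param domainTable Optional TSV of domain calls (`protein_id`, `name`,
#'   `start`, `end`).
#' @param structures Optional named character vector of PDB paths.
#' @param exemplars Optional named character vector (clade label per
#'   protein id) or a two-column TSV path (`protein_id`, `clade`).
#' @param motifCatalog Motif catalog path (default: shipped catalog).
#' @param gapOpen,gapExtend Alignment penalties (defaults 10, 0.5).
#' @param windowGenes Linkage gene window (default 5).
#' @param maxGapGenes,maxGapBp Cluster chaining thresholds (defaults 2,
#'   3000).
#' @param couplingGap Translational-coupling gap in bp (default 4).
#' @param cladeCeiling Nearest-exemplar distance ceiling for `unassigned`
#'   (default 75).
#' @param sgMax Disulfide SG-SG threshold in Angstrom (default 2.5).
#' @param seed Seed recorded in the report (default 1).
#' @param outdir Output directory (default `"pily_out"`).
#' @return A validated config list of class `pilyConfig`.
#' @export
pilyConfig <- function(fasta = NULL, gff3 = NULL, domainTable = NULL,
                       structures = NULL, exemplars = NULL,
                       motifCatalog = system.file("extdata", "motifs.tsv",
                                                  package = "pilyprofiler"),
                       gapOpen = 10, gapExtend = 0.5, windowGenes = 5,
                       maxGapGenes = 2, maxGapBp = 3000, couplingGap = 4,
                       cladeCeiling = 75, sgMax = 2.5, seed = 1,
                       outdir = "pily_out") {
  stopifnot(gapOpen >= gapExtend, gapExtend >= 0, windowGenes >= 1,
            maxGapGenes >= 0, maxGapBp >= 0, couplingGap >= 0,
            cladeCeiling > 0, sgMax > 0)
  cfg <- list(fasta = fasta, gff3 = gff3, domainTable = domainTable,
              structures = structures, exemplars = exemplars,
              motifCatalog = motifCatalog, gapOpen = gapOpen,
              gapExtend = gapExtend, windowGenes = windowGenes,
              maxGapGenes = maxGapGenes, maxGapBp = maxGapBp,
              couplingGap = couplingGap, cladeCeiling = cladeCeiling,
              sgMax = sgMax, seed = seed, outdir = outdir)
  class(cfg) <- "pilyConfig"
  cfg
}

.load_exemplars <- function(ex) {
  if (is.null(ex)) return(NULL)
  if (is.character(ex) && length(ex) == 1L && file.exists(ex)) {
    tab <- utils::read.delim(ex, stringsAsFactors = FALSE)
    return(setNames(tab$clade, tab$protein_id))
  }
  ex
}

#' Run the motif/cysteine profiling stage
#'
#' @param config A [pilyConfig()].
#' @return The feature-profile data.frame (also written to
#'   `feature_table.tsv` in `config$outdir`).
#' @export
runProfile <- function(config) {
  if (is.null(config$fasta) || !file.exists(config$fasta))
    .input_error("input FASTA missing: ", config$fasta)
  prot <- tryCatch(readFasta(config$fasta, domains = config$domainTable),
                   error = function(e) .input_error("bad FASTA: ",
                                                    conditionMessage(e)))
  profiles <- profileFeatures(prot, defaultMotifs(config$motifCatalog))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- profiles[order(profiles$protein_id), , drop = FALSE]
  utils::write.table(out, file.path(config$outdir, "feature_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profiles)
}

#' Run the full pipeline
#'
#' Stages in order: profile, identity matrix, NJ tree, clade assignment,
#' PCA, synteny, structures. Stages whose inputs are missing are skipped
#' with a notice and marked `"skipped"` in `report.json`; the report
#' summarizes counts (proteins, per clade, linked/unlinked, clusters by
#' type, disulfides per model) and echoes the configuration.
#'
#' @param config A [pilyConfig()].
#' @return list with every stage result plus the report list, invisibly.
#' @export
runFull <- function(config) {
  if (is.null(config$fasta) || !file.exists(config$fasta))
    .input_error("input FASTA missing: ", config$fasta)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "structures")])
  report$config$structures <- as.list(config$structures)

  prot <- readFasta(config$fasta, domains = config$domainTable)
  exemplars <- .load_exemplars(config$exemplars)
  rc <- refClades(prot)
  if (is.null(exemplars) && any(!is.na(rc)))
    exemplars <- rc[!is.na(rc)]
  profiles <- profileFeatures(prot, defaultMotifs(config$motifCatalog))
  report$n_proteins <- nrow(profiles)

  params <- alignParams(gapOpen = config$gapOpen,
                        gapExtend = config$gapExtend)
  tree <- NULL; assignments <- NULL; pca <- NULL; mats <- NULL
  if (length(prot) >= 3L) {
    mats <- identityMatrix(prot, params)
    tree <- njTree(mats$distance)
    ape::write.tree(tree, file.path(outdir, "tree.nwk"))
    if (!is.null(exemplars) && length(exemplars)) {
      assignments <- assignClades(tree, profiles, exemplars,
                                  mats$distance,
                                  ceiling = config$cladeCeiling)
      utils::write.table(assignments,
                         file.path(outdir, "assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- cladeSummary(assignments, profiles)
      utils::write.table(summ, file.path(outdir, "clade_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$n_per_clade <- as.list(table(assignments$clade))
    } else {
      message("no exemplars: clade assignment skipped")
      report$clades <- "skipped"
    }
    pca <- pcaIdentity(mats$identity, k = 2)
    ptab <- data.frame(protein_id = rownames(pca$coords),
                       PC1 = pca$coords[, 1], PC2 = pca$coords[, 2])
    if (!is.null(assignments))
      ptab$clade <- assignments$clade[match(ptab$protein_id,
                                            assignments$protein_id)]
    utils::write.table(ptab, file.path(outdir, "pca.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    message("fewer than 3 proteins: tree/PCA skipped")
    report$tree <- "skipped"
  }

  clusters <- NULL; linkage <- NULL
  if (!is.null(config$gff3) && length(config$gff3)) {
    feats <- lapply(config$gff3, readGff3)
    clusters <- do.call(rbind, lapply(feats, detectClusters,
                                      maxGapGenes = config$maxGapGenes,
                                      maxGapBp = config$maxGapBp,
                                      couplingGap = config$couplingGap))
    linkage <- do.call(rbind, lapply(feats, classifyLinkage,
                                     windowGenes = config$windowGenes))
    utils::write.table(clusters, file.path(outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(linkage, file.path(outdir, "linkage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$linkage <- as.list(table(linkage$status))
    report$clusters_by_type <- as.list(table(clusters$cluster_type))
  } else {
    message("no GFF3 inputs: synteny skipped")
    report$synteny <- "skipped"
  }

  disulfides <- NULL
  if (!is.null(config$structures) && length(config$structures)) {
    models <- lapply(config$structures, readPdb)
    disulfides <- lapply(models, detectDisulfides, sgMax = config$sgMax)
    dd <- do.call(rbind, lapply(names(disulfides), function(nm) {
      p <- disulfides[[nm]]$pairs
      if (!nrow(p)) return(NULL)
      cbind(model = nm, p)
    }))
    if (is.null(dd))
      dd <- data.frame(model = character(), res_i = integer(),
                       res_j = integer(), sg_distance = numeric())
    utils::write.table(dd, file.path(outdir, "disulfides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$n_disulfides <- lapply(disulfides, `[[`, "count")
  } else {
    message("no structures: structure stage skipped")
    report$structures <- "skipped"
  }

  writeOutputs(profiles, clusters, tree, assignments, linkage, outdir)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(proteins = prot, profiles = profiles, matrices = mats,
                 tree = tree, assignments = assignments, pca = pca,
                 clusters = clusters, linkage = linkage,
                 disulfides = disulfides, report = report))
}

#' Pairwise structure superposition over a pair list
#'
#' @param config A [pilyConfig()] with `structures` (named PDB paths).
#' @param pairs Two-column matrix/data.frame of model names to superpose.
#' @param reject Iterative outlier rejection (see [kabschSuperpose()]).
#' @return data.frame: `model_a`, `model_b`, `n_pairs`, `rmsd`, `mode`,
#'   `error` (NA on success; failed rows keep the pipeline running but the
#'   failure is recorded). Also written to `superpositions.tsv`.
#' @export
runCompare <- function(config, pairs, reject = FALSE) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  if (is.null(config$structures))
    .input_error("config$structures required for runCompare")
  mode <- if (reject) "outlier_reject" else "all_pairs"
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    na <- pairs[r, 1]; nb <- pairs[r, 2]
    tryCatch({
      ma <- readPdb(config$structures[[na]], modelId = na)
      mb <- readPdb(config$structures[[nb]], modelId = nb)
      sp <- modelRmsd(ma, mb, reject = reject)
      data.frame(model_a = na, model_b = nb, n_pairs = sp@nPairs,
                 rmsd = sp@rmsd, mode = mode, error = NA_character_)
    }, error = function(e)
      data.frame(model_a = na, model_b = nb, n_pairs = NA_integer_,
                 rmsd = NA_real_, mode = mode,
                 error = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, file.path(config$outdir, "superpositions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(!is.na(out$error)))
    warning("some model pairs failed: ",
            paste(out$model_a[!is.na(out$error)], collapse = ","))
  out
}
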