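#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace becomes the protein id.
#' Sequences are uppercased; the ambiguity letters U, B, Z and J are folded
#' to `X` with a warning (an `X` never satisfies a fixed motif residue).
#'
#' @param path Path to a FASTA text file.
#' @param organism Organism label applied to every record (recycled).
#' @param domains Optional domain-annotation table (data.frame or path to a
#'   TSV with columns `protein_id`, `name`, `start`, `end`).
#' @return A [ProteinSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "acd", "c"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, organism = NA_character_, domains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein id: ", ids[duplicated(ids)][1L])
  chr <- toupper(as.character(seqs))
  if (any(nchar(chr) == 0L))
    stop("empty sequence for id: ", ids[nchar(chr) == 0L][1L])
  if (any(grepl("[UBZJ]", chr))) {
    warning("non-standard residue letters U/B/Z/J folded to X")
    chr <- chartr("UBZJ", "XXXX", chr)
  }
  if (is.character(domains) && length(domains) == 1L)
    domains <- utils::read.delim(domains, stringsAsFactors = FALSE)
  ProteinSet(setNames(chr, ids), organism = organism, domains = domains)
}

#' Write a ProteinSet to FASTA
#'
#' @param x A [ProteinSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x@sequences, filepath = path, width = 70L)
  invisible(path)
}

.parse_role <- function(role_attr, gene_attr, n = max(length(role_attr),
                                                      length(gene_attr))) {
  role_attr <- rep_len(role_attr, n)
  gene_attr <- rep_len(gene_attr, n)
  pick <- ifelse(!is.na(role_attr) & nzchar(role_attr), role_attr,
                 ifelse(!is.na(gene_attr) & nzchar(gene_attr), gene_attr, ""))
  idx <- match(tolower(pick), tolower(.ROLE_LEVELS))
  out <- .ROLE_LEVELS[idx]
  out[is.na(out)] <- "other"
  out
}

#' Read gene features from GFF3
#'
#' Consumes rows of type `CDS` or `gene` (CDS preferred when both exist for
#' a locus_tag). The T4aP role is taken from a `role=` attribute, falling
#' back to `gene=`, matched case-insensitively against the role vocabulary
#' (pilY1, pilX, pilW, pilV, fimU, tfcP, pilA/B/T/C/M/N/O/P/Q), else
#' `other`. Coordinates stay 1-based inclusive; `##sequence-region` pragmas
#' populate the contig lengths (`seqlengths`).
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `locus_tag` and
#'   `role`, in file order.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  # contig lengths from ##sequence-region pragmas (not all writers are
  # seen by rtracklayer's seqinfo handling)
  prag <- grep("^##sequence-region", readLines(path, warn = FALSE),
               value = TRUE)
  if (length(prag)) {
    parts <- strsplit(trimws(prag), "\\s+")
    ctg <- vapply(parts, `[`, "", 2L)
    len <- as.integer(vapply(parts, `[`, "", 4L))
    keep <- ctg %in% GenomeInfoDb::seqlevels(gr)
    if (any(keep))
      GenomeInfoDb::seqlengths(gr)[ctg[keep]] <- len[keep]
  }
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  if (!length(gr)) stop("no CDS/gene rows in ", path)
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("unknown strand symbol in ", path,
         " (every CDS/gene row needs + or -)")
  mc <- S4Vectors::mcols(gr)
  lt <- if ("locus_tag" %in% colnames(mc)) as.character(mc$locus_tag)
        else if ("ID" %in% colnames(mc)) as.character(mc$ID)
        else NA_character_
  if (anyNA(lt)) stop("every CDS/gene row needs a locus_tag attribute")
  role <- .parse_role(
    if ("role" %in% colnames(mc)) as.character(mc$role) else NA_character_,
    if ("gene" %in% colnames(mc)) as.character(mc$gene) else NA_character_,
    n = length(gr))
  type <- as.character(mc$type)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(locus_tag = lt, role = role,
                                               type = type)
  # CDS preferred over gene for the same locus_tag
  keep <- rep(TRUE, length(gr))
  dup <- lt[duplicated(lt)]
  for (tag in unique(dup)) {
    idx <- which(lt == tag)
    if (any(type[idx] == "CDS")) keep[idx[type[idx] != "CDS"]] <- FALSE
    else keep[idx[-1L]] <- FALSE
  }
  gr <- gr[keep]
  if (anyDuplicated(gr$locus_tag))
    stop("duplicate locus_tag after CDS/gene reconciliation: ",
         gr$locus_tag[duplicated(gr$locus_tag)][1L])
  gr$type <- NULL
  gr
}

# fixed-column PDB ATOM reader; HETATM ignored, altloc '' or 'A' only
#' Read a coordinate model from PDB-format ATOM records
#'
#' Parses the fixed columns of ATOM records (atom name 13-16, altLoc 17,
#' residue name 18-20, residue number 23-26, x/y/z 31-54). HETATM records
#' are ignored; of alternate locations only blank or `A` are kept.
#'
#' @param path Path to a PDB text file.
#' @param modelId Model identifier; defaults to the file base name.
#' @return A [StructureModel].
#' @export
readPdb <- function(path, modelId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(modelId))
    modelId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  at <- lines[startsWith(lines, "ATOM")]
  if (!length(at)) stop("no ATOM records in ", path)
  altloc <- trimws(substr(at, 17L, 17L))
  at <- at[altloc %in% c("", "A")]
  if (!length(at)) stop("no ATOM records with blank/'A' altloc in ", path)
  atoms <- data.frame(
    res_index = as.integer(trimws(substr(at, 23L, 26L))),
    res_name = trimws(substr(at, 18L, 20L)),
    atom_name = trimws(substr(at, 13L, 16L)),
    x = as.numeric(substr(at, 31L, 38L)),
    y = as.numeric(substr(at, 39L, 46L)),
    z = as.numeric(substr(at, 47L, 54L)),
    stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in ", path)
  StructureModel(modelId, atoms)
}

#' Write a StructureModel to PDB format
#' @param model A [StructureModel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePdb <- function(model, path) {
  at <- model@atoms
  elem <- substr(at$atom_name, 1L, 1L)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom_name) < 4L, paste0(" ", at$atom_name), at$atom_name),
    at$res_name, at$res_index, at$x, at$y, at$z, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the deterministic pipeline output bundle
#'
#' Emits `feature_table.tsv` (one row per protein: length, cysteine count,
#' motif flags and 1-based hit positions, domain flags, clade, linkage),
#' `clusters.tsv`, `tree.nwk` and `report.json`. Row order is sorted by
#' protein id and column order is fixed, so identical inputs give
#' byte-identical files.
#'
#' @param profiles Feature-profile data.frame from [profileFeatures()].
#' @param clusters Cluster-call data.frame from [detectClusters()] (or NULL).
#' @param tree An `ape::phylo` tree from [njTree()] (or NULL; an empty tree
#'   is flagged in the report rather than written).
#' @param assignments Clade-assignment data.frame from [assignClades()]
#'   (or NULL).
#' @param linkage Linkage-call data.frame from [classifyLinkage()] (or NULL).
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
writeOutputs <- function(profiles, clusters = NULL, tree = NULL,
                         assignments = NULL, linkage = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  written <- character()
  tsv <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  ft <- profiles
  if (!is.null(assignments))
    ft$clade <- assignments$clade[match(ft$protein_id,
                                        assignments$protein_id)]
  if (!is.null(linkage))
    ft$linkage <- linkage$status[match(ft$protein_id, linkage$pilY1_tag)]
  ft <- ft[order(ft$protein_id), , drop = FALSE]
  tsv(ft, "feature_table.tsv")
  if (is.null(clusters))
    clusters <- data.frame(contig = character(), cluster_type = character(),
                           members = character(), pilY1_tags = character(),
                           coupling_pairs = character())
  tsv(clusters, "clusters.tsv")
  report <- list(n_proteins = nrow(profiles))
  if (!is.null(tree) && !is.null(tree$tip.label) && length(tree$tip.label)) {
    p <- file.path(outdir, "tree.nwk")
    ape::write.tree(tree, file = p)
    written <- c(written, p)
    report$tree <- "written"
  } else {
    report$tree <- "empty (not written)"
  }
  if (!is.null(assignments))
    report$n_per_clade <- as.list(table(assignments$clade))
  if (!is.null(linkage))
    report$linkage <- as.list(table(linkage$status))
  if (!is.null(clusters) && nrow(clusters))
    report$clusters_by_type <- as.list(table(clusters$cluster_type))
  p <- file.path(outdir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, p)
  invisible(written)
}
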