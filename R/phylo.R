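#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the classical Q criterion. Ties in the
#' Q minimum are broken deterministically by the lowest (i, j) index pair
#' in the current node ordering (nodes are ordered by creation: input ids
#' first, then internal nodes as they are produced). Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch, preserving the pair's summed length. The result is the standard
#' unrooted topology represented with a trifurcating root.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal and
#'   dimnames (e.g. `identityMatrix(...)$distance`).
#' @return An `ape::phylo` tree; leaf names are the matrix ids.
#' @export
njTree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 ids")
  if (is.null(rownames(d))) stop("distance matrix needs dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < -1e-12)) stop("distances must be finite and non-negative")
  ids <- rownames(d)
  # newick fragment per active node
  frag <- ids
  D <- d
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (i, j) pair among the minima
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                      fmt(lj), ")")
    k <- setdiff(seq_len(r), c(i, j))
    dnew <- 0.5 * (D[i, k] + D[j, k] - D[i, j])
    dnew <- pmax(dnew, 0)
    D <- rbind(cbind(D[k, k, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[k], newfrag)
  }
  # trifurcating root from the last three nodes
  l1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  l2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  l3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- paste0("(", frag[1], ":", fmt(ls[1]), ",", frag[2], ":",
                fmt(ls[2]), ",", frag[3], ":", fmt(ls[3]), ");")
  ape::read.tree(text = nwk)
}

# tip indices descended from each node, via one edge-table pass
.tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- vector("list", ntip + nnode)
  rec <- function(v) {
    if (v <= ntip) return(v)
    acc <- integer(0)
    for (ch in kids[[as.character(v)]]) acc <- c(acc, rec(ch))
    out[[v]] <<- acc
    acc
  }
  rec(ntip + 1L)
  for (v in seq_len(ntip)) out[[v]] <- v
  out
}

#' Assign clade labels from reference exemplars
#'
#' Each query is labeled with the clade whose exemplar-spanning subtree
#' (the clade exemplars' most recent common ancestor on the tree, read
#' rooted at its trifurcation) contains the query; when several contain it
#' the smallest is chosen. A clade whose exemplars straddle the root spans
#' every tip; such an uninformative subtree is reduced to the exemplars
#' themselves so membership is decided by nearest-exemplar distance
#' instead. A query contained in none, or in conflicting
#' (non-nested) subtrees, falls back to the nearest exemplar by matrix
#' distance; `unassigned` is used only for a conflicted query whose
#' nearest exemplar is farther than `ceiling`. Assignments are then checked
#' for feature consistency: DUF4114 expected for clades 1.1/1.2, vWFA for
#' 1.3/1.4b/1.5/1.6/1.7, neither required for 1.4a/1.4c; an inconsistent
#' assignment keeps its label but is flagged.
#'
#' @param tree `ape::phylo` from [njTree()].
#' @param profiles Feature profiles from [profileFeatures()].
#' @param exemplars Named character vector: clade label per exemplar
#'   protein id (at least one exemplar; ids must be tree tips).
#' @param distance Distance matrix used for nearest-exemplar fallback.
#' @param ceiling Distance ceiling for `unassigned` (default 75).
#' @return data.frame, one row per tip: `protein_id`, `clade`,
#'   `nearest_exemplar`, `nearest_distance`, `by_subtree` (logical),
#'   `feature_consistent` (logical).
#' @export
assignClades <- function(tree, profiles, exemplars, distance,
                         ceiling = 75) {
  if (!length(exemplars)) stop("no exemplars given")
  if (is.null(names(exemplars))) stop("exemplars must be named by protein id")
  missing <- setdiff(names(exemplars), tree$tip.label)
  if (length(missing))
    stop("exemplar(s) not in tree: ", paste(missing, collapse = ","))
  tips <- tree$tip.label
  tipsets <- .tips_under(tree)
  clades <- sort(unique(exemplars))
  clade_tipset <- list()
  for (cl in clades) {
    ex <- match(names(exemplars)[exemplars == cl], tips)
    if (length(ex) == 1L) {
      clade_tipset[[cl]] <- ex
    } else {
      mrca <- ape::getMRCA(tree, ex)
      ts <- tipsets[[mrca]]
      # a clade straddling the trifurcating root yields the whole tip set;
      # that subtree carries no information, so the clade falls back to
      # nearest-exemplar assignment
      clade_tipset[[cl]] <- if (length(ts) == length(tips)) ex else ts
    }
  }
  d <- as.matrix(distance)
  exn <- names(exemplars)
  rows <- lapply(seq_along(tips), function(t) {
    id <- tips[t]
    containing <- clades[vapply(clades, function(cl)
      t %in% clade_tipset[[cl]], TRUE)]
    # nearest exemplar (excluding self unless the query is the exemplar)
    dd <- d[id, exn]
    dd[exn == id] <- 0
    nearest <- exn[which.min(dd)]
    ndist <- min(dd)
    by_subtree <- FALSE
    if (id %in% exn) {
      clade <- unname(exemplars[id])
      by_subtree <- TRUE
    } else if (length(containing) == 0L) {
      clade <- unname(exemplars[nearest])
    } else {
      sizes <- vapply(containing, function(cl)
        length(clade_tipset[[cl]]), 1L)
      smallest <- containing[sizes == min(sizes)]
      nested <- all(vapply(containing, function(cl)
        all(clade_tipset[[smallest[1]]] %in% clade_tipset[[cl]]) ||
        all(clade_tipset[[cl]] %in% clade_tipset[[smallest[1]]]), TRUE))
      if (length(smallest) == 1L && nested) {
        clade <- smallest
        by_subtree <- TRUE
      } else if (ndist > ceiling) {
        clade <- "unassigned"
      } else {
        clade <- unname(exemplars[nearest])
      }
    }
    data.frame(protein_id = id, clade = clade, nearest_exemplar = nearest,
               nearest_distance = unname(ndist), by_subtree = by_subtree,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # feature-consistency check against the expected N-terminal domain
  expect_duf <- c("1.1", "1.2")
  expect_vwfa <- c("1.3", "1.4b", "1.5", "1.6", "1.7")
  pf <- profiles[match(out$protein_id, profiles$protein_id), , drop = FALSE]
  out$feature_consistent <- TRUE
  has <- !is.na(pf$protein_id)
  cl <- out$clade
  out$feature_consistent[has & cl %in% expect_duf] <-
    pf$DUF4114[has & cl %in% expect_duf] == 1L &
    pf$vWFA[has & cl %in% expect_duf] == 0L
  out$feature_consistent[has & cl %in% expect_vwfa] <-
    pf$vWFA[has & cl %in% expect_vwfa] == 1L &
    pf$DUF4114[has & cl %in% expect_vwfa] == 0L
  out
}

#' Per-clade feature summaries
#'
#' @param assignments data.frame from [assignClades()].
#' @param profiles data.frame from [profileFeatures()].
#' @return data.frame, one row per clade: `clade`, `n`, median/min/max of
#'   length and cysteine count, and the fraction of members carrying each
#'   motif. The median of an even-sized group is the mean of the two
#'   central values (`stats::median`).
#' @export
cladeSummary <- function(assignments, profiles) {
  pf <- profiles[match(assignments$protein_id, profiles$protein_id), ,
                 drop = FALSE]
  pf$clade <- assignments$clade
  motif_cols <- grep("^has_", colnames(pf), value = TRUE)
  rows <- lapply(split(pf, pf$clade), function(g) {
    row <- data.frame(clade = g$clade[1], n = nrow(g),
                      median_length = stats::median(g$length),
                      min_length = min(g$length),
                      max_length = max(g$length),
                      median_n_cys = stats::median(g$n_cys),
                      min_n_cys = min(g$n_cys),
                      max_n_cys = max(g$n_cys),
                      stringsAsFactors = FALSE)
    for (mc in motif_cols)
      row[[sub("^has_", "frac_", mc)]] <- mean(g[[mc]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$clade), , drop = FALSE]
}

#' PCA of the percent-identity matrix
#'
#' Rows of the identity matrix are the feature vectors; columns are
#' centered (not scaled) and the top-k principal components are returned.
#' Sign convention: each component is flipped so its largest-magnitude
#' loading is positive, making coordinates reproducible across platforms.
#'
#' @param identity Symmetric percent-identity matrix (diagonal 100).
#' @param k Number of components (default 2; must be < number of ids).
#' @return list: `coords` (n x k matrix, rows named by id), `explained`
#'   (variance fractions, length k), `loadings`.
#' @export
pcaIdentity <- function(identity, k = 2) {
  m <- as.matrix(identity)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 ids")
  if (k >= n) stop("k must be smaller than the number of ids")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  tot <- sum(pc$sdev^2)
  explained <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  rownames(coords) <- rownames(m)
  list(coords = coords, explained = explained, loadings = loadings)
}
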