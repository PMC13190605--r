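#' Pair atoms of two models by residue index
#'
#' Pairs the `atomName` atom (CA by default) of every residue index present
#' in both models, ascending by residue index.
#'
#' @param modelA,modelB [StructureModel] objects.
#' @param atomName Atom to pair (default `"CA"`).
#' @return list: `A`, `B` (n x 3 coordinate matrices), `res_index`,
#'   `n_pairs`, `unpaired_a`, `unpaired_b` (counts).
#' @export
pairAtoms <- function(modelA, modelB, atomName = "CA") {
  pick <- function(m) {
    at <- m@atoms[m@atoms$atom_name == atomName, , drop = FALSE]
    at <- at[!duplicated(at$res_index), , drop = FALSE]
    at[order(at$res_index), , drop = FALSE]
  }
  a <- pick(modelA)
  b <- pick(modelB)
  shared <- intersect(a$res_index, b$res_index)
  if (length(shared) < 3L)
    stop("fewer than 3 shared '", atomName,
         "' atoms; superposition underdetermined")
  ai <- a[match(shared, a$res_index), , drop = FALSE]
  bi <- b[match(shared, b$res_index), , drop = FALSE]
  un_a <- nrow(a) - length(shared)
  un_b <- nrow(b) - length(shared)
  if (un_a + un_b > 0)
    message(un_a + un_b, " unpaired '", atomName, "' atoms dropped")
  list(A = as.matrix(ai[, c("x", "y", "z")]),
       B = as.matrix(bi[, c("x", "y", "z")]),
       res_index = shared, n_pairs = length(shared),
       unpaired_a = un_a, unpaired_b = un_b)
}

.kabsch_fit <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(B0, A0))   # 3x3 covariance of B against A
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  fitted <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - fitted)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% t(R)),
       rmsd = rmsd, singular = sv$d)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body fit of paired coordinates: centroid alignment,
#' covariance SVD, reflection corrected by the determinant sign so the
#' rotation is proper. The returned transform maps B onto A
#' (`B %*% t(rotation) + translation`); RMSD is computed after applying it.
#' An optional iterative outlier-rejection mode re-fits after discarding
#' pairs deviating more than `cutoff` standard deviations (PyMOL-align-like
#' behavior); the default uses all pairs.
#'
#' @param A,B n x 3 coordinate matrices (or the list from [pairAtoms()] as
#'   `A`, in which case `B` is ignored).
#' @param reject Use iterative outlier rejection? Default FALSE.
#' @param cycles,cutoff Rejection cycles (default 5) and sigma cutoff
#'   (default 2).
#' @return A [Superposition].
#' @export
kabschSuperpose <- function(A, B = NULL, reject = FALSE, cycles = 5,
                            cutoff = 2.0) {
  if (is.list(A) && !is.null(A$A)) { B <- A$B; A <- A$A }
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == 3L, ncol(B) == 3L, nrow(A) == nrow(B))
  if (nrow(A) < 3L) stop("need at least 3 atom pairs")
  # collinearity check: second singular value of the centered cloud
  collinear <- function(M) {
    s <- svd(sweep(M, 2, colMeans(M)))$d
    s[2] < 1e-8 * max(s[1], 1)
  }
  if (collinear(A) || collinear(B))
    stop("degenerate (collinear) coordinates; rotation underdetermined")
  keep <- seq_len(nrow(A))
  fit <- .kabsch_fit(A, B)
  if (reject) {
    for (cy in seq_len(cycles)) {
      fitted <- sweep(B[keep, , drop = FALSE] %*% t(fit$rotation), 2,
                      -fit$translation)
      dev <- sqrt(rowSums((A[keep, , drop = FALSE] - fitted)^2))
      thr <- mean(dev) + cutoff * stats::sd(dev)
      drop <- dev > thr
      if (!any(drop) || sum(!drop) < 3L) break
      keep <- keep[!drop]
      fit <- .kabsch_fit(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    }
  }
  methods::new("Superposition", rotation = fit$rotation,
               translation = fit$translation, rmsd = fit$rmsd,
               nPairs = length(keep))
}

#' RMSD between two structure models
#'
#' Convenience wrapper: [pairAtoms()] then [kabschSuperpose()].
#'
#' @param modelA,modelB [StructureModel] objects.
#' @param atomName Atom used for pairing (default CA).
#' @param reject Iterative outlier rejection (see [kabschSuperpose()]).
#' @return A [Superposition].
#' @export
modelRmsd <- function(modelA, modelB, atomName = "CA", reject = FALSE) {
  kabschSuperpose(pairAtoms(modelA, modelB, atomName), reject = reject)
}

#' Geometric disulfide-bridge detection
#'
#' Candidate bridges are cysteine SG-SG pairs at most `sgMax` Angstrom
#' apart (canonical S-S bond is about 2.05 A). Greedy matching by
#' ascending distance ensures each cysteine joins at most one bridge.
#'
#' @param model A [StructureModel].
#' @param sgMax Maximum SG-SG distance in Angstrom (default 2.5).
#' @return list: `pairs` (data.frame `res_i`, `res_j` with `res_i < res_j`,
#'   `sg_distance`) and `count`.
#' @export
detectDisulfides <- function(model, sgMax = 2.5) {
  at <- model@atoms
  sg <- at[at$res_name == "CYS" & at$atom_name == "SG", , drop = FALSE]
  sg <- sg[!duplicated(sg$res_index), , drop = FALSE]
  empty <- data.frame(res_i = integer(), res_j = integer(),
                      sg_distance = numeric())
  if (nrow(sg) < 2L) return(list(pairs = empty, count = 0L))
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(dm) & dm <= sgMax, arr.ind = TRUE)
  if (!nrow(cand)) return(list(pairs = empty, count = 0L))
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    ri <- sg$res_index[i]; rj <- sg$res_index[j]
    rows[[length(rows) + 1L]] <- data.frame(
      res_i = min(ri, rj), res_j = max(ri, rj),
      sg_distance = dm[i, j])
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(pairs$res_i), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, count = nrow(pairs))
}
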