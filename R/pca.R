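#' Center a genotype matrix by row (locus) means
#'
#' Subtracts each locus's mean genotype across subjects. The stored row
#' means are reused when projecting external or haploid data onto the same
#' axes, so training and test data share one origin.
#'
#' @param X Numeric loci x subjects genotype matrix (minor-allele counts),
#'   or a `genotype_matrix` object from [collapse_genotypes()].
#' @return A `centered_genotypes` object: `Xc` (centered matrix), `row_means`,
#'   and the locus table when available.
#' @export
center_matrix <- function(X) {
  loci <- NULL
  if (is.list(X) && !is.null(X$X)) {
    loci <- X$loci
    X <- X$X
  }
  rm <- rowMeans(X)
  structure(list(Xc = X - rm, row_means = rm, loci = loci),
            class = "centered_genotypes")
}

#' Eigendecomposition of the subject-by-subject covariance matrix
#'
#' Forms C = t(Xc) %*% Xc (unscaled) and decomposes it. Eigenvalues are
#' returned in decreasing order; eigenvectors are sign-oriented so that each
#' one's largest-magnitude coordinate is positive, making the decomposition
#' deterministic. Eigenvalues below `tol` times the largest are treated as
#' null space and dropped; eigenvalues below `-tol` times the largest raise
#' an error since C is positive semi-definite.
#'
#' @param cg A `centered_genotypes` object.
#' @param k_max Optional cap on the number of components retained.
#' @param tol Relative null-space tolerance.
#' @param block_size Accumulate C over locus blocks of this many rows
#'   (identical result; lets genome-scale matrices stream through without
#'   a second full-size copy). Default: one pass over the whole matrix.
#' @return An `eigen_system`: `values`, `vectors` (orthonormal columns),
#'   `rank`, and `flipped` (which eigenvectors were sign-flipped).
#' @export
eigen_decompose <- function(cg, k_max = NULL, tol = 1e-9, block_size = NULL) {
  Xc <- cg$Xc
  if (any(!is.finite(Xc))) stop("non-finite entries in centered matrix")
  if (ncol(Xc) < 2) stop("need at least 2 subjects")
  if (is.null(block_size) || block_size >= nrow(Xc)) {
    C <- crossprod(Xc)
  } else {
    C <- matrix(0, ncol(Xc), ncol(Xc))
    for (a in seq(1, nrow(Xc), by = block_size)) {
      b <- min(a + block_size - 1, nrow(Xc))
      C <- C + crossprod(Xc[a:b, , drop = FALSE])
    }
  }
  es <- eigen(C, symmetric = TRUE)
  top <- max(es$values, 0)
  if (any(es$values < -tol * max(top, 1))) {
    stop("covariance matrix has a significantly negative eigenvalue")
  }
  keep <- if (top == 0) integer(0) else which(es$values > tol * top)
  if (length(keep) == 0) { # degenerate all-zero matrix: keep one null axis
    keep <- 1L
  }
  values <- pmax(es$values[keep], 0)
  vectors <- es$vectors[, keep, drop = FALSE]
  flipped <- logical(length(keep))
  for (k in seq_along(keep)) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) {
      vectors[, k] <- -vectors[, k]
      flipped[k] <- TRUE
    }
  }
  if (!is.null(k_max) && k_max < length(values)) {
    values <- values[seq_len(k_max)]
    vectors <- vectors[, seq_len(k_max), drop = FALSE]
    flipped <- flipped[seq_len(k_max)]
  }
  structure(list(values = values, vectors = vectors,
                 rank = length(values), flipped = flipped),
            class = "eigen_system")
}

#' Per-locus SVD loadings
#'
#' The loading of locus j on component k quantifies that locus's
#' contribution to the component. Evaluated as Xc %*% V, which equals the
#' product of the left singular vectors and singular values without ever
#' forming the loci-by-loci decomposition.
#'
#' @param cg A `centered_genotypes` object.
#' @param es An `eigen_system` from [eigen_decompose()].
#' @return Numeric loci x components loadings matrix.
#' @export
compute_loadings <- function(cg, es) {
  cg$Xc %*% es$vectors
}

#' Subject projections on the principal components
#'
#' Two algebraically identical routes are exposed: `"eigen"` scales the
#' eigenvectors by their eigenvalues, `"loadings"` multiplies the centered
#' data by the per-locus loadings. They agree to numerical tolerance and the
#' identity is exercised in the test suite.
#'
#' @param cg A `centered_genotypes` object.
#' @param es An `eigen_system` (required for route `"eigen"`).
#' @param loadings Loadings matrix (required for route `"loadings"`).
#' @param route `"eigen"` or `"loadings"`.
#' @return Numeric subjects x components projection matrix.
#' @export
project <- function(cg, es = NULL, loadings = NULL,
                    route = c("eigen", "loadings")) {
  route <- match.arg(route)
  if (route == "eigen") {
    if (is.null(es)) stop("route 'eigen' needs an eigen_system")
    sweep(es$vectors, 2, es$values, "*")
  } else {
    if (is.null(loadings)) loadings <- compute_loadings(cg, es)
    if (nrow(loadings) != nrow(cg$Xc)) stop("dimension mismatch")
    crossprod(cg$Xc, loadings)
  }
}

#' Partial projection over a subset of loci
#'
#' The projection of each subject restricted to loci in `subset`: the sum of
#' loading-weighted centered genotypes over those loci only. Linear in the
#' subset, so disjoint subsets add and the full set recovers the projection.
#'
#' @param cg A `centered_genotypes` object.
#' @param loadings Loadings matrix.
#' @param subset Integer locus indices (empty gives zeros).
#' @param k Component index.
#' @return Numeric vector, one value per subject.
#' @export
partial_projection <- function(cg, loadings, subset, k) {
  if (length(subset) == 0) return(numeric(ncol(cg$Xc)))
  if (any(subset < 1 | subset > nrow(cg$Xc))) stop("locus subset out of range")
  drop(crossprod(cg$Xc[subset, , drop = FALSE],
                 loadings[subset, k, drop = FALSE]))
}

#' Full PCA of a genotype matrix in one call
#'
#' Convenience wrapper chaining [center_matrix()], [eigen_decompose()],
#' [compute_loadings()] and [project()].
#'
#' @param X Genotype matrix or `genotype_matrix` object.
#' @param k_max Components to retain (default: full rank).
#' @return List with `centered`, `eigen`, `loadings`, `projections`.
#' @export
pca_genotypes <- function(X, k_max = NULL) {
  cg <- center_matrix(X)
  es <- eigen_decompose(cg, k_max = k_max)
  G <- compute_loadings(cg, es)
  list(centered = cg, eigen = es, loadings = G,
       projections = project(cg, es = es, loadings = G, route = "loadings"))
}
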