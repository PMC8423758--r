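#' Harmonize loci between a reference and an external cohort
#'
#' Intersects the two locus tables on (chromosome, position), drops loci
#' whose major/minor allele sequences disagree between the cohorts (these
#' cannot share an orientation), and assembles the joint genotype matrix of
#' reference plus external subjects over the surviving loci.
#'
#' @param ref A `genotype_matrix` (reference cohort).
#' @param ext A `genotype_matrix` (external cohort).
#' @return A `harmonized_joint`: `X` (joint matrix), `loci`, `is_ref`
#'   (logical per joint subject), `subjects`, `n_discordant`.
#' @export
harmonize_loci <- function(ref, ext) {
  key_ref <- paste(ref$loci$chrom, ref$loci$pos)
  key_ext <- paste(ext$loci$chrom, ext$loci$pos)
  i_ext <- match(key_ref, key_ext)
  shared <- which(!is.na(i_ext))
  if (length(shared) == 0) stop("no loci shared between the cohorts")
  j <- i_ext[shared]
  concordant <- ref$loci$major[shared] == ext$loci$major[j] &
    ref$loci$minor[shared] == ext$loci$minor[j]
  n_disc <- sum(!concordant)
  shared <- shared[concordant]
  j <- j[concordant]
  if (length(shared) == 0) stop("no concordant loci after allele matching")
  X <- cbind(ref$X[shared, , drop = FALSE], ext$X[j, , drop = FALSE])
  structure(list(X = X,
                 loci = ref$loci[shared, , drop = FALSE],
                 ref_rows = shared,
                 is_ref = rep(c(TRUE, FALSE), c(ncol(ref$X), ncol(ext$X))),
                 subjects = c(ref$subjects, ext$subjects),
                 n_discordant = n_disc),
            class = "harmonized_joint")
}

#' Approximate joint projections from reference-derived loadings
#'
#' Runs PCA on the reference subjects restricted to the harmonized loci,
#' then evaluates, for every joint subject, the loading-weighted sum of
#' joint-centered genotypes over the informative loci of each component —
#' an approximation to the joint-data PCA that needs no decomposition of
#' the joint matrix. The exact joint PCA is computed alongside for
#' comparison.
#'
#' @param hj A `harmonized_joint` from [harmonize_loci()].
#' @param k_max Number of components.
#' @param isets Optional list (by component) of informative-locus indices
#'   into the harmonized locus table; default: all harmonized loci.
#' @param center `"joint"` (default) centers with joint row means; `"ref"`
#'   centers with reference row means.
#' @return A `transfer_projection`: `transfer` (subjects x k), `joint`
#'   (joint-PCA projections), `is_ref`, plus the reference PCA in `ref_pca`.
#' @export
transfer_projection <- function(hj, k_max = 7, isets = NULL,
                                center = c("joint", "ref")) {
  center <- match.arg(center)
  ref_pca <- pca_genotypes(hj$X[, hj$is_ref, drop = FALSE], k_max = k_max)
  k_max <- min(k_max, ncol(ref_pca$loadings))
  cg_joint <- center_matrix(hj$X)
  if (center == "ref") {
    cg_joint$Xc <- hj$X - ref_pca$centered$row_means
    cg_joint$row_means <- ref_pca$centered$row_means
  }
  transfer <- matrix(NA_real_, ncol(hj$X), k_max)
  for (k in seq_len(k_max)) {
    idx <- if (is.null(isets)) seq_len(nrow(hj$X)) else isets[[k]]
    if (length(idx) == 0) {
      warning("empty informative set for component ", k)
      transfer[, k] <- 0
      next
    }
    transfer[, k] <- partial_projection(cg_joint, ref_pca$loadings, idx, k)
  }
  joint_pca <- pca_genotypes(hj$X, k_max = k_max)
  structure(list(transfer = transfer,
                 joint = joint_pca$projections[, seq_len(min(k_max, ncol(joint_pca$projections))), drop = FALSE],
                 is_ref = hj$is_ref,
                 ref_pca = ref_pca),
            class = "transfer_projection")
}

#' Match joint-PCA components to transferred components
#'
#' Nearby eigenvalues let components swap order between the joint
#' decomposition and the reference-derived approximation. Pairs are
#' assigned greedily by descending |r| over all subjects; signed
#' correlations are reported separately for reference and external
#' subjects. Pairs whose best |r| falls below `min_r` stay unmatched.
#'
#' @param tp A `transfer_projection`.
#' @param min_r Minimum |r| to accept a match (default 0.2).
#' @return Data frame: `pc_joint`, `pc_proxy`, `r_all`, `r_reference`,
#'   `r_external` (external column NA when there are no external subjects).
#' @export
match_pcs <- function(tp, min_r = 0.2) {
  kj <- ncol(tp$joint)
  kp <- ncol(tp$transfer)
  R <- matrix(NA_real_, kj, kp)
  for (a in seq_len(kj)) for (b in seq_len(kp)) {
    R[a, b] <- as.numeric(safe_cor(tp$joint[, a], tp$transfer[, b]))
  }
  avail_j <- seq_len(kj)
  avail_p <- seq_len(kp)
  rows <- list()
  while (length(avail_j) && length(avail_p)) {
    sub <- abs(R[avail_j, avail_p, drop = FALSE])
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- avail_j[best[1]]
    b <- avail_p[best[2]]
    if (abs(R[a, b]) < min_r) break
    r_ref <- as.numeric(safe_cor(tp$joint[tp$is_ref, a], tp$transfer[tp$is_ref, b]))
    r_ext <- if (any(!tp$is_ref)) {
      as.numeric(safe_cor(tp$joint[!tp$is_ref, a], tp$transfer[!tp$is_ref, b]))
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      pc_joint = a, pc_proxy = b, r_all = R[a, b],
      r_reference = r_ref, r_external = r_ext)
    avail_j <- setdiff(avail_j, a)
    avail_p <- setdiff(avail_p, b)
  }
  out <- do.call(rbind, rows)
  out[order(out$pc_joint), , drop = FALSE]
}
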