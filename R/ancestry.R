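#' Declare one decision of an ancestry hierarchy
#'
#' A decision separates a set of reference groups along one or more
#' components (each component contributes an independently trained tract
#' partition and an independent vote at inference time). Children refine a
#' group's intervals with a further decision, e.g. a root decision
#' African/non-African whose non-African child separates European from
#' native American.
#'
#' @param pcs Component indices used by this decision.
#' @param groups Named list: group label -> character vector of reference
#'   populations making up the group. Group order is the projection order
#'   along the decision's components.
#' @param children Optional named list: group label -> child decision.
#' @return An `ancestry_decision` object.
#' @export
ancestry_decision <- function(pcs, groups, children = NULL) {
  if (length(groups) < 2) stop("a decision needs at least 2 reference groups")
  if (length(pcs) < 1) stop("a decision needs at least 1 component")
  structure(list(pcs = pcs, groups = groups, children = children),
            class = "ancestry_decision")
}

# pooled within-group SD and minimal pairwise centroid margin of projection
# values grouped by `grp`
group_separation <- function(vals, grp) {
  mu <- tapply(vals, grp, mean)
  v <- tapply(vals, grp, stats::var)
  ng <- tapply(vals, grp, length)
  pooled <- sqrt(sum((ng - 1) * v) / max(sum(ng - 1), 1))
  d <- abs(outer(mu, mu, "-"))
  min_diff <- min(d[upper.tri(d)])
  list(centroids = mu, pooled_sd = pooled, min_diff = min_diff,
       z = if (pooled > 0) min_diff / pooled else if (min_diff > 0) Inf else 0)
}

#' Partition a genome into minimal ancestry-separating tracts
#'
#' Training phase of the tract deconvolution. Scanning each chromosome's
#' informative loci left to right, the current window grows until the
#' partial projections of the reference haplotypes separate every pair of
#' reference groups by at least `alpha` pooled within-group standard
#' deviations; the window is then closed as a tract and the scan continues.
#' A trailing window that never reaches separation merges into the previous
#' tract; a chromosome that never separates at all becomes a single tract
#' flagged low-confidence. Tract bp boundaries are midpoints between
#' flanking informative loci, extended to the chromosome ends.
#'
#' Haplotype projections use doubled alleles centered with the training row
#' means, so a haploid copy of a homozygote projects like its diploid
#' source.
#'
#' @param haps Loci x haplotypes reference allele matrix (0/1).
#' @param hap_groups Group label per haplotype column.
#' @param iset `informative_loci` data frame of the component (must carry
#'   `chrom` and `pos`).
#' @param gamma Full-length loading vector of the component.
#' @param row_means Training genotype row means (from [center_matrix()]).
#' @param alpha Required separation in pooled-SD units (default 3).
#' @param chrom_lengths Named chromosome lengths in bp (default: last
#'   informative position per chromosome, extended symmetrically).
#' @return A `tract_partition`: `tracts` data frame (chrom, start, end in
#'   0-based half-open bp, n_loci, z, low_confidence), with parallel lists
#'   `loci_idx`, `centroids`, `pooled_sd`, plus `gamma`, `row_means`,
#'   `groups` (level order) and `alpha`.
#' @export
partition_tracts <- function(haps, hap_groups, iset, gamma, row_means,
                             alpha = 3, chrom_lengths = NULL) {
  hap_groups <- as.character(hap_groups)
  if (length(unique(hap_groups)) < 2) stop("need >= 2 reference groups")
  if (min(table(hap_groups)) < 2) stop("every reference group needs >= 2 haplotypes")
  group_levels <- unique(hap_groups)
  ord <- order(iset$chrom, iset$pos)
  iset <- iset[ord, , drop = FALSE]
  chroms <- unique(iset$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(iset$pos, iset$chrom, max)
  }
  tracts <- list(); loci_idx <- list(); centroids <- list(); pooled <- list()
  for (ch in chroms) {
    sub <- iset[iset$chrom == ch, , drop = FALSE]
    idx <- sub$locus
    contrib <- (2 * haps[idx, , drop = FALSE] - row_means[idx]) * gamma[idx]
    cs <- rbind(0, apply(contrib, 2, cumsum))
    n_inf <- length(idx)
    H <- ncol(contrib)
    onehot <- outer(hap_groups, group_levels, "==") * 1
    ng <- colSums(onehot)
    pairs <- utils::combn(length(group_levels), 2)
    starts <- integer(0); ends <- integer(0)
    zs <- numeric(0); cents <- list(); sds <- numeric(0)
    # grow windows in vectorized chunks: evaluate the separation statistic
    # for a block of candidate window ends at once, take the first passing
    a <- 1L
    chunk <- 64L
    while (a <= n_inf) {
      i0 <- a
      hit <- NA_integer_
      while (is.na(hit) && i0 <= n_inf) {
        i1 <- min(i0 + chunk - 1L, n_inf)
        vals <- cs[(i0 + 1L):(i1 + 1L), , drop = FALSE] -
          matrix(cs[a, ], i1 - i0 + 1L, H, byrow = TRUE)
        sums <- vals %*% onehot
        sums2 <- (vals * vals) %*% onehot
        mu <- sweep(sums, 2, ng, "/")
        ssw <- rowSums(sums2 - sweep(sums^2, 2, ng, "/"))
        pooled_w <- sqrt(pmax(ssw, 0) / max(sum(ng - 1), 1))
        mind <- apply(abs(mu[, pairs[1, ], drop = FALSE] -
                            mu[, pairs[2, ], drop = FALSE]), 1, min)
        z <- ifelse(pooled_w > 0, mind / pooled_w, ifelse(mind > 0, Inf, 0))
        pass <- which(z >= alpha)
        if (length(pass)) {
          hit <- i0 + pass[1] - 1L
          row <- pass[1]
          starts <- c(starts, a); ends <- c(ends, hit)
          zs <- c(zs, z[row]); sds <- c(sds, pooled_w[row])
          cents[[length(cents) + 1L]] <- stats::setNames(mu[row, ], group_levels)
        } else {
          i0 <- i1 + 1L
        }
      }
      if (is.na(hit)) break
      a <- hit + 1L
    }
    low_conf <- FALSE
    if (length(starts) == 0) { # never separated: whole chromosome, flagged
      vals <- cs[n_inf + 1L, ] - cs[1L, ]
      sep <- group_separation(vals, hap_groups)
      starts <- 1L; ends <- n_inf; zs <- sep$z; sds <- sep$pooled_sd
      cents <- list(sep$centroids[group_levels])
      low_conf <- TRUE
    } else if (a <= n_inf) { # trailing window merges into the last tract
      last <- length(starts)
      ends[last] <- n_inf
      vals <- cs[n_inf + 1L, ] - cs[starts[last], ]
      sep <- group_separation(vals, hap_groups)
      zs[last] <- sep$z; sds[last] <- sep$pooled_sd
      cents[[last]] <- sep$centroids[group_levels]
    }
    # bp boundaries: midpoints between flanking informative loci
    pos <- sub$pos
    bounds <- if (length(starts) > 1) {
      floor((pos[ends[-length(ends)]] + pos[starts[-1]]) / 2)
    } else numeric(0)
    bp_start <- c(0, bounds)
    bp_end <- c(bounds, chrom_lengths[[ch]])
    tracts[[ch]] <- data.frame(chrom = ch, start = bp_start, end = bp_end,
                               n_loci = ends - starts + 1L, z = zs,
                               low_confidence = low_conf,
                               stringsAsFactors = FALSE)
    loci_idx <- c(loci_idx, lapply(seq_along(starts),
                                   function(t) idx[starts[t]:ends[t]]))
    centroids <- c(centroids, cents)
    pooled <- c(pooled, as.list(sds))
  }
  structure(list(tracts = do.call(rbind, tracts),
                 loci_idx = loci_idx, centroids = centroids,
                 pooled_sd = unlist(pooled),
                 gamma = gamma, row_means = row_means,
                 groups = group_levels, alpha = alpha,
                 chrom_lengths = chrom_lengths),
            class = "tract_partition")
}

#' Classify haplotypes on the tracts of a partition
#'
#' Test phase: each haplotype's partial projection on each tract (doubled
#' alleles, training centering) is assigned to the nearest reference-group
#' centroid. The score is the margin between the best and second-best
#' centroid distance in pooled-SD units. Haplotypes missing more than half
#' of a tract's loci are unassigned there; exact ties go to the
#' first-listed group under the relaxed criterion and to "unassigned"
#' under the stringent criterion.
#'
#' @param partition A `tract_partition`.
#' @param haps Loci x haplotypes test allele matrix (0/1, NA = missing).
#' @param criterion `"relaxed"` or `"stringent"` (tie handling).
#' @return List of matrices (tracts x haplotypes): `label`, `score`.
#' @export
classify_tracts <- function(partition, haps, criterion = c("relaxed", "stringent")) {
  criterion <- match.arg(criterion)
  n_tracts <- nrow(partition$tracts)
  H <- ncol(haps)
  label <- matrix(NA_character_, n_tracts, H)
  score <- matrix(NA_real_, n_tracts, H)
  for (t in seq_len(n_tracts)) {
    idx <- partition$loci_idx[[t]]
    contrib <- (2 * haps[idx, , drop = FALSE] - partition$row_means[idx]) *
      partition$gamma[idx]
    miss <- colMeans(is.na(contrib))
    vals <- colSums(contrib, na.rm = TRUE)
    cents <- partition$centroids[[t]]
    d <- abs(outer(vals, cents, "-"))
    best <- apply(d, 1, which.min)
    dsort <- t(apply(d, 1, sort))
    margin <- dsort[, 2] - dsort[, 1]
    sd_t <- partition$pooled_sd[t]
    sc <- if (sd_t > 0) margin / sd_t else ifelse(margin > 0, Inf, 0)
    lab <- names(cents)[best]
    tie <- margin == 0
    if (criterion == "stringent") lab[tie] <- "unassigned"
    lab[miss > 0.5] <- "unassigned"
    sc[miss > 0.5] <- 0
    label[t, ] <- lab
    score[t, ] <- sc
  }
  list(label = label, score = score)
}

#' Train a hierarchical ancestry model
#'
#' Walks an [ancestry_decision()] tree and trains, for every decision and
#' every component it uses, a minimal tract partition on the reference
#' haplotypes of that decision's populations.
#'
#' @param haps Loci x haplotypes reference allele matrix.
#' @param panel Reference panel (`subject`, `population`), subjects in
#'   column order (two haplotype columns per subject).
#' @param hierarchy Root [ancestry_decision()].
#' @param loadings Loadings matrix from the training PCA.
#' @param row_means Training genotype row means.
#' @param isets List of `informative_loci` data frames indexed by component.
#' @param alpha Separation requirement in pooled-SD units.
#' @param chrom_lengths Optional named chromosome lengths (bp).
#' @return An `ancestry_model` tree mirroring the hierarchy.
#' @export
train_ancestry <- function(haps, panel, hierarchy, loadings, row_means,
                           isets, alpha = 3, chrom_lengths = NULL) {
  hap_pop <- rep(panel$population, each = 2L)
  train_node <- function(decision) {
    pop2group <- stats::setNames(
      rep(names(decision$groups), lengths(decision$groups)),
      unlist(decision$groups))
    use <- hap_pop %in% names(pop2group)
    if (!any(use)) stop("no reference haplotypes for decision")
    grp <- pop2group[hap_pop[use]]
    partitions <- lapply(decision$pcs, function(pc) {
      partition_tracts(haps[, use, drop = FALSE], grp, isets[[pc]],
                       loadings[, pc], row_means, alpha = alpha,
                       chrom_lengths = chrom_lengths)
    })
    names(partitions) <- as.character(decision$pcs)
    children <- NULL
    if (!is.null(decision$children)) {
      children <- lapply(decision$children, train_node)
    }
    list(decision = decision, partitions = partitions, children = children)
  }
  structure(list(root = train_node(hierarchy)), class = "ancestry_model")
}

# labeled intervals of one haplotype for one decision node: intersect the
# per-component tract labelings, resolving disagreements per criterion
node_intervals <- function(node, hap_idx, cls_by_pc, criterion) {
  parts <- node$partitions
  chroms <- unique(unlist(lapply(parts, function(p) p$tracts$chrom)))
  out <- list()
  for (ch in chroms) {
    per_pc <- lapply(seq_along(parts), function(p) {
      tr <- parts[[p]]$tracts
      sel <- tr$chrom == ch
      data.frame(start = tr$start[sel], end = tr$end[sel],
                 label = cls_by_pc[[p]]$label[sel, hap_idx],
                 score = cls_by_pc[[p]]$score[sel, hap_idx],
                 stringsAsFactors = FALSE)
    })
    bounds <- sort(unique(unlist(lapply(per_pc, function(d) c(d$start, d$end)))))
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    lab <- character(length(st)); sc <- numeric(length(st))
    for (i in seq_along(st)) {
      mid <- (st[i] + en[i]) / 2
      votes_lab <- character(0); votes_sc <- numeric(0)
      for (d in per_pc) {
        j <- which(d$start <= mid & d$end > mid)
        if (length(j) == 1) {
          votes_lab <- c(votes_lab, d$label[j])
          votes_sc <- c(votes_sc, d$score[j])
        }
      }
      keep <- votes_lab != "unassigned"
      if (!any(keep)) {
        lab[i] <- "unassigned"; sc[i] <- 0
      } else if (criterion == "stringent") {
        ul <- unique(votes_lab[keep])
        if (length(ul) == 1 && sum(keep) == length(votes_lab)) {
          lab[i] <- ul; sc[i] <- min(votes_sc[keep])
        } else {
          lab[i] <- "unassigned"; sc[i] <- 0
        }
      } else {
        w <- which(keep)[which.max(votes_sc[keep])]
        lab[i] <- votes_lab[w]; sc[i] <- votes_sc[w]
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                            label = lab, score = sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Infer hierarchical ancestry tracts for test haplotypes
#'
#' Applies a trained model root-to-leaf. At each decision the per-component
#' tract labels of a haplotype are intersected into refinement intervals;
#' the relaxed criterion keeps the strongest-scoring label, the stringent
#' criterion requires unanimity across components and leaves disagreeing
#' intervals unassigned. A child decision only refines intervals that
#' carry its parent group's label, appending to the label path (e.g.
#' `nonAFR/EUR/SEU`).
#'
#' @param model An `ancestry_model` from [train_ancestry()].
#' @param haps Loci x haplotypes test allele matrix (two columns/subject).
#' @param subjects Subject id per diploid test individual.
#' @param criterion `"relaxed"` or `"stringent"`.
#' @return Data frame of tracts: `subject`, `haplotype` (0/1), `chrom`,
#'   `start`, `end` (0-based half-open bp), `path` (label path or
#'   "unassigned"), `label` (terminal path component), `score`,
#'   `criterion`. Tracts tile each haplotype.
#' @export
infer_ancestry <- function(model, haps, subjects,
                           criterion = c("relaxed", "stringent")) {
  criterion <- match.arg(criterion)
  H <- ncol(haps)
  classify_node <- function(node) {
    cls <- lapply(node$partitions, classify_tracts, haps = haps,
                  criterion = criterion)
    kids <- if (!is.null(node$children)) lapply(node$children, classify_node)
    list(cls = cls, kids = kids, node = node)
  }
  cache <- classify_node(model$root)
  resolve <- function(cached, hap_idx) {
    iv <- node_intervals(cached$node, hap_idx, cached$cls, criterion)
    iv$path <- iv$label
    if (is.null(cached$kids)) return(iv)
    # each child's genome-wide labeling is computed once per haplotype and
    # then intersected with every parent interval carrying its label
    child_iv <- lapply(cached$kids, resolve, hap_idx = hap_idx)
    pieces <- list()
    for (i in seq_len(nrow(iv))) {
      g <- iv$label[i]
      child <- child_iv[[g]]
      if (is.null(child)) {
        pieces[[length(pieces) + 1L]] <- iv[i, , drop = FALSE]
        next
      }
      sub <- child[child$chrom == iv$chrom[i] &
                     child$end > iv$start[i] & child$start < iv$end[i], ,
                   drop = FALSE]
      if (nrow(sub) == 0) {
        pieces[[length(pieces) + 1L]] <- iv[i, , drop = FALSE]
        next
      }
      sub$start <- pmax(sub$start, iv$start[i])
      sub$end <- pmin(sub$end, iv$end[i])
      sub$path <- paste(g, sub$path, sep = "/")
      pieces[[length(pieces) + 1L]] <- sub
    }
    do.call(rbind, pieces)
  }
  out <- list()
  for (h in seq_len(H)) {
    iv <- resolve(cache, h)
    iv$subject <- subjects[(h + 1L) %/% 2L]
    iv$haplotype <- (h + 1L) %% 2L
    out[[h]] <- iv
  }
  res <- do.call(rbind, out)
  res$label <- vapply(strsplit(res$path, "/", fixed = TRUE),
                      function(p) p[length(p)], "")
  res$criterion <- criterion
  rownames(res) <- NULL
  res[, c("subject", "haplotype", "chrom", "start", "end",
          "path", "label", "score", "criterion")]
}

# path component at a hierarchy level; "unassigned" anywhere wins, and a
# path shorter than the level reports its deepest component
path_at_level <- function(path, level) {
  vapply(strsplit(path, "/", fixed = TRUE), function(p) {
    if ("unassigned" %in% p) return("unassigned")
    p[min(level, length(p))]
  }, "")
}

#' Per-subject ancestry proportions from inferred tracts
#'
#' Aggregates tract lengths (bp, both haplotypes) into per-subject label
#' proportions at a chosen hierarchy level. Proportions over labels plus
#' "unassigned" sum to 1 for every subject.
#'
#' @param tracts Tract data frame from [infer_ancestry()].
#' @param level Hierarchy depth at which to report labels (default: deepest).
#' @return Data frame: one row per subject, one proportion column per label.
#' @export
summarize_proportions <- function(tracts, level = Inf) {
  lab <- path_at_level(tracts$path, level)
  len <- tracts$end - tracts$start
  tot <- tapply(len, tracts$subject, sum)
  agg <- tapply(len, list(tracts$subject, lab), sum, default = 0)
  frac <- sweep(agg, 1, tot[rownames(agg)], "/")
  data.frame(subject = rownames(frac), frac, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}
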