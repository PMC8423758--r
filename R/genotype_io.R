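#' Read and filter a phased VCF into a haplotype allele matrix
#'
#' Parses a VCF (plain or bgzipped) with vcfR and applies the three locus
#' filters: autosomal chromosome, biallelic SNV, and valid genotype calls in
#' more than `1 - max_missing` of the subjects. Allele coding is then
#' oriented so that 0 is the cohort-wide major allele: records whose ALT
#' allele is the majority among called haplotypes are swapped (an exact
#' 50/50 tie keeps REF as major).
#'
#' @param path Path to a VCF 4.x file with GT fields.
#' @param max_missing Maximum per-locus missing fraction (default 0.10).
#' @param autosomes Chromosome allow-list (default "1".."22", with or
#'   without a "chr" prefix).
#' @param require_phased Reject loci containing unphased ("/") genotypes.
#'   The default keeps them (the genotype-count path does not need phase);
#'   the haplotype-based local-ancestry path must set this to TRUE.
#' @return A `phased_genotypes` object: `alleles` (loci x 2m matrix of 0/1,
#'   NA missing), `loci` table (`chrom`, `pos`, `major`, `minor`,
#'   `call_rate`), `subjects`, and filter counters in `dropped`.
#' @export
read_vcf <- function(path, max_missing = 0.10,
                     autosomes = c(as.character(1:22), paste0("chr", 1:22)),
                     require_phased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  subjects <- colnames(gt)
  n0 <- nrow(fix)
  dropped <- c(non_autosome = 0L, multiallelic = 0L, low_call = 0L, unphased = 0L)

  keep_auto <- fix[, "CHROM"] %in% autosomes
  dropped["non_autosome"] <- sum(!keep_auto)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  dropped["multiallelic"] <- sum(keep_auto & !biallelic)
  keep <- keep_auto & biallelic
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  m <- length(subjects)
  n <- nrow(gt)
  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  phased_ok <- matrix(TRUE, n, m)
  if (n > 0) {
    gtv <- as.vector(gt)
    phased <- grepl("|", gtv, fixed = TRUE)
    parts <- matrix(NA_character_, length(gtv), 2)
    split2 <- strsplit(gtv, "[|/]")
    lens <- lengths(split2)
    ok <- !is.na(gtv) & lens == 2
    parts[ok, ] <- t(vapply(split2[ok], identity, character(2)))
    a1v <- suppressWarnings(as.integer(parts[, 1]))
    a2v <- suppressWarnings(as.integer(parts[, 2]))
    a1v[!a1v %in% c(0L, 1L)] <- NA_integer_
    a2v[!a2v %in% c(0L, 1L)] <- NA_integer_
    called <- !is.na(a1v) & !is.na(a2v)
    a1v[!called] <- NA_integer_
    a2v[!called] <- NA_integer_
    a1 <- matrix(a1v, n, m)
    a2 <- matrix(a2v, n, m)
    phased_ok <- matrix(phased | is.na(gtv), n, m)
  }
  call_rate <- rowMeans(!is.na(a1) & !is.na(a2))
  keep2 <- call_rate > 1 - max_missing
  dropped["low_call"] <- sum(!keep2)
  if (require_phased) {
    all_phased <- rowSums(!phased_ok) == 0
    dropped["unphased"] <- sum(keep2 & !all_phased)
    keep2 <- keep2 & all_phased
  }
  fix <- fix[keep2, , drop = FALSE]
  a1 <- a1[keep2, , drop = FALSE]
  a2 <- a2[keep2, , drop = FALSE]
  call_rate <- call_rate[keep2]

  # orient so that 0 = major allele in this cohort
  alt_freq <- rowMeans(cbind(a1, a2) == 1, na.rm = TRUE)
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  a1[flip, ] <- 1L - a1[flip, , drop = FALSE]
  a2[flip, ] <- 1L - a2[flip, , drop = FALSE]
  major <- ifelse(flip, fix[, "ALT"], fix[, "REF"])
  minor <- ifelse(flip, fix[, "REF"], fix[, "ALT"])

  alleles <- matrix(NA_integer_, nrow(a1), 2L * length(subjects))
  alleles[, seq(1, ncol(alleles), by = 2)] <- a1
  alleles[, seq(2, ncol(alleles), by = 2)] <- a2
  structure(list(
    alleles = alleles,
    loci = data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      major = as.character(major),
                      minor = as.character(minor),
                      call_rate = call_rate,
                      stringsAsFactors = FALSE),
    subjects = subjects,
    dropped = dropped),
    class = "phased_genotypes")
}

#' Collapse phased haplotypes into minor-allele counts
#'
#' Sums the two haplotype alleles of each subject into a genotype in
#' \{0, 1, 2\}. Missing calls are imputed to the locus mean genotype among
#' called subjects (equivalently they contribute zero after centering).
#'
#' @param pg A `phased_genotypes` object (or a `sim_cohort`).
#' @param impute Impute missing entries to the locus mean (default TRUE).
#' @return A `genotype_matrix`: `X` (loci x subjects), `loci`, `subjects`.
#' @export
collapse_genotypes <- function(pg, impute = TRUE) {
  alleles <- if (!is.null(pg$phased)) pg$phased else pg$alleles
  if (is.null(alleles) || nrow(alleles) == 0) stop("empty genotype data")
  a1 <- alleles[, seq(1, ncol(alleles), by = 2), drop = FALSE]
  a2 <- alleles[, seq(2, ncol(alleles), by = 2), drop = FALSE]
  X <- a1 + a2
  if (impute && anyNA(X)) {
    mu <- rowMeans(X, na.rm = TRUE)
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- mu[miss[, 1]]
  }
  structure(list(X = X, loci = pg$loci, subjects = pg$subjects),
            class = "genotype_matrix")
}

#' Read a subject panel table
#'
#' Reads a TSV with header columns `subject` (or `subject_id`) and
#' `population`. Duplicate rows with identical labels are accepted with a
#' warning; conflicting duplicates are an error. When `subjects` is given,
#' every subject must be present (missing ones are named in the error).
#' Optional groups merge populations under a super-group label.
#'
#' @param path Path to a panel TSV.
#' @param subjects Optional subject ids that must all be covered.
#' @param groups Optional named list, group label -> populations.
#' @return Data frame `subject`, `population` (and `group` when requested).
#' @export
read_panel <- function(path, subjects = NULL, groups = NULL) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("subject_id" %in% names(p)) names(p)[names(p) == "subject_id"] <- "subject"
  if (!all(c("subject", "population") %in% names(p))) {
    stop("panel must have 'subject' (or 'subject_id') and 'population' columns")
  }
  if (anyDuplicated(p$subject)) {
    lab <- tapply(p$population, p$subject, function(x) length(unique(x)))
    if (any(lab > 1)) {
      stop("conflicting population labels for subjects: ",
           paste(names(lab)[lab > 1], collapse = ", "))
    }
    warning("duplicate subject rows in panel; keeping first occurrence")
    p <- p[!duplicated(p$subject), , drop = FALSE]
  }
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, p$subject)
    if (length(missing)) {
      stop("subjects missing from panel: ", paste(missing, collapse = ", "))
    }
    p <- p[match(subjects, p$subject), , drop = FALSE]
  }
  if (!is.null(groups)) {
    pop2group <- stats::setNames(rep(names(groups), lengths(groups)),
                                 unlist(groups))
    p$group <- ifelse(p$population %in% names(pop2group),
                      pop2group[p$population], p$population)
  }
  rownames(p) <- NULL
  p
}

#' Write a phased cohort as a VCF
#'
#' Emits one record per locus with REF = major and ALT = minor allele and
#' phased GT fields ("a|b"). Written through vcfR; the file is
#' gzip-compressed (`.vcf.gz`) as vcfR's writer always compresses.
#'
#' @param pg A `phased_genotypes` object or `sim_cohort`.
#' @param path Output path (should end in `.vcf.gz`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(pg, path) {
  alleles <- if (!is.null(pg$phased)) pg$phased else pg$alleles
  loci <- pg$loci
  subjects <- pg$subjects
  a1 <- alleles[, seq(1, ncol(alleles), by = 2), drop = FALSE]
  a2 <- alleles[, seq(2, ncol(alleles), by = 2), drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow(a1), ncol(a1))
  gt[is.na(a1) | is.na(a2)] <- ".|."
  colnames(gt) <- subjects
  gt <- cbind(FORMAT = "GT", gt)
  fix <- cbind(CHROM = loci$chrom, POS = as.character(loci$pos),
               ID = ".", REF = loci$major, ALT = loci$minor,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", unique(loci$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Export a simulated cohort to disk
#'
#' Writes the phased VCF (`cohort.vcf.gz`), the subject panel TSV
#' (`panel.tsv`: subject_id, population) and the lineage truth as a
#' BED-like TSV (`truth.tsv`: chrom, 0-based half-open start/end in locus
#' units and in bp, haplotype 0/1, lineage label).
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort, file.path(dir, "cohort.vcf.gz"))
  utils::write.table(
    data.frame(subject_id = cohort$panel$subject,
               population = cohort$panel$population),
    file.path(dir, "panel.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- cohort$scenario$locus_spacing_bp
  if (is.null(sp)) sp <- 1L
  tr <- cohort$truth
  utils::write.table(
    data.frame(chrom = tr$chrom,
               start_locus = tr$start_locus - 1L, end_locus = tr$end_locus,
               start_bp = (tr$start_locus - 1L) * sp, end_bp = tr$end_locus * sp,
               subject = tr$subject, haplotype = tr$haplotype,
               lineage = tr$lineage),
    file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
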