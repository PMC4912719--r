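#' Construct a site table
#'
#' Per-site quality information plus per-sample raw genotype calls, the
#' input to genotype encoding and filtering. Calls are allele-pair strings
#' such as `"A/G"`; missing calls are `"./."`. Parental genotypes use the
#' same notation.
#'
#' @param info data.frame with columns `scaffold`, `pos` (1-based bp),
#'   `ref`, `alt`, `depth` (summed reads at the site), `QD`
#'   (quality-of-depth), `parent1`, `parent2` (parental genotype strings).
#' @param calls Character matrix (sites x samples) of genotype strings.
#' @param gq Numeric matrix (sites x samples) of genotype qualities.
#' @return An object of class `site_table`.
#' @export
site_table <- function(info, calls, gq) {
  req <- c("scaffold", "pos", "ref", "alt", "depth", "QD",
           "parent1", "parent2")
  stopifnot(all(req %in% names(info)),
            is.matrix(calls), is.matrix(gq),
            nrow(info) == nrow(calls), all(dim(calls) == dim(gq)))
  if (any(info$depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
  if (anyDuplicated(info[, c("scaffold", "pos")]))
    stop("one record per (scaffold, pos) required")
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("S", seq_len(ncol(calls)))
  colnames(gq) <- colnames(calls)
  structure(list(info = info, calls = calls, gq = gq,
                 samples = colnames(calls)), class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> %d sites x %d samples\n",
              nrow(x$info), length(x$samples)))
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Markers x individuals codes over the 4-letter alphabet:
#' `A` = homozygous reference allele, `B` = homozygous alternate allele,
#' `H` = heterozygous, `U` = missing.
#'
#' @param geno Character matrix (markers x samples) over \{A,H,B,U\}.
#' @param markers data.frame with columns `id`, `scaffold`, `pos`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers) {
  stopifnot(is.matrix(geno),
            all(c("id", "scaffold", "pos") %in% names(markers)),
            nrow(geno) == nrow(markers))
  bad <- setdiff(unique(as.vector(geno)), c("A", "H", "B", "U"))
  if (length(bad))
    stop("genotype codes outside {A,H,B,U}: ", paste(bad, collapse = ", "))
  if (nrow(geno) > 0) rownames(geno) <- markers$id
  if (is.null(colnames(geno)) && ncol(geno) > 0)
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  structure(list(geno = geno, markers = as.data.frame(markers),
                 samples = colnames(geno)), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d markers x %d individuals (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(x$geno == "U")))
  invisible(x)
}

split_gt <- function(gt) strsplit(gt, "[/|]")

#' Encode raw calls as A/H/B/U genotypes
#'
#' Applies the coding used for a codominant F2: `A` for a homozygous
#' reference genotype, `B` for a homozygous alternate genotype, `H` for the
#' heterozygote. Calls with genotype quality GQ below `gq_min` are replaced
#' by the missing value `U`, as are calls carrying an allele present in
#' neither parent (the per-site fraction of such third-allele calls is
#' recorded for the downstream filter).
#'
#' @param sites A [site_table()].
#' @param gq_min GQ threshold; calls with GQ < `gq_min` become `U`
#'   (default 20, i.e. GQ 19 is masked, GQ 20 kept).
#' @return A [genotype_matrix()] whose `markers` table carries the per-site
#'   `third_allele_frac` and `parents_het` columns; rows ordered by
#'   (scaffold, pos).
#' @export
encode_genotypes <- function(sites, gq_min = 20) {
  stopifnot(inherits(sites, "site_table"))
  info <- sites$info
  n_sites <- nrow(info)
  n_samp <- length(sites$samples)
  geno <- matrix("U", n_sites, n_samp,
                 dimnames = list(NULL, sites$samples))
  third_frac <- numeric(n_sites)
  parents_het <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    p1 <- split_gt(info$parent1[i])[[1]]
    p2 <- split_gt(info$parent2[i])[[1]]
    if (length(p1) != 2 || length(p2) != 2)
      stop("parental genotypes must be diploid at site ", i)
    parents_het[i] <- (p1[1] != p1[2]) && (p2[1] != p2[2])
    parental <- unique(c(p1, p2))
    ref <- info$ref[i]; alt <- info$alt[i]
    alleles <- split_gt(sites$calls[i, ])
    n_nonmiss <- 0L; n_third <- 0L
    for (j in seq_len(n_samp)) {
      al <- alleles[[j]]
      if (length(al) != 2 || any(al == ".")) next       # missing
      n_nonmiss <- n_nonmiss + 1L
      if (sites$gq[i, j] < gq_min) next                 # low confidence
      if (!all(al %in% parental)) { n_third <- n_third + 1L; next }
      code <- if (al[1] == ref && al[2] == ref) "A"
              else if (al[1] == alt && al[2] == alt) "B"
              else if (all(sort(al) == sort(c(ref, alt)))) "H"
              else NA_character_
      if (is.na(code)) { n_third <- n_third + 1L; next }
      geno[i, j] <- code
    }
    third_frac[i] <- if (n_nonmiss > 0) n_third / n_nonmiss else 0
  }
  markers <- data.frame(id = marker_ids(info), scaffold = info$scaffold,
                        pos = info$pos, depth = info$depth, QD = info$QD,
                        third_allele_frac = third_frac,
                        parents_het = parents_het,
                        stringsAsFactors = FALSE)
  ord <- order(markers$scaffold, markers$pos)
  genotype_matrix(geno[ord, , drop = FALSE], markers[ord, , drop = FALSE])
}

marker_ids <- function(info) {
  if (!is.null(info$id)) info$id else paste(info$scaffold, info$pos, sep = "_")
}

#' Site filter cascade
#'
#' Applies, in order, the two-stage SNP filter used for map construction,
#' recording the first-triggering rejection reason per site:
#' \enumerate{
#'   \item `qd` — quality-of-depth QD < `qd_min`;
#'   \item `cluster` — site belongs to a run of >= `cluster_size` sites
#'     spanning <= `cluster_window` bp on one scaffold;
#'   \item `depth` — summed site depth outside `[depth_min, depth_max]`
#'     (inclusive);
#'   \item `third_allele` — fraction of non-missing calls carrying a
#'     non-parental allele >= `third_allele_max`;
#'   \item `missing` — fraction of `U` calls >= `missing_max`;
#'   \item `parents_het` — both parents heterozygous.
#' }
#'
#' @param matrix A [genotype_matrix()] produced by [encode_genotypes()]
#'   (its `markers` table must carry `depth`, `QD`, `third_allele_frac`,
#'   `parents_het`).
#' @param qd_min,depth_min,depth_max,third_allele_max,missing_max,
#'   cluster_window,cluster_size Filter thresholds (defaults: QD >= 3,
#'   depth in \[40, 10000\], third-allele < 5\%, missing < 10\%, >= 3 sites
#'   within 10 bp).
#' @return A list with `retained` (a filtered [genotype_matrix()], rows in
#'   positional order) and `rejected` (data.frame `id`, `scaffold`, `pos`,
#'   `reason`).
#' @export
filter_sites <- function(matrix, qd_min = 3,
                         cluster_window = 10, cluster_size = 3,
                         depth_min = 40, depth_max = 10000,
                         third_allele_max = 0.05, missing_max = 0.10) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  mk <- matrix$markers
  if (nrow(mk) == 0L) {
    warning("empty site table; nothing to filter")
    return(list(retained = matrix,
                rejected = data.frame(id = character(), scaffold = character(),
                                      pos = integer(), reason = character())))
  }
  n <- nrow(mk)
  reason <- rep(NA_character_, n)

  # NA quality values (absent from the source file) fail open
  fail_qd <- !is.na(mk$QD) & mk$QD < qd_min
  reason[is.na(reason) & fail_qd] <- "qd"

  # cluster filter: any run of >= cluster_size sites within cluster_window bp
  in_cluster <- logical(n)
  for (sc in unique(mk$scaffold)) {
    idx <- which(mk$scaffold == sc)
    idx <- idx[order(mk$pos[idx])]
    pos <- mk$pos[idx]
    k <- cluster_size
    if (length(pos) >= k) {
      for (i in seq_len(length(pos) - k + 1L)) {
        if (pos[i + k - 1L] - pos[i] <= cluster_window)
          in_cluster[idx[i:(i + k - 1L)]] <- TRUE
      }
    }
  }
  reason[is.na(reason) & in_cluster] <- "cluster"

  fail_depth <- !is.na(mk$depth) & (mk$depth < depth_min | mk$depth > depth_max)
  reason[is.na(reason) & fail_depth] <- "depth"

  reason[is.na(reason) & mk$third_allele_frac >= third_allele_max] <-
    "third_allele"

  miss_frac <- rowMeans(matrix$geno == "U")
  reason[is.na(reason) & miss_frac >= missing_max] <- "missing"

  reason[is.na(reason) & mk$parents_het] <- "parents_het"

  keep <- is.na(reason)
  rejected <- data.frame(id = mk$id[!keep], scaffold = mk$scaffold[!keep],
                         pos = mk$pos[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  retained <- genotype_matrix(matrix$geno[keep, , drop = FALSE],
                              mk[keep, , drop = FALSE])
  ord <- order(retained$markers$scaffold, retained$markers$pos)
  retained <- genotype_matrix(retained$geno[ord, , drop = FALSE],
                              retained$markers[ord, , drop = FALSE])
  list(retained = retained, rejected = rejected)
}

#' Per-sample marker integrity
#'
#' Fraction of markers with a non-missing genotype call per sample; samples
#' with very low integrity (e.g. failed libraries) are candidates for
#' exclusion before map construction.
#'
#' @param matrix A [genotype_matrix()].
#' @return Named numeric vector in `[0, 1]`, one entry per sample.
#' @export
marker_integrity <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$geno) == 0L) stop("genotype matrix has zero markers")
  colMeans(matrix$geno != "U")
}
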