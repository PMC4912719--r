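#' Chi-square test of 1:2:1 segregation
#'
#' Goodness-of-fit of observed F2 codominant genotype counts against the
#' Mendelian 1:2:1 expectation, df = 2. Missing calls must be excluded
#' before counting.
#'
#' @param nA,nH,nB Observed counts of the three genotype classes.
#' @return List with `chi2` and `p`.
#' @examples
#' segregation_chi2(40, 40, 16)  # chi2 = 14.667
#' @export
segregation_chi2 <- function(nA, nH, nB) {
  if (any(c(nA, nH, nB) < 0)) stop("counts must be non-negative")
  n <- nA + nH + nB
  if (n == 0) stop("no informative genotype calls")
  e <- c(n / 4, n / 2, n / 4)
  chi2 <- sum((c(nA, nH, nB) - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Test every marker of a map for segregation distortion
#'
#' Applies [segregation_chi2()] to each mapped marker's genotype counts and
#' flags markers with p below `alpha`, then scans each linkage group for
#' segregation distortion regions (SDRs): maximal runs of >= `min_run`
#' consecutive distorted markers.
#'
#' @param map A `genetic_map`.
#' @param matrix The [genotype_matrix()] holding the mapped markers'
#'   genotype vectors (bin consensus matrix for a bin map).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param min_run Minimum SDR run length (default 4, i.e. more than three
#'   adjacent distorted loci).
#' @param bonferroni Apply a Bonferroni correction across mapped markers
#'   before flagging (default FALSE, matching raw-p practice).
#' @return List of class `distortion_scan`: `results` (data.frame `marker`,
#'   `LG`, `nA`, `nH`, `nB`, `chi2`, `p`, `distorted`) and `sdrs`
#'   (data.frame `LG`, `start_index`, `end_index`, `length`, `members`).
#' @export
test_distortion <- function(map, matrix, alpha = 0.05, min_run = 4,
                            bonferroni = FALSE) {
  stopifnot(inherits(map, "genetic_map"), inherits(matrix, "genotype_matrix"))
  rows <- list()
  for (lg in names(map$linkage_groups)) {
    for (id in map$linkage_groups[[lg]]$id) {
      v <- matrix$geno[match(id, matrix$markers$id), ]
      nA <- sum(v == "A"); nH <- sum(v == "H"); nB <- sum(v == "B")
      ct <- segregation_chi2(nA, nH, nB)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = id, LG = lg, nA = nA, nH = nH, nB = nB,
        chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  thr <- if (bonferroni) alpha / nrow(res) else alpha
  res$distorted <- res$p < thr
  sdr_rows <- list()
  for (lg in names(map$linkage_groups)) {
    flags <- res$distorted[res$LG == lg]
    ids <- res$marker[res$LG == lg]
    for (run in detect_sdrs(flags, min_run)) {
      sdr_rows[[length(sdr_rows) + 1L]] <- data.frame(
        LG = lg, start_index = run[1], end_index = run[2],
        length = run[2] - run[1] + 1L,
        members = paste(ids[run[1]:run[2]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  sdrs <- if (length(sdr_rows)) do.call(rbind, sdr_rows) else
    data.frame(LG = character(), start_index = integer(),
               end_index = integer(), length = integer(),
               members = character(), stringsAsFactors = FALSE)
  structure(list(results = res, sdrs = sdrs,
                 params = list(alpha = alpha, min_run = min_run,
                               bonferroni = bonferroni)),
            class = "distortion_scan")
}

#' Detect segregation distortion regions in an ordered flag vector
#'
#' Maximal runs of consecutive `TRUE` flags with length >= `min_run`.
#'
#' @param flags Logical (or 0/1) vector in linkage-group order.
#' @param min_run Minimum run length reported (default 4).
#' @return List of integer pairs `c(start, end)` (1-based inclusive
#'   indices), in order of occurrence.
#' @export
detect_sdrs <- function(flags, min_run = 4) {
  flags <- as.logical(flags)
  if (!length(flags)) return(list())
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  mapply(function(s, e) c(s, e), starts[keep], ends[keep], SIMPLIFY = FALSE)
}
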