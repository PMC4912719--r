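#' Collapse co-segregating SNPs into bin markers
#'
#' Greedy left-to-right scan per scaffold: a SNP joins the current bin iff
#' it lies on the same scaffold, within `window_bp` of the bin's first
#' member, and its genotype vector is compatible with the bin consensus
#' (equal at every individual where both calls are non-missing); otherwise
#' a new bin starts. The consensus call per individual is the unique non-U
#' value among members (else `U`). With `strict = TRUE` compatibility
#' requires exact vector equality instead.
#'
#' @param matrix A [genotype_matrix()] whose markers carry scaffold + bp.
#' @param window_bp Window anchored at the first bin member (default
#'   100000, i.e. 100 kb).
#' @param strict Require exact genotype-vector equality (default FALSE:
#'   missing-tolerant compatibility).
#' @return List of class `bin_set`: `bins` (data.frame `bin_id`,
#'   `scaffold`, `pos_min`, `pos_max`, `n_members`, `members`
#'   (comma-separated ids)), and `consensus` — a [genotype_matrix()] of bin
#'   consensus vectors positioned at each bin's first member.
#' @export
bin_cosegregating <- function(matrix, window_bp = 1e5, strict = FALSE) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  mk <- matrix$markers
  ord <- order(mk$scaffold, mk$pos)
  if (!identical(ord, seq_len(nrow(mk)))) {
    warning("markers not sorted by (scaffold, pos); sorting internally")
    matrix <- genotype_matrix(matrix$geno[ord, , drop = FALSE],
                              mk[ord, , drop = FALSE])
    mk <- matrix$markers
  }
  g <- matrix$geno
  bins <- list(); cons <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    bid <- sprintf("bin_%05d", length(bins) + 1L)
    bins[[bid]] <<- data.frame(
      bin_id = bid, scaffold = cur$scaffold,
      pos_min = min(cur$pos), pos_max = max(cur$pos),
      n_members = length(cur$members),
      members = paste(cur$members, collapse = ","),
      stringsAsFactors = FALSE)
    cons[[bid]] <<- cur$consensus
  }
  compatible <- function(consensus, v) {
    if (strict) return(all(consensus == v))
    both <- consensus != "U" & v != "U"
    all(consensus[both] == v[both])
  }
  for (i in seq_len(nrow(mk))) {
    v <- g[i, ]
    if (!is.null(cur) &&
        mk$scaffold[i] == cur$scaffold &&
        mk$pos[i] - cur$first_pos <= window_bp &&
        compatible(cur$consensus, v)) {
      newc <- cur$consensus
      fill <- newc == "U" & v != "U"
      newc[fill] <- v[fill]
      cur$consensus <- newc
      cur$members <- c(cur$members, mk$id[i])
      cur$pos <- c(cur$pos, mk$pos[i])
    } else {
      flush()
      cur <- list(scaffold = mk$scaffold[i], first_pos = mk$pos[i],
                  pos = mk$pos[i], members = mk$id[i], consensus = v)
    }
  }
  flush()
  bins_df <- do.call(rbind, bins)
  rownames(bins_df) <- NULL
  cons_mat <- do.call(rbind, cons)
  rownames(cons_mat) <- bins_df$bin_id
  consensus <- genotype_matrix(
    cons_mat, data.frame(id = bins_df$bin_id, scaffold = bins_df$scaffold,
                         pos = bins_df$pos_min, stringsAsFactors = FALSE))
  structure(list(bins = bins_df, consensus = consensus), class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set> %d bins from %d SNPs\n",
              nrow(x$bins), sum(x$bins$n_members)))
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-linkage-group map summary
#'
#' Summarises a genetic map built from bin markers: per LG the member-SNP
#' total, bin count, linkage distance (last cM position), mean distance
#' (linkage distance / bin count) and largest adjacent gap, plus a totals
#' row. Distances are rounded half-up to 1 decimal, means to 2 decimals.
#'
#' @param map A `genetic_map` whose markers are bin ids.
#' @param bins The `bin_set` the map was built from (supplies member
#'   counts); omit to treat every marker as its own bin.
#' @param distortion Optional result of [test_distortion()] adding
#'   distorted-marker and SDR counts per LG.
#' @return data.frame with one row per LG plus a `Total` row.
#' @export
map_summary <- function(map, bins = NULL, distortion = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (!length(map$linkage_groups)) stop("map has no linkage groups")
  members_of <- function(ids) {
    if (is.null(bins)) return(length(ids))
    sum(bins$bins$n_members[match(ids, bins$bins$bin_id)])
  }
  rows <- lapply(names(map$linkage_groups), function(lg) {
    tab <- map$linkage_groups[[lg]]
    if (!nrow(tab)) stop("empty linkage group ", lg)
    dist <- max(tab$cM)
    gaps <- diff(tab$cM)
    n_dist <- n_sdr <- NA_integer_
    if (!is.null(distortion)) {
      flags <- distortion$results$distorted[match(tab$id,
                                                  distortion$results$marker)]
      n_dist <- sum(flags, na.rm = TRUE)
      n_sdr <- sum(distortion$sdrs$LG == lg)
    }
    data.frame(LG = lg, snp_markers = members_of(tab$id),
               bin_markers = nrow(tab),
               linkage_distance_cM = round_half_up(dist, 1),
               mean_distance_cM = round_half_up(dist / nrow(tab), 2),
               largest_gap_cM = if (length(gaps))
                 round_half_up(max(gaps), 1) else 0,
               n_distorted = n_dist, n_sdr = n_sdr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total_dist <- sum(out$linkage_distance_cM)
  out <- rbind(out, data.frame(
    LG = "Total", snp_markers = sum(out$snp_markers),
    bin_markers = sum(out$bin_markers),
    linkage_distance_cM = round_half_up(total_dist, 1),
    mean_distance_cM = round_half_up(total_dist / sum(out$bin_markers), 2),
    largest_gap_cM = NA_real_,
    n_distorted = if (is.null(distortion)) NA_integer_ else
      sum(out$n_distorted),
    n_sdr = if (is.null(distortion)) NA_integer_ else sum(out$n_sdr),
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
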