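#' Kosambi map function
#'
#' Converts a recombination fraction to centimorgans under the Kosambi
#' mapping function, d = 25 * ln((1 + 2r) / (1 - 2r)).
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi(0.25)  # 27.465
#' @export
kosambi <- function(r) {
  if (any(r < 0)) stop("recombination fraction must be >= 0")
  if (any(r >= 0.5)) stop("Kosambi distance is infinite at r >= 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d_cM Map distance(s) in cM (>= 0).
#' @return Recombination fraction(s), r = (e^{4d} - 1) / (2 (e^{4d} + 1))
#'   with d in Morgans.
#' @export
kosambi_inverse <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be >= 0")
  d <- d_cM / 100
  0.5 * (exp(4 * d) - 1) / (exp(4 * d) + 1)
}

# Two-locus F2 genotype class probabilities for codominant markers.
# Classes indexed by (g1, g2) in {A,H,B}^2; gametes from each F1 parent are
# parental with prob (1-r)/2 each and recombinant with prob r/2 each.
f2_class_probs <- function(r) {
  pp <- (1 - r)^2 / 4      # A/A and B/B
  rr <- r^2 / 4            # A/B and B/A
  pr <- r * (1 - r) / 2    # the four single-heterozygote classes
  hh <- ((1 - r)^2 + r^2) / 2
  list(pp = pp, rr = rr, pr = pr, hh = hh)
}

# Vectorised EM for the F2 recombination fraction from 9-class counts.
# Count arguments may be scalars, vectors, or matrices of equal shape;
# naming: nAH = count of individuals with code A at locus 1, H at locus 2.
rf_em <- function(nAA, nAH, nAB, nHA, nHH, nHB, nBA, nBH, nBB,
                  tol = 1e-10, max_iter = 200) {
  n <- nAA + nAH + nAB + nHA + nHH + nHB + nBA + nBH + nBB
  R1 <- nAH + nHA + nHB + nBH      # classes carrying 1 recombinant gamete
  R2 <- nAB + nBA                  # classes carrying 2
  r <- ifelse(n > 0, 0.25, 0.5)
  for (it in seq_len(max_iter)) {
    w <- r^2 / ((1 - r)^2 + r^2)   # posterior P(2 recombinants | double het)
    r_new <- ifelse(n > 0, (R1 + 2 * R2 + 2 * nHH * w) / (2 * n), 0.5)
    r_new <- pmin(r_new, 0.5)
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  r
}

# Vectorised LOD = sum_c n_c * log10(P_c(r) / P_c(0.5)); exactly 0 at r=0.5.
rf_lod <- function(r, nAA, nAH, nAB, nHA, nHH, nHB, nBA, nBH, nBB) {
  p <- f2_class_probs(r)
  term <- function(count, prob, null) {
    out <- count * log10(prob / null)
    out[count == 0] <- 0
    out
  }
  lod <- term(nAA + nBB, p$pp, 1 / 16) +
    term(nAB + nBA, p$rr, 1 / 16) +
    term(nAH + nHA + nHB + nBH, p$pr, 1 / 8) +
    term(nHH, p$hh, 1 / 4)
  pmax(lod, 0)
}

#' Estimate the recombination fraction between two markers
#'
#' Maximum-likelihood estimate for a codominant F2 intercross via EM over
#' the nine two-locus genotype classes. Individuals missing (`U`) at either
#' marker are excluded. The double-heterozygote class mixes 0-recombinant
#' and 2-recombinant gamete configurations; the E-step assigns it 2
#' recombinant gametes with posterior r^2 / ((1-r)^2 + r^2). The LOD score
#' compares the likelihood at r-hat against independence (r = 0.5).
#'
#' @param g1,g2 Character vectors of codes over \{A,H,B,U\}, same length.
#' @return List with `r_hat` (in `[0, 0.5]`), `lod`, `n_informative`, and
#'   `flagged` (TRUE when fewer than 2 informative individuals).
#' @export
estimate_rf <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- g1 != "U" & g2 != "U"
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2L)
    return(list(r_hat = 0.5, lod = 0, n_informative = n, flagged = TRUE))
  cnt <- table(factor(g1, c("A", "H", "B")), factor(g2, c("A", "H", "B")))
  r <- rf_em(cnt[1, 1], cnt[1, 2], cnt[1, 3],
             cnt[2, 1], cnt[2, 2], cnt[2, 3],
             cnt[3, 1], cnt[3, 2], cnt[3, 3])
  lod <- rf_lod(r, cnt[1, 1], cnt[1, 2], cnt[1, 3],
                cnt[2, 1], cnt[2, 2], cnt[2, 3],
                cnt[3, 1], cnt[3, 2], cnt[3, 3])
  list(r_hat = as.numeric(r), lod = as.numeric(lod),
       n_informative = n, flagged = FALSE)
}

#' All pairwise recombination fractions and LOD scores
#'
#' Vectorised over marker pairs: the nine class counts for every pair are
#' obtained by indicator-matrix products, then the EM and LOD are run
#' element-wise on the full matrices.
#'
#' @param matrix A [genotype_matrix()].
#' @return List of symmetric matrices `r` (r-hat), `lod`, `n`
#'   (informative individuals), with marker ids as dimnames. Pairs with
#'   fewer than 2 informative individuals get r = 0.5, lod = 0.
#' @export
pairwise_linkage <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  g <- matrix$geno
  IA <- (g == "A") * 1; IH <- (g == "H") * 1; IB <- (g == "B") * 1
  nAA <- IA %*% t(IA); nAH <- IA %*% t(IH); nAB <- IA %*% t(IB)
  nHA <- IH %*% t(IA); nHH <- IH %*% t(IH); nHB <- IH %*% t(IB)
  nBA <- IB %*% t(IA); nBH <- IB %*% t(IH); nBB <- IB %*% t(IB)
  n <- nAA + nAH + nAB + nHA + nHH + nHB + nBA + nBH + nBB
  r <- rf_em(nAA, nAH, nAB, nHA, nHH, nHB, nBA, nBH, nBB)
  lod <- rf_lod(r, nAA, nAH, nAB, nHA, nHH, nHB, nBA, nBH, nBB)
  r[n < 2] <- 0.5
  lod[n < 2] <- 0
  diag(r) <- 0
  diag(lod) <- 0
  ids <- matrix$markers$id
  dimnames(r) <- dimnames(lod) <- dimnames(n) <- list(ids, ids)
  list(r = r, lod = lod, n = n)
}

#' Group markers by LOD threshold
#'
#' Single-linkage transitive closure: markers joined by any chain of pairs
#' with LOD >= the threshold share a linkage group. Groups are numbered by
#' descending marker count, ties by smallest member id.
#'
#' @param pairs Result of [pairwise_linkage()].
#' @param lod_threshold Grouping threshold (default 15).
#' @return Named list of character vectors of marker ids (names `LG1`,
#'   `LG2`, ...); singleton markers form their own groups.
#' @export
group_markers <- function(pairs, lod_threshold = 15) {
  if (lod_threshold <= 0) stop("lod_threshold must be positive")
  adj <- pairs$lod >= lod_threshold
  diag(adj) <- FALSE
  ids <- rownames(adj)
  n <- length(ids)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      if (length(nb)) stack <- c(stack, nb)
    }
  }
  groups <- split(ids, comp)
  sizes <- vapply(groups, length, integer(1))
  mins <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-sizes, mins)
  groups <- groups[ord]
  names(groups) <- paste0("LG", seq_along(groups))
  groups
}

sarf <- function(order_idx, r) {
  if (length(order_idx) < 2L) return(0)
  sum(r[cbind(order_idx[-length(order_idx)], order_idx[-1])])
}

#' Order the markers of one linkage group
#'
#' Heuristic minimisation of the sum of adjacent recombination fractions
#' (SARF): a greedy nearest-neighbour chain seeded at the pair with maximal
#' LOD, followed by 2-opt segment-reversal improvement to a local optimum.
#' Ties break to the smaller marker id; the returned orientation puts the
#' smaller of the two terminal marker ids first.
#'
#' @param group Character vector of marker ids.
#' @param pairs Result of [pairwise_linkage()] (must contain the group).
#' @return Character vector: the ordered marker ids.
#' @export
order_group <- function(group, pairs) {
  m <- length(group)
  if (m <= 2L) return(sort(group))
  r <- pairs$r[group, group, drop = FALSE]
  lod <- pairs$lod[group, group, drop = FALSE]
  # seed: maximal LOD pair, ties by smallest ids
  diag(lod) <- -Inf
  best <- which(lod == max(lod), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  chain <- as.integer(best[1, c(1, 2)])
  chain <- chain[order(group[chain])]
  left <- setdiff(seq_len(m), chain)
  while (length(left)) {
    head_r <- r[chain[1], left]
    tail_r <- r[chain[length(chain)], left]
    # candidate (end, marker) with minimal r; ties: tail end, then smaller id
    cand <- data.frame(idx = rep(left, 2),
                       end = rep(c("head", "tail"), each = length(left)),
                       r = c(head_r, tail_r))
    cand <- cand[order(cand$r, cand$end == "head", group[cand$idx]), ]
    pick <- cand[1, ]
    if (pick$end == "head") chain <- c(pick$idx, chain)
    else chain <- c(chain, pick$idx)
    left <- setdiff(left, pick$idx)
  }
  chain <- two_opt(chain, r)
  if (group[chain[1]] > group[chain[length(chain)]]) chain <- rev(chain)
  group[chain]
}

# 2-opt on the open path: reverse the segment [i..j] whenever it lowers the
# sum of adjacent r; best-improvement sweeps until a local optimum.
two_opt <- function(chain, r) {
  m <- length(chain)
  if (m < 3L) return(chain)
  repeat {
    best_delta <- -1e-12
    best_ij <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        delta <- 0
        if (i > 1L)
          delta <- delta + r[chain[i - 1L], chain[j]] - r[chain[i - 1L], chain[i]]
        if (j < m)
          delta <- delta + r[chain[i], chain[j + 1L]] - r[chain[j], chain[j + 1L]]
        if (delta < best_delta) { best_delta <- delta; best_ij <- c(i, j) }
      }
    }
    if (is.null(best_ij)) break
    i <- best_ij[1]; j <- best_ij[2]
    chain[i:j] <- chain[j:i]
  }
  chain
}

#' Count singletons along an ordered marker sequence
#'
#' A call (marker m, individual i) is a singleton when individual i's
#' nearest non-missing calls on both sides of m exist and both differ from
#' the call at m — a double-recombinant signature that is overwhelmingly a
#' genotyping error at dense marker spacing. Terminal markers (no flank on
#' one side) are never singletons.
#'
#' @param matrix A [genotype_matrix()] whose rows are in map order (one
#'   linkage group).
#' @return List with `per_marker` (named integer vector of singleton counts)
#'   and `calls` (data.frame `marker`, `sample` of singleton coordinates).
#' @export
count_singletons <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  g <- matrix$geno
  ids <- matrix$markers$id
  per_marker <- stats::setNames(integer(nrow(g)), ids)
  hits_m <- character(0); hits_s <- character(0)
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    nm <- which(col != "U")
    if (length(nm) < 3L) next
    v <- col[nm]
    k <- 2:(length(nm) - 1L)
    sing <- v[k] != v[k - 1L] & v[k] != v[k + 1L]
    if (any(sing)) {
      at <- nm[k[sing]]
      per_marker[at] <- per_marker[at] + 1L
      hits_m <- c(hits_m, ids[at])
      hits_s <- c(hits_s, rep(colnames(g)[j], length(at)))
    }
  }
  list(per_marker = per_marker,
       calls = data.frame(marker = hits_m, sample = hits_s,
                          stringsAsFactors = FALSE))
}

#' Build and refine a genetic map
#'
#' Full mapping stage: pairwise linkage, LOD grouping, per-group SARF
#' ordering, then iterative singleton-based refinement — markers with more
#' than `singleton_max` singletons are dropped, the affected groups
#' reordered and singletons recounted, until no marker exceeds the
#' threshold or the order stabilises. Map distances are Kosambi-converted
#' adjacent recombination fractions.
#'
#' @param matrix A filtered [genotype_matrix()].
#' @param lod_threshold LOD grouping threshold (default 15).
#' @param singleton_max Markers with singleton count strictly greater than
#'   this are excluded (default 5, i.e. 6 singletons trigger exclusion).
#' @param max_iter Refinement iteration guard (default 50).
#' @param min_group_size Groups smaller than this are reported as
#'   unplaced rather than mapped (default 2).
#' @return An object of class `genetic_map`: list of linkage groups, each a
#'   data.frame (`id`, `scaffold`, `pos`, `adj_r`, `cM`), plus `dropped`
#'   (marker ids removed by refinement), `unplaced`, and `provenance`.
#' @export
refine_map <- function(matrix, lod_threshold = 15, singleton_max = 5,
                       max_iter = 50, min_group_size = 2) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  pairs <- pairwise_linkage(matrix)
  groups <- group_markers(pairs, lod_threshold)
  small <- vapply(groups, length, integer(1)) < min_group_size
  unplaced <- unlist(groups[small], use.names = FALSE)
  groups <- groups[!small]
  names(groups) <- if (length(groups)) paste0("LG", seq_along(groups))
  orders <- lapply(groups, order_group, pairs = pairs)

  dropped <- character(0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    offenders <- character(0)
    for (gi in seq_along(orders)) {
      sub <- subset_markers(matrix, orders[[gi]])
      sing <- count_singletons(sub)
      offenders <- c(offenders,
                     names(sing$per_marker)[sing$per_marker > singleton_max])
    }
    if (!length(offenders)) break
    if (iters > max_iter) {
      warning("singleton refinement did not stabilise within ", max_iter,
              " iterations; returning last state")
      break
    }
    dropped <- c(dropped, offenders)
    prev_orders <- orders
    for (gi in seq_along(orders)) {
      remaining <- setdiff(orders[[gi]], offenders)
      if (length(remaining) < length(orders[[gi]])) {
        orders[[gi]] <- if (length(remaining) >= 2L)
          order_group(remaining, pairs) else remaining
      }
    }
    if (identical(orders, prev_orders)) break
  }
  orders <- orders[vapply(orders, length, integer(1)) >= 1L]

  lgs <- lapply(orders, function(ord) {
    mk <- matrix$markers[match(ord, matrix$markers$id), , drop = FALSE]
    adj_r <- c(NA_real_, pairs$r[cbind(ord[-length(ord)], ord[-1])])
    capped <- pmin(adj_r, 0.4999)
    cM <- cumsum(c(0, kosambi(capped[-1])))
    data.frame(id = ord, scaffold = mk$scaffold, pos = mk$pos,
               adj_r = adj_r, cM = cM, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  structure(list(
    linkage_groups = lgs, dropped = unique(dropped), unplaced = unplaced,
    provenance = list(lod_threshold = lod_threshold,
                      singleton_max = singleton_max, iterations = iters)),
    class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  n_mark <- sum(vapply(x$linkage_groups, nrow, integer(1)))
  len <- sum(vapply(x$linkage_groups, function(lg) max(lg$cM), numeric(1)))
  cat(sprintf("<genetic_map> %d linkage groups, %d markers, %.1f cM total\n",
              length(x$linkage_groups), n_mark, len))
  invisible(x)
}

#' Subset a genotype matrix by marker ids (in the given order)
#' @param matrix A [genotype_matrix()].
#' @param ids Marker ids; rows are returned in this order.
#' @return A [genotype_matrix()].
#' @export
subset_markers <- function(matrix, ids) {
  idx <- match(ids, matrix$markers$id)
  if (anyNA(idx)) stop("unknown marker id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  genotype_matrix(matrix$geno[idx, , drop = FALSE],
                  matrix$markers[idx, , drop = FALSE])
}
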