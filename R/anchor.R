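#' Anchor scaffolds onto linkage groups
#'
#' Assigns each scaffold carrying at least one mapped bin marker to the
#' linkage group holding the majority of its bins (ties to the LG of its
#' lowest-cM bin); the anchor position is the mean cM of its bins on that
#' LG. Scaffolds whose bins span multiple LGs are flagged as conflicts but
#' remain anchored to the majority LG.
#'
#' @param map A `genetic_map` of bin markers.
#' @param bins The `bin_set` behind the map (supplies bin -> scaffold).
#' @return data.frame of class `scaffold_anchors`: `scaffold`, `LG`,
#'   `position_cM`, `n_bins`, `conflict`, `orientation` (filled by
#'   [orient_scaffolds()], initially `"unoriented"`).
#' @export
anchor_scaffolds <- function(map, bins) {
  stopifnot(inherits(map, "genetic_map"))
  placed <- do.call(rbind, lapply(names(map$linkage_groups), function(lg) {
    tab <- map$linkage_groups[[lg]]
    data.frame(bin_id = tab$id, LG = lg, cM = tab$cM,
               stringsAsFactors = FALSE)
  }))
  placed$scaffold <- bins$bins$scaffold[match(placed$bin_id,
                                              bins$bins$bin_id)]
  rows <- lapply(split(placed, placed$scaffold), function(d) {
    counts <- table(d$LG)
    best <- names(counts)[counts == max(counts)]
    lg <- if (length(best) == 1L) best else d$LG[which.min(d$cM)]
    on_lg <- d[d$LG == lg, , drop = FALSE]
    data.frame(scaffold = d$scaffold[1], LG = lg,
               position_cM = mean(on_lg$cM), n_bins = nrow(on_lg),
               conflict = length(unique(d$LG)) > 1L,
               orientation = "unoriented", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$LG, out$position_cM, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scaffold_anchors", "data.frame")
  out
}

#' Orient anchored scaffolds by the trend of map distance
#'
#' For scaffolds with two or more bins at distinct cM positions the
#' orientation is the sign of the Spearman rank correlation between member
#' bin bp position (on the scaffold) and cM position: positive = forward,
#' negative = reverse, zero or all-tied = unoriented. Single-bin scaffolds
#' cannot be oriented.
#'
#' @param anchors Result of [anchor_scaffolds()].
#' @param map The `genetic_map` of bin markers.
#' @param bins The `bin_set` (supplies bin bp positions).
#' @return `anchors` with the `orientation` column filled.
#' @export
orient_scaffolds <- function(anchors, map, bins) {
  placed <- do.call(rbind, lapply(names(map$linkage_groups), function(lg) {
    tab <- map$linkage_groups[[lg]]
    data.frame(bin_id = tab$id, LG = lg, cM = tab$cM,
               stringsAsFactors = FALSE)
  }))
  placed$scaffold <- bins$bins$scaffold[match(placed$bin_id,
                                              bins$bins$bin_id)]
  placed$bp <- bins$bins$pos_min[match(placed$bin_id, bins$bins$bin_id)]
  for (i in seq_len(nrow(anchors))) {
    d <- placed[placed$scaffold == anchors$scaffold[i] &
                  placed$LG == anchors$LG[i], , drop = FALSE]
    if (nrow(d) < 2L || length(unique(d$cM)) < 2L ||
        length(unique(d$bp)) < 2L) next
    rho <- suppressWarnings(stats::cor(d$bp, d$cM, method = "spearman"))
    if (is.na(rho) || rho == 0) next
    anchors$orientation[i] <- if (rho > 0) "forward" else "reverse"
  }
  anchors
}

#' Build pseudochromosomes from anchored scaffolds
#'
#' Concatenates the scaffolds of each linkage group in anchor order
#' (reverse-oriented scaffolds reverse-complemented; unoriented scaffolds
#' emitted in source orientation), separated by fixed-length N gaps, and
#' computes per-chromosome statistics: total length (sum of scaffold
#' lengths, excluding gap padding), effective length (total minus N bases
#' within scaffolds), linkage distance, and cM/Mb.
#'
#' @param anchors Result of [orient_scaffolds()].
#' @param genome Named sequences ([Biostrings::DNAStringSet] or named
#'   character vector) containing every anchored scaffold.
#' @param map The `genetic_map` (supplies per-LG linkage distances).
#' @param gap_n Inter-scaffold gap length in N (default 100).
#' @return List of class `pseudochromosome_set`: `sequences`
#'   (DNAStringSet, one per LG), `agp` (data.frame in AGP v2.0 layout),
#'   `summary` (per-chromosome statistics with totals row).
#' @export
build_pseudochromosomes <- function(anchors, genome, map, gap_n = 100) {
  genome <- as_dnastringset(genome)
  if (anyDuplicated(anchors$scaffold))
    stop("duplicate scaffold assignment")
  missing <- setdiff(anchors$scaffold, names(genome))
  if (length(missing))
    stop("scaffolds absent from genome: ", paste(missing, collapse = ", "))
  seqs <- list(); agp <- list(); summ <- list()
  for (lg in unique(anchors$LG)) {
    a <- anchors[anchors$LG == lg, , drop = FALSE]
    chr_name <- sub("^LG", "chr", lg)
    parts <- character(nrow(a))
    pos <- 0L; part_no <- 0L
    for (k in seq_len(nrow(a))) {
      sc <- a$scaffold[k]
      s <- genome[[sc]]
      if (a$orientation[k] == "reverse")
        s <- Biostrings::reverseComplement(s)
      if (k > 1L && gap_n > 0L) {
        part_no <- part_no + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = chr_name, object_beg = pos + 1L, object_end = pos + gap_n,
          part_number = part_no, component_type = "N",
          component_id = gap_n, component_beg = "scaffold",
          component_end = "yes", orientation = "map",
          stringsAsFactors = FALSE)
        pos <- pos + gap_n
      }
      part_no <- part_no + 1L
      w <- length(s)
      agp[[length(agp) + 1L]] <- data.frame(
        object = chr_name, object_beg = pos + 1L, object_end = pos + w,
        part_number = part_no, component_type = "W",
        component_id = sc, component_beg = 1L, component_end = w,
        orientation = switch(a$orientation[k], forward = "+",
                             reverse = "-", unoriented = "?"),
        stringsAsFactors = FALSE)
      parts[k] <- as.character(s)
      pos <- pos + w
    }
    seqs[[chr_name]] <- paste(parts,
                              collapse = strrep("N", gap_n))
    sc_lens <- Biostrings::width(genome[a$scaffold])
    n_within <- sum(vapply(a$scaffold, function(sc)
      sum(Biostrings::alphabetFrequency(genome[[sc]])[["N"]]), numeric(1)))
    total <- sum(as.numeric(sc_lens))
    dist_cM <- max(map$linkage_groups[[lg]]$cM)
    summ[[chr_name]] <- data.frame(
      chromosome = chr_name, n_scaffolds = nrow(a), total_length_bp = total,
      linkage_distance_cM = round_half_up(dist_cM, 1),
      cM_per_Mb = round_half_up(dist_cM / (total / 1e6), 2),
      effective_length_bp = total - n_within,
      n_oriented = sum(a$orientation != "unoriented"),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  tot_len <- sum(summary$total_length_bp)
  tot_cM <- sum(summary$linkage_distance_cM)
  summary <- rbind(summary, data.frame(
    chromosome = "Total", n_scaffolds = sum(summary$n_scaffolds),
    total_length_bp = tot_len,
    linkage_distance_cM = round_half_up(tot_cM, 1),
    cM_per_Mb = round_half_up(tot_cM / (tot_len / 1e6), 2),
    effective_length_bp = sum(summary$effective_length_bp),
    n_oriented = sum(summary$n_oriented), stringsAsFactors = FALSE))
  rownames(summary) <- NULL
  structure(list(sequences = Biostrings::DNAStringSet(unlist(seqs)),
                 agp = do.call(rbind, agp), summary = summary),
            class = "pseudochromosome_set")
}

#' Write an AGP v2.0 file
#'
#' Component lines use type `W` with 1-based inclusive coordinates; gap
#' lines use type `N`, gap type `scaffold`, linkage `yes`, evidence `map`.
#'
#' @param pcs A `pseudochromosome_set`.
#' @param path Output path.
#' @export
write_agp <- function(pcs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  utils::write.table(pcs$agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rebuild pseudochromosome sequences from an AGP file
#'
#' Reconstructs each object by concatenating components (reverse
#' complemented for `-` orientation) and N runs, for round-trip
#' verification against the emitted FASTA.
#'
#' @param path AGP v2.0 file written by [write_agp()].
#' @param genome Scaffold sequences (DNAStringSet or named character).
#' @return [Biostrings::DNAStringSet] of reconstructed objects.
#' @export
read_agp_assemble <- function(path, genome) {
  genome <- as_dnastringset(genome)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  objs <- list()
  for (x in f) {
    obj <- x[1]
    if (!obj %in% names(objs)) objs[[obj]] <- character()
    if (x[5] == "N") {
      objs[[obj]] <- c(objs[[obj]], strrep("N", as.integer(x[6])))
    } else {
      s <- genome[[x[6]]]
      s <- Biostrings::subseq(s, as.integer(x[7]), as.integer(x[8]))
      if (x[9] == "-") s <- Biostrings::reverseComplement(s)
      objs[[obj]] <- c(objs[[obj]], as.character(s))
    }
  }
  Biostrings::DNAStringSet(vapply(objs, paste, "", collapse = ""))
}
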