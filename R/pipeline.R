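#' Pipeline configuration
#'
#' Aggregates every stage parameter with defaults matching the mapping
#' protocol: size window 250-500 bp, QD >= 3, GQ >= 20, site depth in
#' [40, 10000], third-allele < 5%, missing < 10%, LOD threshold 15,
#' singleton maximum 5, 100 kb bin window, alpha 0.05, SDR minimum run 4,
#' 100 N inter-scaffold gap. Unknown keys are rejected.
#'
#' @param ... Overrides for any default parameter.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    enzymes = c("EcoRI", "MspI"), min_len = 250, max_len = 500,
    ends_mode = "mixed",
    gq_min = 20, qd_min = 3, cluster_window = 10, cluster_size = 3,
    depth_min = 40, depth_max = 10000,
    third_allele_max = 0.05, missing_max = 0.10,
    lod_threshold = 15, singleton_max = 5, min_group_size = 2,
    bin_window = 1e5, alpha = 0.05, min_sdr_run = 4,
    gap_n = 100, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON document of parameter overrides.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full mapping pipeline
#'
#' Executes encode + filter -> map -> bin -> distortion scan -> anchor on a
#' site table, optionally writing every intermediate artifact and a
#' structured JSON run report (parameters and per-stage counts) to an
#' output directory. Counts satisfy conservation at every stage
#' (in = retained + rejected).
#'
#' @param sites A [site_table()] (e.g. from [simulate_f2()],
#'   [read_site_tsv()] or [read_vcf_subset()]).
#' @param genome Scaffold sequences for the anchoring stage
#'   (DNAStringSet or named character), or NULL to skip
#'   pseudochromosome construction.
#' @param config A [pipeline_config()].
#' @param outdir Output directory for artifacts, or NULL for in-memory
#'   results only.
#' @return List of class `pipeline_result`: `matrix` (filtered genotype
#'   matrix), `rejected`, `map` (bin-level genetic map), `bins`,
#'   `distortion`, `anchors`, `pseudochromosomes` (or NULL), `summary`
#'   (Table-2-style per-LG summary), `log` (per-stage counts).
#' @export
run_pipeline <- function(sites, genome = NULL, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(sites, "site_table"),
            inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, fun) if (!is.null(outdir))
    fun(file.path(outdir, name))
  log <- list(sites_in = nrow(sites$info))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # encode + filter
  filt <- run_stage("filter", {
    enc <- encode_genotypes(sites, gq_min = config$gq_min)
    filter_sites(enc, qd_min = config$qd_min,
                 cluster_window = config$cluster_window,
                 cluster_size = config$cluster_size,
                 depth_min = config$depth_min, depth_max = config$depth_max,
                 third_allele_max = config$third_allele_max,
                 missing_max = config$missing_max)
  })
  log$markers_retained <- nrow(filt$retained$geno)
  log$rejected_by_reason <- as.list(table(filt$rejected$reason))
  emit("markers.tsv", function(p) write_genotype_tsv(filt$retained, p))
  emit("rejected.tsv", function(p)
    utils::write.table(filt$rejected, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  # map the SNPs, then bin and rebuild the map from bin consensus vectors
  snp_map <- run_stage("map", refine_map(
    filt$retained, lod_threshold = config$lod_threshold,
    singleton_max = config$singleton_max,
    min_group_size = config$min_group_size))
  log$markers_grouped <- sum(vapply(snp_map$linkage_groups, nrow, integer(1)))
  log$markers_dropped_singleton <- length(snp_map$dropped)
  log$markers_unplaced <- length(snp_map$unplaced)
  log$n_linkage_groups <- length(snp_map$linkage_groups)
  emit("snp_map.tsv", function(p) write_map_tsv(snp_map, p))

  binstage <- run_stage("bin", {
    mapped_ids <- unlist(lapply(snp_map$linkage_groups, function(x) x$id),
                         use.names = FALSE)
    mapped <- subset_markers(filt$retained, mapped_ids)
    ord <- order(mapped$markers$scaffold, mapped$markers$pos)
    mapped <- genotype_matrix(mapped$geno[ord, , drop = FALSE],
                              mapped$markers[ord, , drop = FALSE])
    bins <- bin_cosegregating(mapped, window_bp = config$bin_window)
    bin_map <- refine_map(bins$consensus,
                          lod_threshold = config$lod_threshold,
                          singleton_max = config$singleton_max,
                          min_group_size = config$min_group_size)
    list(bins = bins, map = bin_map)
  })
  log$n_bins <- nrow(binstage$bins$bins)
  emit("bins.tsv", function(p)
    utils::write.table(binstage$bins$bins, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("bin_map.tsv", function(p) write_map_tsv(binstage$map, p))

  dist <- run_stage("distort", test_distortion(
    binstage$map, binstage$bins$consensus, alpha = config$alpha,
    min_run = config$min_sdr_run))
  log$n_distorted <- sum(dist$results$distorted)
  log$n_sdrs <- nrow(dist$sdrs)
  emit("distortion.tsv", function(p)
    utils::write.table(dist$results, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("sdrs.tsv", function(p)
    utils::write.table(dist$sdrs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  anchors <- run_stage("anchor", {
    a <- anchor_scaffolds(binstage$map, binstage$bins)
    orient_scaffolds(a, binstage$map, binstage$bins)
  })
  log$n_scaffolds_anchored <- nrow(anchors)
  log$n_scaffolds_oriented <- sum(anchors$orientation != "unoriented")
  emit("anchors.tsv", function(p)
    utils::write.table(anchors, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  pcs <- NULL
  if (!is.null(genome)) {
    pcs <- run_stage("anchor", build_pseudochromosomes(
      anchors, genome, binstage$map, gap_n = config$gap_n))
    emit("pseudochromosomes.fa", function(p)
      Biostrings::writeXStringSet(pcs$sequences, p))
    emit("pseudochromosomes.agp", function(p) write_agp(pcs, p))
    emit("chromosome_summary.tsv", function(p)
      utils::write.table(pcs$summary, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  summary <- map_summary(binstage$map, binstage$bins, dist)
  emit("map_summary.tsv", function(p)
    utils::write.table(summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  res <- structure(list(matrix = filt$retained, rejected = filt$rejected,
                        snp_map = snp_map, map = binstage$map,
                        bins = binstage$bins, distortion = dist,
                        anchors = anchors, pseudochromosomes = pcs,
                        summary = summary,
                        log = c(log, list(parameters = unclass(config)))),
                   class = "pipeline_result")
  if (!is.null(outdir))
    jsonlite::write_json(res$log, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  sites in: %d; markers retained: %d; LGs: %d; bins: %d\n",
              x$log$sites_in, x$log$markers_retained,
              x$log$n_linkage_groups, x$log$n_bins))
  cat(sprintf("  distorted bins: %d; SDRs: %d; scaffolds anchored: %d (%d oriented)\n",
              x$log$n_distorted, x$log$n_sdrs,
              x$log$n_scaffolds_anchored, x$log$n_scaffolds_oriented))
  invisible(x)
}

#' Kendall concordance between a recovered order and the truth
#'
#' Fraction of marker pairs ordered concordantly with the true order,
#' maximised over the two orientations (a linkage group has no intrinsic
#' direction).
#'
#' @param recovered Character vector of marker ids in recovered order.
#' @param truth Character vector of the same ids in true order.
#' @return Fraction in `[0, 1]` of concordant pairs (1 = perfect order or
#'   its exact reversal).
#' @export
order_concordance <- function(recovered, truth) {
  common <- intersect(recovered, truth)
  if (length(common) < 2L) return(NA_real_)
  a <- match(common, recovered)
  b <- match(common, truth)
  o <- order(a)
  tau <- stats::cor(a[o], b[o], method = "kendall")
  conc <- (tau + 1) / 2
  max(conc, 1 - conc)
}
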