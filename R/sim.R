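#' Simulation configuration
#'
#' Defines the study design emulated by the synthetic-data generator: a
#' biparental F2 of codominant SNP markers segregating 1:2:1 on an
#' 8-chromosome genome split into scaffolds separated by N-gaps, with
#' configurable genotyping error, missingness, and localized viability
#' selection producing segregation-distorted clusters.
#'
#' Defaults mirror the emulated study: 96 F2 individuals, 8 chromosomes,
#' and per-chromosome genetic lengths of 188.7, 78.4, 40.2, 48.5, 64.5,
#' 63.3, 48.9 and 49.0 cM.
#'
#' @param n_chromosomes Number of chromosomes (default 8).
#' @param chromosome_length_bp Physical length(s) in bp; recycled
#'   (default 500 kb, a desk-scale stand-in for chromosome-scale sequence).
#' @param chromosome_length_cM Genetic length(s) in cM; recycled.
#' @param n_scaffolds_per_chr Scaffolds per chromosome (default 4).
#' @param gap_bp N-gap length inserted between scaffold-origin segments on
#'   a chromosome (default 100).
#' @param n_markers_per_chr Markers per chromosome (default 50).
#' @param n_individuals F2 population size (default 96).
#' @param genotyping_error_rate Per-call probability of a genotype flip
#'   (A->H, B->H, H->A or B; default 0).
#' @param missing_rate Per-call probability of a missing call (default 0).
#' @param distortion_loci List of lists with fields `chr`, `cM`,
#'   `s` (selection coefficient against one homozygote) and optional
#'   `against` (`"B"` default, or `"A"`): viability selection applied at
#'   the marker nearest to `cM`.
#' @param depth_mean,depth_dispersion Negative-binomial parameters for the
#'   summed site depth (defaults 500, 8 — comfortably inside the
#'   \[40, 10000\] filter window).
#' @param qd_range,gq_range Uniform ranges for simulated QD and GQ
#'   (defaults c(10, 40) and c(30, 99), above the 3 / 20 thresholds).
#' @param scramble_scaffolds Shuffle scaffold output order and flip a
#'   random half to reverse orientation (default TRUE), so anchoring and
#'   orientation have real work to do.
#' @param seed Integer seed; fixed seed reproduces all outputs exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 8,
                       chromosome_length_bp = 5e5,
                       chromosome_length_cM = c(188.7, 78.4, 40.2, 48.5,
                                                64.5, 63.3, 48.9, 49.0),
                       n_scaffolds_per_chr = 4,
                       gap_bp = 100,
                       n_markers_per_chr = 50,
                       n_individuals = 96,
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       distortion_loci = list(),
                       depth_mean = 500, depth_dispersion = 8,
                       qd_range = c(10, 40), gq_range = c(30, 99),
                       scramble_scaffolds = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = rep_len(as.integer(chromosome_length_bp),
                                   n_chromosomes),
    chromosome_length_cM = rep_len(as.numeric(chromosome_length_cM),
                                   n_chromosomes),
    n_scaffolds_per_chr = rep_len(as.integer(n_scaffolds_per_chr),
                                  n_chromosomes),
    gap_bp = as.integer(gap_bp),
    n_markers_per_chr = rep_len(as.integer(n_markers_per_chr),
                                n_chromosomes),
    n_individuals = as.integer(n_individuals),
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    distortion_loci = distortion_loci,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    qd_range = qd_range, gq_range = gq_range,
    scramble_scaffolds = isTRUE(scramble_scaffolds),
    seed = as.integer(seed))
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  if (any(cfg$chromosome_length_bp <= 0) || any(cfg$n_markers_per_chr <= 0) ||
      any(cfg$n_scaffolds_per_chr <= 0) || cfg$n_individuals <= 0 ||
      cfg$gap_bp < 0)
    stop("lengths and counts must be positive")
  rates <- c(cfg$genotyping_error_rate, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  for (dl in cfg$distortion_loci) {
    stopifnot(!is.null(dl$chr), !is.null(dl$cM), !is.null(dl$s))
    if (dl$chr < 1 || dl$chr > cfg$n_chromosomes)
      stop("distortion locus chromosome out of range")
    if (dl$cM < 0 || dl$cM > cfg$chromosome_length_cM[dl$chr])
      stop("distortion locus position outside the chromosome map")
    if (dl$s < 0 || dl$s > 1) stop("selection coefficient must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a scaffolded genome with a truth marker map
#'
#' Generates random chromosome sequences, splits each into contiguous
#' scaffold-origin segments separated by N-gaps, places markers at evenly
#' spaced physical and genetic positions, and emits the scaffolds (shuffled
#' and randomly flipped when `scramble_scaffolds`) together with the truth
#' bookkeeping needed for parameter-recovery tests. Adjacent true
#' recombination fractions are the Kosambi-inverse of the marker spacing,
#' so true map distances are exactly recoverable from true r.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome`:
#'   `scaffolds` ([Biostrings::DNAStringSet], output order),
#'   `scaffold_info` (data.frame: scaffold, chr, order_on_chr, orientation,
#'   chr_start (0-based), length), and `truth` — a list with `markers`
#'   (id, chr, chr_bp, scaffold, scaffold_bp 1-based, cM, true r to the
#'   next marker) per the true order.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scaff_seqs <- list(); scaff_rows <- list(); marker_rows <- list()
  for (chr in seq_len(config$n_chromosomes)) {
    L <- config$chromosome_length_bp[chr]      # assembled (non-gap) length
    nsc <- config$n_scaffolds_per_chr[chr]
    # contiguous scaffold-origin segments; N-gaps of gap_bp separate them on
    # the chromosome, so chromosome-origin length = L + (nsc - 1) * gap_bp
    bounds <- unique(round(seq(0, L, length.out = nsc + 1)))
    nsc <- length(bounds) - 1L
    seg_start <- bounds[-length(bounds)]       # 0-based, gaps excluded
    seg_len <- diff(bounds)
    chr_start <- seg_start + (seq_len(nsc) - 1L) * config$gap_bp
    for (k in seq_len(nsc)) {
      sc_id <- sprintf("scaffold_c%02d_%02d", chr, k)
      scaff_seqs[[sc_id]] <- paste(
        sample(c("A", "C", "G", "T"), seg_len[k], replace = TRUE),
        collapse = "")
      scaff_rows[[sc_id]] <- data.frame(
        scaffold = sc_id, chr = chr, order_on_chr = k,
        orientation = "forward", chr_start = chr_start[k],
        length = seg_len[k], stringsAsFactors = FALSE)
    }
    # markers evenly spaced over assembled sequence, evenly spaced in cM
    m <- config$n_markers_per_chr[chr]
    pos0 <- round(seq_len(m) * (L / (m + 1)))  # 0-based, gaps excluded
    cM <- if (m == 1) 0 else
      (seq_len(m) - 1) * (config$chromosome_length_cM[chr] / (m - 1))
    r_next <- c(if (m > 1) kosambi_inverse(diff(cM)), NA_real_)
    seg_of <- findInterval(pos0, bounds, rightmost.closed = TRUE)
    marker_rows[[chr]] <- data.frame(
      id = sprintf("c%02d_m%03d", chr, seq_len(m)),
      chr = chr, chr_bp = pos0 + (seg_of - 1L) * config$gap_bp,
      scaffold = sprintf("scaffold_c%02d_%02d", chr, seg_of),
      scaffold_bp = pos0 - seg_start[seg_of] + 1L,    # 1-based on scaffold
      cM = cM, r_next = r_next, stringsAsFactors = FALSE)
  }
  scaffold_info <- do.call(rbind, scaff_rows)
  markers <- do.call(rbind, marker_rows)
  rownames(scaffold_info) <- rownames(markers) <- NULL

  if (config$scramble_scaffolds) {
    flip <- sample(c(TRUE, FALSE), nrow(scaffold_info), replace = TRUE)
    for (i in which(flip)) {
      sc <- scaffold_info$scaffold[i]
      scaff_seqs[[sc]] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(scaff_seqs[[sc]])))
      scaffold_info$orientation[i] <- "reverse"
      at <- markers$scaffold == sc
      markers$scaffold_bp[at] <- scaffold_info$length[i] -
        markers$scaffold_bp[at] + 1L
    }
    out_order <- sample(nrow(scaffold_info))
  } else {
    out_order <- seq_len(nrow(scaffold_info))
  }
  scaffolds <- Biostrings::DNAStringSet(
    unlist(scaff_seqs[scaffold_info$scaffold[out_order]]))
  structure(list(scaffolds = scaffolds,
                 scaffold_info = scaffold_info,
                 truth = list(markers = markers, config = config)),
            class = "sim_genome")
}

#' Simulate an F2 population on a truth map
#'
#' Draws, per individual and chromosome, two independent gametes from
#' heterozygous F1 parents (parents fixed AA x BB at every marker): each
#' gamete is a Markov chain along the true marker order with transition
#' (crossover) probability equal to the true adjacent r — a
#' no-interference meiosis model. Viability selection is then applied at
#' each configured distortion locus (an individual carrying the selected
#' homozygote survives with probability 1 - s; non-survivors are redrawn),
#' followed by genotyping error and missingness. A site table with
#' simulated depth/QD/GQ is produced alongside, so filter behaviour can be
#' exercised.
#'
#' @param config A [sim_config()].
#' @param genome A [simulate_genome()] result built from the same config.
#' @return List of class `sim_f2`: `matrix` (a [genotype_matrix()], rows in
#'   true order), `sites` (a [site_table()] in (scaffold, pos) order whose
#'   calls re-encode to the matrix), and `truth` — `errors` and `missing`
#'   (data.frames of injected coordinates), `crossovers` (per-gamete
#'   crossover counts), `distortion_markers` (ids of the markers under
#'   selection).
#' @export
simulate_f2 <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  mk <- genome$truth$markers
  n <- config$n_individuals
  samples <- sprintf("F2_%03d", seq_len(n))

  sel <- lapply(config$distortion_loci, function(dl) {
    on_chr <- mk[mk$chr == dl$chr, ]
    list(id = on_chr$id[which.min(abs(on_chr$cM - dl$cM))],
         s = dl$s, against = if (is.null(dl$against)) "B" else dl$against)
  })

  draw_individual <- function(chr_mk) {
    m <- nrow(chr_mk)
    r <- chr_mk$r_next[-m]
    gamete <- function() {
      x <- integer(m)
      x[1] <- stats::rbinom(1, 1, 0.5)
      if (m > 1) {
        sw <- stats::rbinom(m - 1L, 1, r)
        x <- (x[1] + c(0L, cumsum(sw))) %% 2L
      }
      x
    }
    gamete() + gamete()        # 0 = A, 1 = H, 2 = B
  }
  draw_surviving <- function() {
    repeat {
      g <- unlist(lapply(split(mk, mk$chr), draw_individual))
      names(g) <- unlist(lapply(split(mk, mk$chr), function(x) x$id))
      ok <- TRUE
      for (s in sel) {
        code <- c("A", "H", "B")[g[s$id] + 1L]
        if (code == s$against && stats::runif(1) < s$s) { ok <- FALSE; break }
      }
      if (ok) return(g)
    }
  }
  dosage <- vapply(seq_len(n), function(i) draw_surviving(),
                   numeric(nrow(mk)))
  geno <- matrix(c("A", "H", "B")[dosage + 1L], nrow(mk), n,
                 dimnames = list(mk$id, samples))

  # genotyping error: homozygotes flip to H, heterozygotes to A or B
  err <- which(matrix(stats::runif(length(geno)) <
                        config$genotyping_error_rate, nrow(geno)))
  for (e in err) {
    geno[e] <- switch(geno[e], A = "H", B = "H",
                      H = sample(c("A", "B"), 1))
  }
  miss <- which(matrix(stats::runif(length(geno)) < config$missing_rate,
                       nrow(geno)))
  geno[miss] <- "U"

  gm <- genotype_matrix(geno, data.frame(id = mk$id, scaffold = mk$scaffold,
                                         pos = mk$scaffold_bp,
                                         stringsAsFactors = FALSE))
  sites <- sim_site_table(config, mk, geno, samples)
  coords <- function(idx) data.frame(
    marker = mk$id[(idx - 1L) %% nrow(mk) + 1L],
    sample = samples[(idx - 1L) %/% nrow(mk) + 1L], stringsAsFactors = FALSE)
  structure(list(matrix = gm, sites = sites,
                 truth = list(errors = coords(err), missing = coords(miss),
                              distortion_markers =
                                vapply(sel, `[[`, "", "id"))),
            class = "sim_f2")
}

# Build the raw site table consistent with the coded genotype matrix.
sim_site_table <- function(config, mk, geno, samples) {
  n_sites <- nrow(mk)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                "")
  depth <- stats::rnbinom(n_sites, mu = config$depth_mean,
                          size = config$depth_dispersion)
  qd <- stats::runif(n_sites, config$qd_range[1], config$qd_range[2])
  gq <- matrix(stats::runif(n_sites * length(samples),
                            config$gq_range[1], config$gq_range[2]),
               n_sites, dimnames = list(NULL, samples))
  calls <- matrix("./.", n_sites, length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(n_sites)) {
    gt <- c(A = paste(ref[i], ref[i], sep = "/"),
            H = paste(ref[i], alt[i], sep = "/"),
            B = paste(alt[i], alt[i], sep = "/"),
            U = "./.")
    calls[i, ] <- gt[geno[i, ]]
  }
  info <- data.frame(id = mk$id, scaffold = mk$scaffold, pos = mk$scaffold_bp,
                     ref = ref, alt = alt, depth = depth, QD = qd,
                     parent1 = paste(ref, ref, sep = "/"),
                     parent2 = paste(alt, alt, sep = "/"),
                     stringsAsFactors = FALSE)
  ord <- order(info$scaffold, info$pos)
  site_table(info[ord, , drop = FALSE], calls[ord, , drop = FALSE],
             gq[ord, , drop = FALSE])
}

#' Inject filter-violating decoy sites into a site table
#'
#' Appends decoy sites that each violate exactly one filter rule, at
#' positions distinct from existing sites, and returns the augmented table
#' together with the injected ids per violation. Used to verify that the
#' filter cascade rejects exactly the injected set.
#'
#' @param sites A [site_table()].
#' @param n_low_qd,n_bad_depth,n_high_missing,n_third_allele,
#'   n_parents_het,n_cluster Counts of decoys per violation class
#'   (`n_cluster` counts cluster *triples*).
#' @param seed Seed for decoy placement.
#' @return List with `sites` (augmented table) and `injected` (named list
#'   of decoy site ids per reason).
#' @export
inject_bad_sites <- function(sites, n_low_qd = 0, n_bad_depth = 0,
                             n_high_missing = 0, n_third_allele = 0,
                             n_parents_het = 0, n_cluster = 0, seed = 1L) {
  stopifnot(inherits(sites, "site_table"))
  set.seed(seed)
  n_samp <- length(sites$samples)
  info <- sites$info; calls <- sites$calls; gq <- sites$gq
  injected <- list(qd = character(), depth = character(),
                   missing = character(), third_allele = character(),
                   parents_het = character(), cluster = character())
  base_pos <- max(info$pos) + 10000L
  ctr <- 0L; pctr <- 0L
  next_pos <- function() {
    pctr <<- pctr + 1L
    base_pos + pctr * 1000L
  }
  new_site <- function(reason, pos, QD = 20, depth = 500,
                       call_fun = NULL, parent1 = "A/A", parent2 = "G/G") {
    ctr <<- ctr + 1L
    id <- sprintf("decoy_%s_%03d", reason, ctr)
    sc <- info$scaffold[1]
    cl <- rep("A/G", n_samp); g <- stats::runif(n_samp, 60, 99)
    if (!is.null(call_fun)) cl <- call_fun(cl)
    info <<- rbind(info, data.frame(
      id = id, scaffold = sc, pos = pos, ref = "A", alt = "G",
      depth = depth, QD = QD, parent1 = parent1, parent2 = parent2,
      stringsAsFactors = FALSE))
    calls <<- rbind(calls, matrix(cl, 1)); gq <<- rbind(gq, matrix(g, 1))
    id
  }
  for (i in seq_len(n_low_qd))
    injected$qd <- c(injected$qd, new_site("qd", next_pos(), QD = 1.5))
  for (i in seq_len(n_bad_depth))
    injected$depth <- c(injected$depth,
                        new_site("depth", next_pos(),
                                 depth = if (i %% 2) 39 else 10001))
  for (i in seq_len(n_high_missing))
    injected$missing <- c(injected$missing, new_site(
      "missing", next_pos(),
      call_fun = function(cl) { cl[seq_len(ceiling(0.2 * n_samp))] <- "./."; cl }))
  for (i in seq_len(n_third_allele))
    injected$third_allele <- c(injected$third_allele, new_site(
      "third", next_pos(),
      call_fun = function(cl) { cl[seq_len(ceiling(0.1 * n_samp))] <- "C/C"; cl }))
  for (i in seq_len(n_parents_het))
    injected$parents_het <- c(injected$parents_het,
                              new_site("bothhet", next_pos(),
                                       parent1 = "A/G", parent2 = "A/G"))
  for (i in seq_len(n_cluster)) {
    p0 <- next_pos()
    injected$cluster <- c(injected$cluster,
                          new_site("cluster", p0),
                          new_site("cluster", p0 + 4L),
                          new_site("cluster", p0 + 8L))
  }
  list(sites = site_table(info, calls, gq), injected = injected)
}
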