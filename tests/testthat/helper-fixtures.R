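# Shared fixture builders. Heavier simulated objects are cached per test run
# so several test files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small 2-chromosome error-free simulation used across linkage tests.
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- sim_config(n_chromosomes = 2, chromosome_length_bp = 5e4,
                      chromosome_length_cM = c(60, 50),
                      n_markers_per_chr = 15, n_individuals = 96, seed = 11)
    genome <- simulate_genome(cfg)
    f2 <- simulate_f2(cfg, genome)
    list(cfg = cfg, genome = genome, f2 = f2)
  })
}

# Error-free 8-chromosome simulation at SNP-level marker density
# (~0.03-0.13 cM between adjacent markers, the co-segregating regime in
# which genuine double recombinants between adjacent markers are absent and
# every singleton is an error).
dense_sim <- function() {
  cached("dense_sim", function() {
    spacing <- c(188.7 / 3131, 78.4 / 1416, 40.2 / 1155, 48.5 / 682,
                 64.5 / 716, 63.3 / 760, 48.9 / 719, 49.0 / 392)
    cfg <- sim_config(chromosome_length_cM = 49 * spacing, seed = 17)
    genome <- simulate_genome(cfg)
    f2 <- simulate_f2(cfg, genome)
    list(cfg = cfg, genome = genome, f2 = f2)
  })
}

# Build a site_table from explicit pieces with sane defaults.
make_sites <- function(pos, calls, gq = NULL, depth = 500, QD = 20,
                       scaffold = "sc1", parent1 = "A/A", parent2 = "G/G") {
  n_sites <- length(pos)
  n_samp <- ncol(calls)
  if (is.null(gq)) gq <- matrix(60, n_sites, n_samp)
  info <- data.frame(
    id = sprintf("s%03d", seq_len(n_sites)),
    scaffold = rep_len(scaffold, n_sites), pos = pos,
    ref = "A", alt = "G",
    depth = rep_len(depth, n_sites), QD = rep_len(QD, n_sites),
    parent1 = rep_len(parent1, n_sites), parent2 = rep_len(parent2, n_sites),
    stringsAsFactors = FALSE)
  site_table(info, calls, gq)
}

# Genotype matrix literal: rows = markers given as code strings, e.g.
# make_gm(c("AABAA", "AABBA")) builds 2 markers x 5 individuals.
make_gm <- function(rows, scaffold = "sc1", pos = NULL, ids = NULL) {
  g <- do.call(rbind, strsplit(rows, ""))
  if (is.null(ids)) ids <- sprintf("m%03d", seq_along(rows))
  if (is.null(pos)) pos <- seq_along(rows) * 1000L
  genotype_matrix(g, data.frame(id = ids, scaffold = scaffold, pos = pos,
                                stringsAsFactors = FALSE))
}

# Naive substring-scan oracle for restriction-site finding.
naive_find_sites <- function(seq, enz) {
  k <- nchar(enz$recognition)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == enz$recognition)
      hits <- c(hits, i - 1L + enz$cut_offset)
  }
  hits
}

# Brute-force run-length scan oracle for SDR detection.
naive_sdr_scan <- function(flags, min_run) {
  flags <- as.logical(flags)
  out <- list(); i <- 1L; n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Multinomial grid-search oracle for the F2 recombination fraction.
grid_rf <- function(cnt, step = 0.001) {
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    pp <- (1 - r)^2 / 4; rr <- r^2 / 4
    pr <- r * (1 - r) / 2; hh <- ((1 - r)^2 + r^2) / 2
    p <- c(pp, pr, rr, pr, hh, pr, rr, pr, pp)
    sum(ifelse(cnt > 0, cnt * log(p), 0))
  }, numeric(1))
  grid[which.max(ll)]
}

# All permutations of 1..n (n small), for exhaustive SARF minimisation.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i)
  }
  out
}

min_sarf_exhaustive <- function(ids, r) {
  best <- Inf
  for (p in all_perms(length(ids))) {
    o <- ids[p]
    s <- sum(r[cbind(o[-length(o)], o[-1])])
    if (s < best) best <- s
  }
  best
}
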