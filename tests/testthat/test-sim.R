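test_that("degenerate single-scaffold genome has exact length and no Ns", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 10000,
                    chromosome_length_cM = 50, n_scaffolds_per_chr = 1,
                    gap_bp = 0, n_markers_per_chr = 5, n_individuals = 10,
                    scramble_scaffolds = FALSE, seed = 1)
  g <- simulate_genome(cfg)
  expect_equal(length(g$scaffolds), 1L)
  expect_equal(Biostrings::width(g$scaffolds), 10000)
  freq <- Biostrings::alphabetFrequency(g$scaffolds[[1]])
  expect_equal(freq[["N"]], 0)
})

test_that("chromosome-origin length is scaffold lengths plus gaps", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 10000,
                    chromosome_length_cM = 50, n_scaffolds_per_chr = 2,
                    gap_bp = 100, n_markers_per_chr = 5, n_individuals = 10,
                    scramble_scaffolds = FALSE, seed = 1)
  g <- simulate_genome(cfg)
  info <- g$scaffold_info
  expect_equal(sum(info$length), 10000)
  # last scaffold's chromosome-origin end = sum of lengths + one 100 bp gap
  expect_equal(max(info$chr_start + info$length), 10000 + 100)
})

test_that("fixed seed reproduces the genome FASTA byte-for-byte", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length_bp = 20000,
                    n_markers_per_chr = 5, n_individuals = 10, seed = 99)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(simulate_genome(cfg)$scaffolds, f1)
  Biostrings::writeXStringSet(simulate_genome(cfg)$scaffolds, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("true r = 0 makes marker columns identical (complete linkage)", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 10000,
                    chromosome_length_cM = 0, n_markers_per_chr = 2,
                    n_individuals = 50, seed = 5)
  g <- simulate_genome(cfg)
  expect_equal(g$truth$markers$r_next[1], 0)
  f2 <- simulate_f2(cfg, g)
  expect_identical(f2$matrix$geno[1, ], f2$matrix$geno[2, ])
})

test_that("single-marker genotype frequencies are within 3 SE of 1:2:1", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 10000,
                    chromosome_length_cM = 0, n_markers_per_chr = 1,
                    n_individuals = 10000, seed = 12)
  f2 <- simulate_f2(cfg, simulate_genome(cfg))
  v <- f2$matrix$geno[1, ]
  n <- length(v)
  for (probe in list(c("A", 0.25), c("H", 0.5), c("B", 0.25))) {
    p <- as.numeric(probe[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(v == probe[1]) - p), 3 * se)
  }
})

test_that("lethal selection removes the selected homozygote entirely", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 50000,
                    chromosome_length_cM = 60, n_markers_per_chr = 10,
                    n_individuals = 96,
                    distortion_loci = list(list(chr = 1, cM = 30, s = 1)),
                    seed = 8)
  f2 <- simulate_f2(cfg, simulate_genome(cfg))
  sel_id <- f2$truth$distortion_markers
  expect_length(sel_id, 1)
  expect_equal(sum(f2$matrix$geno[sel_id, ] == "B"), 0)
  # and the deficit shows up as significant distortion
  v <- f2$matrix$geno[sel_id, ]
  ct <- segregation_chi2(sum(v == "A"), sum(v == "H"), sum(v == "B"))
  expect_lt(ct$p, 1e-6)
})

test_that("error and missing injections are logged at their coordinates", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 50000,
                    chromosome_length_cM = 50, n_markers_per_chr = 20,
                    n_individuals = 96, genotyping_error_rate = 0.02,
                    missing_rate = 0.03, seed = 13)
  f2 <- simulate_f2(cfg, simulate_genome(cfg))
  expect_equal(sum(f2$matrix$geno == "U"), nrow(f2$truth$missing))
  # every logged missing coordinate is U
  for (i in seq_len(min(20, nrow(f2$truth$missing))))
    expect_equal(f2$matrix$geno[f2$truth$missing$marker[i],
                                f2$truth$missing$sample[i]], "U")
  # rates are in the right ballpark
  expect_gt(nrow(f2$truth$errors), 0)
  expect_lt(abs(nrow(f2$truth$errors) / (20 * 96) - 0.02), 0.015)
})

test_that("empirical adjacent recombination fractions converge to truth", {
  ok <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 50000,
                      chromosome_length_cM = 40, n_markers_per_chr = 10,
                      n_individuals = 96, seed = seed)
    g <- simulate_genome(cfg)
    f2 <- simulate_f2(cfg, g)
    pl <- pairwise_linkage(f2$matrix)
    mk <- g$truth$markers
    for (k in seq_len(nrow(mk) - 1)) {
      r_true <- mk$r_next[k]
      r_hat <- pl$r[mk$id[k], mk$id[k + 1]]
      tol <- 4 * sqrt(r_true * (1 - r_true) / (2 * 96))
      total <- total + 1L
      if (abs(r_hat - r_true) < tol) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("error-free singletons vanish at tight linkage, match 4r^2 when sparse", {
  # SNP-density spacing (~0.065 cM): double recombinants between adjacent
  # markers do not occur, so an error-free matrix is singleton-free
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 5e4,
                    chromosome_length_cM = 1, n_markers_per_chr = 15,
                    n_individuals = 96, seed = 19)
  g <- simulate_genome(cfg)
  f2 <- simulate_f2(cfg, g)
  sub <- subset_markers(f2$matrix, g$truth$markers$id)
  expect_equal(sum(count_singletons(sub)$per_marker), 0)

  # at ~4 cM spacing genuine double recombinants appear at ~4 r^2 per
  # interior call (crossovers in adjacent intervals across the two gametes)
  sim <- small_sim()
  mk <- sim$genome$truth$markers
  tot <- 0
  for (chr in unique(mk$chr)) {
    sub <- subset_markers(sim$f2$matrix, mk$id[mk$chr == chr])
    tot <- tot + sum(count_singletons(sub)$per_marker)
  }
  expected <- sum(4 * mk$r_next^2, na.rm = TRUE) * 96
  expect_gt(tot, expected / 3)
  expect_lt(tot, expected * 3)
})

test_that("distortion locus outside the map is a configuration error", {
  expect_error(sim_config(n_chromosomes = 1, chromosome_length_cM = 50,
                          distortion_loci = list(list(chr = 1, cM = 60, s = 0.5))),
               "outside")
  expect_error(sim_config(n_chromosomes = 1,
                          distortion_loci = list(list(chr = 2, cM = 10, s = 0.5))),
               "out of range")
  expect_error(sim_config(chromosome_length_bp = -5), "positive")
  expect_error(sim_config(missing_rate = 1.2), "rates")
})
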