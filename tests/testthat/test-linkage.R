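test_that("Kosambi function and inverse behave and round-trip", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(1.5 / 0.5))
  expect_equal(kosambi_inverse(0), 0)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_inverse(kosambi(r)) - r)), 1e-10)
  expect_error(kosambi(0.5), "infinite")
  expect_error(kosambi(-0.1), ">= 0")
  expect_error(kosambi_inverse(-1), ">= 0")
})

test_that("estimate_rf finds complete linkage and independence", {
  set.seed(31)
  col <- sample(c("A", "H", "B"), 96, TRUE, prob = c(0.25, 0.5, 0.25))
  same <- estimate_rf(col, col)
  expect_equal(same$r_hat, 0)
  expect_gt(same$lod, 10)

  # independence: one column a random permutation of the other
  lods <- replicate(20, {
    perm <- sample(col)
    est <- estimate_rf(col, perm)
    expect_gte(est$r_hat, 0.3)
    est$lod
  })
  expect_lt(stats::median(lods), 0.5)

  # too few informative individuals
  und <- estimate_rf(c("A", "U", "U"), c("U", "H", "B"))
  expect_true(und$flagged)
  expect_equal(und$r_hat, 0.5)
  expect_equal(und$lod, 0)
})

test_that("EM estimate matches the grid-search oracle on random tables", {
  set.seed(32)
  for (i in 1:100) {
    cnt <- as.vector(stats::rmultinom(1, 20, rep(1 / 9, 9)))
    em <- ddradmap:::rf_em(cnt[1], cnt[2], cnt[3], cnt[4], cnt[5],
                           cnt[6], cnt[7], cnt[8], cnt[9])
    expect_lt(abs(em - grid_rf(cnt)), 1e-3)
  }
})

test_that("LOD is exactly zero at r = 0.5", {
  set.seed(33)
  for (i in 1:20) {
    cnt <- as.vector(stats::rmultinom(1, 30, rep(1 / 9, 9)))
    lod <- ddradmap:::rf_lod(0.5, cnt[1], cnt[2], cnt[3], cnt[4], cnt[5],
                             cnt[6], cnt[7], cnt[8], cnt[9])
    expect_identical(as.numeric(lod), 0)
  }
})

test_that("pairwise_linkage agrees with per-pair estimate_rf", {
  sim <- small_sim()
  gm <- sim$f2$matrix
  pl <- pairwise_linkage(gm)
  set.seed(34)
  for (k in 1:15) {
    ij <- sample(nrow(gm$geno), 2)
    single <- estimate_rf(gm$geno[ij[1], ], gm$geno[ij[2], ])
    expect_equal(pl$r[ij[1], ij[2]], single$r_hat, tolerance = 1e-8)
    expect_equal(pl$lod[ij[1], ij[2]], single$lod, tolerance = 1e-8)
  }
  expect_true(isSymmetric(pl$r))
  expect_true(all(pl$r >= 0 & pl$r <= 0.5))
  expect_true(all(pl$lod >= 0))
})

test_that("LOD grouping recovers the chromosome partition", {
  sim <- small_sim()
  pl <- pairwise_linkage(sim$f2$matrix)
  groups <- group_markers(pl, 10)
  expect_length(groups, 2)
  mk <- sim$genome$truth$markers
  for (g in groups) {
    chrs <- unique(mk$chr[match(g, mk$id)])
    expect_length(chrs, 1)
  }
  # groups numbered by size then smallest id
  expect_true(min(groups[[1]]) < min(groups[[2]]))

  # threshold above every pairwise lod: every marker alone
  solo <- group_markers(pl, max(pl$lod) + 1)
  expect_length(solo, nrow(pl$lod))

  # sweep monotonicity: group count non-decreasing in the threshold
  counts <- vapply(seq(5, 20, by = 2.5),
                   function(th) length(group_markers(pl, th)), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(group_markers(pl, 0), "positive")
})

test_that("ordering recovers truth and achieves the exhaustive SARF minimum", {
  # truth recovery on the error-free simulated group
  sim <- small_sim()
  pl <- pairwise_linkage(sim$f2$matrix)
  groups <- group_markers(pl, 10)
  mk <- sim$genome$truth$markers
  for (g in groups) {
    ord <- order_group(g, pl)
    truth_ord <- mk$id[mk$chr == mk$chr[match(g[1], mk$id)]]
    expect_true(identical(ord, truth_ord) || identical(ord, rev(truth_ord)))
  }

  # exhaustive-permutation optimality on small groups
  for (seed in 1:4) {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 30000,
                      chromosome_length_cM = 45, n_markers_per_chr = 7,
                      n_individuals = 96, seed = 100 + seed)
    f2 <- simulate_f2(cfg, simulate_genome(cfg))
    pl7 <- pairwise_linkage(f2$matrix)
    ids <- rownames(pl7$r)
    ord <- order_group(ids, pl7)
    got <- sum(pl7$r[cbind(ord[-length(ord)], ord[-1])])
    expect_equal(got, min_sarf_exhaustive(ids, pl7$r), tolerance = 1e-12)
  }

  # single-marker and pair groups
  expect_equal(order_group("m1", pl), "m1")
})

test_that("singletons are calls disagreeing with both flanks", {
  gm <- make_gm(c("A", "A", "B", "A", "A"))   # one individual, 5 markers
  s <- count_singletons(gm)
  expect_equal(sum(s$per_marker), 1)
  expect_equal(unname(s$per_marker[3]), 1L)

  gm2 <- make_gm(c("A", "A", "B", "B", "A"))
  expect_equal(sum(count_singletons(gm2)$per_marker), 0)

  # missing flanks: nearest non-missing neighbour is used
  gm3 <- make_gm(c("A", "U", "B", "U", "A"))
  s3 <- count_singletons(gm3)
  expect_equal(unname(s3$per_marker[3]), 1L)

  # terminal markers are never singletons
  gm4 <- make_gm(c("B", "A", "A", "A", "B"))
  expect_equal(sum(count_singletons(gm4)$per_marker), 0)
})

test_that("refinement drops error-laden markers and shrinks the map", {
  sim <- small_sim()
  gm <- sim$f2$matrix
  # inject 6 isolated errors into one interior marker, at individuals whose
  # flanking calls agree (each flip is then guaranteed to be a singleton)
  victim <- "c01_m008"
  g <- gm$geno
  idx <- which(g["c01_m007", ] == "H" & g[victim, ] == "H" &
                 g["c01_m009", ] == "H")[1:6]
  g[victim, idx] <- "A"
  noisy <- genotype_matrix(g, gm$markers)
  m <- refine_map(noisy, lod_threshold = 10, singleton_max = 5)
  expect_true(victim %in% m$dropped)

  # clean matrix: fixed point, zero markers dropped
  m0 <- refine_map(gm, lod_threshold = 10, singleton_max = 5)
  expect_length(m0$dropped, 0)

  # map length after refinement <= unrefined (errors inflate the map)
  cfg <- sim_config(n_chromosomes = 2, chromosome_length_bp = 5e4,
                    chromosome_length_cM = c(60, 50), n_markers_per_chr = 15,
                    n_individuals = 96, genotyping_error_rate = 0.02,
                    seed = 77)
  f2e <- simulate_f2(cfg, simulate_genome(cfg))
  refined <- refine_map(f2e$matrix, lod_threshold = 10, singleton_max = 5)
  unrefined <- refine_map(f2e$matrix, lod_threshold = 10,
                          singleton_max = 10000)
  len <- function(m) sum(vapply(m$linkage_groups, function(x) max(x$cM),
                                numeric(1)))
  expect_lte(len(refined), len(unrefined))
  expect_gt(length(refined$dropped), 0)
})

test_that("map positions start at zero and are non-decreasing", {
  sim <- small_sim()
  m <- refine_map(sim$f2$matrix, lod_threshold = 10)
  for (lg in m$linkage_groups) {
    expect_equal(lg$cM[1], 0)
    expect_true(all(diff(lg$cM) >= 0))
    expect_true(is.na(lg$adj_r[1]))
    expect_true(all(lg$adj_r[-1] >= 0 & lg$adj_r[-1] <= 0.5))
  }
  # total length within 10% of the simulated truth (60 + 50 cM)
  len <- sum(vapply(m$linkage_groups, function(x) max(x$cM), numeric(1)))
  expect_lt(abs(len - 110) / 110, 0.10)
})
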