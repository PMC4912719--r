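fake_map_bins <- function(spec) {
  # spec: data.frame bin_id, scaffold, pos_min, LG, cM
  lgs <- lapply(split(spec, spec$LG), function(d) {
    d <- d[order(d$cM), ]
    data.frame(id = d$bin_id, scaffold = d$scaffold, pos = d$pos_min,
               adj_r = c(NA, rep(0.01, nrow(d) - 1)), cM = d$cM,
               stringsAsFactors = FALSE)
  })
  map <- structure(list(linkage_groups = lgs, dropped = character(),
                        unplaced = character(), provenance = list()),
                   class = "genetic_map")
  bins <- structure(list(
    bins = data.frame(bin_id = spec$bin_id, scaffold = spec$scaffold,
                      pos_min = spec$pos_min, pos_max = spec$pos_min,
                      n_members = 1L, members = spec$bin_id,
                      stringsAsFactors = FALSE)), class = "bin_set")
  list(map = map, bins = bins)
}

test_that("scaffolds anchor to the majority LG at the mean bin cM", {
  spec <- data.frame(
    bin_id = c("b1", "b2", "b3", "b4"),
    scaffold = c("scA", "scA", "scA", "scB"),
    pos_min = c(10000L, 50000L, 90000L, 5000L),
    LG = c("LG2", "LG2", "LG2", "LG1"),
    cM = c(10, 12, 14, 3), stringsAsFactors = FALSE)
  fx <- fake_map_bins(spec)
  a <- anchor_scaffolds(fx$map, fx$bins)
  scA <- a[a$scaffold == "scA", ]
  expect_equal(scA$LG, "LG2")
  expect_equal(scA$position_cM, 12)
  expect_equal(scA$n_bins, 3)
  expect_false(scA$conflict)
  # a scaffold with no mapped bins simply does not appear
  expect_false("scC" %in% a$scaffold)
})

test_that("multi-LG scaffolds keep the majority LG but are flagged", {
  spec <- data.frame(
    bin_id = c("b1", "b2", "b3"),
    scaffold = "scA", pos_min = c(1000L, 2000L, 3000L),
    LG = c("LG1", "LG1", "LG2"), cM = c(5, 6, 40),
    stringsAsFactors = FALSE)
  fx <- fake_map_bins(spec)
  a <- anchor_scaffolds(fx$map, fx$bins)
  expect_equal(a$LG, "LG1")
  expect_equal(a$n_bins, 2)
  expect_true(a$conflict)
})

test_that("orientation follows the bp-vs-cM trend", {
  spec <- data.frame(
    bin_id = c("b1", "b2", "b3", "b4", "b5"),
    scaffold = c("fw", "fw", "rv", "rv", "single"),
    pos_min = c(10000L, 90000L, 10000L, 90000L, 5000L),
    LG = "LG1", cM = c(5, 9, 22, 18, 30), stringsAsFactors = FALSE)
  fx <- fake_map_bins(spec)
  a <- orient_scaffolds(anchor_scaffolds(fx$map, fx$bins), fx$map, fx$bins)
  expect_equal(a$orientation[a$scaffold == "fw"], "forward")
  expect_equal(a$orientation[a$scaffold == "rv"], "reverse")
  expect_equal(a$orientation[a$scaffold == "single"], "unoriented")
})

test_that("pseudochromosome statistics match published-style arithmetic", {
  # one LG spanning 49.0 cM anchored to one 20,903,902 bp scaffold:
  # cM/Mb rounds to 2.34
  len <- 20903902
  spec <- data.frame(bin_id = c("b1", "b2"), scaffold = "sc1",
                     pos_min = c(1L, 1000000L), LG = "LG8", cM = c(0, 49.0),
                     stringsAsFactors = FALSE)
  fx <- fake_map_bins(spec)
  a <- orient_scaffolds(anchor_scaffolds(fx$map, fx$bins), fx$map, fx$bins)
  genome <- Biostrings::DNAStringSet(c(sc1 = paste0(
    strrep("ACGT", (len - 10) %/% 4), strrep("N", 10),
    strrep("A", (len - 10) %% 4))))
  pcs <- build_pseudochromosomes(a, genome, fx$map, gap_n = 100)
  row <- pcs$summary[pcs$summary$chromosome == "chr8", ]
  expect_equal(row$total_length_bp, len)
  expect_equal(row$linkage_distance_cM, 49.0)
  expect_equal(row$cM_per_Mb, 2.34)
  expect_equal(row$effective_length_bp, len - 10)
})

test_that("AGP round-trips to byte-identical pseudochromosome FASTA", {
  spec <- data.frame(
    bin_id = c("b1", "b2", "b3", "b4"),
    scaffold = c("s1", "s1", "s2", "s3"),
    pos_min = c(100L, 900L, 200L, 100L),
    LG = "LG1", cM = c(0, 2, 5, 9), stringsAsFactors = FALSE)
  fx <- fake_map_bins(spec)
  set.seed(61)
  genome <- Biostrings::DNAStringSet(c(
    s1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
    s2 = paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""),
    s3 = paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")))
  a <- orient_scaffolds(anchor_scaffolds(fx$map, fx$bins), fx$map, fx$bins)
  # force one reverse to exercise orientation in the AGP
  a$orientation[a$scaffold == "s2"] <- "reverse"
  pcs <- build_pseudochromosomes(a, genome, fx$map, gap_n = 100)

  fa1 <- tempfile(fileext = ".fa"); agp <- tempfile(fileext = ".agp")
  fa2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(pcs$sequences, fa1)
  write_agp(pcs, agp)
  rebuilt <- read_agp_assemble(agp, genome)
  Biostrings::writeXStringSet(rebuilt, fa2)
  expect_identical(readBin(fa1, "raw", file.size(fa1)),
                   readBin(fa2, "raw", file.size(fa2)))
  # AGP coordinates tile the object
  expect_equal(pcs$agp$object_beg[1], 1)
  expect_equal(max(pcs$agp$object_end),
               sum(Biostrings::width(genome)) + 2 * 100)
  unlink(c(fa1, fa2, agp))
})

test_that("simulated scaffolds anchor to their chromosome of origin", {
  sim <- small_sim()
  res <- run_pipeline(sim$f2$sites, genome = sim$genome$scaffolds,
                      config = pipeline_config(lod_threshold = 10))
  info <- sim$genome$scaffold_info
  a <- res$anchors
  # every scaffold carrying >=1 marker is anchored (error-free data)
  with_markers <- unique(sim$genome$truth$markers$scaffold)
  expect_setequal(a$scaffold, with_markers)
  # all scaffolds of one LG share one true chromosome
  for (lg in unique(a$LG)) {
    chrs <- info$chr[match(a$scaffold[a$LG == lg], info$scaffold)]
    expect_length(unique(chrs), 1)
  }
  # anchored order equals true order or its reversal per chromosome
  for (lg in unique(a$LG)) {
    sc <- a$scaffold[a$LG == lg]
    true_ord <- info$order_on_chr[match(sc, info$scaffold)]
    expect_true(all(diff(true_ord) > 0) || all(diff(true_ord) < 0))
  }
  # orientation recovery: oriented scaffolds match truth up to global flip
  merged <- merge(a, info, by = "scaffold")
  or <- merged[merged$orientation != "unoriented", ]
  for (lg in unique(or$LG)) {
    d <- or[or$LG == lg, ]
    agree <- mean(d$orientation.x == d$orientation.y)
    expect_true(agree == 1 || agree == 0)
  }
})
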