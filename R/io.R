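#' Write a genotype matrix as TSV
#'
#' Columns: `id`, `scaffold`, `pos`, then one column per individual with
#' codes A/H/B/U.
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  tab <- cbind(matrix$markers[, c("id", "scaffold", "pos")],
               as.data.frame(matrix$geno, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' @param path File written by [write_genotype_tsv()].
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot(all(c("id", "scaffold", "pos") %in% names(tab)))
  geno <- as.matrix(tab[, -(1:3), drop = FALSE])
  bad <- which(!geno %in% c("A", "H", "B", "U"))
  if (length(bad)) {
    row <- (bad[1] - 1L) %% nrow(geno) + 1L
    stop("invalid genotype code \"", geno[bad[1]], "\" at line ", row + 1L,
         " of ", path)
  }
  genotype_matrix(geno, tab[, 1:3])
}

#' Write a site table as TSV
#'
#' Columns: scaffold, pos, ref, alt, depth, QD, parent1, parent2, then one
#' `genotype:GQ` column per sample.
#'
#' @param sites A [site_table()].
#' @param path Output path.
#' @export
write_site_tsv <- function(sites, path) {
  stopifnot(inherits(sites, "site_table"))
  gtgq <- matrix(paste(sites$calls, round(sites$gq, 2), sep = ":"),
                 nrow(sites$calls), dimnames = dimnames(sites$calls))
  tab <- cbind(sites$info[, c("scaffold", "pos", "ref", "alt", "depth", "QD",
                              "parent1", "parent2")],
               as.data.frame(gtgq, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table from TSV
#'
#' @param path File written by [write_site_tsv()].
#' @return A [site_table()].
#' @export
read_site_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  fixed <- c("scaffold", "pos", "ref", "alt", "depth", "QD",
             "parent1", "parent2")
  stopifnot(all(fixed %in% names(tab)))
  samp <- setdiff(names(tab), fixed)
  parts <- lapply(tab[samp], function(col) {
    sp <- strsplit(col, ":", fixed = TRUE)
    bad <- which(lengths(sp) != 2L)
    if (length(bad))
      stop("malformed genotype:GQ field at line ", bad[1] + 1L, " of ", path)
    list(gt = vapply(sp, `[`, "", 1), gq = as.numeric(vapply(sp, `[`, "", 2)))
  })
  calls <- do.call(cbind, lapply(parts, `[[`, "gt"))
  gq <- do.call(cbind, lapply(parts, `[[`, "gq"))
  colnames(calls) <- colnames(gq) <- samp
  site_table(tab[fixed], calls, gq)
}

#' Write a site table as minimal VCF 4.2
#'
#' One sample column per individual plus the two parents (named `P1`,
#' `P2`), FORMAT `GT:GQ`, INFO `DP` and `QD`.
#'
#' @param sites A [site_table()].
#' @param path Output path.
#' @export
write_vcf <- function(sites, path) {
  stopifnot(inherits(sites, "site_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "P1", "P2", sites$samples),
                     collapse = "\t")), con)
  info <- sites$info
  gt_index <- function(gt, ref, alt) {
    al <- split_gt(gt)[[1]]
    if (length(al) != 2 || any(al == ".")) return("./.")
    idx <- ifelse(al == ref, "0", ifelse(al == alt, "1", "."))
    paste(sort(idx), collapse = "/")
  }
  for (i in seq_len(nrow(info))) {
    fields <- vapply(seq_along(sites$samples), function(j)
      paste0(gt_index(sites$calls[i, j], info$ref[i], info$alt[i]), ":",
             round(sites$gq[i, j])), "")
    p1 <- paste0(gt_index(info$parent1[i], info$ref[i], info$alt[i]), ":99")
    p2 <- paste0(gt_index(info$parent2[i], info$ref[i], info$alt[i]), ":99")
    writeLines(paste(c(info$scaffold[i], info$pos[i],
                       if (!is.null(info$id)) info$id[i] else ".",
                       info$ref[i], info$alt[i], ".", "PASS",
                       sprintf("DP=%d;QD=%.2f", info$depth[i], info$QD[i]),
                       "GT:GQ", p1, p2, fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF 4.2 subset into a site table
#'
#' Consumes GT and GQ per sample and DP/QD from INFO. Parental genotypes
#' are taken from the two sample columns named in `parents`. Absent
#' optional fields fail open: a missing QD or DP is set to `NA` (which the
#' filter cascade treats as passing) with a warning; a missing GQ becomes
#' `Inf` (never masked).
#'
#' @param path VCF file.
#' @param parents Length-2 character: sample names of the two parents.
#' @return A [site_table()].
#' @export
read_vcf_subset <- function(path, parents = c("P1", "P2")) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("missing #CHROM header line in ", path)
  cols <- strsplit(hdr, "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  samp_all <- cols[-(1:9)]
  if (!all(parents %in% samp_all))
    stop("parent samples not found in VCF: ",
         paste(setdiff(parents, samp_all), collapse = ", "))
  progeny <- setdiff(samp_all, parents)
  warned_qd <- warned_dp <- FALSE
  n <- length(body)
  info_rows <- vector("list", n)
  calls <- matrix("./.", n, length(progeny),
                  dimnames = list(NULL, progeny))
  gq <- matrix(Inf, n, length(progeny), dimnames = list(NULL, progeny))
  for (i in seq_len(n)) {
    x <- strsplit(body[i], "\t")[[1]]
    if (length(x) != length(cols))
      stop("malformed VCF record at line ",
           which(lines == body[i]), ": wrong field count")
    ref <- x[4]; alt <- strsplit(x[5], ",")[[1]][1]
    kv <- strsplit(strsplit(x[8], ";")[[1]], "=")
    info <- stats::setNames(vapply(kv, function(p) p[2] %||% "", ""),
                            vapply(kv, `[`, "", 1))
    dp <- suppressWarnings(as.numeric(info["DP"]))
    qd <- suppressWarnings(as.numeric(info["QD"]))
    if (is.na(dp) && !warned_dp) {
      warning("DP absent from INFO; depth filter will pass these sites")
      warned_dp <- TRUE
    }
    if (is.na(qd) && !warned_qd) {
      warning("QD absent from INFO; QD filter will pass these sites")
      warned_qd <- TRUE
    }
    fmt <- strsplit(x[9], ":")[[1]]
    gt_at <- match("GT", fmt); gq_at <- match("GQ", fmt)
    if (is.na(gt_at)) stop("FORMAT lacks GT at line ", i)
    decode <- function(field) {
      p <- strsplit(field, ":")[[1]]
      gt <- p[gt_at]
      if (grepl("\\|", gt) + grepl("/", gt) == 0 && gt != ".")
        stop("mixed or non-diploid ploidy at line ", i, ": ", gt)
      al <- strsplit(gt, "[/|]")[[1]]
      if (length(al) == 1L && al == ".") al <- c(".", ".")
      if (length(al) != 2L)
        stop("mixed or non-diploid ploidy at line ", i, ": ", gt)
      seq_gt <- vapply(al, function(a) switch(a, "0" = ref, "1" = alt,
                                              "." = ".", alt), "")
      list(gt = paste(seq_gt, collapse = "/"),
           gq = if (is.na(gq_at) || length(p) < gq_at) Inf
                else suppressWarnings(as.numeric(p[gq_at])))
    }
    sample_fields <- stats::setNames(x[-(1:9)], samp_all)
    for (s in progeny) {
      d <- decode(sample_fields[[s]])
      calls[i, s] <- d$gt
      gq[i, s] <- if (is.na(d$gq)) Inf else d$gq
    }
    p1 <- decode(sample_fields[[parents[1]]])$gt
    p2 <- decode(sample_fields[[parents[2]]])$gt
    info_rows[[i]] <- data.frame(
      id = if (x[3] == ".") paste(x[1], x[2], sep = "_") else x[3],
      scaffold = x[1], pos = as.integer(x[2]), ref = ref, alt = alt,
      depth = dp, QD = qd, parent1 = p1, parent2 = p2,
      stringsAsFactors = FALSE)
  }
  site_table(do.call(rbind, info_rows), calls, gq)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a genetic map as TSV
#'
#' Columns: LG, order index, marker id, scaffold, bp, adjacent r,
#' cumulative cM.
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(names(map$linkage_groups), function(lg) {
    tab <- map$linkage_groups[[lg]]
    cbind(data.frame(LG = lg, order = seq_len(nrow(tab))), tab)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulation truth as JSON
#'
#' @param genome A `sim_genome`.
#' @param f2 A `sim_f2` (optional).
#' @param path Output path.
#' @export
write_truth_json <- function(genome, f2 = NULL, path) {
  truth <- list(markers = genome$truth$markers,
                scaffolds = genome$scaffold_info)
  if (!is.null(f2)) truth <- c(truth, f2$truth)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
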