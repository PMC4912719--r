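#' Restriction enzyme definitions
#'
#' An enzyme is described by its recognition sequence and the cut offset,
#' i.e. the number of bases 5' of the cut within the recognition site
#' (MspI C/CGG has offset 1; EcoRI G/AATTC has offset 1).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence over A/C/G/T.
#' @param cut_offset Integer in `[0, nchar(recognition)]`; bases 5' of the
#'   cut within the recognition sequence.
#' @return An object of class `enzyme`.
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  stopifnot(is.character(name), length(name) == 1L, nzchar(recognition))
  if (!grepl("^[ACGT]+$", recognition))
    stop("recognition sequence must be over {A,C,G,T}: ", recognition)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must be in [0, recognition length]")
  if (!is_palindromic(recognition))
    warning("recognition site of ", name, " is not palindromic; ",
            "forward-strand scanning will miss reverse-strand sites")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

is_palindromic <- function(seq) {
  comp <- chartr("ACGT", "TGCA", seq)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  identical(seq, rc)
}

#' @export
print.enzyme <- function(x, ...) {
  cut <- paste0(substr(x$recognition, 1, x$cut_offset), "/",
                substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<enzyme> %s  5'%s3'\n", x$name, cut))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' Returns one of the built-in enzyme definitions used for ddRAD library
#' design (the five pairs commonly screened are combinations of these).
#'
#' @param name One of "EcoRI", "MspI", "SbfI", "SphI", "MluCI", "NlaIII".
#' @return An `enzyme` object.
#' @examples
#' builtin_enzyme("MspI")
#' @export
builtin_enzyme <- function(name) {
  defs <- list(
    EcoRI  = list("GAATTC", 1L),   # G/AATTC
    MspI   = list("CCGG",   1L),   # C/CGG
    SbfI   = list("CCTGCAGG", 6L), # CCTGCA/GG
    SphI   = list("GCATGC", 5L),   # GCATG/C
    MluCI  = list("AATT",   0L),   # /AATT
    NlaIII = list("CATG",   4L)    # CATG/
  )
  if (!name %in% names(defs)) stop("unknown built-in enzyme: ", name)
  d <- defs[[name]]
  enzyme(name, d[[1]], d[[2]])
}

#' Read enzyme definitions from a TSV file
#'
#' Expects columns `name`, `site`, `offset` (tab-separated, with header).
#'
#' @param path Path to the TSV file.
#' @return A named list of `enzyme` objects.
#' @export
read_enzymes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site", "offset") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i)
    enzyme(tab$name[i], tab$site[i], tab$offset[i]))
  names(out) <- tab$name
  out
}

#' Find restriction cut positions in a sequence
#'
#' Scans the forward strand for exact occurrences of the enzyme's
#' recognition sequence and returns 0-based cut coordinates
#' (match start + cut offset). Overlapping occurrences are all reported;
#' matches spanning an N are skipped (assembly gaps cannot be cut).
#'
#' @param sequence A character string or [Biostrings::DNAString] over
#'   A/C/G/T/N.
#' @param enz An `enzyme` object.
#' @return Integer vector of 0-based cut positions, sorted ascending.
#' @examples
#' find_sites("AAGAATTCAA", builtin_enzyme("EcoRI"))  # 3
#' @export
find_sites <- function(sequence, enz) {
  stopifnot(inherits(enz, "enzyme"))
  if (!inherits(sequence, "DNAString"))
    sequence <- Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(sequence) == 0L) return(integer(0))
  # fixed = TRUE: N in the subject never matches a pattern base
  m <- Biostrings::matchPattern(enz$recognition, sequence, fixed = TRUE)
  starts0 <- Biostrings::start(m) - 1L
  sort(starts0 + enz$cut_offset)
}

#' In silico double-restriction digestion
#'
#' Digests every scaffold of a genome with two enzymes: the sorted union of
#' both enzymes' cut positions (plus the scaffold termini) delimits
#' fragments. Each fragment records which enzyme produced each end
#' (`"TERMINUS"` at scaffold ends). Fragments tile each scaffold exactly.
#'
#' @param genome A named character vector, named list of sequences, or
#'   [Biostrings::DNAStringSet].
#' @param enzA,enzB Two distinct `enzyme` objects.
#' @return A data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `left_enzyme`, `right_enzyme`, `length`.
#' @export
double_digest <- function(genome, enzA, enzB) {
  stopifnot(inherits(enzA, "enzyme"), inherits(enzB, "enzyme"))
  if (identical(enzA$recognition, enzB$recognition))
    stop("the two enzymes have identical recognition sequences")
  genome <- as_dnastringset(genome)
  res <- lapply(names(genome), function(sc) {
    seq <- genome[[sc]]
    L <- length(seq)
    cutsA <- find_sites(seq, enzA)
    cutsB <- find_sites(seq, enzB)
    pos <- c(cutsA, cutsB)
    who <- c(rep(enzA$name, length(cutsA)), rep(enzB$name, length(cutsB)))
    o <- order(pos)
    pos <- pos[o]; who <- who[o]
    # drop cuts coinciding with termini (zero-length fragments are not real)
    keep <- pos > 0L & pos < L
    pos <- pos[keep]; who <- who[keep]
    starts <- c(0L, pos)
    ends <- c(pos, L)
    data.frame(scaffold = sc, start = starts, end = ends,
               left_enzyme = c("TERMINUS", who),
               right_enzyme = c(who, "TERMINUS"),
               length = ends - starts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Size-select digestion fragments
#'
#' Keeps fragments with length in `[min_len, max_len]` (inclusive both
#' ends). With `ends_mode = "mixed"` (the ddRAD adapter chemistry) only
#' fragments whose two ends were cut by the two *different* enzymes are
#' kept; `"any"` keeps every in-range fragment.
#'
#' @param fragments Fragment data.frame from [double_digest()].
#' @param min_len,max_len Inclusive length bounds in bp.
#' @param ends_mode `"mixed"` or `"any"`.
#' @return A list with `count` and `subset` (the selected fragments).
#' @export
select_fragments <- function(fragments, min_len, max_len,
                             ends_mode = c("mixed", "any")) {
  ends_mode <- match.arg(ends_mode)
  if (min_len < 0 || max_len < 0) stop("length bounds must be non-negative")
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (ends_mode == "mixed") {
    keep <- keep &
      fragments$left_enzyme != "TERMINUS" &
      fragments$right_enzyme != "TERMINUS" &
      fragments$left_enzyme != fragments$right_enzyme
  }
  subset <- fragments[keep, , drop = FALSE]
  rownames(subset) <- NULL
  list(count = nrow(subset), subset = subset)
}

#' Rank enzyme pairs by predicted in-window fragment yield
#'
#' Digests the genome with each candidate pair and counts fragments in the
#' size-selection window, ranking pairs by in-window count (descending).
#' This is the screen used to choose the library enzymes before sequencing.
#'
#' @param genome Sequences as for [double_digest()].
#' @param pairs List of two-element lists/vectors of `enzyme` objects or
#'   built-in enzyme names.
#' @param min_len,max_len Size-selection window in bp (inclusive).
#' @param ends_mode Passed to [select_fragments()].
#' @return A data.frame with one row per pair: `pair`, `total_fragments`,
#'   `in_window`, `per_mb` (in-window density per Mb of genome), sorted by
#'   `in_window` descending (ties by pair name).
#' @export
compare_enzyme_pairs <- function(genome, pairs, min_len = 250, max_len = 500,
                                 ends_mode = "mixed") {
  stopifnot(length(pairs) >= 1L)
  genome <- as_dnastringset(genome)
  genome_mb <- sum(as.numeric(Biostrings::width(genome))) / 1e6
  rows <- lapply(pairs, function(p) {
    p <- lapply(p, function(e) if (inherits(e, "enzyme")) e else builtin_enzyme(e))
    frags <- double_digest(genome, p[[1]], p[[2]])
    sel <- select_fragments(frags, min_len, max_len, ends_mode)
    data.frame(pair = paste(p[[1]]$name, p[[2]]$name, sep = "/"),
               total_fragments = nrow(frags),
               in_window = sel$count,
               per_mb = sel$count / genome_mb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$in_window, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.list(genome)) genome <- unlist(lapply(genome, as.character))
  x <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("scaffold_", seq_along(x))
  x
}

#' Write fragments as BED-like table
#'
#' BED3+3 (scaffold, start, end, left_enzyme, right_enzyme, length) with
#' 0-based half-open coordinates, stated in a header comment line.
#'
#' @param fragments Fragment data.frame from [double_digest()].
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open (BED)", con)
  utils::write.table(fragments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
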