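#' Read a marker map from delimited text
#'
#' A marker map lists the loci of a genotyping panel together with their
#' linkage group (LG), genetic position and the phased alleles of one or two
#' parents. The expected columns are `locus`, `lg`, `cm`, `class`
#' (`"SSR"` or `"SNP"`), `p1_a1`, `p1_a2` and optionally `p2_a1`, `p2_a2`.
#' Parent 1 is the focal (heterozygous) parent whose gametes are analysed;
#' `p1_a1` is the allele carried on haplotype P1 and `p1_a2` on haplotype P2.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @param centromeres optional path to a two-column (`lg`, `cm`) file with
#'   centromere positions, or a named numeric vector (names = linkage
#'   groups).
#' @return a `marker_map`: a data.frame sorted by (`lg`, `cm`, `locus`) with
#'   a `centromeres` attribute (named numeric vector, possibly empty).
#' @export
read_marker_map <- function(path, sep = "\t", centromeres = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  required <- c("locus", "lg", "cm", "class", "p1_a1", "p1_a2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("marker map is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"p2_a1" %in% names(df)) df[["p2_a1"]] <- rep(NA_character_, nrow(df))
  if (!"p2_a2" %in% names(df)) df[["p2_a2"]] <- rep(NA_character_, nrow(df))
  cen <- if (is.character(centromeres)) read_centromeres(centromeres, sep = sep)
         else if (is.numeric(centromeres)) centromeres
         else stats::setNames(numeric(0), character(0))
  marker_map(df[, c(required, "p2_a1", "p2_a2")], centromeres = cen)
}

#' Construct and validate a marker map
#'
#' @param df data.frame with columns `locus`, `lg`, `cm`, `class`, `p1_a1`,
#'   `p1_a2` and optionally `p2_a1`, `p2_a2`.
#' @param centromeres named numeric vector of centromere positions (cM) by
#'   linkage group.
#' @return a validated, sorted `marker_map`.
#' @export
marker_map <- function(df, centromeres = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"p2_a1" %in% names(df)) df[["p2_a1"]] <- rep(NA_character_, nrow(df))
  if (!"p2_a2" %in% names(df)) df[["p2_a2"]] <- rep(NA_character_, nrow(df))
  df$lg <- suppressWarnings(as.integer(df$lg))
  cm <- suppressWarnings(as.numeric(df$cm))
  if (nrow(df) && anyNA(cm))
    stop("non-numeric cM position in marker map")
  df$cm <- cm
  if (nrow(df)) {
    if (anyNA(df$lg)) stop("non-integer linkage group in marker map")
    if (any(df$cm < 0)) stop("negative cM position in marker map")
    bad <- setdiff(unique(df$class), c("SSR", "SNP"))
    if (length(bad))
      stop("unknown marker class: ", paste(bad, collapse = ", "))
    dup <- duplicated(df[, c("locus", "lg")])
    if (any(dup))
      stop("duplicate locus on one linkage group: ",
           paste(unique(df$locus[dup]), collapse = ", "))
    if (any(df$p1_a1 == "" | df$p1_a2 == "", na.rm = TRUE))
      stop("empty parental allele label")
    # stable sort; ties in cM broken by locus id
    df <- df[order(df$lg, df$cm, df$locus), , drop = FALSE]
    rownames(df) <- NULL
  }
  cen <- if (is.null(centromeres)) stats::setNames(numeric(0), character(0))
         else centromeres
  structure(df, centromeres = cen, class = c("marker_map", "data.frame"))
}

#' Read centromere positions
#'
#' @param path two-column delimited file with header `lg`, `cm`.
#' @param sep field separator.
#' @return named numeric vector: centromere cM position by linkage group.
#' @export
read_centromeres <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("lg", "cm") %in% names(df)))
    stop("centromere file must have columns 'lg' and 'cm'")
  stats::setNames(as.numeric(df$cm), as.character(df$lg))
}

#' Centromere positions of a marker map
#' @param map a `marker_map`.
#' @return named numeric vector (names = linkage groups).
#' @export
centromeres <- function(map) attr(map, "centromeres")

#' Restrict a marker map to one linkage group
#' @param map a `marker_map`.
#' @param chromosome linkage group number.
#' @return the `marker_map` rows of that linkage group, order preserved.
#' @export
map_chromosome <- function(map, chromosome) {
  out <- map[map$lg == chromosome, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, centromeres = centromeres(map),
            class = c("marker_map", "data.frame"))
}

#' Construct a genotype matrix
#'
#' Calls are allele labels (opaque text): a single label for haploid units,
#' an unordered `"a/b"` pair for diploid units, `NA` for missing. Diploid
#' calls are normalised so the two alleles are in sorted order.
#'
#' @param calls character matrix, rows = units, columns = loci, with
#'   rownames and colnames set.
#' @param ploidy 1 (gametes) or 2 (progeny).
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ploidy = 1) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  calls[!is.na(calls) & calls == ""] <- NA_character_
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("genotype matrix needs unit ids (rownames) and loci (colnames)")
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  has_pair <- grepl("/", calls[!is.na(calls)], fixed = TRUE)
  if (ploidy == 1 && any(has_pair))
    stop("diploid 'a/b' call found in a haploid matrix")
  if (ploidy == 2) {
    idx <- which(!is.na(calls))
    calls[idx] <- vapply(strsplit(calls[idx], "/", fixed = TRUE),
                         function(a) paste(sort(a), collapse = "/"), "")
  }
  structure(calls, ploidy = ploidy, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d unit(s) x %d locus(i), ploidy %d\n",
              nrow(x), ncol(x), ploidy(x)))
  invisible(x)
}

#' Ploidy of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return 1 or 2.
#' @export
ploidy <- function(gm) attr(gm, "ploidy")

#' Read a genotype matrix from delimited text
#'
#' First column = unit id, remaining columns = loci. The column set must
#' match the marker map (order-insensitive); columns are reordered to map
#' order. Allele labels not present in the union of the map's parental
#' alleles are kept but flagged (off-ladder), never silently dropped.
#'
#' @param path delimited text file.
#' @param map a `marker_map` defining the panel.
#' @param ploidy 1 or 2.
#' @param sep field separator.
#' @param missing character vector of sentinels to treat as missing
#'   (empty string is always missing).
#' @param ignore_unknown drop file columns not in the map instead of
#'   raising an error.
#' @return a `genotype_matrix` with an `off_ladder` attribute (logical
#'   matrix) marking calls with alleles outside the parental sets.
#' @export
read_genotypes <- function(path, map, ploidy = 1, sep = "\t",
                           missing = "NA", ignore_unknown = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "", na.strings = NULL)
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  unknown <- setdiff(names(df), map$locus)
  if (length(unknown)) {
    if (!ignore_unknown)
      stop("genotype columns not in marker map: ",
           paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  absent <- setdiff(map$locus, names(df))
  if (length(absent))
    stop("marker map loci absent from genotype file: ",
         paste(absent, collapse = ", "))
  calls <- as.matrix(df[, map$locus, drop = FALSE])
  calls[calls %in% c(missing, "")] <- NA_character_
  rownames(calls) <- ids
  gm <- genotype_matrix(calls, ploidy = ploidy)
  flag_off_ladder(gm, map)
}

# Flag calls whose alleles are outside the union of parental alleles.
flag_off_ladder <- function(gm, map) {
  off <- matrix(FALSE, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  for (j in seq_len(ncol(gm))) {
    loc <- colnames(gm)[j]
    k <- match(loc, map$locus)
    known <- stats::na.omit(unlist(map[k, c("p1_a1", "p1_a2", "p2_a1", "p2_a2")]))
    obs <- gm[, j]
    ok <- is.na(obs)
    alleles <- strsplit(ifelse(ok, "", obs), "/", fixed = TRUE)
    off[, j] <- !ok & !vapply(alleles, function(a) all(a %in% known), TRUE)
  }
  if (any(off))
    warning(sum(off), " call(s) carry alleles outside the parental allele ",
            "sets (flagged off-ladder, not dropped)")
  attr(gm, "off_ladder") <- off
  gm
}

#' Gamete-level quality control
#'
#' Computes, per unit, the fraction of positive (non-missing) calls over the
#' full marker panel and retains units at or above `threshold` — the
#' amplification-success filter applied to whole-genome-amplified single
#' nuclei before any genetic analysis. The overall positive rate is total
#' positive calls over total attempted calls for the matrix given.
#'
#' @param gm a `genotype_matrix`.
#' @param threshold minimum per-unit positive-call fraction in `[0, 1]`
#'   (default 0.65).
#' @return a `qc_report` list: `per_unit_positive_rate` (named), `n_positive`
#'   (named), `retained_units`, `overall_positive_rate`, `retention_rate`,
#'   `threshold`, `n_units`, `n_loci`.
#' @export
qc_filter <- function(gm, threshold = 0.65) {
  stopifnot(threshold >= 0, threshold <= 1)
  pos <- rowSums(!is.na(unclass(gm)))
  rate <- pos / ncol(gm)
  retained <- rownames(gm)[rate >= threshold]
  structure(list(
    per_unit_positive_rate = stats::setNames(rate, rownames(gm)),
    n_positive = stats::setNames(as.integer(pos), rownames(gm)),
    retained_units = retained,
    overall_positive_rate = sum(pos) / (nrow(gm) * ncol(gm)),
    retention_rate = length(retained) / nrow(gm),
    threshold = threshold,
    n_units = nrow(gm), n_loci = ncol(gm)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d/%d units retained (%.1f%%) at threshold %.2f; overall positive rate %.1f%%\n",
    length(x$retained_units), x$n_units, 100 * x$retention_rate,
    x$threshold, 100 * x$overall_positive_rate))
  invisible(x)
}

#' Subset a genotype matrix to a set of units
#' @param gm a `genotype_matrix`.
#' @param units character vector of unit ids to keep.
#' @return a `genotype_matrix`.
#' @export
keep_units <- function(gm, units) {
  out <- unclass(gm)[units, , drop = FALSE]
  genotype_matrix(out, ploidy = ploidy(gm))
}

#' Write an analysis result as delimited text
#'
#' Writes marker maps, genotype matrices, QC reports and any tabular result
#' as TSV; text and integer fields round-trip bit-identically through the
#' corresponding reader.
#'
#' @param x a `marker_map`, `genotype_matrix`, `qc_report` or data.frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = "\t") {
  df <- as_output_table(x)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

as_output_table <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    m <- unclass(x)
    attr(m, "ploidy") <- NULL
    attr(m, "off_ladder") <- NULL
    return(data.frame(unit_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "qc_report"))
    return(data.frame(unit_id = names(x$per_unit_positive_rate),
                      n_positive = x$n_positive,
                      positive_rate = x$per_unit_positive_rate,
                      retained = names(x$per_unit_positive_rate) %in%
                        x$retained_units,
                      stringsAsFactors = FALSE, row.names = NULL))
  if (inherits(x, "crossover_summary")) return(x$per_gamete)
  if (is.data.frame(x)) return(as.data.frame(x))
  stop("don't know how to serialise an object of class ",
       paste(class(x), collapse = "/"))
}

#' Path to a packaged example data file
#'
#' The package ships the published marker panels (the lemon chromosome-1
#' panel and the tangor 9-LG panel with derived centromere positions), the
#' published per-marker transmission counts for the pollen and progeny
#' populations, and the published chromosome-1 per-arm crossover cross-tab.
#'
#' @param file file name under `extdata`; with no argument, lists available
#'   files.
#' @return a file path, or a character vector of file names.
#' @export
pollenscan_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "pollenscan")))
  system.file("extdata", file, package = "pollenscan", mustWork = TRUE)
}
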