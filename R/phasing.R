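#' Build a phase table from a marker map
#'
#' The phase table maps, per locus, each allele label to the parental
#' haplotype it derives from (`P1` or `P2`). For the lemon panel, for
#' example, P1 is the sour-orange-derived haplotype and P2 the
#' citron-derived one; which physical allele sits on which haplotype comes
#' from parental genotyping and is an explicit input, so any demonstration
#' phase shipped with a map is an assumed convention.
#'
#' @param map a `marker_map`.
#' @param parent `"p1"` or `"p2"`: whose allele columns define the phase
#'   (`*_a1` -> P1, `*_a2` -> P2).
#' @return data.frame `locus`, `allele`, `haplotype`.
#' @export
phase_from_map <- function(map, parent = c("p1", "p2")) {
  parent <- match.arg(parent)
  a1 <- map[[paste0(parent, "_a1")]]
  a2 <- map[[paste0(parent, "_a2")]]
  data.frame(locus = rep(map$locus, 2L),
             allele = c(a1, a2),
             haplotype = rep(c("P1", "P2"), each = nrow(map)),
             stringsAsFactors = FALSE)
}

#' Read a phase table
#' @param path TSV with columns `locus`, `allele`, `haplotype`.
#' @param sep field separator.
#' @return data.frame `locus`, `allele`, `haplotype`.
#' @export
read_phase <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("locus", "allele", "haplotype")
  if (!all(need %in% names(df)))
    stop("phase file must have columns locus, allele, haplotype")
  if (!all(df$haplotype %in% c("P1", "P2")))
    stop("phase haplotype must be 'P1' or 'P2'")
  df[, need]
}

#' Assign parental origin to haploid allele calls
#'
#' Converts each gamete's allele call into a parental-origin code using the
#' phased parental alleles: `P1`/`P2` where the observed allele matches
#' exactly one haplotype, `AMBIGUOUS` where the allele is carried by both
#' haplotypes (uninformative marker), `OFF_LADDER` where it matches
#' neither, `MISSING` for missing calls.
#'
#' @param gm a haploid `genotype_matrix`.
#' @param map a `marker_map` (defines locus order).
#' @param phase a phase table (see [phase_from_map()]); every locus of `gm`
#'   must appear in it.
#' @return an `origin_matrix`: character matrix with the same dimnames as
#'   `gm` and values in `P1`, `P2`, `MISSING`, `AMBIGUOUS`, `OFF_LADDER`.
#' @export
assign_origin <- function(gm, map, phase) {
  stopifnot(ploidy(gm) == 1)
  absent <- setdiff(colnames(gm), phase$locus)
  if (length(absent))
    stop("loci absent from phase table: ", paste(absent, collapse = ", "))
  om <- matrix("MISSING", nrow(gm), ncol(gm), dimnames = dimnames(gm))
  for (j in seq_len(ncol(gm))) {
    loc <- colnames(gm)[j]
    ph <- phase[phase$locus == loc, , drop = FALSE]
    obs <- unclass(gm)[, j]
    hit <- !is.na(obs)
    code <- vapply(obs[hit], function(a) {
      hap <- unique(ph$haplotype[ph$allele == a])
      if (length(hap) == 0L) "OFF_LADDER"
      else if (length(hap) == 2L) "AMBIGUOUS"
      else hap
    }, "")
    om[hit, j] <- code
  }
  structure(om, class = c("origin_matrix", "matrix"))
}

#' @export
print.origin_matrix <- function(x, ...) {
  cat(sprintf("origin_matrix: %d unit(s) x %d locus(i)\n", nrow(x), ncol(x)))
  print(table(factor(unclass(x))))
  invisible(x)
}

#' Per-locus informativeness of an origin matrix
#'
#' @param om an `origin_matrix`.
#' @return data.frame per locus with the fractions of `P1`, `P2`,
#'   `MISSING`, `AMBIGUOUS` and `OFF_LADDER` codes (rows sum to 1).
#' @export
informativeness_report <- function(om) {
  codes <- c("P1", "P2", "MISSING", "AMBIGUOUS", "OFF_LADDER")
  frac <- t(vapply(seq_len(ncol(om)), function(j) {
    tab <- table(factor(unclass(om)[, j], levels = codes))
    as.numeric(tab) / nrow(om)
  }, numeric(length(codes))))
  colnames(frac) <- codes
  data.frame(locus = colnames(om), frac, stringsAsFactors = FALSE,
             row.names = NULL)
}
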