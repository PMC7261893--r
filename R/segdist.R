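#' Extract the focal parent's transmitted allele from each call
#'
#' For haploid gametes the transmitted allele is the call itself (when it
#' is one of the focal parent's two alleles). For diploid progeny the call
#' `"x/y"` is decomposed over both parents by brute force: an assignment
#' (focal gave x, other gave y) is valid when x is a focal allele and y an
#' allele of the other parent, and vice versa. If exactly one focal allele
#' is consistent with the valid assignments it is returned; if both focal
#' alleles are (the parents share alleles and the call cannot be resolved)
#' the cell is `AMBIGUOUS`; if no assignment is valid it is `INVALID`.
#'
#' @param gm a `genotype_matrix` (ploidy 1 or 2).
#' @param map a `marker_map` carrying both parents' alleles.
#' @param parent `"p1"` or `"p2"`: the focal heterozygous parent.
#' @return character matrix of transmitted focal alleles, with `NA` for
#'   missing and the sentinels `"AMBIGUOUS"` / `"INVALID"` where the call
#'   cannot be decomposed; class `haplotype_matrix`.
#' @export
transmitted_alleles <- function(gm, map, parent = c("p1", "p2")) {
  parent <- match.arg(parent)
  other <- setdiff(c("p1", "p2"), parent)
  out <- matrix(NA_character_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  for (j in seq_len(ncol(gm))) {
    loc <- colnames(gm)[j]
    k <- match(loc, map$locus)
    if (is.na(k)) stop("locus not in map: ", loc)
    focal <- unlist(map[k, paste0(parent, c("_a1", "_a2"))])
    oth <- stats::na.omit(unlist(map[k, paste0(other, c("_a1", "_a2"))]))
    obs <- unclass(gm)[, j]
    hit <- which(!is.na(obs))
    if (ploidy(gm) == 1) {
      out[hit, j] <- ifelse(obs[hit] %in% focal, obs[hit], "INVALID")
    } else {
      out[hit, j] <- vapply(strsplit(obs[hit], "/", fixed = TRUE),
                            function(pair) {
        x <- pair[1]; y <- if (length(pair) > 1) pair[2] else pair[1]
        cand <- character(0)
        if (x %in% focal && y %in% oth) cand <- c(cand, x)
        if (y %in% focal && x %in% oth) cand <- c(cand, y)
        cand <- unique(cand)
        if (length(cand) == 1L) cand
        else if (length(cand) > 1L) "AMBIGUOUS"
        else "INVALID"
      }, "")
    }
  }
  structure(out, class = c("haplotype_matrix", "matrix"))
}

#' Per-marker transmission counts of the focal parent's two alleles
#'
#' Counts, among non-missing unambiguous units, how often the focal
#' parent transmitted its first (`a1`) versus second (`a2`) allele.
#' Ambiguous diploid decompositions and off-panel calls are excluded and
#' reported, not silently dropped.
#'
#' @param gm a `genotype_matrix` (haploid gametes or diploid progeny).
#' @param map a `marker_map`.
#' @param parent the focal heterozygous parent, `"p1"` or `"p2"`.
#' @return data.frame per marker: `locus`, `lg`, `cm`, `a1`, `a2`,
#'   `n_ambiguous`, `n_invalid`, `usable` (FALSE when no unit could be
#'   scored).
#' @export
allele_counts <- function(gm, map, parent = c("p1", "p2")) {
  parent <- match.arg(parent)
  tr <- transmitted_alleles(gm, map, parent)
  keep <- match(colnames(gm), map$locus)
  a1_lab <- map[[paste0(parent, "_a1")]][keep]
  a2_lab <- map[[paste0(parent, "_a2")]][keep]
  res <- data.frame(locus = colnames(gm), lg = map$lg[keep],
                    cm = map$cm[keep], a1 = 0L, a2 = 0L,
                    n_ambiguous = 0L, n_invalid = 0L,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gm))) {
    v <- unclass(tr)[, j]
    res$a1[j] <- sum(v == a1_lab[j], na.rm = TRUE)
    res$a2[j] <- if (a2_lab[j] == a1_lab[j]) 0L else
      sum(v == a2_lab[j], na.rm = TRUE)
    res$n_ambiguous[j] <- sum(v == "AMBIGUOUS", na.rm = TRUE)
    res$n_invalid[j] <- sum(v == "INVALID", na.rm = TRUE)
  }
  # a homozygous focal parent cannot segregate: mark unusable
  res$usable <- res$a1 + res$a2 > 0 & a1_lab != a2_lab
  res
}

#' Chi-square test of 1:1 allelic transmission
#'
#' The two-category goodness-of-fit statistic against a Mendelian 1:1
#' ratio, `(a1 - a2)^2 / (a1 + a2)`, compared to the chi-square
#' distribution with 1 degree of freedom. No continuity correction is
#' applied. Vectorised over markers.
#'
#' @param a1,a2 non-negative integer count(s); `a1 + a2` must be positive.
#' @return list with `chi_square` and `p_value` (same length as input).
#' @export
chi_square_1to1 <- function(a1, a2) {
  if (any(a1 + a2 <= 0)) stop("a1 + a2 must be positive")
  if (any(a1 < 0 | a2 < 0)) stop("negative count")
  chi <- (a1 - a2)^2 / (a1 + a2)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Segregation-distortion scan over a marker panel
#'
#' Applies the 1:1 chi-square test to each marker's transmission counts
#' and flags distorted markers at level `alpha`. Following standard
#' transmission-ratio scans of this kind, the per-marker tests are not
#' multiplicity-corrected by default; set `adjust` to apply a correction.
#'
#' @param counts per-marker counts from [allele_counts()] (or any
#'   data.frame with `locus`, `a1`, `a2`; `lg`/`cm` carried through).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @param population optional population label stored on the result.
#' @return an `sd_scan` data.frame: per marker `chi_square`, `p_value`,
#'   `p_adjusted`, `distorted`; attributes `alpha`, `population` and
#'   `distortion_rate` (distorted / tested markers).
#' @export
sd_scan <- function(counts, alpha = 0.05, adjust = "none",
                    population = NA_character_) {
  stopifnot(alpha > 0, alpha < 1)
  tested <- counts$a1 + counts$a2 > 0
  chi <- p <- rep(NA_real_, nrow(counts))
  if (any(tested)) {
    t_ <- chi_square_1to1(counts$a1[tested], counts$a2[tested])
    chi[tested] <- t_$chi_square
    p[tested] <- t_$p_value
  }
  padj <- rep(NA_real_, nrow(counts))
  padj[tested] <- stats::p.adjust(p[tested], method = adjust)
  out <- counts
  out$chi_square <- chi
  out$p_value <- p
  out$p_adjusted <- padj
  out$distorted <- !is.na(padj) & padj < alpha
  structure(out, alpha = alpha, population = population,
            distortion_rate = sum(out$distorted) / sum(tested),
            class = c("sd_scan", "data.frame"))
}

#' Distortion rate of a scan
#' @param scan an `sd_scan`.
#' @return fraction of tested markers flagged as distorted.
#' @export
distortion_rate <- function(scan) attr(scan, "distortion_rate")

#' Cluster distorted markers into segregation-distortion regions
#'
#' A segregation-distortion region (SDR) is a maximal run of consecutive
#' distorted markers on one linkage group, in map order, of length at
#' least `min_run` — the clustering expected when selection acts on a
#' linked locus and neighbouring markers hitchhike.
#'
#' @param scan an `sd_scan` (must carry `lg` and `cm` columns).
#' @param min_run minimum run length (default 2).
#' @return data.frame per region: `lg`, `n_markers`, `loci`
#'   (comma-separated, map order), `span_min_cm`, `span_max_cm`.
#' @export
sd_regions <- function(scan, min_run = 2) {
  stopifnot(min_run >= 1)
  df <- as.data.frame(scan)[order(scan$lg, scan$cm), , drop = FALSE]
  out <- list()
  for (lg in unique(df$lg)) {
    sub <- df[df$lg == lg, , drop = FALSE]
    r <- rle(sub$distorted)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      run <- sub[starts[k]:ends[k], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        lg = lg, n_markers = nrow(run),
        loci = paste(run$locus, collapse = ","),
        span_min_cm = min(run$cm), span_max_cm = max(run$cm),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(lg = integer(0), n_markers = integer(0), loci = character(0),
               span_min_cm = numeric(0), span_max_cm = numeric(0))
}

#' Compare distortion between two populations scanned on one panel
#'
#' Classifies every marker of a shared panel as distorted in both
#' populations, in one only, or in neither — the contrast that separates
#' gametic selection (visible already in the pollen pool) from
#' gametophytic/zygotic selection (visible only in the recovered progeny).
#'
#' @param scan_a,scan_b `sd_scan` results over the same marker panel.
#' @return list: `table` (data.frame `locus`, `lg`, `status` in
#'   `both`/`a_only`/`b_only`/`neither`), `n_union`, `n_both`, `n_a_only`,
#'   `n_b_only`.
#' @export
compare_populations <- function(scan_a, scan_b) {
  if (!identical(scan_a$locus, scan_b$locus))
    stop("the two scans cover different marker panels")
  status <- ifelse(scan_a$distorted & scan_b$distorted, "both",
            ifelse(scan_a$distorted, "a_only",
            ifelse(scan_b$distorted, "b_only", "neither")))
  tab <- data.frame(locus = scan_a$locus, lg = scan_a$lg, status = status,
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_union = sum(status != "neither"),
       n_both = sum(status == "both"),
       n_a_only = sum(status == "a_only"),
       n_b_only = sum(status == "b_only"))
}
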