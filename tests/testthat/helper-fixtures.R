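# Shared fixtures: packaged panels and small in-code maps/matrices.

cso_map <- function() {
  read_marker_map(pollenscan_example("cso_map.tsv"),
                  centromeres = pollenscan_example("cso_centromeres.tsv"))
}

eureka_map <- function() {
  read_marker_map(pollenscan_example("eureka_map.tsv"),
                  centromeres = pollenscan_example("eureka_centromeres.tsv"))
}

# Published per-marker transmission counts for both populations, with the
# printed chi-square/p reference columns.
sd_counts_table <- function() {
  utils::read.table(pollenscan_example("sd_counts.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}

# Published chromosome-1 arm1 x arm2 crossover cross-tab.
arm_crosstab <- function() {
  utils::read.table(pollenscan_example("eureka_arm_crosstab.tsv"),
                    header = TRUE, sep = "\t")
}

# Minimal single-parent map: loci Mk at the given cM positions, alleles A/B.
toy_map <- function(cm, lg = 1, centromere = NULL, prefix = "M") {
  df <- data.frame(locus = paste0(prefix, seq_along(cm)),
                   lg = lg, cm = cm, class = "SSR",
                   p1_a1 = "A", p1_a2 = "B", stringsAsFactors = FALSE)
  cen <- if (is.null(centromere)) NULL else
    stats::setNames(centromere, as.character(unique(lg)))
  marker_map(df, centromeres = cen)
}

# Build an origin_matrix from a character matrix of codes.
as_origin <- function(m, units = NULL, loci = NULL) {
  if (!is.null(units)) rownames(m) <- units
  if (!is.null(loci)) colnames(m) <- loci
  structure(m, class = c("origin_matrix", "matrix"))
}

# Haploid genotype matrix from a character matrix.
as_gm <- function(m, ploidy = 1) genotype_matrix(m, ploidy = ploidy)

# Per-unit positive-call counts consistent with the published QC totals:
# Eureka lemon, 44 nuclei on 12 loci, 34 at >= 65% with 362 positives.
eureka_qc_counts <- function() c(rep(11L, 22), rep(10L, 12), rep(4L, 10))

# CSO tangor, 54 nuclei on 30 loci, 48 at >= 65% with 1393 positives.
cso_qc_counts <- function() c(30L, rep(29L, 47), rep(10L, 6))
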