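#' Run the full single-pollen analysis pipeline
#'
#' Orchestrates QC, parental-origin phasing, per-chromosome crossover
#' analysis, segregation-distortion scans for the pollen population (and,
#' when supplied, a diploid progeny population), the pollen-vs-progeny
#' distortion contrast, and the joint diversity tree. All tables are
#' written to the output directory together with a manifest of input
#' checksums and parameters, so a run is reproducible from the manifest
#' alone.
#'
#' @param config a named list or the path of a YAML file with fields:
#'   `map`, `centromeres`, `pollen_genotypes` (required paths),
#'   `progeny_genotypes` (optional path), `phase` (optional path; defaults
#'   to the map's p1 columns), `qc_threshold` (default 0.65), `alpha`
#'   (default 0.05), `chromosomes` (default: all linkage groups with a
#'   centromere entry), `min_run` (default 2), `out_dir`, `seed` (for any
#'   stochastic step), `labels` (default `c("pollen", "progeny")`).
#' @return invisibly, the report bundle: `qc`, `origins`, `crossovers`
#'   (per chromosome), `intervals` (per chromosome), `sd` (per
#'   population), `comparison`, `regions`, `tree_report`, `manifest`.
#' @export
run_all <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- c("map", "centromeres", "pollen_genotypes", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  defaults <- list(qc_threshold = 0.65, alpha = 0.05, min_run = 2,
                   labels = c("pollen", "progeny"), seed = NULL)
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  for (f in c("map", "centromeres", "pollen_genotypes", "progeny_genotypes",
              "phase"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("stage [input]: file not found: ", cfg[[f]])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  map <- stage("map", read_marker_map(cfg$map, centromeres = cfg$centromeres))
  pollen <- stage("genotypes",
                  read_genotypes(cfg$pollen_genotypes, map, ploidy = 1))
  progeny <- if (!is.null(cfg$progeny_genotypes))
    stage("genotypes", read_genotypes(cfg$progeny_genotypes, map, ploidy = 2))
  phase <- if (!is.null(cfg$phase)) stage("phase", read_phase(cfg$phase))
           else phase_from_map(map, "p1")

  bundle <- list()
  bundle$qc <- stage("qc", qc_filter(pollen, cfg$qc_threshold))
  retained <- stage("qc", keep_units(pollen, bundle$qc$retained_units))
  write_table(bundle$qc, file.path(cfg$out_dir, "qc_pollen.tsv"))

  bundle$origins <- stage("phasing", assign_origin(retained, map, phase))
  utils::write.table(
    data.frame(unit_id = rownames(bundle$origins), unclass(bundle$origins),
               check.names = FALSE),
    file.path(cfg$out_dir, "origins_pollen.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  chroms <- cfg$chromosomes
  if (is.null(chroms))
    chroms <- intersect(unique(map$lg), as.integer(names(centromeres(map))))
  bundle$crossovers <- list(); bundle$intervals <- list()
  for (ch in chroms) {
    key <- as.character(ch)
    sw <- stage("crossovers", detect_switches(bundle$origins, map, ch))
    bundle$crossovers[[key]] <- stage("crossovers", count_per_arm(sw, map))
    bundle$intervals[[key]] <-
      stage("crossovers", interval_recombination(sw, map, ch))
    write_table(bundle$crossovers[[key]],
                file.path(cfg$out_dir, sprintf("crossovers_lg%s.tsv", key)))
    write_table(bundle$intervals[[key]],
                file.path(cfg$out_dir, sprintf("intervals_lg%s.tsv", key)))
  }

  bundle$sd <- list()
  cnt_pollen <- stage("sdscan", allele_counts(retained, map, "p1"))
  bundle$sd[[cfg$labels[1]]] <-
    stage("sdscan", sd_scan(cnt_pollen, alpha = cfg$alpha,
                            population = cfg$labels[1]))
  write_table(as.data.frame(bundle$sd[[cfg$labels[1]]]),
              file.path(cfg$out_dir, "sd_pollen.tsv"))
  if (!is.null(progeny)) {
    cnt_prog <- stage("sdscan", allele_counts(progeny, map, "p1"))
    bundle$sd[[cfg$labels[2]]] <-
      stage("sdscan", sd_scan(cnt_prog, alpha = cfg$alpha,
                              population = cfg$labels[2]))
    write_table(as.data.frame(bundle$sd[[cfg$labels[2]]]),
                file.path(cfg$out_dir, "sd_progeny.tsv"))
    bundle$comparison <- stage("sdcompare",
      compare_populations(bundle$sd[[cfg$labels[1]]],
                          bundle$sd[[cfg$labels[2]]]))
    write_table(bundle$comparison$table,
                file.path(cfg$out_dir, "sd_comparison.tsv"))
  }
  bundle$regions <- lapply(bundle$sd, sd_regions, min_run = cfg$min_run)

  if (!is.null(progeny) && nrow(retained) + nrow(progeny) >= 3) {
    male <- stage("diversity", male_haplotype_matrix(progeny, map, "p1"))
    bundle$tree_report <- stage("diversity",
      population_tree_report(retained, male, labels = cfg$labels))
    write_newick(bundle$tree_report$tree,
                 file.path(cfg$out_dir, "populations.nwk"))
    write_table(bundle$tree_report$leaf_populations,
                file.path(cfg$out_dir, "tree_labels.tsv"))
  }

  inputs <- unlist(cfg[c("map", "centromeres", "pollen_genotypes",
                         "progeny_genotypes", "phase")])
  bundle$manifest <- list(
    package = "pollenscan",
    version = as.character(utils::packageVersion("pollenscan")),
    parameters = cfg[c("qc_threshold", "alpha", "min_run", "seed")],
    chromosomes = chroms,
    inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(bundle$manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- make_report(bundle)
  writeLines(report, file.path(cfg$out_dir, "report.md"))
  invisible(bundle)
}

#' Extract the male-transmitted haplotypes from a diploid progeny
#'
#' Decomposes each progeny genotype into the focal (male) parent's
#' transmitted allele ([transmitted_alleles()]) and returns them as a
#' haploid genotype matrix; ambiguous or undecomposable calls become
#' missing. This reconstructs the male gamete that fertilised each seed,
#' the unit compared against the pollen-nucleus population.
#'
#' @param gm a diploid `genotype_matrix`.
#' @param map a `marker_map`.
#' @param parent the focal (male) parent, `"p1"` or `"p2"`.
#' @return a haploid `genotype_matrix`.
#' @export
male_haplotype_matrix <- function(gm, map, parent = "p1") {
  tr <- unclass(transmitted_alleles(gm, map, parent))
  tr[tr %in% c("AMBIGUOUS", "INVALID")] <- NA_character_
  genotype_matrix(tr, ploidy = 1)
}

#' Render a markdown report of a pipeline bundle
#'
#' Renders the per-arm crossover cross-tab (arm 1 across, arm 2 down) and
#' the per-population distortion scan (locus, LG, cM, allele counts,
#' chi-square, p) as a plain markdown document.
#'
#' @param bundle the list returned by [run_all()] (only the parts present
#'   are rendered).
#' @return character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  out <- c("# Single-pollen genotyping report", "")
  for (key in names(bundle$crossovers)) {
    cs <- bundle$crossovers[[key]]
    out <- c(out, sprintf("## Crossovers, linkage group %s", key), "",
             sprintf("%d gametes analysed; mean %.2f crossovers/chromosome; %.1f%% with none; per-arm maxima (%d, %d).",
                     cs$n_gametes_analyzed, cs$mean_co_per_chromosome,
                     100 * cs$zero_co_fraction, cs$max_arm1, cs$max_arm2),
             "", render_crosstab(cs), "")
  }
  if (length(bundle$sd)) {
    out <- c(out, "## Allelic segregation (chi-square vs 1:1)", "")
    for (popn in names(bundle$sd)) {
      scan <- bundle$sd[[popn]]
      if (!nrow(scan)) {
        out <- c(out, sprintf("### %s", popn), "", "no markers tested", "")
        next
      }
      hdr <- "| Locus | LG | cM | A1 | A2 | Chi-square | P value |"
      sepr <- "|---|---|---|---|---|---|---|"
      rows <- sprintf("| %s | %d | %.2f | %d | %d | %.3f | %.3f |",
                      scan$locus, scan$lg, scan$cm, scan$a1, scan$a2,
                      scan$chi_square, scan$p_value)
      out <- c(out, sprintf("### %s (distortion rate %.1f%%)", popn,
                            100 * distortion_rate(scan)),
               "", hdr, sepr, rows, "")
    }
  }
  if (!is.null(bundle$comparison)) {
    cmp <- bundle$comparison
    out <- c(out, "## Population contrast", "",
             sprintf("%d markers distorted in total: %d in both populations, %d pollen-only, %d progeny-only.",
                     cmp$n_union, cmp$n_both, cmp$n_a_only, cmp$n_b_only), "")
  }
  if (!is.null(bundle$tree_report))
    out <- c(out, "## Diversity", "",
             sprintf("Joint neighbor-joining tree over %d gametes; %d population-exclusive clade(s).",
                     nrow(bundle$tree_report$leaf_populations),
                     bundle$tree_report$n_exclusive), "")
  out
}

render_crosstab <- function(cs) {
  if (!cs$n_gametes_analyzed) return("no gametes analysed")
  a1 <- 0:max(cs$per_gamete$arm1); a2 <- 0:max(cs$per_gamete$arm2)
  tab <- table(factor(cs$per_gamete$arm2, levels = a2),
               factor(cs$per_gamete$arm1, levels = a1))
  hdr <- paste0("| Arm 2 \\\\ Arm 1 | ", paste(a1, collapse = " | "), " |")
  sepr <- paste0("|", paste(rep("---", length(a1) + 1), collapse = "|"), "|")
  rows <- vapply(seq_along(a2), function(i)
    paste0("| **", a2[i], "** | ", paste(tab[i, ], collapse = " | "), " |"),
    "")
  c(hdr, sepr, rows)
}
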