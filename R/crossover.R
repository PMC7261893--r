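#' Detect parental-origin switches along one chromosome
#'
#' Walks each gamete's consecutive informative markers (`P1`/`P2` codes
#' only) along the ordered markers of one linkage group. Each consecutive
#' informative pair is one observation; a switch (crossover signal) is
#' recorded when the two origins differ. Uninformative points (missing,
#' ambiguous or off-ladder calls) are skipped, so an observation may span
#' several elementary marker intervals — the marker-pair omission rule for
#' missing data. Gametes with fewer than two informative markers on the
#' chromosome are excluded with a reason.
#'
#' @param om an `origin_matrix`.
#' @param map a `marker_map`.
#' @param chromosome linkage group to analyse.
#' @return a `switch_set` list: `observations` (data.frame `unit`,
#'   `left_idx`, `right_idx`, `left_locus`, `right_locus`, `left_cm`,
#'   `right_cm`, `switch`), `gametes_analyzed`, `excluded` (data.frame
#'   `unit`, `reason`), `markers` (the chromosome's map slice),
#'   `chromosome`.
#' @export
detect_switches <- function(om, map, chromosome) {
  mk <- map_chromosome(map, chromosome)
  if (nrow(mk) < 2)
    stop("chromosome ", chromosome, " has fewer than 2 mapped markers")
  sub <- unclass(om)[, mk$locus, drop = FALSE]
  obs <- list(); analyzed <- character(0); excluded <- list()
  for (i in seq_len(nrow(sub))) {
    unit <- rownames(sub)[i]
    inf <- which(sub[i, ] %in% c("P1", "P2"))
    if (length(inf) < 2) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        unit = unit, reason = sprintf("only %d informative marker(s)",
                                      length(inf)),
        stringsAsFactors = FALSE)
      next
    }
    analyzed <- c(analyzed, unit)
    l <- inf[-length(inf)]; r <- inf[-1]
    obs[[length(obs) + 1L]] <- data.frame(
      unit = unit, left_idx = l, right_idx = r,
      left_locus = mk$locus[l], right_locus = mk$locus[r],
      left_cm = mk$cm[l], right_cm = mk$cm[r],
      switch = sub[i, l] != sub[i, r],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(
    observations = if (length(obs)) do.call(rbind, obs) else
      data.frame(unit = character(0), left_idx = integer(0),
                 right_idx = integer(0), left_locus = character(0),
                 right_locus = character(0), left_cm = numeric(0),
                 right_cm = numeric(0), switch = logical(0)),
    gametes_analyzed = analyzed,
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(unit = character(0), reason = character(0)),
    markers = mk, chromosome = chromosome), class = "switch_set")
}

#' Count crossovers per chromosome arm
#'
#' Assigns every detected switch to a chromosome arm using the centromere
#' position: a switch whose observation interval lies entirely on one side
#' goes to that arm; a centromere-spanning interval is assigned to the arm
#' holding the larger genetic (cM) share of the interval, arm 1 on an
#' exact tie. Arm 1 is the arm at positions below the centromere.
#'
#' @param sw a `switch_set` from [detect_switches()].
#' @param map a `marker_map` whose centromere table covers the chromosome
#'   (defaults to the map stored in `sw`).
#' @return a `crossover_summary`; see [crossover_summary()].
#' @export
count_per_arm <- function(sw, map = NULL) {
  cen <- centromeres(if (is.null(map)) sw$markers else map)
  key <- as.character(sw$chromosome)
  if (!key %in% names(cen))
    stop("no centromere position for linkage group ", sw$chromosome)
  c_cm <- cen[[key]]
  ob <- sw$observations
  counts <- data.frame(unit = sw$gametes_analyzed, arm1 = 0L, arm2 = 0L,
                       stringsAsFactors = FALSE)
  hits <- ob[ob$switch, , drop = FALSE]
  if (nrow(hits)) {
    arm <- ifelse(hits$right_cm <= c_cm, 1L,
           ifelse(hits$left_cm >= c_cm, 2L,
           ifelse(c_cm - hits$left_cm >= hits$right_cm - c_cm, 1L, 2L)))
    t1 <- table(factor(hits$unit[arm == 1L], levels = counts$unit))
    t2 <- table(factor(hits$unit[arm == 2L], levels = counts$unit))
    counts$arm1 <- as.integer(t1)
    counts$arm2 <- as.integer(t2)
  }
  crossover_summary(counts)
}

#' Summarise per-gamete crossover counts
#'
#' Builds the population summary from a per-gamete table of arm-wise
#' crossover counts: the arm1 x arm2 cross-tab, the mean number of
#' crossovers per chromosome, the fraction of gametes with no detected
#' crossover, and the per-arm maxima. The same summary can be computed
#' from detected switches (via [count_per_arm()]) or from a published
#' cross-tab expanded to per-gamete counts (see [expand_crosstab()]).
#'
#' @param per_gamete data.frame with columns `unit`, `arm1`, `arm2`.
#' @return a `crossover_summary` list: `per_gamete` (with `total` added),
#'   `distribution` (data.frame `arm1`, `arm2`, `n`),
#'   `mean_co_per_chromosome`, `zero_co_fraction`, `n_gametes_analyzed`,
#'   `max_arm1`, `max_arm2`.
#' @export
crossover_summary <- function(per_gamete) {
  stopifnot(all(c("unit", "arm1", "arm2") %in% names(per_gamete)))
  pg <- per_gamete[, c("unit", "arm1", "arm2")]
  pg$total <- pg$arm1 + pg$arm2
  dist <- as.data.frame(table(arm1 = pg$arm1, arm2 = pg$arm2),
                        stringsAsFactors = FALSE)
  dist <- dist[dist$Freq > 0, , drop = FALSE]
  dist <- data.frame(arm1 = as.integer(dist$arm1),
                     arm2 = as.integer(dist$arm2), n = dist$Freq)
  dist <- dist[order(dist$arm1, dist$arm2), , drop = FALSE]
  rownames(dist) <- NULL
  n <- nrow(pg)
  structure(list(
    per_gamete = pg,
    distribution = dist,
    mean_co_per_chromosome = if (n) sum(pg$total) / n else NaN,
    zero_co_fraction = if (n) mean(pg$total == 0) else NaN,
    n_gametes_analyzed = n,
    max_arm1 = if (n) max(pg$arm1) else NA_integer_,
    max_arm2 = if (n) max(pg$arm2) else NA_integer_),
    class = "crossover_summary")
}

#' @export
print.crossover_summary <- function(x, ...) {
  cat(sprintf(
    "crossovers: %d gametes; mean %.2f/chromosome; %.1f%% without crossover; max per arm (%d, %d)\n",
    x$n_gametes_analyzed, x$mean_co_per_chromosome,
    100 * x$zero_co_fraction, x$max_arm1, x$max_arm2))
  invisible(x)
}

#' Expand an arm1 x arm2 cross-tab to per-gamete counts
#'
#' @param crosstab data.frame in wide layout: first column `arm2`, then
#'   columns `arm1_0`, `arm1_1`, ... holding gamete counts.
#' @return data.frame `unit`, `arm1`, `arm2`, one row per gamete.
#' @export
expand_crosstab <- function(crosstab) {
  arm1_cols <- grep("^arm1_", names(crosstab), value = TRUE)
  arm1_vals <- as.integer(sub("^arm1_", "", arm1_cols))
  rows <- list()
  for (i in seq_len(nrow(crosstab)))
    for (k in seq_along(arm1_cols)) {
      n <- crosstab[i, arm1_cols[k]]
      if (n > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          arm1 = rep(arm1_vals[k], n), arm2 = rep(crosstab$arm2[i], n))
    }
  out <- do.call(rbind, rows)
  data.frame(unit = sprintf("g%03d", seq_len(nrow(out))), out,
             stringsAsFactors = FALSE)
}

#' Per-arm maxima of a crossover summary
#' @param summary a `crossover_summary`.
#' @return integer vector `c(max_arm1, max_arm2)`.
#' @export
max_crossovers <- function(summary) {
  if (!summary$n_gametes_analyzed) stop("empty crossover summary")
  c(max_arm1 = summary$max_arm1, max_arm2 = summary$max_arm2)
}

#' Per-interval recombination frequency along a chromosome
#'
#' For every elementary interval between adjacent mapped markers, computes
#' the crossover ratio n(CO) / n(M): the number of observed switches over
#' the number of informative observations. An observation whose flanks span
#' skipped (uninformative) markers contributes to every elementary interval
#' it covers when `denominator = "spanning"` (default); with
#' `denominator = "adjacent"` only flank-exact observations count. A
#' spanning observation's switch is assigned to the genetically longest
#' elementary interval in its span (leftmost on ties), which preserves the
#' identity sum(n_co) = total detected switches.
#'
#' @param om an `origin_matrix` (or a precomputed `switch_set`).
#' @param map a `marker_map`.
#' @param chromosome linkage group.
#' @param denominator `"spanning"` or `"adjacent"`.
#' @return data.frame per elementary interval: `left_locus`, `right_locus`,
#'   `left_cm`, `right_cm`, `n_co`, `n_informative`, `co_ratio`
#'   (`NaN` where `n_informative` is 0).
#' @export
interval_recombination <- function(om, map, chromosome,
                                   denominator = c("spanning", "adjacent")) {
  denominator <- match.arg(denominator)
  sw <- if (inherits(om, "switch_set")) om else
    detect_switches(om, map, chromosome)
  mk <- sw$markers
  nint <- nrow(mk) - 1L
  n_inf <- integer(nint); n_co <- integer(nint)
  ob <- sw$observations
  len <- diff(mk$cm)
  for (i in seq_len(nrow(ob))) {
    span <- seq.int(ob$left_idx[i], ob$right_idx[i] - 1L)
    if (denominator == "adjacent" && length(span) > 1L) next
    n_inf[span] <- n_inf[span] + 1L
    if (ob$switch[i]) {
      k <- span[which.max(len[span])]
      n_co[k] <- n_co[k] + 1L
    }
  }
  data.frame(left_locus = mk$locus[-nrow(mk)], right_locus = mk$locus[-1],
             left_cm = mk$cm[-nrow(mk)], right_cm = mk$cm[-1],
             n_co = n_co, n_informative = n_inf,
             co_ratio = ifelse(n_inf > 0, n_co / n_inf, NaN),
             stringsAsFactors = FALSE)
}
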