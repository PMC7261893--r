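#' Map distance to recombination fraction
#'
#' Converts a genetic-map distance to the probability that a gamete shows an
#' odd number of crossovers (an origin switch) between the two loci, under
#' the Haldane (no interference; r = (1 - exp(-2d))/2 with d in Morgans) or
#' Kosambi (r = tanh(2d)/2) mapping function.
#'
#' @param d_cm non-negative distance(s) in centiMorgans (vectorised).
#' @param fn `"haldane"` (default) or `"kosambi"`.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
recomb_fraction <- function(d_cm, fn = c("haldane", "kosambi")) {
  fn <- match.arg(fn)
  if (any(d_cm < 0)) stop("negative map distance")
  d <- d_cm / 100  # Morgans
  switch(fn,
         haldane = 0.5 * (1 - exp(-2 * d)),
         kosambi = 0.5 * tanh(2 * d))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. seed = NULL runs with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else rm(".Random.seed", envir = env))
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds derived from a single master seed.
seed_offset <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1000003 * k) %% 2147483647)
}

#' Simulate a haploid gamete population on a genetic map
#'
#' Gametes of one heterozygous parent are simulated per linkage group as a
#' Markov chain along the ordered markers: the first marker's parental
#' origin is P1 or P2 with probability 1/2 and the origin switches between
#' adjacent markers with probability [recomb_fraction()] of the interval.
#' Under the Haldane function the per-interval crossover count is drawn
#' Poisson(d/100) and the origin switches on odd counts, so multi-crossover
#' intervals exist in the recorded truth; under Kosambi a single
#' Bernoulli(r) switch is drawn. Gametic selection is applied by rejection
#' sampling on the realised allele at each selected locus; dropout is
#' applied i.i.d. per call.
#'
#' @param map a `marker_map`.
#' @param n number of gametes to return (after selection).
#' @param parent `"p1"` or `"p2"`: whose allele columns supply the calls.
#' @param mapping_function `"haldane"` or `"kosambi"`.
#' @param gametic_selection named numeric vector: transmission probability
#'   of the haplotype-P1 allele at each named locus (0.5 = Mendelian).
#' @param dropout_rate per-call probability of a missing call in `[0, 1)`.
#' @param seed integer seed; fixed seed gives identical output.
#' @param truth record per-gamete origins and crossover positions.
#' @param max_batches rejection-sampling batch limit before giving up.
#' @return list with `genotypes` (haploid `genotype_matrix`), and if
#'   `truth`, `origins` (unit x locus matrix of `"P1"`/`"P2"`) and
#'   `crossovers` (data.frame `unit`, `lg`, `interval`, `left_locus`,
#'   `right_locus`, `pos_cm`; one row per crossover).
#' @export
simulate_gametes <- function(map, n, parent = c("p1", "p2"),
                             mapping_function = c("haldane", "kosambi"),
                             gametic_selection = NULL, dropout_rate = 0,
                             seed = NULL, truth = TRUE, max_batches = 1000L) {
  parent <- match.arg(parent)
  mapping_function <- match.arg(mapping_function)
  stopifnot(n >= 1, dropout_rate >= 0, dropout_rate < 1)
  if (!is.null(gametic_selection)) {
    if (is.null(names(gametic_selection)) ||
        !all(names(gametic_selection) %in% map$locus))
      stop("gametic_selection loci must name loci present in the map")
    if (any(gametic_selection < 0 | gametic_selection > 1))
      stop("transmission probabilities must lie in [0, 1]")
  }
  with_seed(seed, {
    kept <- 0L
    acc_org <- vector("list", 0L); acc_co <- vector("list", 0L)
    batch <- n
    for (b in seq_len(max_batches)) {
      draw <- draw_gamete_batch(map, batch, mapping_function, truth)
      keep <- accept_gametic(draw$origins, map, gametic_selection)
      if (any(keep)) {
        acc_org[[length(acc_org) + 1L]] <- draw$origins[keep, , drop = FALSE]
        if (truth && nrow(draw$crossovers))
          acc_co[[length(acc_co) + 1L]] <-
            draw$crossovers[draw$crossovers$row %in% which(keep), , drop = FALSE]
        else if (truth)
          acc_co[[length(acc_co) + 1L]] <- draw$crossovers
        if (truth) {
          # remap batch row index -> cumulative kept index
          co <- acc_co[[length(acc_co)]]
          co$row <- kept + match(co$row, which(keep))
          acc_co[[length(acc_co)]] <- co
        }
        kept <- kept + sum(keep)
      }
      if (kept >= n) break
      rate <- max(kept / (b * batch), 0.01)
      batch <- min(max(ceiling((n - kept) / rate), n), 10L * n)
    }
    if (kept < n)
      stop("rejection sampling failed to accept ", n, " gametes after ",
           max_batches, " batches; selection constraints may be infeasible")
    origins <- do.call(rbind, acc_org)[seq_len(n), , drop = FALSE]
    ids <- sprintf("G%03d", seq_len(n))
    rownames(origins) <- ids
    colnames(origins) <- map$locus
    co <- if (truth) {
      co <- if (length(acc_co)) do.call(rbind, acc_co)
            else empty_crossover_truth()
      co <- co[co$row <= n, , drop = FALSE]
      data.frame(unit = ids[co$row], lg = co$lg, interval = co$interval,
                 left_locus = co$left_locus, right_locus = co$right_locus,
                 pos_cm = co$pos_cm, stringsAsFactors = FALSE)
    } else NULL
    alleles <- if (parent == "p1") cbind(map$p1_a1, map$p1_a2)
               else cbind(map$p2_a1, map$p2_a2)
    calls <- matrix(NA_character_, n, nrow(map), dimnames = list(ids, map$locus))
    for (j in seq_len(nrow(map)))
      calls[, j] <- alleles[j, origins[, j]]
    gm <- genotype_matrix(calls, ploidy = 1)
    if (dropout_rate > 0)
      gm <- apply_dropout(gm, dropout_rate, seed = NULL)
    out <- list(genotypes = gm)
    if (truth) {
      out$origins <- matrix(c("P1", "P2")[origins], n, nrow(map),
                            dimnames = list(ids, map$locus))
      out$crossovers <- co[order(co$unit, co$lg, co$interval), , drop = FALSE]
      rownames(out$crossovers) <- NULL
    }
    out
  })
}

empty_crossover_truth <- function() {
  data.frame(row = integer(0), lg = integer(0), interval = integer(0),
             left_locus = character(0), right_locus = character(0),
             pos_cm = numeric(0), stringsAsFactors = FALSE)
}

# One batch of `n` gametes: origins as integer matrix (1 = P1, 2 = P2) and,
# when truth is requested, per-crossover rows keyed by batch row index.
draw_gamete_batch <- function(map, n, mapping_function, truth) {
  m <- nrow(map)
  origins <- matrix(1L, n, m)
  co <- if (truth) list() else NULL
  for (lg in unique(map$lg)) {
    jj <- which(map$lg == lg)
    k <- length(jj)
    first <- stats::rbinom(n, 1L, 0.5)  # 0 = P1, 1 = P2
    if (k == 1L) { origins[, jj] <- first + 1L; next }
    d <- diff(map$cm[jj])
    if (mapping_function == "haldane") {
      counts <- matrix(stats::rpois(n * (k - 1L), rep(d / 100, each = n)),
                       n, k - 1L)
      switches <- counts %% 2L
    } else {
      r <- recomb_fraction(d, "kosambi")
      switches <- matrix(stats::rbinom(n * (k - 1L), 1L, rep(r, each = n)),
                         n, k - 1L)
      counts <- switches
    }
    cum <- matrix(0L, n, k)
    cum[, 1L] <- first
    for (q in 2:k) cum[, q] <- (cum[, q - 1L] + switches[, q - 1L]) %% 2L
    origins[, jj] <- cum + 1L
    if (truth && any(counts > 0L)) {
      idx <- which(counts > 0L, arr.ind = TRUE)
      reps <- counts[idx]
      row <- rep(idx[, 1L], reps)
      int <- rep(idx[, 2L], reps)
      left <- map$cm[jj][int]; right <- map$cm[jj][int + 1L]
      co[[length(co) + 1L]] <- data.frame(
        row = row, lg = lg, interval = int,
        left_locus = map$locus[jj][int], right_locus = map$locus[jj][int + 1L],
        pos_cm = stats::runif(length(row), left, right),
        stringsAsFactors = FALSE)
    }
  }
  list(origins = origins,
       crossovers = if (truth) {
         if (length(co)) do.call(rbind, co) else empty_crossover_truth()
       } else NULL)
}

# Rejection step for gametic selection: accept each gamete with probability
# proportional to the product over selected loci of t (P1 realised) or 1 - t.
accept_gametic <- function(origins, map, gametic_selection) {
  n <- nrow(origins)
  if (is.null(gametic_selection) || !length(gametic_selection))
    return(rep(TRUE, n))
  p <- rep(1, n); pmaxv <- 1
  for (loc in names(gametic_selection)) {
    t1 <- gametic_selection[[loc]]
    j <- match(loc, map$locus)
    p <- p * ifelse(origins[, j] == 1L, t1, 1 - t1)
    pmaxv <- pmaxv * max(t1, 1 - t1)
  }
  if (pmaxv == 0) return(rep(FALSE, n))
  stats::runif(n) < p / pmaxv
}

#' Apply amplification dropout to a genotype matrix
#'
#' Each non-missing call is independently set to missing with probability
#' `rate`, emulating locus dropout of whole-genome-amplified single nuclei.
#'
#' @param gm a `genotype_matrix`.
#' @param rate dropout probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return a `genotype_matrix` with additional missing calls.
#' @export
apply_dropout <- function(gm, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(gm)
  with_seed(seed, {
    calls <- unclass(gm)
    pl <- ploidy(gm)
    idx <- which(!is.na(calls))
    drop <- idx[stats::runif(length(idx)) < rate]
    calls[drop] <- NA_character_
    attr(calls, "off_ladder") <- NULL
    genotype_matrix(calls, ploidy = pl)
  })
}

#' Simulate a diploid progeny population from paired gametes
#'
#' Pairs the i-th male gamete with the i-th female gamete and thins the
#' resulting zygotes by zygotic selection: each selected locus maps the
#' progeny's unordered genotype class to a survival probability (classes
#' not listed survive with probability 1), and the zygote survives a
#' Bernoulli draw on the product. This is how post-fertilization selection
#' (e.g. gametophytic incompatibility acting in the style, or differential
#' zygote viability) is emulated: the male gamete pool itself is untouched,
#' only the recovered progeny are filtered.
#'
#' @param male,female haploid `genotype_matrix` objects over the same loci.
#' @param zygotic_selection named list: locus -> named numeric vector
#'   mapping genotype class `"a/b"` (alleles sorted) to survival
#'   probability.
#' @param seed optional integer seed.
#' @return list with `progeny` (diploid `genotype_matrix` of survivors),
#'   `male_rows` and `female_rows` (indices of the surviving pairs).
#' @export
simulate_progeny <- function(male, female, zygotic_selection = NULL,
                             seed = NULL) {
  stopifnot(identical(colnames(male), colnames(female)),
            ploidy(male) == 1, ploidy(female) == 1)
  if (!is.null(zygotic_selection) &&
      !all(names(zygotic_selection) %in% colnames(male)))
    stop("zygotic_selection loci must name loci present in the matrices")
  n <- min(nrow(male), nrow(female))
  with_seed(seed, {
    mm <- unclass(male)[seq_len(n), , drop = FALSE]
    ff <- unclass(female)[seq_len(n), , drop = FALSE]
    geno <- matrix(paste(pmin(mm, ff), pmax(mm, ff), sep = "/"),
                   n, ncol(mm), dimnames = dimnames(mm))
    geno[is.na(mm) | is.na(ff)] <- NA_character_
    surv <- rep(1, n)
    for (loc in names(zygotic_selection)) {
      j <- match(loc, colnames(mm))
      s <- zygotic_selection[[loc]]
      g <- geno[, j]
      pj <- ifelse(is.na(g), 1, ifelse(g %in% names(s), s[g], 1))
      surv <- surv * pj
    }
    keep <- which(stats::runif(n) < surv)
    if (!length(keep))
      stop("no zygote survived zygotic selection; simulate more gametes")
    out <- geno[keep, , drop = FALSE]
    rownames(out) <- sprintf("H%03d", seq_along(keep))
    list(progeny = genotype_matrix(out, ploidy = 2),
         male_rows = keep, female_rows = keep)
  })
}

#' Build a synthetic genotype matrix with prescribed positive-call counts
#'
#' Constructs a haploid matrix whose i-th unit has exactly `n_positive[i]`
#' non-missing calls (the map's haplotype-P1 alleles, missing calls at the
#' panel's last loci). Used to reconstruct quality-control accounting from
#' published per-population totals when the per-call raw data are not
#' available; the QC rates depend only on the counts, not on which calls
#' are missing.
#'
#' @param n_positive integer vector of per-unit positive-call counts.
#' @param map a `marker_map` supplying the loci and fill-in alleles.
#' @param prefix unit-id prefix.
#' @return a haploid `genotype_matrix`.
#' @export
synthetic_qc_matrix <- function(n_positive, map, prefix = "U") {
  m <- nrow(map)
  stopifnot(all(n_positive >= 0), all(n_positive <= m))
  calls <- matrix(NA_character_, length(n_positive), m,
                  dimnames = list(sprintf("%s%03d", prefix,
                                          seq_along(n_positive)),
                                  map$locus))
  for (i in seq_along(n_positive))
    if (n_positive[i] > 0)
      calls[i, seq_len(n_positive[i])] <- map$p1_a1[seq_len(n_positive[i])]
  genotype_matrix(calls, ploidy = 1)
}
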