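test_that("mapping functions convert distance to recombination fraction", {
  expect_equal(recomb_fraction(0), 0)
  expect_equal(recomb_fraction(0, "kosambi"), 0)
  expect_equal(recomb_fraction(10, "haldane"), 0.5 * (1 - exp(-0.2)))
  expect_equal(recomb_fraction(10, "kosambi"), 0.5 * tanh(0.2))
  expect_equal(recomb_fraction(10000), 0.5, tolerance = 1e-12)
  expect_equal(recomb_fraction(10000, "kosambi"), 0.5, tolerance = 1e-12)
  expect_error(recomb_fraction(-1), "negative")
  d <- seq(0, 300, by = 5)
  expect_true(all(diff(recomb_fraction(d)) > 0))
  expect_true(all(recomb_fraction(d) < 0.5))
  # Kosambi rises faster than Haldane at short distances
  expect_true(recomb_fraction(10, "kosambi") > recomb_fraction(10, "haldane"))
})

test_that("simulated gametes have Mendelian origins and Markov switches", {
  map <- toy_map(c(0, 10, 10, 50))
  sim <- simulate_gametes(map, 10000, seed = 42, truth = TRUE)
  # each locus is P1 in about half the gametes (4 binomial SD bound)
  p1 <- colMeans(sim$origins == "P1")
  expect_true(all(abs(p1 - 0.5) < 4 * sqrt(0.25 / 10000)))
  # co-located markers (0 cM apart) always share an origin
  expect_true(all(sim$origins[, 2] == sim$origins[, 3]))
  # switch frequency across a 10 cM interval approximates Haldane r
  r <- recomb_fraction(10)
  sw <- mean(sim$origins[, 1] != sim$origins[, 2])
  expect_true(abs(sw - r) < 4 * sqrt(r * (1 - r) / 10000))
  # fixed seed implies bit-identical output
  sim2 <- simulate_gametes(map, 10000, seed = 42, truth = TRUE)
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_identical(sim$crossovers, sim2$crossovers)
})

test_that("origin switches iff an odd crossover count falls in the interval", {
  map <- toy_map(c(0, 30, 80, 81, 200))
  sim <- simulate_gametes(map, 400, seed = 5, truth = TRUE)
  for (i in seq_len(nrow(sim$origins))) {
    unit <- rownames(sim$origins)[i]
    co <- sim$crossovers[sim$crossovers$unit == unit, ]
    for (j in seq_len(nrow(map) - 1)) {
      n_co <- sum(co$interval == j)
      switched <- sim$origins[i, j] != sim$origins[i, j + 1]
      expect_identical(switched, n_co %% 2 == 1)
      if (n_co > 0) {
        pos <- co$pos_cm[co$interval == j]
        expect_true(all(pos >= map$cm[j] & pos <= map$cm[j + 1]))
      }
    }
  }
})

test_that("gametic selection biases transmission by rejection sampling", {
  map <- toy_map(c(0, 40, 100))
  sim <- simulate_gametes(map, 500, seed = 9,
                          gametic_selection = c(M2 = 1.0))
  # t = 1: every gamete carries the haplotype-P1 allele at the locus
  expect_true(all(unclass(sim$genotypes)[, "M2"] == "A"))
  # t = 0.9: transmitted fraction near 0.9, and linked locus hitchhikes
  sim <- simulate_gametes(map, 4000, seed = 10,
                          gametic_selection = c(M2 = 0.9))
  f2 <- mean(unclass(sim$genotypes)[, "M2"] == "A")
  expect_true(abs(f2 - 0.9) < 4 * sqrt(0.09 / 4000))
  f1 <- mean(unclass(sim$genotypes)[, "M1"] == "A")
  expect_true(f1 > 0.55)   # linked at 40 cM: pulled above 1/2
  expect_error(simulate_gametes(map, 10, seed = 1, max_batches = 2,
                                gametic_selection = c(M1 = 1, M2 = 0)),
               "rejection sampling|failed to accept")
})

test_that("selection power at t = 0.9, n = 86 matches the noncentral limit", {
  map <- toy_map(c(0, 200))
  nrep <- 300
  flags <- logical(nrep)
  set.seed(86)
  for (k in seq_len(nrep)) {
    sim <- simulate_gametes(map, 86, gametic_selection = c(M1 = 0.9),
                            truth = FALSE)
    cnt <- allele_counts(sim$genotypes, map, "p1")
    flags[k] <- sd_scan(cnt)$distorted[1]
  }
  power_mc <- mean(flags)
  # analytic check: exact binomial power, approximated by the noncentral
  # chi-square with ncp = n (2t - 1)^2
  a <- 0:86
  power_exact <- sum(dbinom(a, 86, 0.9)[(2 * a - 86)^2 / 86 >=
                                          qchisq(0.95, 1)])
  power_ncp <- pchisq(qchisq(0.95, 1), df = 1, ncp = 86 * 0.8^2,
                      lower.tail = FALSE)
  expect_true(abs(power_ncp - power_exact) < 0.01)
  expect_true(power_mc > 0.95)
  expect_true(abs(power_mc - power_exact) < 4 * sqrt(power_exact *
                                                       (1 - power_exact) / nrep))
})

test_that("dropout masks calls at the nominal rate and is idempotent on NA", {
  map <- toy_map(seq(0, 110, by = 10))
  sim <- simulate_gametes(map, 34, seed = 12, truth = FALSE)
  expect_identical(apply_dropout(sim$genotypes, 0), sim$genotypes)
  # rate 0.113 over 408 attempted calls: positives within 4 binomial SD of 362
  gm <- apply_dropout(sim$genotypes, 0.113, seed = 13)
  npos <- sum(!is.na(unclass(gm)))
  expect_true(abs(npos - 408 * 0.887) < 4 * sqrt(408 * 0.113 * 0.887))
  # all-missing matrix is unchanged at any rate
  allna <- genotype_matrix(matrix(NA_character_, 3, 12,
                                  dimnames = list(paste0("g", 1:3),
                                                  map$locus)))
  expect_identical(unclass(apply_dropout(allna, 0.5, seed = 1))[, ],
                   unclass(allna)[, ])
})

test_that("progeny simulation pairs gametes and applies zygotic thinning", {
  map <- toy_map(c(0, 25, 60))
  # give the second parent distinct alleles so decomposition is unequivocal
  df <- as.data.frame(map)
  df$p2_a1 <- "C"; df$p2_a2 <- "D"
  map <- marker_map(df, centromeres = centromeres(map))
  male <- simulate_gametes(map, 150, parent = "p1", seed = 21)$genotypes
  female <- simulate_gametes(map, 120, parent = "p2", seed = 22)$genotypes
  # no selection: progeny count equals the number of pairs
  pr <- simulate_progeny(male, female, seed = 23)
  expect_equal(nrow(pr$progeny), 120)
  expect_equal(ploidy(pr$progeny), 2)
  # determinism
  pr2 <- simulate_progeny(male, female, seed = 23)
  expect_identical(unclass(pr$progeny)[, ], unclass(pr2$progeny)[, ])
  # survival 0 for zygotes holding the male "B" allele at M2: excluded
  sel <- list(M2 = c("B/C" = 0, "B/D" = 0))
  pr3 <- simulate_progeny(male, female, zygotic_selection = sel, seed = 24)
  cnt <- allele_counts(pr3$progeny, map, "p1")
  expect_equal(cnt$a2[cnt$locus == "M2"], 0L)
  expect_gt(cnt$a1[cnt$locus == "M2"], 0L)
  # impossible selection: explicit error, not an empty matrix
  kill_all <- list(M2 = c("A/C" = 0, "A/D" = 0, "B/C" = 0, "B/D" = 0))
  expect_error(simulate_progeny(male, female, zygotic_selection = kill_all,
                                seed = 25),
               "no zygote survived")
})
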