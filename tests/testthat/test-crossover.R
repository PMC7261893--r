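test_that("switch detection walks informative markers with the skip rule", {
  map <- toy_map(c(0, 10, 20, 30), centromere = 15)
  om <- as_origin(rbind(
    g1 = c("P1", "P1", "P2", "P2"),
    g2 = c("P1", "MISSING", "P1", "P1"),
    g3 = c("P1", "MISSING", "P2", "P2"),
    g4 = c("P2", "AMBIGUOUS", "OFF_LADDER", "MISSING")),
    loci = map$locus)
  sw <- detect_switches(om, map, 1)
  expect_setequal(sw$gametes_analyzed, c("g1", "g2", "g3"))
  expect_equal(sw$excluded$unit, "g4")
  expect_match(sw$excluded$reason, "1 informative")
  ob <- sw$observations
  # g1: one switch between markers 2 and 3
  g1 <- ob[ob$unit == "g1" & ob$switch, ]
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$left_idx, g1$right_idx), c(2L, 3L))
  # g2: markers 1 vs 3 compared across the missing point, no switch
  expect_equal(sum(ob$switch[ob$unit == "g2"]), 0)
  expect_true(any(ob$unit == "g2" & ob$left_idx == 1 & ob$right_idx == 3))
  # g3: one switch on the merged interval 1-3
  g3 <- ob[ob$unit == "g3" & ob$switch, ]
  expect_equal(c(g3$left_idx, g3$right_idx), c(1L, 3L))
})

test_that("switches are assigned to arms by the centromere rule", {
  # centromere at 15; interval (10,30) spans it with the larger share distal
  map <- toy_map(c(0, 10, 30), centromere = 15)
  om <- as_origin(rbind(g1 = c("P1", "P1", "P2")), loci = map$locus)
  cs <- count_per_arm(detect_switches(om, map, 1))
  expect_equal(cs$per_gamete$arm2, 1L)
  expect_equal(cs$per_gamete$arm1, 0L)
  # exact tie goes to arm 1
  map_tie <- toy_map(c(0, 10, 20), centromere = 15)
  cs <- count_per_arm(detect_switches(om, map_tie, 1))
  expect_equal(cs$per_gamete$arm1, 1L)
  # fully proximal and fully distal switches land on their own arms
  om2 <- as_origin(rbind(g1 = c("P1", "P2", "P2", "P1")),
                   loci = toy_map(c(0, 5, 20, 30))$locus)
  cs <- count_per_arm(detect_switches(om2, toy_map(c(0, 5, 20, 30),
                                                   centromere = 10), 1))
  expect_equal(c(cs$per_gamete$arm1, cs$per_gamete$arm2), c(1L, 1L))
  expect_error(count_per_arm(detect_switches(om2, toy_map(c(0, 5, 20, 30)),
                                             1)),
               "centromere")
  # a single gamete with no switches: distribution {(0,0): 1}, mean 0
  om3 <- as_origin(rbind(g1 = c("P1", "P1", "P1")), loci = map$locus)
  cs <- count_per_arm(detect_switches(om3, map, 1))
  expect_equal(cs$distribution, data.frame(arm1 = 0L, arm2 = 0L, n = 1L))
  expect_equal(cs$mean_co_per_chromosome, 0)
})

test_that("published chromosome-1 cross-tab yields its summary statistics", {
  cs <- crossover_summary(expand_crosstab(arm_crosstab()))
  expect_equal(cs$n_gametes_analyzed, 34)
  expect_equal(cs$mean_co_per_chromosome, 67 / 34)
  expect_equal(round(cs$mean_co_per_chromosome, 2), 1.97)
  expect_equal(cs$zero_co_fraction, 5 / 34)
  expect_equal(max_crossovers(cs), c(max_arm1 = 5L, max_arm2 = 4L))
  expect_error(max_crossovers(crossover_summary(
    data.frame(unit = character(0), arm1 = integer(0), arm2 = integer(0)))),
    "empty")
  one <- crossover_summary(data.frame(unit = "g", arm1 = 2L, arm2 = 3L))
  expect_equal(max_crossovers(one), c(max_arm1 = 2L, max_arm2 = 3L))
})

test_that("interval recombination ratios follow n(CO)/n(M) with guards", {
  map <- toy_map(c(0, 10, 20), centromere = 5)
  om <- as_origin(rbind(
    g1 = c("P1", "P1", "P2"),
    g2 = c("P1", "P1", "P1"),
    g3 = c("P2", "P2", "P2")), loci = map$locus)
  ir <- interval_recombination(om, map, 1)
  expect_equal(ir$co_ratio, c(0, 1 / 3))
  # an uncovered interval reports NaN, not zero
  om2 <- as_origin(rbind(g1 = c("P1", "MISSING", "MISSING"),
                         g2 = c("P2", "MISSING", "MISSING")),
                   loci = map$locus)
  sw2 <- detect_switches(om2, map, 1)
  expect_equal(sw2$gametes_analyzed, character(0))
  ir2 <- interval_recombination(sw2, map, 1)
  expect_true(all(is.nan(ir2$co_ratio)))
  expect_equal(ir2$n_informative, c(0L, 0L))
  # a merged observation covers both elementary intervals it spans and its
  # switch goes to the longest one
  map3 <- toy_map(c(0, 2, 30), centromere = 5)
  om3 <- as_origin(rbind(g1 = c("P1", "MISSING", "P2")), loci = map3$locus)
  ir3 <- interval_recombination(om3, map3, 1)
  expect_equal(ir3$n_informative, c(1L, 1L))
  expect_equal(ir3$n_co, c(0L, 1L))
  # under the flank-exact denominator, merged observations are left out
  ir4 <- interval_recombination(om3, map3, 1, denominator = "adjacent")
  expect_equal(ir4$n_informative, c(0L, 0L))
})

test_that("detected switches are conserved across summaries and relabeling", {
  map <- eureka_map()
  sim <- simulate_gametes(map, 60, seed = 44, dropout_rate = 0.12)
  om <- assign_origin(sim$genotypes, map, phase_from_map(map, "p1"))
  sw <- detect_switches(om, map, 1)
  total_switches <- sum(sw$observations$switch)
  ir <- interval_recombination(sw, map, 1)
  expect_equal(sum(ir$n_co), total_switches)
  cs <- count_per_arm(sw)
  expect_equal(sum(cs$per_gamete$total), total_switches)
  expect_equal(sum(cs$distribution$n), cs$n_gametes_analyzed)
  # a gamete can show at most (informative markers - 1) switches
  inf_count <- apply(unclass(om), 1, function(r) sum(r %in% c("P1", "P2")))
  for (i in seq_len(nrow(cs$per_gamete)))
    expect_lte(cs$per_gamete$total[i],
               inf_count[cs$per_gamete$unit[i]] - 1)
  # swapping P1/P2 labels leaves every count unchanged
  om_sw <- unclass(om)
  om_sw[unclass(om) == "P1"] <- "P2"
  om_sw[unclass(om) == "P2"] <- "P1"
  cs2 <- count_per_arm(detect_switches(as_origin(om_sw), map, 1))
  expect_equal(cs2$per_gamete, cs$per_gamete)
})

test_that("detected switches equal the parity of true crossover counts", {
  map <- eureka_map()
  sim <- simulate_gametes(map, 200, seed = 45, dropout_rate = 0)
  om <- assign_origin(sim$genotypes, map, phase_from_map(map, "p1"))
  ob <- detect_switches(om, map, 1)$observations
  # brute force: recount true crossovers inside every observation interval
  for (i in seq_len(nrow(ob))) {
    co <- sim$crossovers
    n_true <- sum(co$unit == ob$unit[i] &
                    co$pos_cm > ob$left_cm[i] & co$pos_cm < ob$right_cm[i])
    expect_identical(ob$switch[i], n_true %% 2 == 1)
  }
})
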