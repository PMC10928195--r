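test_that("multiple harvests sum to annual yields and bad records are rejected", {
  two <- rbind(rec("s1", "p1", 2, "spA", 120, harvest = 1),
               rec("s1", "p1", 2, "spA", 80, harvest = 2))
  expect_equal(aggregate_annual_yield(two)$biomass_g_m2, 200)

  one <- rec("s1", "p1", 2, "spA", 55)
  out <- aggregate_annual_yield(one)
  expect_equal(out$biomass_g_m2, 55)
  expect_equal(nrow(out), 1)

  three <- rbind(rec("s1", "p1", 2, "spA", 10, harvest = 1),
                 rec("s1", "p1", 2, "spA", 0, harvest = 2),
                 rec("s1", "p1", 2, "spA", 5, harvest = 3))
  expect_equal(aggregate_annual_yield(three)$biomass_g_m2, 15)

  dup <- rbind(rec("s1", "p1", 2, "spA", 10), rec("s1", "p1", 2, "spA", 12))
  expect_error(aggregate_annual_yield(dup), "duplicate harvest")
  expect_error(aggregate_annual_yield(rec("s1", "p1", 2, "spA", -3)),
               "negative")
})

test_that("monoculture reference averages replicates and applies the adjustment", {
  d <- rbind(rec("s1", "m1", 2, "spA", 90), rec("s1", "m2", 2, "spA", 110))
  expect_equal(monoculture_reference(d, adjustment_c = 1)$M, 101)
  expect_equal(monoculture_reference(d, adjustment_c = 0)$M, 100)

  zero <- rec("s1", "m1", 2, "spA", 0)
  expect_equal(monoculture_reference(zero, adjustment_c = 1)$M, 1)

  d2 <- rbind(rec("s1", "m1", 2, "spA", 100), rec("s1", "m2", 2, "spA", 200))
  expect_equal(monoculture_reference(d2, adjustment_c = 0)$M, 150)

  expect_error(monoculture_reference(d, adjustment_c = -1), "non-negative")

  # year-averaged policy pools years; per-year policy keeps them apart
  d3 <- rbind(rec("s1", "m1", 2, "spA", 100), rec("s1", "m1", 3, "spA", 200))
  expect_equal(nrow(monoculture_reference(d3, 0, "study_treatment")), 1)
  expect_equal(monoculture_reference(d3, 0, "study_treatment")$M, 150)
  expect_equal(nrow(monoculture_reference(d3, 0, "study_year_treatment")), 2)
})

test_that("two-species worked example matches the brute-force oracle exactly", {
  Y <- c(80, 90); M <- c(100, 200); ry_e <- c(0.5, 0.5)
  p <- partition_effects(Y, M, ry_e)
  expect_equal(p$nbe, 20, tolerance = 1e-12)
  expect_equal(p$ce, 37.5, tolerance = 1e-12)
  expect_equal(p$se, -17.5, tolerance = 1e-12)
  expect_equal(p$ryt, 1.25, tolerance = 1e-12)
  o <- oracle_partition(Y, M, ry_e)
  expect_equal(p$nbe, o$nbe)
  expect_equal(p$ce, o$ce)
  expect_equal(p$se, o$se)
  expect_equal(p$per_species$ry, c(0.80, 0.45))
  expect_equal(p$per_species$delta_ry, c(0.30, -0.05))
})

test_that("null and degenerate communities partition as expected", {
  # mixtures exactly at expectation: all effects vanish
  M <- c(120, 310, 80); ry_e <- c(0.2, 0.5, 0.3)
  p0 <- partition_effects(ry_e * M, M, ry_e)
  expect_equal(p0$nbe, 0); expect_equal(p0$ce, 0); expect_equal(p0$se, 0)
  expect_equal(p0$per_species$delta_ry, rep(0, 3))

  # constant delta RY: zero covariance with M, all effect is complementarity
  M <- c(100, 200); d <- 0.1
  p1 <- partition_effects((c(0.5, 0.5) + d) * M, M, c(0.5, 0.5))
  expect_equal(p1$nbe, 30); expect_equal(p1$ce, 30); expect_equal(p1$se, 0)

  # identical monoculture means: zero variance forces SE = 0
  p2 <- partition_effects(c(90, 150), c(200, 200), c(0.5, 0.5))
  expect_equal(p2$se, 0)

  expect_error(partition_effects(80, 100, 1), "fewer than 2")
  expect_error(partition_effects(c(80, 90), c(100, 200), c(0.6, 0.6)),
               "sum to 1")
})

test_that("partition identities hold on randomly generated communities", {
  set.seed(41)
  for (i in 1:300) {
    cm <- random_community()
    p <- partition_effects(cm$Y, cm$M, cm$ry_e)
    # exact additivity NBE = CE + SE
    expect_lt(abs(p$nbe - (p$ce + p$se)), 1e-9 * max(1, abs(p$nbe)))
    # covariance route equals the identity route
    o <- oracle_partition(cm$Y, cm$M, cm$ry_e)
    expect_equal(p$se, o$nbe - o$ce, tolerance = 1e-12)
    # scale equivariance (c = 0): k scales all three effects
    k <- runif(1, 0.1, 10)
    pk <- partition_effects(k * cm$Y, k * cm$M, cm$ry_e)
    expect_equal(pk$nbe, k * p$nbe, tolerance = 1e-9)
    expect_equal(pk$ce, k * p$ce, tolerance = 1e-9)
    expect_equal(pk$se, k * p$se, tolerance = 1e-9)
    # permutation invariance
    perm <- sample(cm$n)
    pp <- partition_effects(cm$Y[perm], cm$M[perm], cm$ry_e[perm])
    expect_equal(pp$nbe, p$nbe); expect_equal(pp$ce, p$ce)
    expect_equal(pp$se, p$se); expect_equal(pp$ryt, p$ryt)
  }
})

test_that("larger monoculture adjustment weakly shrinks relative yields", {
  set.seed(42)
  for (i in 1:50) {
    cm <- random_community()
    for (cs in list(c(0, 1), c(1, 5))) {
      ry_lo <- cm$Y / (cm$M + cs[1])
      ry_hi <- cm$Y / (cm$M + cs[2])
      expect_true(all(abs(ry_hi) <= abs(ry_lo) + 1e-12))
    }
  }
})

test_that("batch partition applies the drop and flag policy", {
  mk_plot <- function(plot, spA, spB) rbind(
    rec("s1", plot, 2, "spA", spA, prop = 0.5),
    rec("s1", plot, 2, "spB", spB, prop = 0.5))
  monos_d <- rbind(rec("s1", "mA", 2, "spA", 100),
                   rec("s1", "mB", 2, "spB", 200))
  d <- rbind(monos_d, mk_plot("p1", 80, 90), mk_plot("p2", 50, 100),
             mk_plot("p3", 60, 120))
  mono_tab <- monoculture_reference(d, adjustment_c = 0)
  res <- batch_partition(d, mono_tab)
  expect_equal(nrow(res), 3)
  expect_equal(nrow(attr(res, "drops")), 0)
  expect_equal(res$nbe[res$plot_id == "p1"], 20)

  # a sown species without a monoculture drops the plot-year, flagged
  d2 <- rbind(d, rbind(rec("s1", "p4", 2, "spC", 30, prop = 0.5),
                       rec("s1", "p4", 2, "spA", 30, prop = 0.5)))
  res2 <- batch_partition(d2, monoculture_reference(d2, 0))
  expect_equal(nrow(res2), 3)
  drops <- attr(res2, "drops")
  expect_equal(drops$plot_id, "p4")
  expect_equal(drops$reason, "missing_monoculture")

  # an unsown invader is excluded from the algebra and flagged; the result
  # equals the partition of the same plot with the invader row deleted
  d3 <- rbind(d, rec("s1", "p1", 2, "weed", 5, sown = 0, prop = 0))
  res3 <- batch_partition(d3, monoculture_reference(d3, 0))
  r1 <- res3[res3$plot_id == "p1", ]
  expect_match(r1$flags, "unsown_invader")
  expect_equal(r1$nbe, res$nbe[res$plot_id == "p1"])
  expect_equal(r1$ce, res$ce[res$plot_id == "p1"])

  # empty input is not an error
  e <- batch_partition(d[0, ], mono_tab)
  expect_equal(nrow(e), 0)
})

test_that("fallback monoculture matching is used and flagged", {
  # monoculture present in year 2 only; mixture observed in year 3
  d <- rbind(rec("s1", "mA", 2, "spA", 100), rec("s1", "mB", 2, "spB", 200),
             rec("s1", "mA", 3, "spA", 110),
             rbind(rec("s1", "p1", 3, "spA", 80, prop = 0.5),
                   rec("s1", "p1", 3, "spB", 90, prop = 0.5)))
  primary <- monoculture_reference(d, 0, "study_year_treatment")
  fallback <- monoculture_reference(d, 0, "study_treatment")
  # primary alone: spB has no year-3 monoculture -> dropped
  r1 <- batch_partition(d, primary)
  expect_equal(nrow(r1), 0)
  # with the year-averaged fallback the plot is rescued and flagged
  r2 <- batch_partition(d, list(primary, fallback))
  expect_equal(nrow(r2), 1)
  expect_match(r2$flags, "mono_fallback_study_treatment")
})
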