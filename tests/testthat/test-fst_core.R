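test_that("nc follows the unequal-sample-size formula", {
  expect_equal(compute_nc(c(10, 10, 10)), 10)
  expect_equal(compute_nc(c(1, 1)), 1)
  # the nine study sample sizes: S1 = 235, S2 = 6523
  sizes <- c(35, 22, 23, 25, 24, 40, 18, 26, 22)
  expect_equal(sum(sizes), 235)
  expect_equal(sum(sizes^2), 6523)
  expect_equal(compute_nc(sizes), (235 - 6523 / 235) / 8, tolerance = 1e-12)
  expect_equal(compute_nc(sizes), 25.90532, tolerance = 1e-6)
  # empty groups are dropped before the formula
  expect_equal(compute_nc(c(10, 0, 10, 0, 10)), 10)
  expect_error(compute_nc(c(5, 0)), "insufficient populations")
})

test_that("per-population locus statistics match hand tallies", {
  # pop of 3 with dosages {0, 1, 1}: p = 2/6, h = 2/3
  ds <- toy_dataset(matrix(c(0L, 1L, 1L, 2L, 2L, 1L), 6, 1),
                    rep(c("P1", "P2"), each = 3))
  st <- pop_locus_stats(ds, all_pop_grouping(ds), 1)
  expect_equal(st$p, c(2 / 6, 5 / 6), tolerance = 1e-12)
  expect_equal(st$h, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(st$p_bar, 7 / 12, tolerance = 1e-12)
  expect_equal(st$sizes, c(3, 3))

  # a fully missing population is dropped and n decremented
  calls <- matrix(c(0L, 1L, NA, NA, 2L, 2L), 6, 1)
  ds <- toy_dataset(calls, rep(c("P1", "P2", "P3"), each = 2))
  st <- pop_locus_stats(ds, all_pop_grouping(ds), 1)
  expect_equal(st$n, 2L)
  expect_equal(st$pop_names, c("P1", "P3"))

  ds <- toy_dataset(matrix(c(0L, 1L, NA, NA), 4, 1),
                    rep(c("P1", "P2"), each = 2))
  expect_error(pop_locus_stats(ds, all_pop_grouping(ds), 1),
               "insufficient populations")
})

test_that("analytic limits: fixed difference gives 1, all-heterozygote gives 0", {
  ds <- toy_dataset(cbind(c(0L, 0L, 0L, 2L, 2L, 2L), rep(1L, 6)),
                    rep(c("P1", "P2"), each = 3))
  grp <- all_pop_grouping(ds)
  fix <- fst_locus(ds, grp, 1)
  expect_identical(fix$fst, 1)        # MSI = MSG = 0 => MSP/MSP
  expect_equal(fix$MSI, 0)
  expect_equal(fix$MSG, 0)
  het <- fst_locus(ds, grp, 2)
  expect_identical(het$fst, 0)        # numerator 0, denominator nc * 0.5
  expect_equal(het$MSG, 0.5)
  expect_equal(het$MSP, 0)
})

test_that("estimator equals the gamete-expansion oracle on random data", {
  set.seed(77)
  for (r in 1:60) {
    n_pops <- sample(2:6, 1)
    ds <- random_dataset(n_pops, sample(2:30, n_pops, replace = TRUE),
                         L = 4, miss_rate = stats::runif(1, 0, 0.3))
    grp <- all_pop_grouping(ds)
    tab <- fst_scan(ds, grp)
    for (j in seq_len(4)) {
      o <- oracle_fst(ds$calls[, j], ds$individuals$breed)
      rec <- fst_locus(ds, grp, j)
      expect_identical(is.na(rec$fst), is.na(o))
      if (!is.na(o)) {
        expect_equal(rec$fst, o, tolerance = 1e-12)
        expect_equal(tab$fst[j], o, tolerance = 1e-12)
      }
    }
  }
})

test_that("fst is invariant to population labels and allele swapping", {
  set.seed(13)
  ds <- random_dataset(4, c(6, 9, 5, 12), L = 20, miss_rate = 0.1)
  grp <- all_pop_grouping(ds)
  base <- fst_scan(ds, grp)$fst

  # permute breed labels (relabelling populations)
  perm <- c(B01 = "Q3", B02 = "Q1", B03 = "Q4", B04 = "Q2")
  ds2 <- ds
  ds2$individuals$breed <- unname(perm[ds$individuals$breed])
  expect_equal(fst_scan(ds2, all_pop_grouping(ds2))$fst, base,
               tolerance = 1e-12)

  # count the other allele: dosage -> 2 - dosage
  ds3 <- ds
  ds3$calls <- 2L - ds$calls
  expect_equal(fst_scan(ds3, grp)$fst, base, tolerance = 1e-12)
})

test_that("defined fst never exceeds 1 and hits 1 only with zero within-variance", {
  set.seed(19)
  for (r in 1:20) {
    ds <- random_dataset(3, c(5, 8, 11), L = 10, miss_rate = 0.2)
    tab <- fst_scan(ds)
    def <- !is.na(tab$fst)
    expect_true(all(tab$fst[def] <= 1 + 1e-12))
    at_one <- def & abs(tab$fst - 1) < 1e-12
    expect_true(all(tab$MSI[at_one] == 0 & tab$MSG[at_one] == 0))
  }
})

test_that("an entirely-missing individual does not change a locus estimate", {
  set.seed(23)
  ds <- random_dataset(3, c(6, 7, 8), L = 5, miss_rate = 0)
  ds$calls[3, ] <- NA
  with_ind <- fst_scan(ds)$fst
  ds2 <- toy_dataset(ds$calls[-3, , drop = FALSE],
                     ds$individuals$breed[-3])
  expect_equal(fst_scan(ds2)$fst, with_ind, tolerance = 1e-12)
})

test_that("monomorphic loci are UNDEFINED and excluded from the summary", {
  calls <- cbind(rep(1L, 8), rep(0L, 8), c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L))
  ds <- toy_dataset(calls, rep(c("P1", "P2"), each = 4))
  tab <- fst_scan(ds)
  expect_true(is.na(tab$fst[2]))       # monomorphic
  expect_false(is.na(tab$fst[1]))
  s <- attr(tab, "summary")
  expect_equal(s$n_defined, 2L)
  expect_equal(s$mean, mean(tab$fst, na.rm = TRUE))

  # single-individual populations: MSI has no degrees of freedom
  ds1 <- toy_dataset(matrix(c(0L, 2L), 2, 1), c("P1", "P2"))
  expect_true(is.na(fst_locus(ds1, all_pop_grouping(ds1), 1)$fst))
})

test_that("merged groupings pool breeds into single populations", {
  sizes <- c(LC = 40, WZS = 25, BM = 22, LW = 23)
  breeds <- rep(names(sizes), sizes)
  set.seed(3)
  calls <- matrix(rbinom(110 * 6, 2, 0.4), 110, 6)
  ds <- toy_dataset(calls, breeds)

  grp <- merge_grouping(names(sizes),
                        c(LC = "South", WZS = "South", BM = "South",
                          LW = "North"),
                        name = "NORTH_VS_SOUTH")
  expect_equal(grp$n_pops, 2L)
  st <- pop_locus_stats(ds, grp, 1)
  expect_equal(st$sizes[st$pop_names == "South"], 87)

  # identity map reproduces the per-breed grouping
  ident <- merge_grouping(names(sizes), stats::setNames(names(sizes),
                                                        names(sizes)))
  expect_equal(fst_scan(ds, ident)$fst,
               fst_scan(ds, all_pop_grouping(ds))$fst, tolerance = 1e-12)

  expect_error(merge_grouping(c("LC", "XX"), c(LC = "South")),
               "not assigned.*XX")

  # NA values exclude a breed from the contrast
  part <- merge_grouping(names(sizes),
                         c(LC = "South", WZS = "South", BM = NA, LW = "North"))
  st <- pop_locus_stats(ds, part, 1)
  expect_equal(sum(st$sizes), 88)
})

test_that("between-group divergence raises pooled two-group fst at planted loci", {
  cfg <- sim_config(n_loci = 300, n_selected = 30, seed = 41)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  two <- merge_grouping(sort(unique(ds$individuals$breed)),
                        c(TC = "CHN", BM = "CHN", LW = "CHN", WZS = "CHN",
                          NX = "CHN", LC = "CHN", YT = "CHN",
                          Landrace = "EURO", LargeWhite = "EURO"),
                        name = "CHN_VS_EURO")
  t_all <- fst_scan(ds)
  t_two <- fst_scan(ds, two)
  sel <- sim$truth$is_selected
  expect_true(mean(t_two$fst[sel]) > mean(t_all$fst[sel]))
  expect_gt(mean(t_two$fst[sel]), 0.9)
})
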