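test_that("pooled MAF matches hand counts, including under missingness", {
  # 10 individuals: 6 hom-ref, 3 het, 1 hom-alt -> f = 5/20
  ds <- toy_dataset(matrix(c(rep(0L, 6), rep(1L, 3), 2L), 10, 1),
                    rep(c("P1", "P2"), each = 5))
  expect_equal(compute_maf(ds, 1), 0.25)

  expect_equal(compute_maf(toy_dataset(matrix(0L, 10, 1), rep("P", 10)), 1), 0)

  # 4 missing of 10, remaining dosages {0,0,0,1,1,2}: f = 4/12
  ds <- toy_dataset(matrix(c(NA, NA, NA, NA, 0L, 0L, 0L, 1L, 1L, 2L), 10, 1),
                    rep("P", 10))
  expect_equal(compute_maf(ds, 1), 1 / 3, tolerance = 1e-12)

  ds <- toy_dataset(matrix(NA_integer_, 4, 1), rep("P", 4))
  expect_error(compute_maf(ds, 1), "all calls missing")
})

test_that("filters are applied sequentially with exact boundary behaviour", {
  # marker 1 unmapped; marker 2 MAF exactly 0.05 (1/20) -> retained;
  # marker 3 MAF 0.025 < 0.05 -> removed; marker 4 call rate exactly 0.90
  # -> retained; marker 5 call rate 0.80 -> removed
  calls <- cbind(rep(1L, 10),
                 c(1L, rep(0L, 9)),
                 c(rep(0L, 9), NA),       # 0/18 = 0 < 0.05
                 c(rep(1L, 9), NA),
                 c(rep(1L, 8), NA, NA))
  ds <- genotype_dataset(
    calls, data.frame(individual_id = sprintf("i%d", 1:10), breed = "B"),
    data.frame(chrom = c("0", "1", "1", "1", "1"),
               marker_id = sprintf("m%d", 1:5),
               pos_bp = c(0L, 100L, 200L, 300L, 400L),
               allele_a1 = "A", allele_a2 = "G"))
  out <- run_qc(ds)
  expect_equal(out$report$n_removed_unmapped, 1L)
  expect_equal(out$report$n_removed_maf, 1L)
  expect_equal(out$report$n_removed_callrate, 1L)
  expect_equal(out$report$n_output, 2L)
  expect_equal(out$dataset$markers$marker_id, c("m2", "m4"))
  # marker order is genome-sorted, so the unmapped marker sits last
  expect_equal(out$report$removed$reason,
               c("low_maf", "low_callrate", "unmapped"))
  expect_equal(out$report$removed$marker_id, c("m3", "m5", "m1"))
})

test_that("call-rate boundary at 235 individuals matches the 90% rule", {
  mk <- function(n_missing) {
    calls <- matrix(rep(c(0L, 1L), length.out = 235), 235, 1)
    if (n_missing > 0) calls[seq_len(n_missing), 1] <- NA
    toy_dataset(calls, rep(c("P1", "P2"), length.out = 235))
  }
  # 212/235 = 0.9021 retained; 211/235 = 0.8979 removed
  expect_equal(run_qc(mk(23))$report$n_removed_callrate, 0L)
  expect_equal(run_qc(mk(24))$report$n_removed_callrate, 1L)
})

test_that("planted defect counts are recovered exactly from the simulator", {
  cfg <- sim_config(n_loci = 5000, n_unmapped = 500, n_low_maf = 300,
                    n_low_callrate = 200, seed = 31)
  sim <- simulate_dataset(cfg)
  out <- run_qc(sim$dataset)
  expect_equal(out$report$n_removed_unmapped, 500L)
  expect_equal(out$report$n_removed_maf, 300L)
  expect_equal(out$report$n_removed_callrate, 200L)
  expect_equal(out$report$n_output, 4000L)
  expect_equal(out$report$n_input -
                 with(out$report, n_removed_unmapped + n_removed_maf +
                        n_removed_callrate),
               out$report$n_output)

  # removed marker ids match the truth table classes
  truth <- sim$truth
  for (cls in c("unmapped", "low_maf", "low_callrate")) {
    expect_setequal(out$report$removed$marker_id[out$report$removed$reason == cls],
                    truth$marker_id[truth$defect_class == cls])
  }
})

test_that("QC is idempotent and preserves marker order", {
  set.seed(5)
  sim <- simulate_dataset(sim_config(n_loci = 800, n_unmapped = 50,
                                     n_low_maf = 30, n_low_callrate = 20,
                                     seed = 5))
  out1 <- run_qc(sim$dataset)
  out2 <- run_qc(out1$dataset)
  expect_equal(out2$report$n_removed_unmapped, 0L)
  expect_equal(out2$report$n_removed_maf, 0L)
  expect_equal(out2$report$n_removed_callrate, 0L)
  expect_equal(out2$dataset$markers, out1$dataset$markers)
  # survivors keep their relative order
  expect_true(!is.unsorted(match(out1$dataset$markers$marker_id,
                                 sim$dataset$markers$marker_id)))

  empty <- genotype_dataset(matrix(integer(), 0, 0),
                            data.frame(individual_id = character(),
                                       breed = character()),
                            data.frame(chrom = character(),
                                       marker_id = character(),
                                       pos_bp = integer(),
                                       allele_a1 = character(),
                                       allele_a2 = character()))
  expect_error(run_qc(empty), "non-empty")
})
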