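test_that("snapshot cohort reduces to the population curve without heterogeneity", {
  sc <- generate_snapshot_cohort(n_per_level = 50, cv_basal = 0,
                                 cv_amplitude = 0, noise_sd_afu = 0,
                                 noise_sd_nf = 0, seed = 1)
  curve <- function(conc) 135 + 300 / (1 + 10^(1 * (-8.24 - log10(conc))))
  for (cc in c(1e-10, 1e-8, 1e-6)) {
    expect_equal(unique(sc$ppERK[sc$concentration == cc]), curve(cc),
                 tolerance = 1e-12)
  }
  expect_equal(unique(sc$ppERK[sc$concentration == 0]), 135)
})

test_that("the response at EC50 is half-maximal within Monte Carlo error", {
  sc <- generate_snapshot_cohort(concentrations = c(0, 10^-8.24, 1e-5),
                                 n_per_level = 4000, seed = 2)
  m <- tapply(sc$ppERK, sc$concentration, mean)
  expect_equal(unname(m[2]), 135 + 300 / 2, tolerance = 8)
})

test_that("the population dose-response is monotone and noise degrades information", {
  sc <- generate_snapshot_cohort(n_per_level = 400, seed = 3)
  m <- tapply(sc$ppERK, sc$concentration, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > -5))

  mis <- vapply(c(5, 60, 200), function(ns) {
    d <- generate_snapshot_cohort(n_per_level = 400, noise_sd_afu = ns,
                                  seed = 4)
    mutual_information(d, "stimulus", "ppERK")$value
  }, numeric(1))
  expect_true(all(diff(mis) < 0))
  expect_true(all(mis > 0 & mis < 3))
})

test_that("MI is invariant to the affine fluorescence scale", {
  sc <- generate_snapshot_cohort(n_per_level = 300, seed = 5)
  a <- mutual_information(sc, "stimulus", "ppERK")
  sc$ppERK <- 3.7 * sc$ppERK + 1000
  b <- mutual_information(sc, "stimulus", "ppERK")
  expect_identical(a$value, b$value)
})

test_that("joint sensing of the paired readouts beats either alone", {
  sc <- generate_snapshot_cohort(n_per_level = 700, seed = 6)
  jm <- joint_mi(sc, "stimulus", c("ppERK", "nfat_nf"))
  m1 <- mutual_information(sc, "stimulus", "ppERK")
  m2 <- mutual_information(sc, "stimulus", "nfat_nf")
  expect_gt(jm$value, max(m1$value, m2$value) - 3 * jm$sd)
  expect_true(m1$value < 1 & m2$value < 1)  # the sub-1-bit regime
})

test_that("tracked cohorts equal the hybrid run when noiseless and pass QC at defaults", {
  p <- default_parameters()
  tc0 <- generate_tracked_cohort(p, concentrations = c(0, 1e-7),
                                 n_per_level = 20, noise_sd = 0, seed = 7)
  run <- hybrid_simulate(p, pulse_protocol(60, 0), 60, n_cells = 20,
                         fl = 1e4, cv_R = default_effector_cv(),
                         cv_M = default_effector_cv(), seed = 7,
                         out_dt = 2.5)
  first <- tc0[tc0$cell_id == 1, ]
  expect_equal(first$nfat_nf[order(first$t_min)], unname(run$nfat_nf[1, ]),
               tolerance = 1e-12)

  tc <- generate_tracked_cohort(n_per_level = 200, seed = 8)
  q <- qc_filter(tc)
  expect_gte(1 - q$removed / 800, 0.9)

  # population mean at 1e-7 M peaks within 15-60 minutes
  hi <- tc[tc$concentration == 1e-7, ]
  mtrace <- tapply(hi$nfat_nf, hi$t_min, mean)
  tpk <- as.numeric(names(which.max(mtrace)))
  expect_gte(tpk, 15)
  expect_lte(tpk, 60)
})

test_that("the QC gate removes exactly the printed strict-inequality violations", {
  t0 <- c(0.39, 0.40, 0.45, 0.55, 0.56, 0.399999, 0.550001)
  cohort <- data.frame(cell_id = rep(seq_along(t0), 2),
                       t_min = rep(c(0, 5), each = length(t0)),
                       nfat_nf = c(t0, t0 + 0.01))
  q <- qc_filter(cohort)
  expect_equal(sort(q$removed_ids), c(1, 5, 6, 7))
  expect_equal(q$removed, 4)
  all_in <- data.frame(cell_id = 1:5, t_min = 0, nfat_nf = rep(0.45, 5))
  expect_equal(qc_filter(all_in)$removed, 0)
})

test_that("frame stacks: static fields, births and determinism", {
  fs0 <- generate_frames(n_cells = 20, n_frames = 5, displacement_px = 0,
                         seed = 9)
  for (f in 2:5) expect_identical(fs0[[f]], fs0[[1]])

  set.seed(1)
  births <- replicate(20, {
    fs <- generate_frames(n_cells = 10, n_frames = 6, birth_rate = 2,
                          seed = sample.int(1e6, 1))
    nrow(fs[[6]]) - nrow(fs[[1]])
  })
  expect_gt(mean(births), 0)

  a <- generate_frames(n_cells = 15, n_frames = 4, seed = 11)
  b <- generate_frames(n_cells = 15, n_frames = 4, seed = 11)
  expect_identical(a, b)
})
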