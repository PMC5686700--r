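# helpers to build stimulus/response tables
make_sample <- function(s, ...) data.frame(stimulus = as.character(s), ...)

test_that("a noiseless injective 8-level channel carries 3 bits", {
  s <- rep(1:8, each = 1e4)
  d <- make_sample(s, z1 = as.numeric(s))
  est <- mutual_information(d, "stimulus", "z1")
  expect_equal(est$value, 3, tolerance = 0.02)
})

test_that("independent response carries no information; shuffling destroys it", {
  set.seed(21)
  s <- rep(1:4, each = 500)
  d <- make_sample(s, z1 = stats::rnorm(2000))
  est <- mutual_information(d, "stimulus", "z1")
  expect_lt(abs(est$value), 3 * est$sd)

  # permutation null on a strongly informative sample
  d2 <- make_sample(s, z1 = s + stats::rnorm(2000, 0, 0.3))
  vals <- replicate(100, {
    d2$stimulus <- sample(d2$stimulus)
    mutual_information(d2, "stimulus", "z1")$value
  })
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)) + 0.01)
})

test_that("conditional entropy vanishes for level-deterministic responses", {
  s <- rep(1:8, each = 200)
  d <- make_sample(s, z1 = rep(0.3, length(s)))
  expect_equal(conditional_entropy(d, "stimulus", "z1")$value, 0,
               tolerance = 0.05)
  d$z1 <- as.numeric(s)  # one distinct constant per level
  expect_equal(conditional_entropy(d, "stimulus", "z1")$value, 0,
               tolerance = 0.05)
})

test_that("conditional entropy tracks the plug-in value at large n", {
  set.seed(4)
  s <- rep(1:2, each = 5e4)
  z <- stats::rnorm(1e5, mean = ifelse(s == 1, 0, 1.5))
  d <- make_sample(s, z1 = z)
  idx <- discretize(z, bin_spec(30))
  plug <- sum(vapply(1:2, function(lev) {
    0.5 * plugin_entropy(tabulate(idx[s == lev] + 1, 30))
  }, numeric(1)))
  expect_equal(conditional_entropy(d, "stimulus", "z1")$value, plug,
               tolerance = 0.01)
})

test_that("joint MI: duplicated channel adds nothing, independent readouts add", {
  set.seed(5)
  s <- rep(1:4, each = 1500)
  z1 <- s + stats::rnorm(length(s), 0, 1)
  d <- make_sample(s, z1 = z1, z2 = z1)
  jm <- joint_mi(d, "stimulus", c("z1", "z2"))
  mm <- mutual_information(d, "stimulus", "z1")
  expect_lt(abs(jm$value - mm$value), 3 * sqrt(jm$sd^2 + mm$sd^2) + 0.05)

  d2 <- make_sample(s, z1 = z1, z2 = s + stats::rnorm(length(s), 0, 1))
  jm2 <- joint_mi(d2, "stimulus", c("z1", "z2"))
  m1 <- mutual_information(d2, "stimulus", "z1")
  m2 <- mutual_information(d2, "stimulus", "z2")
  expect_gt(jm2$value, max(m1$value, m2$value) - 3 * jm2$sd)
})

test_that("joint and trajectory MI equal direct NSB on the flattened alphabet", {
  set.seed(6)
  s <- rep(1:3, each = 400)
  d <- make_sample(s,
                   z1 = stats::rnorm(1200, s),
                   z2 = stats::rnorm(1200, -s),
                   z3 = stats::rnorm(1200, 2 * s))
  for (resp in list(c("z1", "z2"), c("z1", "z2", "z3"))) {
    nb <- rep(2 + length(resp), length(resp))  # small alphabets
    est <- if (length(resp) == 2) {
      joint_mi(d, "stimulus", resp, nb)
    } else {
      trajectory_mi(d, "stimulus", resp, nb)
    }
    # flattening oracle: explicit product symbol, same NSB entropies
    idx <- mapply(function(r, k) discretize(d[[r]], bin_spec(k)),
                  resp, nb, SIMPLIFY = FALSE)
    sym <- idx[[1]]
    for (j in 2:length(idx)) sym <- sym * nb[j] + idx[[j]]
    K <- prod(nb)
    hz <- nsb_entropy(tabulate(sym + 1, K), K)$entropy
    hzs <- sum(vapply(unique(d$stimulus), function(lev) {
      sel <- d$stimulus == lev
      mean(sel) * nsb_entropy(tabulate(sym[sel] + 1, K), K)$entropy
    }, numeric(1)))
    expect_equal(est$value, hz - hzs, tolerance = 1e-10)
  }
})

test_that("trajectory MI of three identical copies equals the marginal MI", {
  set.seed(8)
  s <- rep(1:4, each = 800)
  z <- s + stats::rnorm(length(s), 0, 0.8)
  d <- make_sample(s, z1 = z, z2 = z, z3 = z)
  tm <- trajectory_mi(d, "stimulus", c("z1", "z2", "z3"), 8)
  mm <- mutual_information(d, "stimulus", "z1", 8)
  expect_lt(abs(tm$value - mm$value), 3 * sqrt(tm$sd^2 + mm$sd^2) + 0.05)
})

test_that("conditional MI: independence gives zero, identity gives H(Z1|S)", {
  set.seed(9)
  s <- rep(1:3, each = 2000)
  d <- make_sample(s,
                   z1 = s + stats::rnorm(6000, 0, 0.5),
                   z2 = s + stats::rnorm(6000, 0, 0.5))
  cm <- conditional_mi(d, "stimulus", c("z1", "z2"))
  expect_lt(abs(cm$value), 3 * cm$sd + 0.05)

  d$z2 <- d$z1
  cm2 <- conditional_mi(d, "stimulus", c("z1", "z2"))
  ce <- conditional_entropy(d, "stimulus", "z1")
  expect_lt(abs(cm2$value - ce$value), 3 * sqrt(cm2$sd^2 + ce$sd^2) + 0.05)
})

test_that("conditional MI matches the plug-in oracle on a discrete toy table", {
  set.seed(10)
  s <- rep(1:3, each = 30000)
  z1 <- stats::rbinom(length(s), 1, 0.3 + 0.1 * s)
  z2 <- ifelse(stats::runif(length(s)) < 0.7, z1,
               stats::rbinom(length(s), 1, 0.5))
  d <- make_sample(s, z1 = z1, z2 = z2)
  cm <- conditional_mi(d, "stimulus", c("z1", "z2"), n_bins = 2)
  plug <- sum(vapply(1:3, function(lev) {
    sel <- s == lev
    mean(sel) * oracle_plugin_mi(z1[sel], z2[sel])
  }, numeric(1)))
  expect_equal(cm$value, plug, tolerance = 0.005)
})

test_that("additional information collapses exactly when Z2 copies Z1", {
  set.seed(12)
  s <- rep(1:4, each = 500)
  z <- s + stats::rnorm(2000, 0, 1)
  d <- make_sample(s, z1 = z, z2 = z)
  add <- additional_information(d, "stimulus", c("z1", "z2"))
  # the chain-rule terms cancel up to the NSB estimator's mild dependence on
  # alphabet size (the pair lives on a 900-cell alphabet, the marginal on 30)
  expect_lt(abs(add$value), 0.02)
})

test_that("additional information reduces to I(Z2;S) for irrelevant Z1", {
  set.seed(13)
  s <- rep(1:4, each = 1500)
  d <- make_sample(s,
                   z1 = stats::rnorm(6000),
                   z2 = s + stats::rnorm(6000, 0, 0.7))
  add <- additional_information(d, "stimulus", c("z1", "z2"))
  i2 <- mutual_information(d, "stimulus", "z2")
  expect_lt(abs(add$value - i2$value), 3 * sqrt(add$sd^2 + i2$sd^2) + 0.05)
})

test_that("additional information equals brute-force enumeration on a tiny alphabet", {
  # discrete joint distribution over (s, z1, z2), s in 1:2, z in 0:1
  set.seed(14)
  n <- 40000
  s <- stats::rbinom(n, 1, 0.5) + 1
  z1 <- stats::rbinom(n, 1, c(0.2, 0.7)[s])
  z2 <- ifelse(stats::runif(n) < 0.6, z1, stats::rbinom(n, 1, c(0.3, 0.8)[s]))
  d <- make_sample(s, z1 = z1, z2 = z2)
  add <- additional_information(d, "stimulus", c("z1", "z2"), n_bins = 2)
  # oracle: I(Z2;S|Z1) = H(Z2|Z1) - H(Z2|Z1,S), plug-in over the 8 cells
  h <- function(tab) plugin_entropy(as.vector(tab))
  H_z2_z1 <- h(table(z1, z2)) - h(table(z1))
  H_z2_z1s <- h(table(paste(z1, s), z2)) - h(table(paste(z1, s)))
  expect_equal(add$value, H_z2_z1 - H_z2_z1s, tolerance = 0.01)
})

test_that("chain rule holds exactly for plug-in and within error for NSB", {
  set.seed(15)
  n <- 10000
  s <- rep(1:4, each = n / 4)
  z1 <- s + stats::rnorm(n, 0, 1)
  z2 <- z1 + stats::rnorm(n, 0, 1)
  i1 <- discretize(z1, bin_spec(8))
  i2 <- discretize(z2, bin_spec(8))
  # plug-in: I(Z1,Z2;S) = I(Z1;S) + I(Z2;S|Z1) exactly
  h <- function(x) plugin_entropy(table(x))
  joint <- paste(i1, i2)
  I_j <- h(joint) - sum(vapply(1:4, function(l)
    0.25 * h(joint[s == l]), numeric(1)))
  I_1 <- h(i1) - sum(vapply(1:4, function(l)
    0.25 * h(i1[s == l]), numeric(1)))
  H_z2_z1 <- h(joint) - h(i1)
  H_z2_z1s <- sum(vapply(1:4, function(l) 0.25 *
    (h(joint[s == l]) - h(i1[s == l])), numeric(1)))
  expect_equal(I_j, I_1 + (H_z2_z1 - H_z2_z1s), tolerance = 1e-12)

  # NSB route: joint_mi vs mutual_information + additional_information
  d <- make_sample(s, z1 = z1, z2 = z2)
  lhs <- joint_mi(d, "stimulus", c("z1", "z2"), 8)
  r1 <- mutual_information(d, "stimulus", "z1", 8)
  r2 <- additional_information(d, "stimulus", c("z2", "z1"), 8)  # I(Z1;S|Z2)
  r2b <- additional_information(d, "stimulus", c("z1", "z2"), 8)
  expect_lt(abs(lhs$value - (r1$value + r2b$value)),
            3 * sqrt(lhs$sd^2 + r1$sd^2 + r2b$sd^2) + 0.05)
  expect_true(is.finite(r2$value))
})

test_that("MI respects the input-entropy bound and coarsening never helps plug-in MI", {
  set.seed(16)
  s <- rep(1:4, each = 1000)
  z <- s + stats::rnorm(4000, 0, 0.2)
  d <- make_sample(s, z1 = z)
  est <- mutual_information(d, "stimulus", "z1")
  expect_lt(est$value, 2 + 3 * est$sd)

  # data-processing under coarsening: merge adjacent bins pairwise
  plug_mi <- function(idx) {
    h <- function(x) plugin_entropy(table(x))
    h(idx) - sum(vapply(unique(s), function(l)
      mean(s == l) * h(idx[s == l]), numeric(1)))
  }
  i30 <- discretize(z, bin_spec(30))
  for (k in c(15, 5, 3, 1)) {
    coarse <- i30 %/% (30 / k)
    expect_lte(plug_mi(coarse), plug_mi(i30) + 1e-12)
  }
})

test_that("invalid samples are rejected", {
  d <- make_sample(rep(1, 10), z1 = stats::rnorm(10))
  expect_error(mutual_information(d, "stimulus", "z1"), "2 distinct")
  d2 <- make_sample(rep(1:2, 5), z1 = c(NA, stats::rnorm(9)))
  expect_error(mutual_information(d2, "stimulus", "z1"), "non-finite")
})
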