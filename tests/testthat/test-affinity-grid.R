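test_that("the default grid is the decade-spaced nine-class ladder", {
  g <- affinity_grid()
  expect_equal(g$n, 9L)
  expect_equal(g$classes$log10_kd, seq(-5, -13))
  expect_equal(g$classes$k2[5], 1e-9)
  expect_equal(g$classes$log10_kd[5], g$mu)
  expect_true(all(diff(g$classes$k2) > 0))
  expect_equal(diff(g$classes$log10_kd), rep(-g$bin_width, 8))
  ## Kd consistency: log10_kd derived from the rate constants
  expect_equal(g$classes$log10_kd,
               log10(g$classes$k_minus2 / g$classes$k2),
               tolerance = 1e-12)
})

test_that("degenerate and invalid grids are handled", {
  g1 <- affinity_grid(n = 1, k2_weakest = 1e-9, k2_strongest = 1e-9)
  expect_equal(g1$classes$log10_kd, -9)
  expect_error(affinity_grid(n = 9, k2_weakest = 1e-13,
                             k2_strongest = 1e-6),
               "decade-spaced")
  expect_error(affinity_grid(n = 0), "n")
  expect_error(bin_mass(affinity_grid(), 10), "out of range")
  expect_error(mutation_split(affinity_grid(), 0), "out of range")
})

test_that("bin masses match adaptive quadrature of the normal density", {
  for (g in list(affinity_grid(),
                 affinity_grid(n = 5, k2_weakest = 1e-12,
                               k2_strongest = 1e-8, mu = -8.3,
                               sigma = 0.7))) {
    for (i in seq_len(g$n)) {
      centre <- g$classes$log10_kd[i]
      expect_equal(bin_mass(g, i),
                   mass_quadrature(centre - 0.5, centre + 0.5,
                                   g$mu, g$sigma),
                   tolerance = 1e-9)
    }
  }
})

test_that("bin masses reproduce the published repertoire fractions", {
  g <- affinity_grid()
  expect_within(bin_mass(g, 5), 0.3829, 1e-4)  # central class
  expect_within(bin_mass(g, 4), 0.2417, 1e-4)  # one step out
  expect_within(bin_mass(g, 6), 0.2417, 1e-4)
  expect_within(bin_mass(g, 3), 0.0606, 1e-4)  # two steps out
  expect_within(bin_mass(g, 1), 0.0002, 5e-5)  # four steps out
})

test_that("mutation splits lump the tails into the adjacent classes", {
  g <- affinity_grid()
  ## published worked example for class 6 (log10 Kd = -10)
  s6 <- mutation_split(g, 6)
  for (j in 1:3) expect_within(s6[j], c(0.6915, 0.2417, 0.0668)[j], 1e-4)
  ## each component equals the corresponding quadrature mass
  expect_equal(s6[["p_stay"]], mass_quadrature(-10.5, -9.5, -9, 1),
               tolerance = 1e-9)
  expect_equal(s6[["p_weaker"]], 1 - mass_quadrature(-Inf, -9.5, -9, 1),
               tolerance = 1e-9)
  expect_equal(s6[["p_stronger"]], mass_quadrature(-Inf, -10.5, -9, 1),
               tolerance = 1e-9)
  ## central class is symmetric
  s5 <- mutation_split(g, 5)
  expect_equal(s5[["p_weaker"]], s5[["p_stronger"]])
  expect_equal(s5[["p_stay"]], mass_quadrature(-9.5, -8.5, -9, 1),
               tolerance = 1e-9)
  ## weakest class: off-grid weaker tail absorbed into stay
  s1 <- mutation_split(g, 1)
  expect_equal(s1[["p_weaker"]], 0)
  expect_within(s1[["p_stronger"]], 0.99977, 1e-4)
  expect_within(s1[["p_stay"]], 0.00023, 1e-4)
  expect_equal(sum(s1), 1)
})

test_that("kernel rows sum to one for any grid shape", {
  cases <- list(list(n = 9, mu = -9, sigma = 1),
                list(n = 5, mu = -7, sigma = 2),
                list(n = 7, mu = -9, sigma = 0.5),
                list(n = 9, mu = -8.3, sigma = 1.4))
  for (cs in cases) {
    g <- affinity_grid(n = cs$n, k2_weakest = 1e-13,
                       k2_strongest = 1e-13 * 10^(cs$n - 1),
                       mu = cs$mu, sigma = cs$sigma)
    k <- mutation_kernel(g)
    expect_equal(rowSums(k$split), rep(1, cs$n), tolerance = 1e-12)
    expect_identical(unname(k$split[1, "p_weaker"]), 0)
    expect_identical(unname(k$split[cs$n, "p_stronger"]), 0)
  }
})

test_that("a centred kernel is mirror-symmetric and drifts toward the mean", {
  g <- affinity_grid()
  k <- mutation_kernel(g)$split
  for (d in 1:4) {
    lo <- k[5 - d, ]; hi <- k[5 + d, ]
    expect_equal(lo[["p_weaker"]], hi[["p_stronger"]], tolerance = 1e-12)
    expect_equal(lo[["p_stay"]], hi[["p_stay"]], tolerance = 1e-12)
    expect_equal(lo[["p_stronger"]], hi[["p_weaker"]], tolerance = 1e-12)
  }
  ## classes on the weak side of the mean mutate preferentially stronger,
  ## and vice versa
  for (i in 1:4) expect_gt(k[i, "p_stronger"], k[i, "p_weaker"])
  for (i in 6:9) expect_gt(k[i, "p_weaker"], k[i, "p_stronger"])
})

test_that("initial composition distributes a total over the bin masses", {
  g <- affinity_grid()
  y0 <- initial_composition(g, 1e6)
  expect_within(y0[5] / 1e6, 0.3829, 1e-4)
  expect_within(y0[3] / 1e6, 0.0606, 1e-4)
  expect_within(y0[1] / 1e6, 0.0002, 5e-5)
  expect_equal(y0, rev(y0))                        # symmetric about class 5
  expect_equal(initial_composition(g, 0), rep(0, 9))
  expect_error(initial_composition(g, -1), "nonnegative")
  ## tails beyond +/- 4.5 sigma are excluded
  frac_total <- sum(y0) / 1e6
  expect_lt(frac_total, 1)
  expect_equal(frac_total, mass_quadrature(-13.5, -4.5, -9, 1),
               tolerance = 1e-9)
})

test_that("the kernel CSV round-trips at full precision", {
  g <- affinity_grid()
  f <- withr::local_tempfile(fileext = ".csv")
  out <- write_kernel_csv(g, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("class_index", "log10_kd", "k2", "k_minus2",
                              "p_weaker", "p_stay", "p_stronger"))
  expect_equal(back$p_weaker, out$p_weaker)
  expect_equal(back$k2, g$classes$k2)
})
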