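test_that("band values match Gaussian closed forms", {
  ax <- default_axis()
  # height: unit Gaussian, window wide enough that the local baseline
  # anchors land on the tails
  s <- raman_spectrum(ax, gauss_on(ax, 960, 8))
  hb <- band_definition("PO4", 960, c(920, 1000), "height")
  expect_equal(band_value(s, hb), 1, tolerance = 0.01)
  # area over +/- 4 sigma: a * sigma * sqrt(2*pi) within 1%
  a <- 2.5; sigma <- 10
  s2 <- raman_spectrum(ax, gauss_on(ax, 1250, sigma, a))
  ab <- band_definition("X", 1250, c(1250 - 4 * sigma, 1250 + 4 * sigma),
                        "area")
  expect_equal(band_value(s2, ab), a * sigma * sqrt(2 * pi),
               tolerance = 0.01 * a * sigma * sqrt(2 * pi))
})

test_that("the local linear baseline removes constants and ramps", {
  ax <- default_axis()
  x <- as.numeric(ax)
  base <- raman_spectrum(ax, gauss_on(ax, 1070, 10))
  for (mode in c("height", "area")) {
    bd <- band_definition("CO3", 1070, c(1050, 1100), mode)
    v0 <- band_value(base, bd)
    shifted <- raman_spectrum(ax, base$intensities + 3.7)
    ramped <- raman_spectrum(ax, base$intensities + 0.01 * x - 5)
    expect_equal(band_value(shifted, bd), v0, tolerance = 1e-10)
    expect_equal(band_value(ramped, bd), v0, tolerance = 1e-8)
  }
  expect_error(band_value(base, band_definition("Z", 2050, c(2000, 2100))),
               "intersect")
})

test_that("area mode is additive over superposition on disjoint windows", {
  ax <- default_axis()
  s1 <- gauss_on(ax, 960, 8); s2 <- gauss_on(ax, 1450, 15, 0.5)
  b1 <- band_definition("PO4", 960, c(930, 980))
  b2 <- band_definition("CH2", 1450, c(1400, 1500))
  sup <- raman_spectrum(ax, s1 + s2)
  expect_equal(band_value(sup, b1),
               band_value(raman_spectrum(ax, s1), b1), tolerance = 1e-8)
  expect_equal(band_value(sup, b2),
               band_value(raman_spectrum(ax, s2), b2), tolerance = 1e-8)
})

test_that("metric ratios behave as ratios", {
  ax <- default_axis()
  mk <- function(po4_amp) raman_spectrum(
    ax, gauss_on(ax, 960, 8, po4_amp) + gauss_on(ax, 1070, 10, 0.4) +
      gauss_on(ax, 1250, 25, 0.5) + gauss_on(ax, 1450, 15, 0.8) +
      gauss_on(ax, 1665, 30, 0.9))
  m1 <- compute_metrics(mk(1))
  m2 <- compute_metrics(mk(2))
  for (r in c("po4_co3", "po4_amideIII", "po4_ch2", "po4_amideI"))
    expect_equal(m2[[r]], 2 * m1[[r]], tolerance = 1e-6, label = r)
  # global intensity scaling leaves every metric unchanged
  s <- mk(1.3)
  m <- compute_metrics(s)
  ms <- compute_metrics(raman_spectrum(ax, 100 * s$intensities))
  expect_equal(ms, m, tolerance = 1e-10)
  # equal-area PO4 and CO3 peaks give unit mineral-quality ratio
  # (windows centered on each peak so truncation is symmetric; fine grid
  # so the two windows sample their peaks identically)
  fine <- wavenumber_axis(seq(800, 1800, length.out = 4999))
  eq_bands <- default_bands()
  eq_bands$PO4 <- band_definition("PO4", 960, c(935, 985))
  eq_bands$CO3 <- band_definition("CO3", 1070, c(1045, 1095))
  eq <- raman_spectrum(fine,
                       gauss_on(fine, 960, 8) + gauss_on(fine, 1070, 8) +
                         gauss_on(fine, 1250, 25) +
                         gauss_on(fine, 1450, 15) +
                         gauss_on(fine, 1665, 30))
  expect_equal(compute_metrics(eq, eq_bands)$po4_co3, 1, tolerance = 0.01)
  # a missing band definition is an error that names the band
  expect_error(compute_metrics(s, default_bands()[-5]), "AmideI")
})

test_that("FWHM matches line-shape closed forms and a dense-grid oracle", {
  ax <- default_axis()
  ch2 <- band_definition("CH2", 1450, c(1350, 1550))
  # Gaussian: 2*sqrt(2*ln 2)*sigma
  g <- raman_spectrum(ax, gauss_on(ax, 1450, 10))
  expect_equal(fwhm(g, ch2), 2 * sqrt(2 * log(2)) * 10, tolerance = 0.1)
  # Lorentzian: 2*gamma
  l <- raman_spectrum(ax, lorentz_on(ax, 1450, 12))
  expect_equal(fwhm(l, ch2), 24, tolerance = 0.1)
  # asymmetric blend: brute-force half-max scan on a 100x finer grid
  shape <- function(x) exp(-(x - 1440)^2 / (2 * 12^2)) +
    0.6 * exp(-(x - 1465)^2 / (2 * 18^2))
  blend <- raman_spectrum(ax, shape(as.numeric(ax)))
  fine <- seq(1350, 1550, length.out = 100 * 499)
  yf <- shape(fine)
  above <- fine[yf >= max(yf) / 2]
  oracle <- max(above) - min(above)
  expect_equal(fwhm(blend, ch2), oracle, tolerance = 0.2)
  # no peak above the local baseline is an error
  flat <- raman_spectrum(ax, rep(2, 499))
  expect_error(fwhm(flat, ch2), "no peak")
})

test_that("group summaries aggregate subjects before classes", {
  recs <- data.frame(subject_id = c("a", "b", "c", "d"),
                     who_class = c("Normal", "Normal", "Normal",
                                   "Osteoporosis"))
  met <- data.frame(subject_id = c("a", "b", "c", "d"),
                    po4_co3 = c(1, 2, 3, 9))
  g <- summarize_groups(met, recs)
  n_row <- g[g$who_class == "Normal" & g$metric == "po4_co3", ]
  expect_equal(n_row$mean, 2)
  expect_equal(n_row$sd, 1)
  expect_equal(n_row$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(n_row$n, 3L)
  # single-subject class: SD = 0 convention, SEM = 0
  op_row <- g[g$who_class == "Osteoporosis", ]
  expect_equal(op_row$sd, 0)
  expect_equal(op_row$sem, 0)
  # duplicated subject rows (two sites) are collapsed before class stats
  met2 <- rbind(met, data.frame(subject_id = "a", po4_co3 = 5))
  g2 <- summarize_groups(met2, recs)
  expect_equal(g2[g2$who_class == "Normal", "n"], 3L)
  expect_equal(g2[g2$who_class == "Normal", "mean"], mean(c(3, 2, 3)))
})

test_that("exact Mann-Whitney handles ties by mid-ranks", {
  recs <- data.frame(subject_id = paste0("s", 1:6),
                     who_class = rep(c("Normal", "Osteoporosis"),
                                     each = 3))
  # identical value multisets: p = 1 exactly
  met <- data.frame(subject_id = paste0("s", 1:6),
                    po4_co3 = c(1, 2, 3, 1, 2, 3))
  expect_equal(compare_classes(met, recs, c("Normal", "Osteoporosis"),
                               "po4_co3"), 1)
  # fully separated triples: most extreme 2 of choose(6,3)=20 orderings
  met$po4_co3 <- c(1, 2, 3, 10, 11, 12)
  expect_equal(compare_classes(met, recs, c("Normal", "Osteoporosis"),
                               "po4_co3"), 0.1)
  # symmetric in the pair's order
  expect_equal(compare_classes(met, recs, c("Osteoporosis", "Normal"),
                               "po4_co3"), 0.1)
  expect_error(compare_classes(met[-(1:2), ], recs,
                               c("Normal", "Osteoporosis"), "po4_co3"),
               "at least 2")
})

test_that("exact enumeration agrees with wilcox.test on tie-free data", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- rnorm(5); y <- rnorm(6) + 0.8
    expect_equal(mann_whitney_exact(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})
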