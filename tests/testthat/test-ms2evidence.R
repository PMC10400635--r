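spec <- function(frag_mz, prec = 399.2191, int = NULL, purity = NA) {
  if (is.null(int)) int <- rep(100, length(frag_mz))
  ms2_spectrum(prec, data.frame(mz = frag_mz, intensity = int),
               purity = purity)
}

test_that("purity filter keeps >= plim and warns on unset purity", {
  keep <- spec(200, purity = 0.9)
  drop <- spec(200, purity = 0.4)
  none <- spec(200)
  expect_length(purity_filter(list(keep, drop)), 1)
  expect_warning(out <- purity_filter(list(keep, drop, none)),
                 "lack a purity")
  expect_length(out, 2)
  expect_length(suppressWarnings(purity_filter(list(keep, drop, none),
                                               plim = 0)), 3)
})

test_that("averaging identical replicates is idempotent", {
  s <- spec(c(185.0712, 238.0980, 283.1562), int = c(40, 100, 80))
  avg <- average_spectra(list(s, s))
  expect_equal(avg$fragments$mz, s$fragments$mz, tolerance = 1e-9)
  expect_equal(avg$fragments$intensity, s$fragments$intensity)
  expect_identical(average_spectra(list(s)), s)
  expect_error(average_spectra(list()), "no spectra")
})

test_that("fragments 2.5 ppm apart merge into one weighted peak", {
  s1 <- spec(200.0000, int = 100)
  s2 <- spec(200.0005, int = 300)
  avg <- average_spectra(list(s1, s2), ppm_tol = 5)
  expect_equal(nrow(avg$fragments), 1)
  # intensity-weighted mean m/z
  expect_equal(avg$fragments$mz,
               (200.0000 * 100 + 200.0005 * 300) / 400, tolerance = 1e-9)
  expect_equal(avg$fragments$intensity, 200)
  # 20 ppm apart stays two peaks
  s3 <- spec(200.004)
  expect_equal(nrow(average_spectra(list(s1, s3))$fragments), 2)
})

test_that("self-alignment conserves every fragment; zero delta has no shifts", {
  parent <- spec(c(185.0712, 210.1028, 238.0980, 255.1247, 283.1562,
                   326.1621))
  ev <- align_to_parent(parent, parent, delta = 0)
  expect_equal(ev$n_conserved, 6)
  expect_equal(ev$n_shifted, 0)
  expect_true(ev$related)
})

test_that("three conserved substructures establish relatedness", {
  parent <- spec(c(185, 238, 283, 326))
  cand <- spec(c(185, 238, 283), prec = 415.2140)
  ev <- align_to_parent(cand, parent, delta = 15.9949)
  expect_equal(ev$n_conserved, 3)
  expect_true(ev$related)
  # two conserved is not enough
  cand2 <- spec(c(185, 238), prec = 415.2140)
  expect_false(align_to_parent(cand2, parent, delta = 15.9949)$related)
  # disjoint spectra share nothing
  ev3 <- align_to_parent(spec(c(101, 153)), parent, delta = 15.9949)
  expect_equal(ev3$n_conserved, 0)
  expect_false(ev3$related)
})

test_that("delta-shifted fragments are counted as shifted", {
  d <- 15.994915
  parent <- spec(c(185.0712, 238.0980, 283.1562, 326.1621))
  cand <- spec(c(185.0712, 238.0980, 283.1562 + d, 326.1621 + d),
               prec = 415.2140)
  ev <- align_to_parent(cand, parent, delta = d)
  expect_equal(ev$n_conserved, 2)
  expect_equal(ev$n_shifted, 2)
})

test_that("averaging identical replicates does not change alignment", {
  parent <- spec(c(185.0712, 238.0980, 283.1562, 326.1621))
  cand <- spec(c(185.0712, 238.0980, 283.1562), prec = 415.2140)
  avg <- average_spectra(list(cand, cand))
  ev1 <- align_to_parent(cand, parent, delta = 15.9949)
  ev2 <- align_to_parent(avg, parent, delta = 15.9949)
  expect_equal(ev1$n_conserved, ev2$n_conserved)
  expect_equal(ev1$related, ev2$related)
})

test_that("MGF and MSP files round-trip spectra", {
  dir <- withr::local_tempdir()
  s1 <- ms2_spectrum(399.2191,
                     data.frame(mz = c(185.0712, 238.0980),
                                intensity = c(40, 100)),
                     precursor_rt = 210, purity = 0.95, title = "parent")
  s2 <- ms2_spectrum(415.214, data.frame(mz = 201.07, intensity = 55),
                     precursor_rt = 225, purity = 0.8, title = "m1")
  mgf <- file.path(dir, "lib.mgf")
  write_mgf(list(s1, s2), mgf)
  back <- read_mgf(mgf)
  expect_length(back, 2)
  expect_equal(back[[1]]$precursor_mz, 399.2191, tolerance = 1e-6)
  expect_equal(back[[1]]$fragments$mz, s1$fragments$mz,
               tolerance = 1e-6)
  expect_equal(back[[2]]$purity, 0.8)
  msp <- file.path(dir, "lib.msp")
  write_msp(list(s1, s2), msp)
  back2 <- read_msp(msp)
  expect_length(back2, 2)
  expect_equal(back2[[1]]$fragments$intensity, c(40, 100))
  expect_equal(back2[[2]]$title, "m1")
})

test_that("spectra link to features at 5 ppm / 10 s", {
  pm <- peak_matrix(
    matrix(1e6, 2, 2),
    data.frame(feature_id = c("A", "B"), mz = c(399.2191, 415.2140),
               rt = c(210, 225)),
    data.frame(sample_id = c("S1", "S2"),
               class = c("exposed", "control")))
  sp <- ms2_spectrum(399.2191, data.frame(mz = 185, intensity = 1),
                     precursor_rt = 215)
  links <- link_spectra_to_features(list(sp), pm)
  expect_equal(links$feature_id, "A")
  far <- ms2_spectrum(399.2191, data.frame(mz = 185, intensity = 1),
                      precursor_rt = 260)
  expect_equal(nrow(link_spectra_to_features(list(far), pm)), 0)
})
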