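Z0 <- 120 * pi

test_that("sheet Fresnel coefficients follow the two-sided algebra", {
  rt <- reflection_transmission(0 + 0i)
  expect_equal(Mod(rt$R), 0, tolerance = 1e-15)
  expect_equal(rt$T, 1 + 0i, tolerance = 1e-15)

  rt2 <- reflection_transmission(complex(real = 2 / Z0))
  expect_equal(Re(rt2$R), -0.5, tolerance = 1e-12)
  expect_equal(Re(rt2$T), 0.5, tolerance = 1e-12)
  A <- absorption(rt2, omega_eV = 1)
  expect_equal(A$A, 0.5, tolerance = 1e-12)
})

test_that("a lossless (purely imaginary) sheet absorbs nothing", {
  y <- seq(-20, 20, by = 0.05)
  rt <- reflection_transmission(complex(imaginary = y / Z0))
  A <- absorption(rt, omega_eV = seq_along(y))
  expect_lt(max(abs(A$A)), 1e-12)
  expect_lt(max(abs(Mod(rt$R)^2 + Mod(rt$T)^2 - 1)), 1e-12)
})

test_that("energy bookkeeping A + |R|^2 + |T|^2 = 1 holds to machine precision", {
  set.seed(9)
  sig <- complex(real = abs(stats::rnorm(200)) / Z0, imaginary = stats::rnorm(200) / Z0)
  rt <- reflection_transmission(sig)
  A <- absorption(rt, omega_eV = seq_len(200))
  expect_lt(max(abs(A$A + A$R2 + A$T2 - 1)), 1e-15)
  expect_true(all(A$A >= 0 & A$A <= 1))
})

test_that("absorption of a real sheet peaks at 50% at sigma Z0 = 2", {
  mx <- max_real_sheet_absorption()
  expect_equal(mx$A_max, 0.5, tolerance = 1e-9)
  expect_equal(mx$x_opt, 2, tolerance = 1e-6)
  # monotone up to the optimum, monotone down after
  x <- seq(0, 2, by = 0.01)
  A_of <- function(x) 4 * x / (2 + x)^2
  expect_true(all(diff(A_of(x)) > 0))
  x2 <- seq(2, 40, by = 0.1)
  expect_true(all(diff(A_of(x2)) < 0))
})

test_that("nonphysical sheet conductivity is rejected", {
  expect_error(reflection_transmission(complex(real = -2 / Z0)), "nonphysical")
})

test_that("thin-film validity warning fires when thickness rivals wavelength", {
  sig <- structure(list(sigma_S = rep(0.001 + 0i, 3), omega_eV = c(4, 8, 12),
                        lambda_nm = 1239.842 / c(4, 8, 12)),
                   class = "conductivity_spectrum")
  expect_warning(reflection_transmission(sig, film_model("end", thickness_nm = 40)),
                 "thin-film")
  expect_silent(reflection_transmission(sig, film_model("end", thickness_nm = 5)))
})

test_that("peak finding resolves isolated Lorentzians", {
  om <- seq(0.5, 6, by = 0.002)
  lam <- 1239.842 / om
  one <- structure(list(lambda_nm = lam, omega_eV = om,
                        A = 0.3 / (1 + ((lam - 700) / 40)^2)),
                   class = "absorption_spectrum")
  pk <- find_absorption_maxima(one)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$lambda_nm, 700, tolerance = 1)

  two <- one
  two$A <- two$A + 0.25 / (1 + ((lam - 300) / 25)^2)
  pk2 <- find_absorption_maxima(two)
  expect_identical(nrow(pk2), 2L)
  expect_equal(sort(pk2$lambda_nm), c(300, 700), tolerance = 1)

  expect_error(find_absorption_maxima(one, prominence = 0), "\\(0, 1\\)")
  short <- structure(list(lambda_nm = c(1, 2), A = c(0, 1)), class = "absorption_spectrum")
  expect_error(find_absorption_maxima(short), "3 points")
})

test_that("defects add absorption peaks without removing pristine ones", {
  # identical supercell, k-grid and photon grid for pristine and defective
  # tubes; window 200-2750 nm (the analysed range; shorter wavelengths are
  # dense van Hove clutter where peaks merge under broadening)
  model <- tb_model()
  cfg <- kubo_config(seq(0.45, 6.2, by = 0.005), eta = 0.05)
  film <- film_model("side")
  spec_of <- function(st) {
    bands <- band_structure(st, model, nk = 8,
                            scell = film_scell(film, st$provenance$chirality,
                                               st$cell$period))
    film_absorption(kubo_conductivity(bands, cfg), film)
  }
  base <- build_periodic_tube(swnt_chirality(13, 0), 3)
  p0 <- find_absorption_maxima(spec_of(base), prominence = 0.005)
  for (d in list(defect_spec("SW", bond = 150L), defect_spec("SV", site = 100L))) {
    p1 <- find_absorption_maxima(spec_of(apply_defect(base, d)), prominence = 0.005)
    expect_gt(nrow(p1), nrow(p0) - 1L)
    # pristine peaks persist (within defect-induced shifts)...
    for (lam in p0$lambda_nm) {
      expect_true(any(abs(p1$lambda_nm - lam) < 0.08 * lam))
    }
    # ...and genuinely new peaks appear away from every pristine peak
    new_peaks <- sum(vapply(p1$lambda_nm, function(l) {
      min(abs(p0$lambda_nm - l) / l) > 0.03
    }, logical(1)))
    expect_gte(new_peaks, 3L)
  }
})

test_that("peak binning follows the left-closed [lo, hi) convention", {
  expect_identical(unname(bin_peaks(numeric(0))), c(0L, 0L, 0L, 0L, 0L))
  expect_identical(unname(bin_peaks(c(300, 700, 1000))), c(1L, 1L, 1L, 0L, 0L))
  expect_identical(unname(bin_peaks(200)), c(1L, 0L, 0L, 0L, 0L))   # lo is inside
  expect_identical(unname(bin_peaks(400)), c(0L, 0L, 0L, 0L, 1L))   # hi is outside
  expect_identical(unname(bin_peaks(c(100, 500, 3000))), c(0L, 0L, 0L, 0L, 3L))
  expect_error(bin_peaks(300, ranges = list(c(200, 500), c(400, 700))), "overlap")
})

test_that("level sets are located by linear interpolation", {
  lam <- seq(100, 1000, by = 10)
  A <- ifelse(lam >= 500 & lam <= 600, 0.6, 0)
  sp <- structure(list(lambda_nm = lam, A = A), class = "absorption_spectrum")
  iv <- wavelengths_at_level(sp, 0.5)
  expect_identical(nrow(iv), 1L)
  expect_lte(iv$lambda_lo, 500); expect_gte(iv$lambda_hi, 600)

  zero <- structure(list(lambda_nm = lam, A = rep(0, length(lam))),
                    class = "absorption_spectrum")
  expect_identical(nrow(wavelengths_at_level(zero, 0.5)), 0L)

  # a real-conductivity film crosses 50% only where sigma Z0 ~ 2
  x <- seq(0, 10, by = 0.001)            # sigma Z0 along a synthetic "wavelength"
  film <- absorption(reflection_transmission(complex(real = x / Z0)),
                     omega_eV = rev(seq_along(x)))   # any monotone grid
  sp2 <- structure(list(lambda_nm = x, A = film$A), class = "absorption_spectrum")
  iv2 <- wavelengths_at_level(sp2, 0.4999)
  expect_identical(nrow(iv2), 1L)
  expect_lt(abs(iv2$lambda_lo - 2), 0.1)
  expect_error(wavelengths_at_level(sp2, 1.2), "\\(0, 1\\)")
})

test_that("film area per tube encodes the 0.5 nm packing gap", {
  ch <- swnt_chirality(4, 4)
  Tlen <- nt_translation_period(ch)
  expect_equal(film_scell(film_model("side"), ch, Tlen),
               Tlen * (nt_diameter(ch) + 0.5), tolerance = 1e-12)
  expect_equal(film_scell(film_model("end"), ch),
               sqrt(3) / 2 * (nt_diameter(ch) + 0.5)^2, tolerance = 1e-12)
  expect_error(film_scell(film_model("side"), ch), "axial period")
})
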