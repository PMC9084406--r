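# Mie series, amplitude functions, scattering-matrix tables and bulk
# optical properties.

test_that("Mie coefficients match the Bessel-function oracle", {
  cases <- list(
    c(x = 0.6604, m = 1.1955),            # r = 0.05 um population
    c(x = 3.9624, m = 1.1955),            # r = 0.3 um population
    c(x = 13.208, m = 1.1955),            # r = 1 um population
    c(x = 0.5, m = 1.5), c(x = 5, m = 1.05), c(x = 10, m = 1.33))
  for (cs in cases) {
    co <- mie_coefficients(cs["x"], cs["m"])
    or <- oracle_mie_coefficients(cs["x"], cs["m"], length(co$a))
    expect_lt(max(Mod(co$a - or$a)) / max(Mod(or$a)), 1e-8)
    expect_lt(max(Mod(co$b - or$b)) / max(Mod(or$b)), 1e-8)
  }
})

test_that("index-matched spheres do not scatter and tiny spheres vanish as x^3", {
  co <- mie_coefficients(2.0, 1.0)
  expect_lt(max(Mod(co$a)), 1e-14)
  expect_lt(max(Mod(co$b)), 1e-14)

  m <- 1.2
  a1 <- function(x) Mod(mie_coefficients(x, m)$a[1])
  # |a_1| ~ x^3 scaling: ratio at x and x/2 close to 8
  expect_equal(a1(2e-2) / a1(1e-2), 8, tolerance = 1e-3)
  expect_lt(a1(1e-3), 1e-8)
})

test_that("input validation rejects non-positive x and m", {
  expect_error(mie_coefficients(-1, 1.2), "size_parameter")
  expect_error(mie_coefficients(0, 1.2), "size_parameter")
  expect_error(mie_coefficients(1, -0.5), "relative_index")
  expect_error(mie_amplitudes(mie_coefficients(1, 1.2), c(0, 3.5)),
               "theta")
})

test_that("amplitude functions obey the forward and backward sphere symmetries", {
  for (cs in list(c(0.66, 1.1955), c(4, 1.2), c(12, 1.1))) {
    co <- mie_coefficients(cs[1], cs[2])
    amp <- mie_amplitudes(co, c(0, pi))
    expect_equal(amp$S1[1], amp$S2[1], tolerance = 1e-12)      # S1(0) = S2(0)
    expect_equal(amp$S1[2], -amp$S2[2], tolerance = 1e-10)     # S1(pi) = -S2(pi)
  }
})

test_that("scattering-matrix tables satisfy the sphere identities and normalization", {
  for (spec in bench_specs) {
    tab <- scattering_matrix_table(spec, 500L)
    expect_true(all(tab$s11 > 0))
    expect_true(all(abs(tab$s12) <= tab$s11 + 1e-12))
    lhs <- tab$s11^2 - tab$s12^2
    rhs <- tab$s33^2 + tab$s34^2
    expect_lt(max(abs(lhs - rhs) / lhs), 1e-6)
    expect_equal(tab$s12[1], 0, tolerance = 1e-12 * tab$s11[1])
    expect_equal(tab$s33[1], tab$s11[1], tolerance = 1e-10)
    # phase-function normalization on the stored grid
    integ <- 2 * pi * sum(diff(tab$theta) *
      (head(tab$s11 * sin(tab$theta), -1) +
       tail(tab$s11 * sin(tab$theta), -1)) / 2)
    expect_equal(integ, 1, tolerance = 1e-12)
  }
})

test_that("small spheres reproduce the Rayleigh angular shape and cross-section", {
  spec <- scatterer_spec(0.005, 1, 1.59, 1.33, 632.8)  # x ~ 0.066
  tab <- scattering_matrix_table(spec, 200L)
  shape <- 1 + cos(tab$theta)^2
  ratio <- tab$s11 / shape
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)

  mi <- mie_input(spec)
  bo <- bulk_properties(spec)
  expect_lt(abs(mi$size_parameter), 0.1)
  expect_lt(abs(bo$anisotropy), 0.01)
  csca_ray <- rayleigh_csca(mi$size_parameter, mi$relative_index,
                            spec$radius_um)
  expect_equal(bo$csca_um2, csca_ray, tolerance = 0.02)
})

test_that("the three equal-mus'-design sphere populations give 1/mm within 1%", {
  musp <- vapply(bench_specs[c("superficial", "bottom", "inclusion")],
                 function(s) bulk_properties(s)$musp_per_mm, numeric(1))
  expect_true(all(abs(musp - 1) < 0.01))
  expect_lt(max(musp) / min(musp) - 1, 0.01)
})

test_that("zero density means zero scattering, and musp = mus (1 - g) exactly", {
  s0 <- scatterer_spec(0.3, 0, 1.59, 1.33, 632.8)
  bo <- bulk_properties(s0, mua_per_mm = 0.5)
  expect_identical(bo$mus_per_mm, 0)
  expect_identical(bo$musp_per_mm, 0)
  expect_identical(bo$mua_per_mm, 0.5)
  for (spec in bench_specs) {
    bo <- bulk_properties(spec)
    expect_identical(bo$musp_per_mm, bo$mus_per_mm * (1 - bo$anisotropy))
  }
})

test_that("bulk properties and matrix elements match the oracle for random specs", {
  set.seed(42)
  for (rep in 1:12) {
    r <- runif(1, 0.02, 1.5)
    spec <- scatterer_spec(r, runif(1, 1e-4, 10), runif(1, 1.4, 1.7),
                           runif(1, 1.3, 1.4), runif(1, 400, 900))
    mi <- mie_input(spec)
    nmax <- length(mie_coefficients(mi$size_parameter, mi$relative_index)$a)
    or <- oracle_mie_coefficients(mi$size_parameter, mi$relative_index, nmax)
    n <- seq_len(nmax)
    qsca <- (2 / mi$size_parameter^2) *
      sum((2 * n + 1) * (Mod(or$a)^2 + Mod(or$b)^2))
    csca <- qsca * pi * r^2
    bo <- bulk_properties(spec)
    expect_equal(bo$csca_um2, csca, tolerance = 1e-6)
    expect_equal(bo$mus_per_mm, spec$density_per_um3 * csca * 1000,
                 tolerance = 1e-6)
    # matrix elements from oracle amplitudes at a few angles
    th <- c(0.3, 1.2, 2.4)
    tab <- scattering_matrix_table(spec, 1000L)
    i <- smatrix_index(tab, th)
    amp <- mie_amplitudes(or, tab$theta[i])    # oracle coefficients
    s11 <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
    s12 <- (Mod(amp$S2)^2 - Mod(amp$S1)^2) / 2
    cr <- amp$S2 * Conj(amp$S1)
    scale <- tab$s11[i] / s11
    expect_equal(tab$s12[i], s12 * scale, tolerance = 1e-6)
    expect_equal(tab$s33[i], Re(cr) * scale, tolerance = 1e-6)
    expect_equal(tab$s34[i], Im(cr) * scale, tolerance = 1e-6)
  }
})

test_that("tables round-trip through the cache format bit-for-bit", {
  tab <- scattering_matrix_table(bench_specs$bottom, 300L)
  f <- withr::local_tempfile(fileext = ".rds")
  write_smatrix_table(tab, f)
  back <- read_smatrix_table(f)
  expect_identical(back$s11, tab$s11)
  expect_identical(back$s34, tab$s34)
  expect_identical(back$theta, tab$theta)
  saveRDS(1:3, f)
  expect_error(read_smatrix_table(f), "scattering-matrix table")
})
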