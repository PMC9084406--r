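# Transport primitives: Stokes rotations, direction updates, the
# polarized scattering composition, free paths, voxel traversal,
# roulette and boundaries.

test_that("Mueller rotation matches its convention and forms a group", {
  expect_equal(rotate_stokes(c(1, 1, 0, 0), 0), c(1, 1, 0, 0))
  expect_equal(rotate_stokes(c(1, 1, 0, 0), pi / 4), c(1, 0, -1, 0),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:100) {
    s <- c(runif(1, 0.5, 2), rnorm(3))
    a <- runif(1, -10, 10); b <- runif(1, -10, 10)
    expect_equal(rotate_stokes(rotate_stokes(s, a), b),
                 rotate_stokes(s, a + b), tolerance = 1e-9)
    expect_equal(rotate_stokes(s, a),
                 as.numeric(mueller_rot(a) %*% s), tolerance = 1e-12)
  }
})

test_that("direction update honours the local-frame convention and preserves angles", {
  expect_equal(update_direction(c(0, 0, 1), pi / 2, 0), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(update_direction(c(0, 0, 1), pi / 2, pi / 2), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:1000) {
    u <- random_unit()
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    u2 <- update_direction(u, th, ph)
    expect_equal(sum(u2^2), 1, tolerance = 1e-9)
    expect_equal(sum(u * u2), cos(th), tolerance = 1e-9)
    # independent axis-angle construction
    fr <- oracle_meridian(u)
    ax <- -sin(ph) * fr$e_par + cos(ph) * fr$e_perp
    expect_equal(u2, as.numeric(axis_angle(ax, th) %*% u),
                 tolerance = 1e-9)
  }
})

test_that("forward scattering is the identity on direction and Stokes vector", {
  tab <- scattering_matrix_table(bench_specs$bottom, 500L)
  set.seed(3)
  for (i in 1:50) {
    u <- random_unit()
    s <- random_polarized_stokes()
    ph <- runif(1, 0, 2 * pi)
    out <- scatter_update(u, s, 0, ph, tab)
    expect_equal(out$direction, u, tolerance = 1e-9)
    expect_equal(out$stokes, s, tolerance = 1e-6)
  }
})

test_that("scattering preserves full polarization and matches the matrix-product oracle", {
  tab <- scattering_matrix_table(bench_specs$bottom, 1000L)
  set.seed(4)
  for (i in 1:300) {
    u <- random_unit()
    s <- random_polarized_stokes()
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    idx <- smatrix_index(tab, th)
    out <- scatter_update(u, s, th, ph, tab)
    dop <- sqrt(sum(out$stokes[2:4]^2)) / out$stokes[1]
    expect_equal(dop, 1, tolerance = 1e-6)
    orc <- oracle_scatter(u, s, th, ph, tab$s11[idx], tab$s12[idx],
                          tab$s33[idx], tab$s34[idx])
    expect_equal(out$direction, orc$direction, tolerance = 1e-9)
    expect_equal(out$stokes, orc$stokes, tolerance = 1e-9)
  }
})

test_that("circularly polarized input scatters with azimuth-independent V", {
  tab <- scattering_matrix_table(bench_specs$superficial, 1000L)
  th <- 0.9
  idx <- smatrix_index(tab, th)
  vs <- vapply(seq(0, 2 * pi, length.out = 17), function(ph) {
    scatter_update(c(0, 0, 1), c(1, 0, 0, 1), th, ph, tab)$stokes[4]
  }, numeric(1))
  expect_lt(diff(range(vs)), 1e-9)
  expect_equal(vs[1], tab$s33[idx] / tab$s11[idx], tolerance = 1e-9)
})

test_that("optical depth draws are Exp(1) and free paths Exp(mus)", {
  set.seed(5)
  tau <- sample_path_optical_depth(1e5)
  expect_true(all(tau > 0))
  expect_lt(abs(mean(tau) - 1), 3 / sqrt(1e5))
  # geometric free paths in a homogeneous medium
  mus <- 6.9
  expect_gt(ks.test(tau[1:10000] / mus, pexp, rate = mus)$p.value, 0.01)
})

test_that("traversal consumes optical depth across voxels correctly", {
  tab <- scattering_matrix_table(bench_specs$bottom, 200L)
  rec1 <- medium_record(0, mus_per_mm = 2, anisotropy = 0, table = tab)
  rec2 <- medium_record(0, mus_per_mm = 5, anisotropy = 0, table = tab)
  vac <- medium_record(0, mus_per_mm = 0)

  # homogeneous: stop distance tau / mus
  g <- voxel_grid(c(10, 10, 10), 1)
  dom <- domain_model(g, list(rec1))
  out <- traverse(c(5, 5, 0.2), c(0, 0, 1), 3, dom)
  expect_equal(out$event, "scatter")
  expect_equal(out$position[3], 0.2 + 3 / 2, tolerance = 1e-6)

  # a non-scattering voxel layer is traversed without consuming tau
  lab <- array(1L, c(10, 10, 10)); lab[, , 3:4] <- 2L
  dom2 <- domain_model(voxel_grid(c(10, 10, 10), 1, lab),
                       list(rec1, vac))
  out2 <- traverse(c(5, 5, 0.2), c(0, 0, 1), 5, dom2)
  # tau = 5 at mus = 2 needs 2.5 scattering mm; 1.8 mm before the gap,
  # the 2 mm gap is free, remaining 0.7 mm after it
  expect_equal(out2$position[3], 0.2 + 1.8 + 2 + 0.7, tolerance = 1e-6)

  # two-media piecewise inversion for random rays along +z
  lab3 <- array(1L, c(4, 4, 10)); lab3[, , 6:10] <- 2L
  dom3 <- domain_model(voxel_grid(c(4, 4, 10), 1, lab3), list(rec1, rec2))
  set.seed(6)
  for (i in 1:100) {
    x <- runif(1, 0.1, 3.9); y <- runif(1, 0.1, 3.9)
    z0 <- runif(1, 0, 3); tau <- runif(1, 0.1, 20)
    d1 <- 5 - z0
    zstop <- if (tau <= 2 * d1) z0 + tau / 2 else 5 + (tau - 2 * d1) / 5
    out3 <- traverse(c(x, y, z0), c(0, 0, 1), tau, dom3)
    if (zstop < 10) {
      expect_equal(out3$event, "scatter")
      expect_equal(out3$position[3], zstop, tolerance = 1e-6)
    } else {
      expect_equal(out3$event, "transmit")
    }
  }

  # ambient label-0 voxel terminates the packet
  lab4 <- array(1L, c(4, 4, 4)); lab4[, , 3] <- 0L
  dom4 <- domain_model(voxel_grid(c(4, 4, 4), 1, lab4), list(vac))
  expect_equal(traverse(c(2, 2, 0.5), c(0, 0, 1), 1, dom4)$event, "ambient")
})

test_that("absorption attenuates exponentially and deposits the difference", {
  a <- absorb(1, 2, 0)
  expect_equal(a$weight, 1); expect_equal(a$deposited, 0)
  a <- absorb(0.8, log(2), 1)
  expect_equal(a$weight, 0.4, tolerance = 1e-12)
  expect_equal(a$deposited, 0.4, tolerance = 1e-12)
})

test_that("a full simulation conserves weight to first principles", {
  res <- run_simulation(benchmark_inclusion(photons = 2e4, seed = 11))
  au <- res$audit
  expect_true(au$balanced)
  expect_lt(abs(au$imbalance), 1e-9)
  got <- au$detected + au$transmitted + au$side_escaped +
    au$ambient_escaped + au$absorbed + au$roulette_killed + au$stuck
  expect_equal(got, au$launched + au$boosted, tolerance = 1e-9)
})

test_that("roulette is unbiased and degenerate parameters behave", {
  expect_equal(roulette(0.5), 0.5)          # above threshold: unchanged
  expect_equal(roulette(1e-5, p_survive = 1), 1e-5)
  set.seed(7)
  w <- 5e-5
  out <- roulette(w, w_threshold = 1e-4, p_survive = 0.1, n = 1e5)
  expect_true(all(out %in% c(0, w / 0.1)))
  se <- w * sqrt((1 / 0.1 - 1) / 1e5)
  expect_lt(abs(mean(out) - w), 3 * se)
})

test_that("angle sampling has the exact marginals of the polarized phase function", {
  tab <- scattering_matrix_table(bench_specs$superficial, 1000L)
  set.seed(8)
  # unpolarized input: phi uniform
  sm <- sample_scattering_angles(c(1, 0, 0, 0), tab, 2e4)
  expect_gt(ks.test(sm[, "phi"], punif, 0, 2 * pi)$p.value, 0.01)
  # theta marginal ~ s11 sin(theta) for any polarization
  sm2 <- sample_scattering_angles(c(1, 1, 0, 0), tab, 2e4)
  probs <- phase_bin_probs(tab, c(1, 1, 0, 0),
                           theta_breaks_idx = seq(0, 1000, by = 40), 1)
  ob <- table(cut(sm2[, "theta"], breaks = c(0, tab$theta[seq(40, 1000, by = 40)])))
  expect_gt(chisq.test(as.vector(ob), p = rowSums(probs))$p.value, 0.001)
  # 2D joint distribution against direct quadrature
  probs2 <- phase_bin_probs(tab, c(1, 1, 0, 0),
                            theta_breaks_idx = seq(0, 1000, by = 100), 12)
  tb <- c(0, tab$theta[seq(100, 1000, by = 100)])
  ob2 <- table(cut(sm2[, "theta"], tb),
               cut(sm2[, "phi"], seq(0, 2 * pi, length.out = 13)))
  expect_gt(chisq.test(as.vector(ob2), p = as.vector(probs2))$p.value,
            0.001)
})

test_that("a table with s12 = 0 gives uniform azimuth for every polarization", {
  tab <- scattering_matrix_table(bench_specs$bottom, 500L)
  tab$s12[] <- 0
  tab$s34[] <- 0
  tab$s33 <- tab$s11
  set.seed(9)
  for (s in list(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))) {
    sm <- sample_scattering_angles(s, tab, 5e3)
    expect_gt(ks.test(sm[, "phi"], punif, 0, 2 * pi)$p.value, 0.01)
  }
})

test_that("launch initialises weight, Stokes and nudged position", {
  src <- parse_config(benchmark_homogeneous(photons = 1))$source
  set.seed(10)
  p <- launch(src)
  expect_equal(p$weight, 1)
  expect_equal(p$stokes, c(1, 1, 0, 0))
  expect_equal(p$direction, c(0, 0, 1))
  expect_equal(p$position_mm, c(10, 10, 1e-9))

  plan <- parse_config(benchmark_inclusion(photons = 1))$source
  xs <- t(vapply(1:1e4, function(i) launch(plan)$position_mm, numeric(3)))
  expect_lt(abs(mean(xs[, 1]) - 5), 3 * 10 / sqrt(12) / sqrt(1e4))
  expect_lt(abs(mean(xs[, 2]) - 5), 3 * 10 / sqrt(12) / sqrt(1e4))
})

test_that("cyclic lateral boundaries keep more light than escaping ones", {
  # narrow slab where lateral escape matters
  base <- list(
    domain = list(dims = c(4, 4, 8), voxel_size_mm = 1),
    media = list(list(mua = 0.001, n = 1.33, r_um = 0.3,
                      rho_per_um3 = 2.198e-2, n_sphere = 1.59)),
    source = list(type = "pencil", position_mm = c(2, 2, 0)),
    photons = 2e4, seed = 12)
  esc <- run_simulation(c(base, list(boundary = list(xy = "escape"))))
  cyc <- run_simulation(c(base, list(boundary = list(xy = "cyclic"))))
  expect_equal(cyc$side_escaped, 0)
  expect_gt(esc$side_escaped, 0.1)
  expect_gt(cyc$reflected, esc$reflected + 3 * combined_se(cyc, esc))
})

test_that("identical seeds reproduce bit-identical results", {
  cfg <- benchmark_inclusion(photons = 5e3, seed = 99)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$images, r2$images)
  expect_identical(r1$totals, r2$totals)
  r3 <- run_simulation(cfg, seed = 100)
  expect_false(identical(r1$totals, r3$totals))
})

test_that("polarized transport with a depolarization-free table matches a scalar MC", {
  # synthetic isotropic-ish table with s12 = s34 = 0: the I channel must
  # behave exactly like an intensity-only Monte Carlo with phase s11
  spec <- scatterer_spec(0.01, 1, 1.59, 1.33, 632.8)  # Rayleigh-like
  tab <- scattering_matrix_table(spec, 400L)
  tab$s12[] <- 0; tab$s34[] <- 0; tab$s33 <- tab$s11
  mus <- 2; L <- 2
  cfg <- list(
    domain = list(dims = c(40, 40, L), voxel_size_mm = 1),
    media = list(list(mua = 0, n = 1.33, mus = mus, g = 0, table = tab)),
    source = list(type = "pencil", position_mm = c(20, 20, 0)),
    boundary = list(xy = "escape"),
    detector = list(pixels = c(200, 200)),
    photons = 4000, seed = 13)
  res <- run_simulation(cfg)
  # exit radii of reflected photons from the pixel images; the reference
  # exits are snapped to the same pixel grid so both distributions carry
  # identical discretisation
  img <- res$images$I
  pitch <- 40 / nrow(img)
  xc <- (seq_len(nrow(img)) - 0.5) * pitch - 20
  r_pix <- sqrt(outer(xc^2, xc^2, `+`))
  set.seed(14)
  ref <- scalar_slab_mc(4000, mus, L, tab)
  refl <- ref$face == "reflect" & !is.na(ref$face)
  # random exit azimuth: the reference tracks radius only
  ang <- runif(sum(refl), 0, 2 * pi)
  rx <- ref$r[refl] * cos(ang); ry <- ref$r[refl] * sin(ang)
  r_ref <- sqrt((floor((rx + 20) / pitch) * pitch + pitch / 2 - 20)^2 +
                (floor((ry + 20) / pitch) * pitch + pitch / 2 - 20)^2)
  breaks <- c(0, 0.5, 1, 2, 4, 8, Inf)
  obs_pol <- vapply(seq_len(length(breaks) - 1), function(b) {
    sum(img[r_pix > breaks[b] & r_pix <= breaks[b + 1]])
  }, numeric(1))
  obs_ref <- as.vector(table(cut(r_ref, breaks)))
  # append the transmitted counts as a final class
  obs_pol <- c(obs_pol, res$transmitted * res$n_photons)
  obs_ref <- c(obs_ref, sum(ref$face == "transmit", na.rm = TRUE))
  M <- rbind(obs_pol, obs_ref)
  keep <- colSums(M) > 5
  expect_gt(chisq.test(M[, keep])$p.value, 0.01)
})
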