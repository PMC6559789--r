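const_table <- function(mu = 1, rho = 1)
  attenuation_table("const", rho, c(5, 50), c(mu, mu))

test_that("linear attenuation interpolates log-log and respects table bounds", {
  expect_equal(linear_attenuation(const_table(), c(5, 17.3, 50)), rep(1, 3))
  tab <- attenuation_table("toy", 1, c(10, 20), c(1, 4))
  # geometric midpoint in E maps to the geometric midpoint in mu/rho
  expect_equal(linear_attenuation(tab, sqrt(10 * 20)), 2, tolerance = 1e-12)
  expect_error(linear_attenuation(tab, 9.9), "range")
  expect_error(linear_attenuation(tab, 21), "range")
  # density scales linearly
  tab2 <- attenuation_table("toy", 2.5, c(10, 20), c(1, 4))
  expect_equal(linear_attenuation(tab2, 12), 2.5 * linear_attenuation(tab, 12))
})

test_that("absorption edges give pre-edge left limits and post-edge values", {
  tab <- attenuation_table("edgy", 1, c(8, 12, 12, 20), c(2, 1, 5, 3))
  expect_equal(linear_attenuation(tab, 12), 5)          # at the edge: post
  below <- linear_attenuation(tab, 12 - 1e-9)
  expect_equal(below, 1, tolerance = 1e-6)              # left limit: pre
  # the jump equals the tabulated ratio
  expect_equal(linear_attenuation(tab, 12) / below, 5, tolerance = 1e-5)
})

test_that("transmission follows Beer-Lambert and composes over thickness", {
  w <- zf_attenuation("water"); tw <- zf_attenuation("tungsten")
  # (near-)vacuum background: nothing attenuates; exact zero is rejected
  expect_error(const_table(0), "positive")
  sv <- cnr_scenario(const_table(1e-14), 1, tw, 0, 0.05, I0 = 7)
  expect_equal(transmitted_intensity(sv, 15), 7, tolerance = 1e-12)
  # half-value layer: mu*d = ln 2 halves the beam
  shv <- cnr_scenario(const_table(log(2)), 1, tw, 0, 0.05, I0 = 10)
  expect_equal(transmitted_intensity(shv, 15), 5)
  expect_equal(transmitted_intensity(shv, 15, with_detail = TRUE), 5)
  # detail ratio identity: I2/I1 = exp(-mu_c d_c)
  s <- cnr_scenario(w, 0.3, tw, 5e-4, 0.05)
  for (E in c(9, 12.5, 16, 25)) {
    i1 <- transmitted_intensity(s, E)
    i2 <- transmitted_intensity(s, E, with_detail = TRUE)
    expect_equal(i2 / i1, exp(-linear_attenuation(tw, E, density = 0.05) * 5e-4),
                 tolerance = 1e-12)
  }
  # composability: d1 then d2 equals d1 + d2
  set.seed(4)
  for (i in 1:20) {
    d1 <- runif(1, 0, 0.3); d2 <- runif(1, 0, 0.3); E <- runif(1, 8.5, 29)
    sa <- cnr_scenario(w, d1, tw, 0, 0.05)
    sb <- cnr_scenario(w, d2, tw, 0, 0.05)
    sc <- cnr_scenario(w, d1 + d2, tw, 0, 0.05)
    expect_equal(transmitted_intensity(sa, E) * transmitted_intensity(sb, E),
                 transmitted_intensity(sc, E), tolerance = 1e-12)
  }
})

test_that("reconstruction variance is k over transmitted intensity", {
  tw <- zf_attenuation("tungsten")
  s <- cnr_scenario(const_table(0.5), 1, tw, 5e-4, 0.05, I0 = 1, k = 1)
  expect_equal(reconstruction_variance(s, 15),
               1 / transmitted_intensity(s, 15))
  s2 <- cnr_scenario(const_table(0.5), 1, tw, 5e-4, 0.05, I0 = 2, k = 1)
  expect_equal(reconstruction_variance(s2, 15),
               reconstruction_variance(s, 15) / 2)
  # the detail only ever removes photons: var2 >= var1, over random scenarios
  w <- zf_attenuation("water")
  set.seed(6)
  for (i in 1:20) {
    ss <- cnr_scenario(w, runif(1, 0.05, 1), tw, runif(1, 0, 0.01),
                       runif(1, 0, 0.3))
    E <- runif(1, 8.5, 29)
    expect_gte(reconstruction_variance(ss, E, TRUE),
               reconstruction_variance(ss, E, FALSE))
  }
})

test_that("CNR vanishes without contrast, scales as sqrt(I0), falls with depth", {
  w <- zf_attenuation("water"); tw <- zf_attenuation("tungsten")
  s0 <- cnr_scenario(w, 0.3, tw, 5e-4, 0)
  expect_equal(cnr(s0, c(9, 13.8, 20)), rep(0, 3))
  s1 <- cnr_scenario(w, 0.3, tw, 5e-4, 0.05, I0 = 1)
  s4 <- cnr_scenario(w, 0.3, tw, 5e-4, 0.05, I0 = 4)
  expect_equal(cnr(s4, 13.8) / cnr(s1, 13.8), 2, tolerance = 1e-12)
  # monotone decreasing in background thickness
  v <- vapply(seq(0.05, 1, by = 0.05), function(d)
    cnr(cnr_scenario(w, d, tw, 5e-4, 0.05), 13.8), numeric(1))
  expect_true(all(diff(v) < 0))
  # the arbitrary variance constant rescales but never reranks energies
  E <- seq(9, 25, by = 0.5)
  ka <- cnr_curve(cnr_scenario(w, 0.3, tw, 5e-4, 0.05, k = 1), E)
  kb <- cnr_curve(cnr_scenario(w, 0.3, tw, 5e-4, 0.05, k = 37), E)
  expect_equal(order(ka$cnr), order(kb$cnr))
  expect_equal(kb$cnr / ka$cnr, rep(1 / sqrt(37), length(E)), tolerance = 1e-12)
})

test_that("CNR curve matches pointwise evaluation, jumps only at edges", {
  w <- zf_attenuation("water"); tw <- zf_attenuation("tungsten")
  s <- cnr_scenario(w, 0.3, tw, 5e-4, 0.05)
  expect_error(cnr_curve(s, numeric(0)), "empty")
  grid <- energy_grid(tw, by = 0.1)
  cu <- cnr_curve(s, grid)
  expect_equal(cu$cnr, cnr(s, grid))
  expect_equal(attr(cu, "cnr_opt"), max(cu$cnr))
  expect_equal(attr(cu, "E_opt"), cu$E_keV[which.max(cu$cnr)])
  # discontinuous at the tungsten L edges, smooth on constant tables
  for (edge in c(10.2068, 11.544, 12.0998)) {
    jump <- cnr(s, edge) / cnr(s, edge - 1e-9)
    expect_gt(abs(log(jump)), 0.05)
  }
  sc <- cnr_scenario(const_table(3), 0.3, const_table(20), 5e-4, 0.05)
  g2 <- seq(6, 49, by = 0.5)
  c2 <- cnr_curve(sc, g2)$cnr
  expect_true(all(abs(diff(c2) / c2[-1]) < 0.05))
})

test_that("throughput arithmetic matches the batch model", {
  p1 <- throughput_params(setup_min = 5, scans_per_fish = 3, scan_min = 20,
                          multiplex = 1, replicates = 1, conditions = 1,
                          scan_days_per_year = 100, hours_per_day = 10)
  r1 <- estimate_throughput(p1)
  expect_equal(r1$total_hours, 65 / 60)
  expect_equal(r1$years, 65 / 60 / 1000)
  # pink-beam style 20 s scans shrink only the scan term, by exactly 60x
  p2 <- p1; p2$scan_min <- 20 / 60
  r2 <- estimate_throughput(p2)
  expect_equal(r1$total_hours - 5 / 60, (r2$total_hours - 5 / 60) * 60)
  # full-campaign scenario: 20,000 conditions x 10 replicates, multiplex 5
  camp <- estimate_throughput(throughput_params())
  expect_equal(camp$specimens, 2e5)
  expect_equal(camp$batches, 4e4)
  expect_equal(camp$years, 4e4 * 65 / 60 / 1000)
  expect_error(throughput_params(scan_min = 0), "positive")
})
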