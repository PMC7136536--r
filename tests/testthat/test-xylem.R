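tbl <- list(l = 50, r = 0.02, k_r = 1.73e-4, k_x = 4.32e-2,
            psi_s = -200, psi_0 = -1000)

test_that("closed form: collar value, tip no-flux, benchmark tip value", {
  expect_equal(single_root_psi(0, tbl$l, tbl$r, tbl$k_r, tbl$k_x,
                               tbl$psi_s, tbl$psi_0), -1000)
  # zero axial flow at the tip: dpsi/dzeta -> 0
  h <- 1e-6
  d <- (single_root_psi(tbl$l, tbl$l, tbl$r, tbl$k_r, tbl$k_x, tbl$psi_s,
                        tbl$psi_0) -
          single_root_psi(tbl$l - h, tbl$l, tbl$r, tbl$k_r, tbl$k_x,
                          tbl$psi_s, tbl$psi_0)) / h
  expect_lt(abs(d), 1e-3)
  # tip value from the cosh closed form: c*l = 1.1217, cosh = 1.6979
  tip <- single_root_psi(tbl$l, tbl$l, tbl$r, tbl$k_r, tbl$k_x, tbl$psi_s,
                         tbl$psi_0)
  expect_equal(tip, -200 - 800 / cosh(sqrt(2 * tbl$r * pi * tbl$k_r /
                                             tbl$k_x) * tbl$l),
               tolerance = 1e-12)
  expect_lt(abs(tip - (-671.2)), 0.1)
  expect_error(single_root_psi(0, tbl$l, tbl$r, tbl$k_r, 0, -200, -1000))
})

test_that("property lookups: constants, knots, clamping", {
  const <- constant_hydraulics()
  p <- props_at(const, c(0, 5, 100))
  expect_equal(p$k_r, rep(1.73e-4, 3))
  expect_equal(p$k_x, rep(4.32e-2, 3))
  aged <- age_dependent_hydraulics()
  # exact at tabulated knots
  expect_equal(props_at(aged, 10, "tap")$k_x, 4.32e-2)
  for (knot in seq_len(nrow(aged$k_r$tap)))
    expect_equal(props_at(aged, aged$k_r$tap$age[knot], "tap")$k_r,
                 aged$k_r$tap$value[knot])
  # clamped beyond the last knot
  expect_equal(props_at(aged, 500, "tap")$k_x,
               props_at(aged, 40, "tap")$k_x)
  expect_error(props_at(aged, 1, "unknown_type"), "unknown root type")
  # maturation pattern: k_r falls, k_x rises
  ages <- c(0, 5, 20)
  expect_true(all(diff(props_at(aged, ages, "tap")$k_r) < 0))
  expect_true(all(diff(props_at(aged, ages, "tap")$k_x) > 0))
})

test_that("network solver converges to the closed form at second order", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(dz) {
    rs <- single_root_system(50, dz)
    sol <- solve_xylem(rs, constant_hydraulics(), -200, collar_head(-1000))
    ana <- single_root_psi(-rs$nodes$z, tbl$l, tbl$r, tbl$k_r, tbl$k_x,
                           tbl$psi_s, tbl$psi_0)
    max(abs(sol$psi_x - ana))
  }, numeric(1))
  expect_lt(errs[3], 1e-3)
  order1 <- log2(errs[1] / errs[2])
  order2 <- log2(errs[2] / errs[3])
  expect_gt(order1, 1.8); expect_gt(order2, 1.8)
})

test_that("k_r = 0 decouples the root from the soil", {
  rs <- single_root_system(20, 0.5)
  sol <- solve_xylem(rs, root_hydraulics(k_r = 0, k_x = 4.32e-2), -200,
                     collar_head(-1000))
  expect_lt(max(abs(sol$psi_x - (-1000))), 1e-8)
  expect_lt(max(abs(sol$Q_rad)), 1e-12)
  expect_lt(abs(sol$collar_flow), 1e-12)
})

test_that("node balance and collar conservation hold on branched systems", {
  rs <- grow_root_system(fixture_params("lupine"), 12, seed = 4)
  rs <- discretize_root_system(rs, 0.5)
  set.seed(1)
  psi_s <- runif(nrow(rs$segments), -400, -150)
  sol <- solve_xylem(rs, constant_hydraulics(), psi_s, collar_head(-800))
  # collar flow equals the sum of radial inflows (global conservation)
  expect_equal(sol$collar_flow, sum(sol$Q_rad), tolerance = 1e-12)
  # node-wise balance: axial inflow + lumped radial inflow = axial outflow
  nd <- rs$nodes; sg <- rs$segments
  id2row <- match(seq_len(max(nd$id)), nd$id)
  ip <- id2row[sg$prox]; jp <- id2row[sg$dist]
  resid <- numeric(nrow(nd))
  seg_rad_half <- 2 * pi * ((nd$radius[ip] + nd$radius[jp]) / 2) *
    segment_lengths(rs) * sol$k_r / 2
  for (s in seq_len(nrow(sg))) {
    resid[ip[s]] <- resid[ip[s]] - sol$Q_ax[s] +
      seg_rad_half[s] * (psi_s[s] - sol$psi_x[ip[s]])
    resid[jp[s]] <- resid[jp[s]] + sol$Q_ax[s] +
      seg_rad_half[s] * (psi_s[s] - sol$psi_x[jp[s]])
  }
  collar_row <- id2row[1L]
  scale <- max(abs(sol$Q_ax))
  expect_lt(max(abs(resid[-collar_row])) / scale, 1e-9)
  # the collar residual is the collar outflow
  expect_equal(resid[collar_row], sol$collar_flow, tolerance = 1e-9)
})

test_that("collar flux mode switches to the critical head when exceeded", {
  rs <- single_root_system(50, 0.25)
  props <- constant_hydraulics()
  mild <- solve_xylem(rs, props, -200, collar_flux(0.1, -15290))
  expect_false(mild$stressed)
  expect_equal(mild$collar_flow, 0.1, tolerance = 1e-9)
  hard <- solve_xylem(rs, props, -200, collar_flux(50, -15290))
  expect_true(hard$stressed)
  expect_equal(hard$collar_psi, -15290)
  expect_lt(hard$collar_flow, 50)
  # the pinned solution equals the equivalent head solve
  pinned <- solve_xylem(rs, props, -200, collar_head(-15290))
  expect_equal(hard$psi_x, pinned$psi_x, tolerance = 1e-10)
})

test_that("age-dependent properties change tip pressure, same collar", {
  rs <- discretize_root_system(make_fixture("lupine-like-14d", seed = 2),
                               0.5)
  sa <- solve_xylem(rs, constant_hydraulics(), -200, collar_head(-500),
                    t = 14)
  sb <- solve_xylem(rs, age_dependent_hydraulics(), -200,
                    collar_head(-500), t = 14)
  expect_equal(sa$collar_psi, -500)
  expect_equal(sb$collar_psi, -500)
  # the tip-region pressures differ between the parameterizations
  tipward <- which(-rs$nodes$z > 0.8 * max(-rs$nodes$z))
  expect_gt(max(abs(sa$psi_x[tipward] - sb$psi_x[tipward])), 1)
})

test_that("gravity flag shifts a no-flow root to a hydrostatic profile", {
  rs <- single_root_system(50, 0.5)
  sol <- solve_xylem(rs, root_hydraulics(k_r = 0, k_x = 4.32e-2), -200,
                     collar_head(-1000), gravity = TRUE)
  # zero flow with gravity: total head constant, psi increases with depth
  expect_lt(max(abs((sol$psi_x + rs$nodes$z) - (-1000))), 1e-8)
})
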