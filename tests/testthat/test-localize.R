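test_that("wrapped normal density: normalization, symmetry, uniform limit", {
  # quadrature over the circle for three sd values
  th <- seq(-pi, pi, length.out = 4001)[-1]
  h <- th[2] - th[1]
  for (s in c(0.3, 1, 3)) {
    integral <- sum(dwrapnorm(th, mean = 0.7, sd = s)) * h
    expect_equal(integral, 1, tolerance = 1e-6)
  }
  # symmetry about the mean
  expect_equal(dwrapnorm(0.7 + 0.4, 0.7, 0.8), dwrapnorm(0.7 - 0.4, 0.7, 0.8))
  # large sd -> circular uniform 1/(2 pi)
  expect_equal(dwrapnorm(c(-2, 0, 2), 0, 50), rep(1 / (2 * pi), 3),
               tolerance = 1e-6)
  expect_error(dwrapnorm(0, 0, -1))
})

test_that("odds ratio: uninformative p = 0, collapsed ratio, scalar oracle", {
  par <- geometry_params()
  an <- list(x = 500, y = 500, mu = 0.3, p = 0, t_s = 10)
  o <- odds_surface(c(100, 900), c(100, 900), an, par)
  expect_equal(o, c(1, 1))
  # p = 1 with response == null geometry: mixture reading collapses to 1,
  # additive reading to 2
  par_eq <- geometry_params(mu1_poly = c(par$mu0, 0, 0, 0),
                            logsigma1_poly = c(log(par$sigma0), 0, 0, 0),
                            logrho1_poly = c(log(par$rho0), 0, 0, 0),
                            mu0 = par$mu0, sigma0 = par$sigma0,
                            rho0 = par$rho0)
  an1 <- list(x = 500, y = 500, mu = 0.3, p = 1, t_s = 10)
  expect_equal(odds_surface(c(100, 900), c(150, 900), an1, par_eq),
               c(1, 1), tolerance = 1e-12)
  expect_equal(odds_surface(c(100, 900), c(150, 900), an1, par_eq,
                            numerator = "additive"),
               c(2, 2), tolerance = 1e-12)
  # hand evaluation at one cell
  an2 <- list(x = 300, y = 0, mu = 0, p = 0.8, t_s = 0)
  par2 <- geometry_params(mu1_poly = c(log(300), 0, 0, 0),
                          logsigma1_poly = c(log(0.4), 0, 0, 0),
                          logrho1_poly = c(log(0.5), 0, 0, 0),
                          mu0 = log(800), sigma0 = 0.7, rho0 = 2)
  cell <- c(0, 0)
  gam <- 300; theta <- 0
  f_resp <- dwrapnorm(theta, 0, 0.5) * dlnorm(gam, log(300), 0.4)
  f_null <- dwrapnorm(theta, 0, 2) * dlnorm(gam, log(800), 0.7)
  expect_equal(odds_surface(cell[1], cell[2], an2, par2),
               (0.8 * f_resp + 0.2 * f_null) / f_null, tolerance = 1e-12)
})

test_that("probability surface: normalization, peak geometry, opposed flights", {
  par <- geometry_params(mu1_poly = c(log(400), 0, 0, 0),
                         logsigma1_poly = c(log(0.3), 0, 0, 0),
                         logrho1_poly = c(log(0.4), 0, 0, 0))
  bb <- ews_bbox(0, 3000, 0, 3000)
  # single animal at centre fleeing east: peak west of it near the mode
  sn <- data.frame(x = 1500, y = 1500, mu = 0, p = 1, t_s = 0)
  su <- probability_surface(sn, par, bb, cell_m = 50)
  expect_equal(surface_integral(su), 1, tolerance = 1e-9)
  expect_lt(su$peak["x"], 1500)
  expect_equal(unname(su$peak["y"]), 1500, tolerance = 100)
  expect_equal(unname(1500 - su$peak["x"]), 400, tolerance = 120)
  # two animals fleeing in opposite directions from a common origin
  sn2 <- data.frame(x = c(1900, 1100), y = c(1500, 1500), mu = c(0, pi),
                    p = 1, t_s = 0)
  su2 <- probability_surface(sn2, par, bb, cell_m = 50)
  expect_equal(unname(su2$peak["x"]), 1500, tolerance = 150)
  expect_equal(unname(su2$peak["y"]), 1500, tolerance = 150)
  # translation equivariance
  sn3 <- sn2
  sn3$x <- sn3$x + 300; sn3$y <- sn3$y - 200
  bb3 <- ews_bbox(300, 3300, -200, 2800)
  su3 <- probability_surface(sn3, par, bb3, cell_m = 50)
  expect_equal(unname(su3$peak["x"] - su2$peak["x"]), 300)
  expect_equal(unname(su3$peak["y"] - su2$peak["y"]), -200)
  expect_equal(as.vector(su3$P), as.vector(su2$P), tolerance = 1e-9)
})

test_that("geometry recovery from 200 simulated flights", {
  par <- geometry_params(mu1_poly = c(5.5, 0.05, -4e-4, 0),
                         logsigma1_poly = c(log(0.45), 0, 0, 0),
                         logrho1_poly = c(log(0.5), 0, 0, 0),
                         mu0 = 7.1, sigma0 = 0.65, rho0 = 8)
  set.seed(13)
  ts_all <- runif(4000, 0, 45)
  g <- response_geometry(par, ts_all)
  resp <- data.frame(t_s = ts_all,
                     dist = rlnorm(4000, g$mu1, g$sigma1),
                     delta = rnorm(4000, 0, g$rho1))
  null <- data.frame(dist = rlnorm(3000, 7.1, 0.65),
                     delta = runif(3000, -pi, pi))
  fit <- suppressMessages(fit_geometry(resp, null))
  for (tt in c(0, 15, 30, 45)) {
    gt <- response_geometry(par, tt); gf <- response_geometry(fit, tt)
    expect_equal(gf$mu1, gt$mu1, tolerance = 0.08)
    expect_equal(gf$sigma1, gt$sigma1, tolerance = 0.12)
    expect_equal(gf$rho1, gt$rho1, tolerance = 0.15)
  }
  # isotropic control directions -> large fitted rho0 (near-uniform)
  expect_gt(fit$rho0, 1.5)
  # t_s beyond truncation is clamped before polynomial evaluation
  expect_equal(response_geometry(fit, 60)$mu1, response_geometry(fit, 45)$mu1)
})

test_that("localization error decreases with the number of responding sentinels", {
  par <- geometry_params(mu1_poly = c(log(400), 0.02, 0, 0),
                         logsigma1_poly = c(log(0.4), 0, 0, 0),
                         logrho1_poly = c(log(0.5), 0, 0, 0))
  bb <- ews_bbox(0, 3000, 0, 3000)
  errs <- sapply(c(1, 4, 12), function(nr) {
    mean(sapply(1:8, function(s) {
      sn <- simulate_snapshot(par, n_respond = nr, n_null = 8,
                              intruder = c(1500, 1500), bbox = bb,
                              seed = s, t_s = 10)
      su <- probability_surface(sn, par, bb, cell_m = 100)
      sqrt(sum((su$peak - c(1500, 1500))^2))
    }))
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[2], errs[1] * 1.3)
})

test_that("surface condensation matches a brute-force top-5% area and drives selection", {
  par <- geometry_params()
  bb <- ews_bbox(0, 2000, 0, 2000)
  set.seed(20)
  surfs <- lapply(1:10, function(s) {
    sn <- simulate_snapshot(par, n_respond = 3, n_null = 5,
                            intruder = c(1000, 1000), bbox = bb, seed = s)
    probability_surface(sn, par, bb, cell_m = 100)
  })
  for (su in surfs) {
    mass <- sort(as.vector(su$P) * su$cell_m^2, decreasing = TRUE)
    brute <- which(cumsum(mass) >= 0.05)[1] * su$cell_m^2
    expect_equal(su$condensation_m2, brute)
  }
  # evaluation: peaked-at-truth surface has zero error; uniform surfaces are
  # the least condensed and drop out of the top selection
  sdf <- data.frame(intrusion_id = "i1",
                    peak_x = c(1000, rep(1500, 3)),
                    peak_y = c(1000, rep(1500, 3)),
                    condensation_m2 = c(1e4, 2e6, 2e6, 2e6),
                    truth_x = 1000, truth_y = 1000)
  ev <- evaluate_localization(sdf, n_best = 1)
  expect_equal(ev$per_intrusion$mean_error_m, 0)
  ev2 <- evaluate_localization(sdf, n_best = 10)
  expect_true(ev2$per_intrusion$flagged_short)
})
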