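# Loop internal coordinates, classification and trends.

test_that("principal_vector is oriented N-to-C and handles lines", {
  z <- cbind(0, 0, seq(0, 9))
  expect_equal(principal_vector(z), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(principal_vector(z[rev(seq_len(nrow(z))), ]), c(0, 0, -1),
               tolerance = 1e-9)
  helix <- loopchron:::ideal_trace("H", 10)
  rot <- helix[, c(3, 1, 2)]  # axis now +x
  pv <- principal_vector(rot)
  expect_gt(pv[1], 0.99)
  expect_error(principal_vector(matrix(1, 5, 3)), "coincident")
  expect_error(principal_vector(z[1:3, ]), ">= 4")
})

test_that("colinear and antiparallel constructions give exact angles", {
  lp0 <- simulate_loop_coordinates("HH", D = 3, delta = 0, theta = 0,
                                   rho = 0, n_res = c(8, 4, 8))
  g0 <- internal_coordinates(lp0)
  expect_equal(g0$D, 3, tolerance = 1e-9)
  expect_lt(g0$delta, 1e-6)
  expect_lt(g0$theta, 1e-6)
  lp180 <- simulate_loop_coordinates("HH", D = 5, delta = 0, theta = 180,
                                     rho = 0, n_res = c(8, 4, 8))
  expect_equal(internal_coordinates(lp180)$theta, 180, tolerance = 1e-6)
})

test_that("requested coordinates round-trip on a (theta, rho) grid", {
  for (type in c("HE", "EH", "GG")) {
    for (th in c(30, 90, 150)) for (rh in c(45, 180, 315)) {
      lp <- simulate_loop_coordinates(type, D = 6.5, delta = 5, theta = th,
                                      rho = rh, n_res = c(8, 6, 8))
      g <- internal_coordinates(lp)
      expect_equal(g$D, 6.5, tolerance = 1e-3)
      expect_equal(g$delta, 5, tolerance = 1)
      expect_equal(g$theta, th, tolerance = 1)
      expect_equal(g$rho, rh, tolerance = 1)
    }
  }
})

test_that("incompatible coordinate requests are rejected", {
  # delta = 90, rho = 90: M2 orthogonal constraint cannot give theta = 30
  expect_error(simulate_loop_coordinates("HH", delta = 90, theta = 30,
                                         rho = 90),
               "incompatible")
  expect_error(simulate_loop_coordinates("HH", D = -1), "positive")
  expect_error(simulate_loop_coordinates("HH", n_res = c(3, 4, 8)), ">= 4")
})

test_that("internal coordinates are rigid-motion invariant", {
  set.seed(55)
  lp <- simulate_loop_coordinates("HE", D = 7, delta = 40, theta = 110,
                                  rho = 200, n_res = c(9, 5, 7))
  g <- internal_coordinates(lp)
  for (i in 1:5) {
    mo <- random_rigid_motion()
    g2 <- internal_coordinates(apply_motion(lp, mo))
    expect_equal(g2$D, g$D, tolerance = 1e-6)
    expect_equal(g2$delta, g$delta, tolerance = 1e-6)
    expect_equal(g2$theta, g$theta, tolerance = 1e-6)
    expect_equal(g2$rho, g$rho, tolerance = 1e-6)
  }
})

test_that("angles stay in range for random valid structures", {
  set.seed(66)
  for (i in 1:200) {
    lp <- simulate_loop_coordinates(sample(c("HH", "HE", "EH", "GG"), 1),
                                    D = runif(1, 3, 12),
                                    delta = runif(1, 5, 175),
                                    theta = 90,  # always feasible
                                    rho = runif(1, 0, 359.9),
                                    n_res = c(8, 5, 8),
                                    noise_sd = 0.1, seed = i)
    g <- internal_coordinates(lp)
    expect_true(g$D > 0)
    expect_true(g$delta >= 0 && g$delta <= 180)
    expect_true(g$theta >= 0 && g$theta <= 180)
    expect_true(g$rho >= 0 && g$rho < 360)
    expect_equal(sqrt(sum(g$M1^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(g$M2^2)), 1, tolerance = 1e-9)
  }
})

test_that("noisy round trips stay within the advertised tolerance", {
  for (i in 1:10) {
    lp <- simulate_loop_coordinates("HH", D = 8, delta = 30, theta = 120,
                                    rho = 250, n_res = c(10, 6, 10),
                                    noise_sd = 0.2, seed = i)
    g <- internal_coordinates(lp)
    expect_equal(g$theta, 120, tolerance = 5)
    expect_equal(g$rho, 250, tolerance = 5)
  }
})

test_that("loop types follow the SS labels with the BN/BK split", {
  mk <- function(type, theta, adjacent = TRUE) {
    lp <- simulate_loop_coordinates(type, D = 6, delta = 30, theta = theta,
                                    rho = 180, n_res = c(6, 4, 6))
    lp$adjacent <- adjacent
    lp
  }
  expect_equal(classify_loop_type(mk("EH", 90)), "EH")
  expect_equal(classify_loop_type(mk("HG", 90)), "HG")
  expect_equal(classify_loop_type(mk("BN", 165)), "BN")
  expect_equal(classify_loop_type(mk("BN", 30)), "BK")
  expect_equal(classify_loop_type(mk("BN", 165, adjacent = FALSE)), "BK")
})

test_that("element lengths equal the generator inputs and conserve totals", {
  lp <- simulate_loop_coordinates("HE", n_res = c(8, 6, 7))
  el <- element_lengths(lp)
  expect_equal(unname(el), c(8, 6, 7))
  expect_equal(sum(el), nrow(lp$ss1) + nrow(lp$loop) + nrow(lp$ss2))
})

test_that("phase trends report exact medians and quartiles", {
  geoms <- data.frame(phase = c(0, 0, 0, 1),
                      loop_type = c("HH", "HH", "HH", "BN"),
                      theta = c(100, 150, 200, 42))
  tr <- geometry_phase_trends(geoms, metrics = "theta")
  m0 <- tr$by_phase[tr$by_phase$phase == 0, ]
  expect_equal(m0$median, 150)
  m1 <- tr$by_phase[tr$by_phase$phase == 1, ]
  expect_equal(m1$median, 42)  # single loop: median is its value
  expect_equal(tr$by_type$median[tr$by_type$loop_type == "HH"], 150)
})

test_that("PDB + sidecar round trip preserves structure and labels", {
  lp <- simulate_loop_coordinates("EH", D = 6, delta = 25, theta = 140,
                                  rho = 300, n_res = c(5, 4, 6))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_loop_structure(lp, path)
  back <- read_loop_structure(path)
  expect_equal(back$ss1, lp$ss1, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$ss2, lp$ss2, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$ss1_type, "E")
  expect_equal(back$ss2_type, "H")
  g1 <- internal_coordinates(lp)
  g2 <- internal_coordinates(back)
  expect_equal(g2$theta, g1$theta, tolerance = 0.1)
})

test_that("the approximate SS guesser separates ideal helix from strand", {
  helix <- loopchron:::ideal_trace("H", 12)
  strand <- loopchron:::ideal_trace("E", 12)
  expect_true(mean(guess_secondary_structure(helix) == "H") > 0.8)
  expect_true(mean(guess_secondary_structure(strand) == "E") > 0.8)
  g310 <- loopchron:::ideal_trace("G", 12)
  expect_true(mean(guess_secondary_structure(g310) == "G") > 0.8)
})
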