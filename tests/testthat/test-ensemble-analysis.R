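test_that("MCH assignment picks the dominant spin component", {
  expect_identical(mch_assignment(diag(5) + 0i, 4), 4L)
  # brute-force argmax oracle on random unitaries
  set.seed(6)
  for (k in 1:20) {
    A <- matrix(complex(real = rnorm(49), imaginary = rnorm(49)), 7, 7)
    U <- qr.Q(qr(A))
    for (col in c(1, 4, 7)) {
      oracle <- 0; best <- -1
      for (i in 1:7) {
        if (Mod(U[i, col])^2 > best) { best <- Mod(U[i, col])^2; oracle <- i }
      }
      expect_identical(mch_assignment(U, col), oracle)
    }
  }
})

test_that("spectroscopic classification partitions dipole magnitudes", {
  expect_identical(classify_spectroscopic(0.2), "bright-pipi")
  expect_identical(classify_spectroscopic(0.01), "dark-npi")
  expect_identical(classify_spectroscopic(1e-7), "triplet")
  # boundary values: 0.05 exactly is dark (strict > for bright), 1e-6 is dark
  expect_identical(classify_spectroscopic(0.05), "dark-npi")
  expect_identical(classify_spectroscopic(1e-6), "dark-npi")
  expect_identical(classify_spectroscopic(0.3, multiplicity = 3L), "triplet")
  expect_identical(classify_spectroscopic(0.3, is_ground = TRUE),
                   "S0-closed-shell")
  expect_error(classify_spectroscopic(-0.1), "non-negative")
  # every input maps to exactly one class
  mags <- c(0, 1e-9, 1e-6, 1e-3, 0.05, 0.0500001, 2)
  labs <- classify_spectroscopic(mags)
  expect_true(all(labs %in% c("S0-closed-shell", "bright-pipi", "dark-npi",
                              "triplet")))
  expect_identical(length(labs), length(mags))
})

test_that("population traces match a hand-enumerated step function", {
  sp <- make_state_space(4, 3)
  tgrid <- seq(0, 10, by = 1)
  # trajectory A: S2 until t=4, then S1; B: S2 throughout; C: S2 -> T1 at t=7
  a <- toy_trajectory(sp, tgrid, c(rep(3L, 5), rep(2L, 6)))
  b <- toy_trajectory(sp, tgrid, rep(3L, 11))
  cc <- toy_trajectory(sp, tgrid, c(rep(3L, 8), rep(5L, 3)))
  tr <- ensemble_populations(list(a, b, cc), "MCH", grid = tgrid)
  expect_equal(tr$S2, c(1, 1, 1, 1, 1, 2/3, 2/3, 2/3, 1/3, 1/3, 1/3))
  expect_equal(tr$S1, c(0, 0, 0, 0, 0, 1/3, 1/3, 1/3, 1/3, 1/3, 1/3))
  expect_equal(tr$T1, c(0, 0, 0, 0, 0, 0, 0, 0, 1/3, 1/3, 1/3))
  # conservation at every time in every representation
  sums <- rowSums(as.data.frame(tr)[, attr(tr, "classes")])
  expect_lt(max(abs(sums - 1)), 1e-10)
  # all trajectories permanently in one state
  tr1 <- ensemble_populations(list(b), "MCH", grid = tgrid)
  expect_true(all(tr1$S2 == 1))
  expect_error(ensemble_populations(list(), "MCH"), "empty")
})

test_that("early-terminated trajectories are held in their terminal class", {
  sp <- make_state_space(4, 3)
  short <- toy_trajectory(sp, 0:5, c(3L, 3L, 3L, 5L, 5L, 5L),
                          status = "crashed")
  full <- toy_trajectory(sp, 0:10, rep(3L, 11))
  tr <- ensemble_populations(list(short, full), "MCH", grid = 0:10)
  expect_equal(tr$T1[7:11], rep(0.5, 5))
})

test_that("the validity filter keeps completed and settled trajectories", {
  sp <- make_state_space(4, 3)
  t_max <- 100
  done <- toy_trajectory(sp, seq(0, 100, 0.5), rep(3L, 201))
  # crashed after 20 fs continuously in T1
  settled <- toy_trajectory(sp, seq(0, 60, 0.5),
                            c(rep(3L, 81), rep(5L, 40)), status = "crashed")
  # crashed with only 5 fs in S0
  brief <- toy_trajectory(sp, seq(0, 60, 0.5),
                          c(rep(3L, 111), rep(1L, 10)), status = "crashed")
  out <- filter_trajectories(list(done, settled, brief), t_max)
  expect_length(out$kept, 2)
  expect_length(out$discarded, 1)
  # monotonicity: raising the threshold never enlarges the kept set
  sizes <- vapply(c(0, 5, 10, 15, 20, 25), function(th) {
    length(filter_trajectories(list(done, settled, brief), t_max, th)$kept)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hop statistics tally the event classes and ISC means", {
  sp <- make_state_space(4, 3)
  none <- toy_trajectory(sp, 0:5, rep(3L, 6))
  hs0 <- hop_statistics(list(none))
  expect_true(all(hs0$counts == 0))
  expect_true(is.na(hs0$mean_soc_cm1))

  ev <- rbind(hop_row(1, 1, 1), hop_row(2, 1, 1), hop_row(3, 3, 3),
              hop_row(4, 1, 3, soc_cm1 = 30, delta_e_ev = 0.02),
              hop_row(5, 1, 3, soc_cm1 = 50, delta_e_ev = -0.04),
              hop_row(6, 3, 1, soc_cm1 = 20, delta_e_ev = 0.01),
              hop_row(7, 1, 2, frustrated = TRUE))
  tj <- toy_trajectory(sp, 0:8, rep(3L, 9), hops = ev)
  hs <- hop_statistics(list(tj))
  expect_identical(unname(hs$counts["singlet IC"]), 2L)
  expect_identical(unname(hs$counts["triplet IC"]), 1L)
  expect_identical(unname(hs$counts["S->T ISC"]), 2L)
  expect_identical(unname(hs$counts["T->S ISC"]), 1L)
  expect_identical(unname(hs$counts["frustrated"]), 1L)
  expect_equal(hs$mean_soc_cm1, mean(c(30, 50, 20)))
  expect_equal(hs$max_soc_cm1, 50)
  expect_equal(hs$mean_abs_de_ev, mean(c(0.02, 0.04, 0.01)))
})

test_that("geometry descriptors are exact on constructed arrangements", {
  g <- rbind(c(0, 0, 0), c(0, 0, 1.5))
  expect_equal(bond_length(g, 1, 2), 1.5)
  expect_error(bond_length(g, 1, 3), "invalid")

  # planar ring with an in-plane substituent: 0 degrees
  ring <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0))
  sub_in <- rbind(ring, c(2, 0, 0))
  expect_equal(out_of_plane_angle(sub_in, 4, 1:3, anchor = 1), 0)

  # pyramidal arrangement with a known analytic angle
  alpha <- 25
  bond <- c(cos(alpha * pi / 180), 0, sin(alpha * pi / 180)) * 1.4
  g2 <- rbind(ring, ring[1, ] + bond)
  expect_equal(out_of_plane_angle(g2, 4, 1:3, anchor = 1), alpha,
               tolerance = 1e-8)

  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))
  expect_error(out_of_plane_angle(coll, 4, 1:3), "collinear")
})
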