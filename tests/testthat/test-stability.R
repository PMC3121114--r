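test_that("analytic Jacobian has the expected block structure", {
  m <- canonical$model
  ss <- steady_state(m, u_const = 50)
  J <- regulon_jacobian(m, ss)$entries
  expect_equal(diag(J)[1:3], -c(0.5, 0.4, 0.3))
  expect_equal(diag(J)[4:6], c(-1, -1, -1))
  expect_equal(J[cbind(4:6, 1:3)], c(0.5, 0.5, 0.5))
  # activation sensitivities d_i in column n+1, rows 2..n
  expect_true(all(J[2:3, 4] > 0))
  # nothing else couples the blocks
  expect_equal(J[1, 4:6], c(0, 0, 0))
})

test_that("analytic Jacobian matches finite differences at random states", {
  set.seed(21)
  for (s in 1:10) {
    sc <- random_scenario(seed = 1000 + s, with_feedback = TRUE)
    m <- sc$model
    for (k in 1:10) {
      st <- system_state(x = exp(runif(3, log(1e-3), log(100))),
                         z = exp(runif(3, log(1e-3), log(100))))
      u <- runif(1, 0, 100)
      Ja <- regulon_jacobian(m, st, spec = sc$feedback)$entries
      Jf <- fd_jacobian(m, st, u, spec = sc$feedback)
      expect_equal(Ja, Jf, tolerance = 1e-6)
    }
  }
})

test_that("feedback Jacobian entries carry the sign of their channel", {
  m <- canonical$model
  sp <- feedback_spec(S1 = 3L, S2 = 2L, k_RL = 2, k_AL = 3, k_ls = 1.5)
  set.seed(5)
  for (k in 1:20) {
    st <- system_state(x = runif(3, 0, 50), z = runif(3, 0, 50))
    J <- regulon_jacobian(m, st, spec = sp)$entries
    expect_lte(J[1, 6], 0)    # repressor entry
    expect_gte(J[1, 5], 0)    # activator entry
  }
})

test_that("open-loop spectrum is the negated degradation rates", {
  m <- canonical$model
  sp <- open_loop_spectrum(m)
  expect_equal(sort(Re(sp$values)), sort(c(-0.5, -0.4, -0.3, -1, -1, -1)))
  expect_false(sp$has_complex)
  expect_lt(sp$max_real, 0)
  # numeric eigendecomposition of the analytic Jacobian agrees
  J <- regulon_jacobian(m, steady_state(m, 50))
  num <- eigen_spectrum(J)
  expect_equal(sort(Re(num$values)), sort(Re(sp$values)), tolerance = 1e-10)
  expect_false(num$has_complex)
  # trace equals the eigenvalue sum
  expect_equal(sum(diag(J$entries)), sum(Re(num$values)), tolerance = 1e-10)
})

test_that("zero degradation yields a critically stable spectrum", {
  sc <- degenerate_scenarios()$zero_kd
  sp <- open_loop_spectrum(sc$model)
  expect_true(any(Re(sp$values) == 0))
  expect_true(sp$critical)
  st <- system_state(rep(1, 3), rep(1, 3))
  expect_equal(stability_index(eigen_spectrum(
    regulon_jacobian(sc$model, st))), -1, ignore_attr = TRUE)
})

test_that("closed-form feedback pair matches the numeric spectrum for any gain", {
  m <- canonical$model
  ss <- steady_state(m, u_const = 50)
  for (om in c(-500, -10, -1, -0.125, -0.01, 0, 0.5, 1, 2, 100)) {
    cf <- feedback_eigs_closed_form(m, om)
    J <- regulon_jacobian(m, ss, omega = c(om, 0, 0))
    ev <- eigen(J$entries, only.values = TRUE)$values
    expect_equal(sort(Re(ev)), sort(Re(c(cf$lambda_pair, cf$unchanged))),
                 tolerance = 1e-8)
    expect_equal(sort(abs(Im(ev))), sort(abs(Im(c(cf$lambda_pair,
                                                  cf$unchanged + 0i)))),
                 tolerance = 1e-8)
  }
  # open-loop reduction
  cf0 <- feedback_eigs_closed_form(m, 0)
  expect_equal(sort(Re(cf0$lambda_pair)), c(-1, -0.5))
})

test_that("autoregulation thresholds take their closed-form values", {
  m <- canonical$model
  cond <- omega1_conditions(m)
  expect_equal(cond$stability, 1)              # eta1 * k1d / r1
  expect_equal(cond$oscillation, -0.125)       # -(eta1 - k1d)^2 / (4 r1)
  # oscillation begins strictly below the threshold
  below <- feedback_eigs_closed_form(m, -0.2)
  above <- feedback_eigs_closed_form(m, -0.1)
  expect_true(any(Im(below$lambda_pair) != 0))
  expect_true(all(Im(above$lambda_pair) == 0))
  # positive gains never produce a complex pair
  for (om in c(0.01, 0.5, 1, 10, 1000)) {
    expect_true(all(Im(feedback_eigs_closed_form(m, om)$lambda_pair) == 0))
  }
  m0 <- m; m0$r[1] <- 0
  expect_error(omega1_conditions(m0), "r_1")
})

test_that("stability and oscillation indices summarize the spectrum", {
  m <- canonical$model
  ss <- steady_state(m, u_const = 50)
  expect_equal(stability_index(open_loop_spectrum(m)), -1)
  expect_equal(oscillation_index(open_loop_spectrum(m)), -1)
  # PFB beyond the critical gain destabilizes
  J2 <- regulon_jacobian(m, ss, omega = c(2, 0, 0))
  expect_equal(stability_index(eigen_spectrum(J2)), 1)
  # strong NFB oscillates but stays stable
  Jn <- regulon_jacobian(m, ss, omega = c(-1, 0, 0))
  spn <- eigen_spectrum(Jn)
  expect_equal(oscillation_index(spn), 1)
  expect_equal(stability_index(spn), -1)
  # all-zero degradation: critical flag
  mz <- m; mz$k_d[] <- 0; mz$eta[] <- 0
  Jz <- regulon_jacobian(mz, system_state(rep(1, 3), rep(1, 3)))
  iz <- stability_index(eigen_spectrum(Jz))
  expect_true(isTRUE(attr(iz, "critical")))
})

test_that("gain scan locates the autoregulation flips", {
  m <- canonical$model
  s <- scan_feedback_gain(m, position = 1,
                          omega_grid = seq(-1000, 1000, length.out = 2001))
  # at omega = 0 both indices are -1 (open loop)
  at0 <- which(s$omega == 0)
  expect_equal(s$stability_index[at0], -1)
  expect_equal(s$oscillation_index[at0], -1)
  # all negative gains stable
  expect_true(all(s$stability_index[s$omega < 0] == -1))
  thr <- s$thresholds
  stab <- thr$omega[thr$type == "stability"]
  expect_length(stab, 1)
  expect_equal(stab, 1, tolerance = 1e-4)
  osc <- thr$omega[thr$type == "oscillation"]
  expect_equal(osc[which.min(abs(osc + 0.125))], -0.125, tolerance = 1e-3)
})

test_that("target-protein scans destabilize at large negative gains", {
  m <- canonical$model
  ss <- steady_state(m, u_const = 50)
  for (pos in 2:3) {
    s <- scan_feedback_gain(m, position = pos, eval_state = ss)
    expect_equal(s$stability_index[s$omega == 0], -1)
    neg <- s$thresholds$omega[s$thresholds$type == "stability" &
                                s$thresholds$omega < 0]
    expect_length(neg, 1)
    expect_lt(neg, -100)
    # below the negative crossing the system is unstable
    expect_true(all(s$stability_index[s$omega < neg - 1] == 1))
    # Routh-Hurwitz oracle for the 4D loop locates the same crossing
    oracle <- loop_hopf_crossing(m, pos, z1_star = ss$z[1])
    expect_equal(neg, oracle$hopf, tolerance = 1e-6)
    pos_cross <- s$thresholds$omega[s$thresholds$type == "stability" &
                                      s$thresholds$omega > 0]
    expect_equal(pos_cross, oracle$zero_eig, tolerance = 1e-6)
  }
})

test_that("bifurcation report characterizes the crossing", {
  m <- canonical$model
  rep <- bifurcation_report(m)
  expect_equal(rep$crossing, 1)
  ev <- sort(Re(rep$eigenvalues_at_crossing))
  expect_equal(ev, c(-1.5, 0), tolerance = 1e-12)
  expect_true(all(Im(rep$eigenvalues_at_crossing) == 0))
  expect_equal(rep$crossing_type, "real zero eigenvalue")
  # crossing scales linearly in eta1 at fixed k1d, r1
  m2 <- m; m2$eta[1] <- 2
  expect_equal(bifurcation_report(m2)$crossing, 2 * rep$crossing)
})
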