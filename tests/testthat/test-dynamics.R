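test_that("initial state is the basal steady state with translation balance", {
  m <- canonical$model
  st <- initial_state(m)
  expect_equal(st$x[1], 0.004)                 # rho1 / k1d
  expect_true(all(st$x > 0))                   # basal leakage keeps x > 0
  expect_equal(st$z, m$r * st$x / m$eta, tolerance = 1e-12)
})

test_that("open-loop pulse response rises from basal and decays back", {
  sc <- canonical
  tr <- simulate_regulon(sc$model, sc$input, t_end = 60, dt_out = 0.1)
  expect_s3_class(tr, "regulon_trajectory")
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$states >= 0))
  expect_equal(unname(tr$states[1, ]), c(initial_state(sc$model)$x,
                                         initial_state(sc$model)$z))
  s <- summary(tr)
  basal <- tr$states[1, ]
  # every component rises well above basal then returns toward it as u -> 0
  expect_true(all(s$peak > 10 * basal))
  expect_true(all(s$t_peak > 0 & s$t_peak < 60))
  expect_true(all(s$final < 0.05 * s$peak))
})

test_that("trajectory converges to the constant-input steady state", {
  m <- canonical$model
  sig <- input_signal(u0 = 50 * (1 + 1e-6), K = 0)   # sustained input
  t_conv <- 20 * max(1 / m$k_d, 1 / m$eta)
  tr <- simulate_regulon(m, sig, t_end = t_conv, dt_out = t_conv / 200)
  ss <- steady_state(m, u_const = 50)
  final <- tr$states[nrow(tr$states), ]
  expect_equal(unname(final), c(ss$x, ss$z), tolerance = 1e-5)
})

test_that("halving integrator tolerances leaves trajectories unchanged to 1e-4", {
  sc <- canonical_fb
  a <- simulate_regulon(sc$model, sc$input, sc$feedback, t_end = 30,
                        dt_out = 0.5, rtol = 1e-8, atol = 1e-10)
  b <- simulate_regulon(sc$model, sc$input, sc$feedback, t_end = 30,
                        dt_out = 0.5, rtol = 5e-9, atol = 5e-11)
  rel <- abs(a$states - b$states) / (abs(a$states) + 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("a silenced feedback channel reproduces the open loop bit-for-bit", {
  sc <- canonical_fb
  open <- simulate_regulon(sc$model, sc$input, NULL, t_end = 30, dt_out = 0.5)
  zero_kls <- sc$feedback; zero_kls$k_ls <- 0
  creA_on <- sc$feedback; creA_on$C_A <- 1
  expect_identical(simulate_regulon(sc$model, sc$input, zero_kls,
                                    t_end = 30, dt_out = 0.5)$states,
                   open$states)
  expect_identical(simulate_regulon(sc$model, sc$input, creA_on,
                                    t_end = 30, dt_out = 0.5)$states,
                   open$states)
})

test_that("feedback with CreA absent elevates expression over the open loop", {
  sc <- canonical_fb
  open <- simulate_regulon(sc$model, sc$input, NULL, t_end = 50, dt_out = 0.1)
  fb <- simulate_regulon(sc$model, sc$input, sc$feedback, t_end = 50,
                         dt_out = 0.1)
  # additive nonnegative drive: master mRNA dominates pointwise
  expect_true(all(fb$states[, "x1"] >= open$states[, "x1"] - 1e-8))
  expect_gt(max(fb$states[, "x1"]), max(open$states[, "x1"]))
  # and the terminal steady state is changed by the persistent drive
  expect_gt(fb$states[nrow(fb$states), "x1"],
            10 * open$states[nrow(open$states), "x1"])
})

test_that("zero delay reproduces the undelayed feedback path", {
  sc <- canonical_fb
  sp0 <- sc$feedback; sp0$tau <- 0
  undelayed <- simulate_regulon(sc$model, sc$input, sp0, t_end = 20,
                                dt_out = 0.5)
  # tiny positive delay converges to the undelayed limit
  spe <- sc$feedback; spe$tau <- 1e-6
  near <- simulate_regulon(sc$model, sc$input, spe, t_end = 20, dt_out = 0.5)
  expect_equal(near$states, undelayed$states, tolerance = 1e-6)
})

test_that("constant pre-trigger history drives the loop for t < tau", {
  sc <- canonical_fb
  sp <- sc$feedback; sp$tau <- 3
  tr <- simulate_regulon(sc$model, sc$input, sp, t_end = 8, dt_out = 0.1)
  # method-of-steps oracle: on [0, tau] the drive is frozen at the initial
  # history, so the system is an ODE with a constant extra source
  st0 <- initial_state(sc$model)
  drive0 <- feedback_drive(st0$z, sp)
  rhs <- function(t, y, p) {
    n <- sc$model$n
    st <- list(x = y[seq_len(n)], z = y[n + seq_len(n)])
    list(c(transcription_rates(st, dxylose(t, sc$input), sc$model,
                               drive = drive0),
           translation_rates(st, sc$model)))
  }
  sol <- deSolve::ode(y = c(st0$x, st0$z), times = seq(0, 3, by = 0.1),
                      func = rhs, parms = NULL, rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(tr$states[tr$times <= 3, ]),
               unname(as.matrix(sol[, -1])), tolerance = 1e-6)
})

test_that("delay variation moves only the neighborhood of the peak", {
  sc <- canonical
  act <- feedback_spec(S2 = 2L, k_AL = 1, k_ls = 1, tau = 1)
  ds <- delay_sensitivity(sc$model, sc$input, act, tau_grid = c(1, 5),
                          t_end = 50, dt_out = 0.1)
  x1 <- ds[ds$species == "x1", ]
  expect_lt(x1$peak[x1$tau == 5], x1$peak[x1$tau == 1])   # longer delay, lower peak
  # profiles nearly coincide: peak reduction is small
  expect_lt(abs(diff(x1$peak)) / max(x1$peak), 0.05)
  # tau = 0 in the grid equals the undelayed simulation exactly
  ds0 <- delay_sensitivity(sc$model, sc$input, act, tau_grid = 0,
                           t_end = 20, dt_out = 0.5)
  sp0 <- act; sp0$tau <- 0
  direct <- summary(simulate_regulon(sc$model, sc$input, sp0, t_end = 20,
                                     dt_out = 0.5))
  expect_equal(ds0$peak, direct$peak)
})

test_that("relaxation times are reciprocal degradation rates", {
  m <- canonical$model
  expect_equal(relaxation_time(m, 1), 2)       # 1/k_1d
  expect_equal(relaxation_time(m, 2), 2.5)
  expect_equal(relaxation_time(m, 3), 1 / 0.3)
  # master regulator relaxes faster than either target
  expect_lt(relaxation_time(m, 1), relaxation_time(m, 2))
  expect_lt(relaxation_time(m, 1), relaxation_time(m, 3))
  m2 <- m; m2$k_d[2] <- 0.25
  expect_equal(relaxation_time(m2, 2), 4)
  m0 <- m; m0$k_d[1] <- 0
  rt <- relaxation_time(m0, 1)
  expect_true(is.infinite(rt) && isTRUE(attr(rt, "critical")))
})

test_that("empirical 1/e relaxation estimator matches 1/k_d for the master", {
  m <- canonical$model
  est <- empirical_relaxation_time(m, gene_index = 1L, u_const = 50)
  expect_equal(est, 2, tolerance = 0.15)
})

test_that("promoter activity along the feedback trajectory stays in bounds", {
  sc <- canonical_fb
  for (kls in c(1, 5)) {
    sp <- sc$feedback; sp$k_ls <- kls
    tr <- simulate_regulon(sc$model, sc$input, sp, t_end = 50, dt_out = 0.2)
    pa <- promoter_activity_trajectory(tr, sp)
    expect_true(all(pa$Gamma_A >= 0 & pa$Gamma_A <= 1))
    expect_true(all(pa$Gamma_R >= 0 & pa$Gamma_R <= 1))
    expect_true(all(pa$combined >= 0 & pa$combined <= 1))
    # peak combined activity sits in a mid-range band, not at 0 or 1
    expect_gt(max(pa$combined), 0.05)
    expect_lt(max(pa$combined), 0.95)
    # the activator occupies most promoter sites in the active window
    expect_gt(max(pa$Gamma_A), 0.5)
    expect_lt(max(pa$Gamma_A), 0.95)
  }
  # under the flipped (more-abundant-activator) assignment the activator-
  # bound fraction dominates the repressor-bound fraction over the window
  flipped <- feedback_spec(S1 = 2L, S2 = 3L, tau = 1)
  trf <- simulate_regulon(sc$model, sc$input, flipped, t_end = 50,
                          dt_out = 0.2)
  paf <- promoter_activity_trajectory(trf, flipped)
  win <- paf$t > 2 & paf$t < 20
  expect_gt(mean(paf$Gamma_A[win] > 1 - paf$Gamma_R[win]), 0.9)
})
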