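# Shared oracles and generators for the test suite.

# Central finite-difference Jacobian of the full 2n rate field, used as the
# independent oracle for the analytic Jacobian.
fd_jacobian <- function(model, state, u, spec = NULL, h = 1e-6) {
  n <- model$n
  y <- c(state$x, state$z)
  rates <- function(y) {
    st <- list(x = y[seq_len(n)], z = y[n + seq_len(n)])
    drive <- if (is.null(spec)) 0 else feedback_drive(st$z, spec)
    c(transcription_rates(st, u, model, drive = drive),
      translation_rates(st, model))
  }
  J <- matrix(0, 2 * n, 2 * n)
  for (j in seq_len(2 * n)) {
    step <- h * max(1, abs(y[j]))
    yp <- y; ym <- y
    yp[j] <- y[j] + step
    ym[j] <- max(y[j] - step, 0)
    J[, j] <- (rates(yp) - rates(ym)) / (yp[j] - ym[j])
  }
  J
}

# Routh-Hurwitz (imaginary-axis) crossing of the 4D loop master gene ->
# master protein -> target gene i -> target protein i -> master gene, with
# gain omega at Jacobian cell (1, n+i). Characteristic polynomial
# (lambda+a)(lambda+b)(lambda+c)(lambda+e) = G with loop gain
# G = omega * r1 * d_i * r_i. Substituting lambda = i*nu gives the
# closed-form crossing used as an independent oracle for the scans.
loop_hopf_crossing <- function(model, i, z1_star) {
  a <- model$k_d[1]; b <- model$eta[1]
  c <- model$k_d[i]; e <- model$eta[i]
  theta <- 1 / model$k_1[i]
  d_i <- model$k_s[i] * theta / (theta + z1_star)^2     # h = 1
  gain <- model$r[1] * d_i * model$r[i]
  s2 <- a * b + a * c + a * e + b * c + b * e + c * e
  s3 <- a * b * c + a * b * e + a * c * e + b * c * e
  s1 <- a + b + c + e
  nu2 <- s3 / s1
  G_hopf <- nu2^2 - s2 * nu2 + a * b * c * e
  list(hopf = G_hopf / gain,                 # negative crossing (complex pair)
       zero_eig = a * b * c * e / gain)      # positive crossing (det = 0)
}

# Long-time integration under constant input: the oracle for steady_state().
integrate_to_plateau <- function(model, u_const, spec = NULL, t_end = 200) {
  sig <- input_signal(u0 = u_const * (1 + 1e-6), K = 0, beta = 1e-6)
  tr <- simulate_regulon(model, sig, spec, t_end = t_end, dt_out = t_end / 100,
                         rtol = 1e-10, atol = 1e-12)
  k <- nrow(tr$states)
  n <- model$n
  list(x = unname(tr$states[k, seq_len(n)]),
       z = unname(tr$states[k, n + seq_len(n)]))
}

canonical <- xlnr_scenario()
canonical_fb <- xlnr_scenario(with_feedback = TRUE)
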