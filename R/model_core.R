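#' Hill activation function
#'
#' Fraction of promoter activated by a transcription factor at concentration
#' `z`, with half-saturation constant `theta` and Hill coefficient `h`:
#' \eqn{\psi^+(z, \theta) = z^h / (\theta^h + z^h)}. XlnR binds its targets as
#' a monomer, so `h = 1` throughout the canonical scenario.
#'
#' @param z transcription-factor concentration (>= 0); vectorized.
#' @param theta half-saturation constant (> 0). The effective affinity used
#'   elsewhere in the package is its reciprocal, `k_1 = 1/theta`.
#' @param h Hill coefficient (> 0).
#' @return Activation fraction in `[0, 1]`, strictly increasing in `z` and
#'   equal to 1/2 at `z = theta`.
#' @examples
#' hill_activation(10, theta = 10)      # 0.5 at half-saturation
#' hill_activation(90, theta = 10)      # 0.9
#' @seealso [hill_repression()]
#' @export
hill_activation <- function(z, theta, h = 1) {
  if (!is.numeric(theta) || any(theta <= 0)) {
    stop("'theta' must be positive", call. = FALSE)
  }
  if (!is.numeric(h) || any(h <= 0)) {
    stop("'h' must be positive", call. = FALSE)
  }
  if (any(z < 0)) stop("'z' must be nonnegative", call. = FALSE)
  zh <- z^h
  zh / (theta^h + zh)
}

#' Hill repression function
#'
#' Complement of [hill_activation()]: \eqn{\psi^-(z,\theta) = 1 - \psi^+(z,\theta)},
#' the fraction of promoter NOT occupied by the regulator.
#'
#' @inheritParams hill_activation
#' @return Repression fraction in `[0, 1]`, strictly decreasing in `z`.
#' @export
hill_repression <- function(z, theta, h = 1) {
  1 - hill_activation(z, theta, h)
}

#' D-xylose input signal
#'
#' The regulon trigger: an initial D-xylose pulse consumed during
#' fermentation, \eqn{u(t) = u_0 / (\beta + e^{Kt})}. For small `beta` the
#' signal starts at essentially `u0` and decays to zero at rate set by `K`
#' (larger `K`, faster consumption).
#'
#' @param u0 initial D-xylose concentration (mM).
#' @param K consumption rate parameter (1/h). `K = 0` gives a sustained
#'   (constant) input, useful for relaxation-time analysis.
#' @param beta shape offset (> 0, dimensionless). Defaults to `1e-6` so that
#'   \eqn{u(0^+) \approx u_0}.
#' @return An object of class `"input_signal"`.
#' @examples
#' sig <- input_signal(u0 = 50, K = 0.3)
#' dxylose(c(0, 5, 10), sig)
#' @export
input_signal <- function(u0, K, beta = 1e-6) {
  stopifnot(is.numeric(u0), length(u0) == 1L, u0 >= 0,
            is.numeric(K), length(K) == 1L,
            is.numeric(beta), length(beta) == 1L, beta > 0)
  structure(list(u0 = u0, K = K, beta = beta), class = "input_signal")
}

#' Evaluate the D-xylose concentration at time t
#'
#' @param t time (h, >= 0); vectorized.
#' @param sig an [input_signal()].
#' @return D-xylose concentration (mM), non-increasing in `t` for `K > 0`.
#' @export
dxylose <- function(t, sig) {
  stopifnot(inherits(sig, "input_signal"))
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  sig$u0 / (sig$beta + exp(sig$K * t))
}

#' @export
print.input_signal <- function(x, ...) {
  cat(sprintf("D-xylose input: u(t) = %g/(%g + exp(%g t)) mM\n",
              x$u0, x$beta, x$K))
  invisible(x)
}

#' Regulon model constructor
#'
#' A master regulator gene (index 1, the xlnR gene) plus `n - 1` target
#' genes, each with first-order mRNA and protein turnover. mRNA dynamics:
#' the master gene is driven linearly by the D-xylose input
#' (\eqn{\dot x_1 = \rho_1 + b_1 u - k_{1d} x_1}) and each target gene is
#' activated by the master protein through a Hill term
#' (\eqn{\dot x_i = \rho_i + k_{is}\,\psi^+(z_1, 1/k_{i1}) - k_{id} x_i}).
#' Protein dynamics are linear: \eqn{\dot z_i = r_i x_i - \eta_i z_i}.
#'
#' @param rho basal (leaky) transcription rates, length n (conc/h).
#' @param k_s maximum synthesis rates (conc/h); entry 1 is unused (the master
#'   gene is input-driven) and may be `NA`.
#' @param k_1 effective affinities of the master protein for each target
#'   promoter, `k_1 = 1/theta` (1/conc); entry 1 unused.
#' @param k_d first-order mRNA degradation rates (1/h).
#' @param r specific translation rates (1/h).
#' @param eta first-order protein degradation rates (1/h).
#' @param b input coupling coefficients; default couples the input to the
#'   master gene only.
#' @param h Hill coefficient (default 1: monomeric binding of XlnR).
#' @return An object of class `"regulon_model"`.
#' @examples
#' m <- xlnr_scenario()$model
#' m
#' open_loop_spectrum(m)
#' @export
regulon_model <- function(rho, k_s, k_1, k_d, r, eta,
                          b = c(1, rep(0, length(rho) - 1L)), h = 1) {
  n <- length(rho)
  stopifnot(n >= 1L,
            length(k_s) == n, length(k_1) == n, length(k_d) == n,
            length(r) == n, length(eta) == n, length(b) == n,
            is.numeric(h), length(h) == 1L, h > 0)
  if (any(rho < 0)) stop("basal rates 'rho' must be >= 0", call. = FALSE)
  if (any(k_d <= 0) || any(eta <= 0)) {
    # zero rates are allowed only through the degenerate-scenario path
    if (any(k_d < 0) || any(eta < 0)) {
      stop("degradation rates must be >= 0", call. = FALSE)
    }
  }
  if (n >= 2L) {
    if (any(!is.finite(k_s[-1])) || any(k_s[-1] < 0)) {
      stop("target synthesis rates 'k_s[2..n]' must be finite and >= 0",
           call. = FALSE)
    }
    if (any(!is.finite(k_1[-1])) || any(k_1[-1] <= 0)) {
      stop("target affinities 'k_1[2..n]' must be positive", call. = FALSE)
    }
  }
  structure(list(n = n, rho = as.numeric(rho), k_s = as.numeric(k_s),
                 k_1 = as.numeric(k_1), k_d = as.numeric(k_d),
                 r = as.numeric(r), eta = as.numeric(eta),
                 b = as.numeric(b), h = h),
            class = "regulon_model")
}

#' @export
print.regulon_model <- function(x, ...) {
  cat(sprintf("Regulon model: %d genes (gene 1 = master xlnR), Hill h = %g\n",
              x$n, x$h))
  tab <- data.frame(gene = seq_len(x$n), rho = x$rho, k_s = x$k_s,
                    k_1 = x$k_1, k_d = x$k_d, r = x$r, eta = x$eta, b = x$b)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Delayed feedback specification
#'
#' Configuration of the post-translational feedback channel onto the xlnR
#' gene. Proteins indexed by `S1` repress and those in `S2` activate the
#' master gene, each through a lumped Hill term with affinities `k_RL`,
#' `k_AL` and a common synthesis scale `k_ls`. The drive is delayed by `tau`
#' hours and gated by the carbon-catabolite repressor CreA: with
#' `creA_binary = TRUE` (the default used to reproduce the published
#' results) the gate is a switch, `H = 0` when CreA is present
#' (`C_A > 0`) and `H = 1` when absent; otherwise the continuous form
#' `H = 1/(1 + k_A C_A)` is used.
#'
#' @param S1 integer indices (into the protein vector z) of repressing
#'   proteins.
#' @param S2 integer indices of activating proteins; disjoint from `S1`.
#' @param k_RL,k_AL lumped affinity constants (1/conc, >= 0).
#' @param k_ls lumped feedback synthesis rate (conc/h, >= 0).
#' @param tau feedback time delay (h, >= 0).
#' @param C_A quantitative CreA activity (>= 0; 0 = absent).
#' @param k_A inverse Hill constant of CreA (>= 0).
#' @param creA_binary logical; use the switch-like CreA gate.
#' @return An object of class `"feedback_spec"`.
#' @examples
#' fb <- feedback_spec(S1 = 3, S2 = 2, tau = 1)
#' crea_gate(fb)               # 1: CreA absent
#' @export
feedback_spec <- function(S1 = integer(), S2 = integer(),
                          k_RL = 1, k_AL = 1, k_ls = 1, tau = 0,
                          C_A = 0, k_A = 0, creA_binary = TRUE) {
  S1 <- as.integer(S1); S2 <- as.integer(S2)
  if (length(intersect(S1, S2))) {
    stop("'S1' and 'S2' must be disjoint", call. = FALSE)
  }
  stopifnot(k_RL >= 0, k_AL >= 0, k_ls >= 0, tau >= 0,
            C_A >= 0, k_A >= 0, is.logical(creA_binary))
  structure(list(S1 = S1, S2 = S2, k_RL = k_RL, k_AL = k_AL, k_ls = k_ls,
                 tau = tau, C_A = C_A, k_A = k_A, creA_binary = creA_binary),
            class = "feedback_spec")
}

#' @export
print.feedback_spec <- function(x, ...) {
  cat(sprintf(
    "Feedback onto xlnR: repressors S1 = {%s}, activators S2 = {%s}\n",
    paste(x$S1, collapse = ","), paste(x$S2, collapse = ",")))
  cat(sprintf("  k_RL = %g, k_AL = %g, k_ls = %g, tau = %g h\n",
              x$k_RL, x$k_AL, x$k_ls, x$tau))
  cat(sprintf("  CreA gate H = %g (%s mode, C_A = %g)\n", crea_gate(x),
              if (x$creA_binary) "switch" else "continuous", x$C_A))
  invisible(x)
}

#' CreA promoter gate
#'
#' Activity of the xlnR promoter as limited by the carbon-catabolite
#' repressor CreA. In binary mode the gate is 0 when CreA is present
#' (`C_A > 0`) and 1 when absent; in continuous mode it is the repressor
#' Hill function `1/(1 + k_A * C_A)`.
#'
#' @param spec a [feedback_spec()].
#' @return Gate value `H` in `[0, 1]`.
#' @export
crea_gate <- function(spec) {
  stopifnot(inherits(spec, "feedback_spec"))
  if (spec$C_A < 0 || spec$k_A < 0) {
    stop("CreA activity and 'k_A' must be nonnegative", call. = FALSE)
  }
  if (spec$creA_binary) {
    if (spec$C_A > 0) 0 else 1
  } else {
    1 / (1 + spec$k_A * spec$C_A)
  }
}

#' System state constructor
#'
#' Bundles the mRNA vector `x` and protein vector `z` at time `t`.
#'
#' @param x mRNA concentrations (length n, >= 0).
#' @param z protein concentrations (length n, >= 0).
#' @param t time (h).
#' @return An object of class `"system_state"`.
#' @export
system_state <- function(x, z, t = 0) {
  stopifnot(length(x) == length(z))
  if (any(x < -1e-12) || any(z < -1e-12)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  structure(list(x = pmax(as.numeric(x), 0), z = pmax(as.numeric(z), 0),
                 t = t), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("State at t = %g h\n", x$t))
  print(rbind(mRNA = x$x, protein = x$z))
  invisible(x)
}

# internal: check a state against a model
check_state <- function(state, model) {
  if (length(state$x) != model$n || length(state$z) != model$n) {
    stop(sprintf("state dimension (%d mRNA, %d protein) does not match model n = %d",
                 length(state$x), length(state$z), model$n), call. = FALSE)
  }
  invisible(TRUE)
}

#' Transcription rates dx/dt
#'
#' Right-hand side of the mRNA equations. The master gene (index 1) is
#' driven linearly by the input `u` plus an optional additive feedback
#' `drive`; target genes are activated by the master protein `z1` through
#' the Hill term.
#'
#' @param state a [system_state()] (or list with `x`, `z`).
#' @param u D-xylose concentration (mM, >= 0).
#' @param model a [regulon_model()].
#' @param drive additive feedback rate on the master gene (conc/h), usually
#'   from [feedback_drive()].
#' @return Numeric vector of n rates (conc/h).
#' @export
transcription_rates <- function(state, u, model, drive = 0) {
  check_state(state, model)
  if (u < 0) stop("'u' must be nonnegative", call. = FALSE)
  n <- model$n
  dx <- numeric(n)
  dx[1] <- model$rho[1] + model$b[1] * u + drive - model$k_d[1] * state$x[1]
  if (n >= 2L) {
    i <- 2:n
    psi <- hill_activation(state$z[1], theta = 1 / model$k_1[i], h = model$h)
    dx[i] <- model$rho[i] + model$b[i] * u + model$k_s[i] * psi -
      model$k_d[i] * state$x[i]
  }
  dx
}

#' Translation rates dz/dt
#'
#' Linear protein kinetics \eqn{\dot z_i = r_i x_i - \eta_i z_i}.
#'
#' @inheritParams transcription_rates
#' @return Numeric vector of n rates (conc/h).
#' @export
translation_rates <- function(state, model) {
  check_state(state, model)
  model$r * state$x - model$eta * state$z
}

#' Delayed feedback drive on the xlnR gene
#'
#' The additive rate contributed to the master-gene mRNA equation by the
#' feedback channel, evaluated at the delayed protein concentrations:
#' \deqn{H k_{ls} \left[\sum_{j \in S_1} \frac{1}{1 + k_{RL} z_j} +
#'   \sum_{l \in S_2} \frac{k_{AL} z_l}{1 + k_{AL} z_l}\right]}
#' where `H` is the CreA gate. The drive is nonnegative and bounded by
#' `H * k_ls * (|S1| + |S2|)`.
#'
#' @param z_delayed protein concentration vector at time `t - tau` (>= 0).
#' @param spec a [feedback_spec()].
#' @return Feedback rate (conc/h).
#' @export
feedback_drive <- function(z_delayed, spec) {
  stopifnot(inherits(spec, "feedback_spec"))
  idx <- c(spec$S1, spec$S2)
  if (length(idx) && (min(idx) < 1L || max(idx) > length(z_delayed))) {
    stop("feedback indices out of range of the protein vector", call. = FALSE)
  }
  if (any(z_delayed < 0)) stop("'z_delayed' must be nonnegative", call. = FALSE)
  H <- crea_gate(spec)
  if (H == 0 || spec$k_ls == 0) return(0)
  rep_term <- if (length(spec$S1)) {
    sum(1 / (1 + spec$k_RL * z_delayed[spec$S1]))
  } else 0
  act_term <- if (length(spec$S2)) {
    a <- spec$k_AL * z_delayed[spec$S2]
    sum(a / (1 + a))
  } else 0
  H * spec$k_ls * (rep_term + act_term)
}

#' Steady state of the regulon at constant input
#'
#' Solves for the fixed point \eqn{(x^*, z^*)} of the transcription and
#' translation equations with the D-xylose input frozen at `u_const`
#' (pseudo-steady-state assumption: over a short window the slowly varying
#' input is treated as constant). Without feedback the fixed point is
#' explicit; with feedback a damped fixed-point iteration is run on the
#' protein vector. At the solution the translation balance
#' \eqn{z_i^* = r_i x_i^* / \eta_i} holds exactly.
#'
#' @param model a [regulon_model()] with `k_d > 0`, `eta > 0`.
#' @param u_const frozen D-xylose concentration (mM).
#' @param spec optional [feedback_spec()] whose (undelayed) drive is included
#'   in the balance.
#' @param tol convergence tolerance on the state max-norm.
#' @param max_iter iteration cap.
#' @param damping fixed-point damping factor in (0, 1].
#' @return A [system_state()] with attributes `iterations` and `residual`.
#' @examples
#' sc <- xlnr_scenario()
#' steady_state(sc$model, u_const = 50)
#' @export
steady_state <- function(model, u_const, spec = NULL,
                         tol = 1e-10, max_iter = 10000L, damping = 0.5) {
  stopifnot(inherits(model, "regulon_model"))
  if (any(model$k_d <= 0) || any(model$eta <= 0)) {
    stop("steady state requires k_d > 0 and eta > 0 for every gene",
         call. = FALSE)
  }
  if (u_const < 0) stop("'u_const' must be nonnegative", call. = FALSE)
  n <- model$n
  solve_given_drive <- function(drive) {
    x <- numeric(n)
    x[1] <- (model$rho[1] + model$b[1] * u_const + drive) / model$k_d[1]
    z1 <- model$r[1] * x[1] / model$eta[1]
    if (n >= 2L) {
      i <- 2:n
      psi <- hill_activation(z1, theta = 1 / model$k_1[i], h = model$h)
      x[i] <- (model$rho[i] + model$b[i] * u_const + model$k_s[i] * psi) /
        model$k_d[i]
    }
    z <- model$r * x / model$eta
    list(x = x, z = z)
  }
  if (is.null(spec)) {
    st <- solve_given_drive(0)
    out <- system_state(st$x, st$z)
    attr(out, "iterations") <- 0L
    attr(out, "residual") <- 0
    return(out)
  }
  st <- solve_given_drive(0)
  z <- st$z
  for (it in seq_len(max_iter)) {
    drive <- feedback_drive(z, spec)
    st_new <- solve_given_drive(drive)
    delta <- max(abs(st_new$z - z))
    z <- (1 - damping) * z + damping * st_new$z
    if (delta < tol) {
      st_fin <- solve_given_drive(feedback_drive(z, spec))
      out <- system_state(st_fin$x, st_fin$z)
      attr(out, "iterations") <- it
      attr(out, "residual") <- delta
      return(out)
    }
  }
  stop(sprintf(
    "steady-state fixed point did not converge in %d iterations (residual %.3e)",
    max_iter, delta), call. = FALSE)
}

#' xlnR promoter activities under feedback
#'
#' Occupancy-style promoter activities for the competitive binding of
#' activating and repressing feedback proteins to the xlnR promoter region.
#' With the default separate-denominator forms,
#' \eqn{\Gamma_A = k_{AL} z_A / (1 + k_{AL} z_A)} (fraction bound by the
#' activator), \eqn{\Gamma_R = 1 / (1 + k_{RL} z_R)} (fraction free of the
#' repressor), and the combined competitive activity is the product
#' \eqn{\Gamma_A \Gamma_R}. `shared_denominator = TRUE` selects the
#' single-site competitive variant
#' \eqn{\Gamma_A = k_{AL} z_A / (1 + k_{AL} z_A + k_{RL} z_R)},
#' \eqn{\Gamma_R = 1 / (1 + k_{AL} z_A + k_{RL} z_R)}.
#' Multiple activators or repressors are lumped by summing their
#' concentrations.
#'
#' @param z_delayed protein vector at the delayed time.
#' @param spec a [feedback_spec()] with nonempty `S2` (activators) and `S1`
#'   (repressors).
#' @param shared_denominator use the single-site competitive variant.
#' @return Named numeric vector `c(Gamma_A, Gamma_R, combined)`, all in
#'   `[0, 1]`.
#' @export
promoter_activity <- function(z_delayed, spec, shared_denominator = FALSE) {
  stopifnot(inherits(spec, "feedback_spec"))
  if (!length(spec$S2)) {
    stop("promoter activity requires at least one activator (S2)", call. = FALSE)
  }
  if (!length(spec$S1)) {
    stop("promoter activity requires at least one repressor (S1)", call. = FALSE)
  }
  idx <- c(spec$S1, spec$S2)
  if (min(idx) < 1L || max(idx) > length(z_delayed)) {
    stop("feedback indices out of range of the protein vector", call. = FALSE)
  }
  zA <- sum(z_delayed[spec$S2])
  zR <- sum(z_delayed[spec$S1])
  if (shared_denominator) {
    den <- 1 + spec$k_AL * zA + spec$k_RL * zR
    gA <- spec$k_AL * zA / den
    gR <- 1 / den
  } else {
    gA <- spec$k_AL * zA / (1 + spec$k_AL * zA)
    gR <- 1 / (1 + spec$k_RL * zR)
  }
  c(Gamma_A = gA, Gamma_R = gR, combined = gA * gR)
}
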