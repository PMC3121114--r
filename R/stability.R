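#' Analytic Jacobian of the regulon system
#'
#' Closed-form Jacobian of the 2n-dimensional system at a state, ordered
#' `(x1..xn, z1..zn)`. Block structure: the mRNA block is
#' `diag(-k_d)`; target rows carry the activation sensitivities
#' \eqn{d_i = \partial \dot x_i / \partial z_1} in column `n + 1`; the
#' protein blocks are `diag(r)` (coupling to mRNA) and `diag(-eta)`. Row 1
#' protein columns carry the feedback entries: the analytic derivatives of
#' [feedback_drive()] when `spec` is given (negative for repressors,
#' positive for activators), or the raw gains `omega` when supplied — the
#' abstraction used by the gain scans. The delay does not enter the
#' Jacobian (delay-free local analysis).
#'
#' @param model a [regulon_model()].
#' @param state a [system_state()] at which to evaluate.
#' @param spec optional [feedback_spec()] for mechanistic feedback entries.
#' @param omega optional numeric vector of length n: raw gains placed at row
#'   1, columns `n+1 .. 2n`, overriding any mechanistic entries.
#' @return An object of class `"regulon_jacobian"`: list with `entries`
#'   (2n x 2n matrix), `eval_state`, `omega`.
#' @examples
#' sc <- xlnr_scenario()
#' J <- regulon_jacobian(sc$model, steady_state(sc$model, 50))
#' eigen_spectrum(J)
#' @export
regulon_jacobian <- function(model, state, spec = NULL, omega = NULL) {
  stopifnot(inherits(model, "regulon_model"))
  check_state(state, model)
  n <- model$n
  J <- matrix(0, 2 * n, 2 * n)
  diag(J)[seq_len(n)] <- -model$k_d
  diag(J)[n + seq_len(n)] <- -model$eta
  J[cbind(n + seq_len(n), seq_len(n))] <- model$r
  if (n >= 2L) {
    # d_i = k_is * dpsi/dz1 with theta_i = 1/k_i1
    z1 <- state$z[1]
    for (i in 2:n) {
      theta <- 1 / model$k_1[i]
      h <- model$h
      dpsi <- if (z1 == 0 && h < 1) Inf else
        h * theta^h * z1^(h - 1) / (theta^h + z1^h)^2
      J[i, n + 1] <- model$k_s[i] * dpsi
    }
  }
  if (!is.null(spec) && is.null(omega)) {
    H <- crea_gate(spec)
    for (j in spec$S1) {
      J[1, n + j] <- J[1, n + j] -
        H * spec$k_ls * spec$k_RL / (1 + spec$k_RL * state$z[j])^2
    }
    for (l in spec$S2) {
      J[1, n + l] <- J[1, n + l] +
        H * spec$k_ls * spec$k_AL / (1 + spec$k_AL * state$z[l])^2
    }
  }
  if (!is.null(omega)) {
    stopifnot(length(omega) == n)
    J[1, n + seq_len(n)] <- omega
  }
  structure(list(entries = J, eval_state = state, omega = omega),
            class = "regulon_jacobian")
}

#' @export
print.regulon_jacobian <- function(x, digits = 4, ...) {
  cat(sprintf("Regulon Jacobian (%d x %d) at t = %g\n",
              nrow(x$entries), ncol(x$entries), x$eval_state$t))
  print(round(x$entries, digits))
  invisible(x)
}

#' Eigenvalue spectrum of a Jacobian
#'
#' @param J a `"regulon_jacobian"` or plain square matrix.
#' @param tol_im threshold on `|Im|` above which the spectrum is flagged
#'   complex; default scales with the matrix norm (eigensolver noise floor).
#' @return An object of class `"eigen_spectrum"`: `values` (complex),
#'   `max_real`, `has_complex`, `tol`.
#' @export
eigen_spectrum <- function(J, tol_im = NULL) {
  M <- if (inherits(J, "regulon_jacobian")) J$entries else J
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  tol <- if (is.null(tol_im)) 1e-9 * max(1, norm(M, "I")) else tol_im
  ev <- eigen(M, only.values = TRUE)$values
  structure(list(values = ev, max_real = max(Re(ev)),
                 has_complex = any(abs(Im(ev)) > tol), tol = tol),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat("Eigenvalues:\n")
  print(x$values)
  cat(sprintf("max Re = %g; complex parts: %s\n", x$max_real,
              if (x$has_complex) "yes" else "no"))
  invisible(x)
}

#' Open-loop spectrum
#'
#' Without feedback the characteristic polynomial factorizes: each gene
#' contributes its two (negated) degradation rates, so the spectrum is
#' exactly `{-k_d} U {-eta}`, all real. The system is globally stable
#' whenever all degradation rates are positive, critically stable if any is
#' zero, and can never oscillate: the time constants depend on the
#' degradation coefficients alone.
#'
#' @param model a [regulon_model()].
#' @return An `"eigen_spectrum"` with an extra `critical` flag when a zero
#'   degradation rate is present.
#' @export
open_loop_spectrum <- function(model) {
  stopifnot(inherits(model, "regulon_model"))
  ev <- complex(real = c(-model$k_d, -model$eta), imaginary = 0)
  out <- structure(list(values = ev, max_real = max(Re(ev)),
                        has_complex = FALSE, tol = 0),
                   class = "eigen_spectrum")
  out$critical <- any(model$k_d == 0) || any(model$eta == 0)
  out
}

#' Closed-form eigenvalues under master-protein autoregulation
#'
#' With a single feedback gain `omega1` at Jacobian cell `(1, n+1)` (the
#' XlnR protein acting back on its own gene), the perturbed pair of
#' eigenvalues is
#' \deqn{\lambda_{5,6} = \tfrac12\left[-(\eta_1 + k_{1d}) \pm
#'   \sqrt{(\eta_1 - k_{1d})^2 + 4 r_1 \omega_1}\right]}
#' while the remaining `2n - 2` eigenvalues stay at the negated degradation
#' rates of the other genes. The pair is complex exactly when
#' `omega1 < -(eta1 - k1d)^2 / (4 r1)` (negative feedback strong enough to
#' oscillate), and complex pairs always have real part
#' `-(eta1 + k1d)/2 < 0` (damped).
#'
#' @param model a [regulon_model()].
#' @param omega1 autoregulation gain (any real).
#' @return List with `lambda_pair` (complex length 2) and `unchanged`
#'   (numeric, the other eigenvalues).
#' @export
feedback_eigs_closed_form <- function(model, omega1) {
  stopifnot(inherits(model, "regulon_model"))
  k1d <- model$k_d[1]; eta1 <- model$eta[1]; r1 <- model$r[1]
  disc <- (eta1 - k1d)^2 + 4 * r1 * omega1
  s <- sqrt(as.complex(disc))
  pair <- 0.5 * (-(eta1 + k1d) + c(s, -s))
  unchanged <- if (model$n >= 2L) c(-model$k_d[-1], -model$eta[-1]) else numeric()
  list(lambda_pair = pair, unchanged = unchanged)
}

#' Stability and oscillation thresholds for the autoregulation gain
#'
#' Closed-form conditions on the gain `omega1` at cell `(1, n+1)`:
#' the pair oscillates iff `omega1 < -(eta1 - k1d)^2/(4 r1)` and the system
#' is stable iff `omega1 < eta1 * k1d / r1`. For the canonical scenario
#' these evaluate to -0.125 and 1. Positive gains never produce a complex
#' pair: positive autoregulation of XlnR cannot oscillate, while any
#' negative gain leaves the system stable.
#'
#' @param model a [regulon_model()] with `r[1] > 0`.
#' @return List with `oscillation` and `stability` thresholds.
#' @export
omega1_conditions <- function(model) {
  stopifnot(inherits(model, "regulon_model"))
  if (model$r[1] <= 0) {
    stop("thresholds undefined for r_1 <= 0", call. = FALSE)
  }
  list(oscillation = -(model$eta[1] - model$k_d[1])^2 / (4 * model$r[1]),
       stability = model$eta[1] * model$k_d[1] / model$r[1])
}

#' Stability index of a spectrum
#'
#' `-1` for a stable spectrum (max real part below `-tol`), `+1` for an
#' unstable one. Values within the tolerance band are critical: mapped to
#' `-1` with attribute `critical = TRUE`.
#'
#' @param spectrum an `"eigen_spectrum"`.
#' @param tol real-part tolerance; defaults to the spectrum's stored
#'   eigensolver tolerance.
#' @return `-1` or `+1`, possibly with attribute `critical`.
#' @export
stability_index <- function(spectrum, tol = NULL) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  if (is.null(tol)) tol <- max(spectrum$tol, 1e-12)
  if (spectrum$max_real > tol) return(1)
  out <- -1
  if (spectrum$max_real >= -tol) attr(out, "critical") <- TRUE
  out
}

#' Oscillation index of a spectrum
#'
#' `+1` when the spectrum contains at least one eigenvalue pair with
#' nonzero imaginary part (oscillatory response), else `-1`.
#'
#' @inheritParams stability_index
#' @return `-1` or `+1`.
#' @export
oscillation_index <- function(spectrum, tol = NULL) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  if (is.null(tol)) {
    if (spectrum$has_complex) 1 else -1
  } else {
    if (any(abs(Im(spectrum$values)) > tol)) 1 else -1
  }
}

# internal: max Re and max |Im| at one gain value
scan_point <- function(J0, n, position, om) {
  J0[1, n + position] <- om
  ev <- eigen(J0, only.values = TRUE)$values
  c(max_re = max(Re(ev)), max_im = max(abs(Im(ev))))
}

# internal: bisection on a sign/indicator flip between two gains
bisect_flip <- function(f, lo, hi, tol = 1e-6, maxit = 200L) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (f(mid) == flo) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Scan a feedback gain over a grid
#'
#' The numerical route to the stability and oscillation maps: place a raw
#' gain `omega` at Jacobian cell `(1, n + position)` — all other feedback
#' entries zero — at a fixed evaluation state, compute the spectrum at each
#' grid value, and record both indices with bisection-refined locations of
#' every index flip. The default evaluation state is the pseudo steady
#' state under sustained input `u = u_eval` (CreA absent, no feedback
#' drive); the located thresholds for `position >= 2` depend materially on
#' this choice, which is therefore recorded in the result.
#'
#' @param model a [regulon_model()].
#' @param position protein index `i` in `1..n`; the scanned cell is
#'   `(1, n + i)`.
#' @param omega_grid gain grid; default 2001 evenly spaced points on
#'   (-1000, 1000).
#' @param eval_state optional [system_state()]; default
#'   `steady_state(model, u_eval)`.
#' @param u_eval sustained input defining the default evaluation state (mM).
#' @param refine_tol bisection tolerance for threshold refinement.
#' @return An object of class `"gain_scan"`: data-frame-like list with
#'   `omega`, `stability_index`, `oscillation_index`, `max_re`, `max_im`,
#'   plus `thresholds` (data frame: `type`, `omega_lo`, `omega_hi`,
#'   `omega`), `position`, `eval_state`.
#' @examples
#' sc <- xlnr_scenario()
#' s <- scan_feedback_gain(sc$model, position = 1,
#'                         omega_grid = seq(-5, 5, by = 0.01))
#' s$thresholds
#' @export
scan_feedback_gain <- function(model, position,
                               omega_grid = seq(-1000, 1000, length.out = 2001),
                               eval_state = NULL, u_eval = 50,
                               refine_tol = 1e-6) {
  stopifnot(inherits(model, "regulon_model"),
            position >= 1L, position <= model$n,
            length(omega_grid) >= 2L, all(is.finite(omega_grid)))
  omega_grid <- sort(omega_grid)
  if (is.null(eval_state)) eval_state <- steady_state(model, u_const = u_eval)
  n <- model$n
  J0 <- regulon_jacobian(model, eval_state)$entries
  # floor below which imaginary parts are eigensolver noise (near-coalescent
  # real pairs can show |Im| ~ sqrt(eps) * scale)
  im_floor <- 1e-8 * max(1, norm(J0, "I"), abs(omega_grid))
  pts <- vapply(omega_grid, function(om) scan_point(J0, n, position, om),
                numeric(2))
  max_re <- pts[1, ]; max_im <- pts[2, ]
  stab <- ifelse(max_re > 0, 1, -1)
  osc <- ifelse(max_im > im_floor, 1, -1)
  thr <- list()
  refine <- function(idx_vec, kind) {
    flips <- which(diff(idx_vec) != 0)
    for (i in flips) {
      f <- function(om) {
        v <- scan_point(J0, n, position, om)
        if (kind == "stability") {
          if (v["max_re"] > 0) 1 else -1
        } else {
          if (v["max_im"] > im_floor) 1 else -1
        }
      }
      om <- bisect_flip(f, omega_grid[i], omega_grid[i + 1],
                        tol = 0.1 * refine_tol)
      thr[[length(thr) + 1L]] <<- data.frame(
        type = kind, omega_lo = omega_grid[i], omega_hi = omega_grid[i + 1],
        omega = om)
    }
  }
  refine(stab, "stability")
  refine(osc, "oscillation")
  thresholds <- if (length(thr)) do.call(rbind, thr) else
    data.frame(type = character(), omega_lo = numeric(),
               omega_hi = numeric(), omega = numeric())
  structure(list(omega = omega_grid, stability_index = stab,
                 oscillation_index = osc, max_re = max_re, max_im = max_im,
                 thresholds = thresholds, position = position,
                 eval_state = eval_state, tol = im_floor),
            class = "gain_scan")
}

#' @export
print.gain_scan <- function(x, ...) {
  cat(sprintf(
    "Feedback-gain scan at Jacobian cell (1, n+%d): %d grid points on [%g, %g]\n",
    x$position, length(x$omega), min(x$omega), max(x$omega)))
  cat(sprintf("Evaluation state: z1 = %g (pseudo steady state)\n",
              x$eval_state$z[1]))
  if (nrow(x$thresholds)) {
    cat("Index flips (bisection-refined):\n")
    print(x$thresholds, row.names = FALSE)
  } else {
    cat("No index flips on the grid.\n")
  }
  invisible(x)
}

#' @export
plot.gain_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$omega, x$stability_index, type = "s", ylim = c(-1.2, 1.2),
                 xlab = expression(omega), ylab = "stability index", ...)
  graphics::plot(x$omega, x$oscillation_index, type = "s", ylim = c(-1.2, 1.2),
                 xlab = expression(omega), ylab = "oscillation index", ...)
  invisible(x)
}

#' Bifurcation report for master-protein autoregulation
#'
#' Reports the critical gain `omega1 = eta1 * k1d / r1` at which the
#' leading eigenvalue's real part crosses zero, the closed-form eigenvalues
#' at the crossing, and the nature of the crossing. At the critical gain
#' the perturbed pair is real — one eigenvalue 0, the other
#' `-(eta1 + k1d)` — so the loss of stability happens through a real zero
#' eigenvalue; a complex pair with zero real part cannot occur for this
#' cell, since complex pairs always sit at `Re = -(eta1 + k1d)/2 < 0`.
#'
#' @param model a [regulon_model()] with `r[1] > 0`.
#' @return An object of class `"bifurcation_report"`.
#' @export
bifurcation_report <- function(model) {
  cond <- omega1_conditions(model)
  eg <- feedback_eigs_closed_form(model, cond$stability)
  structure(list(
    crossing = cond$stability,
    oscillation_threshold = cond$oscillation,
    eigenvalues_at_crossing = eg$lambda_pair,
    crossing_type = "real zero eigenvalue",
    complex_pair_real_part = -(model$eta[1] + model$k_d[1]) / 2),
    class = "bifurcation_report")
}

#' @export
print.bifurcation_report <- function(x, ...) {
  cat(sprintf("Critical autoregulation gain: omega1 = %g\n", x$crossing))
  cat("Eigenvalue pair at the crossing:",
      paste(format(x$eigenvalues_at_crossing), collapse = ", "), "\n")
  cat(sprintf(
    "Crossing type: %s (complex pairs are confined to Re = %g < 0,\n",
    x$crossing_type, x$complex_pair_real_part))
  cat("so no imaginary-axis crossing of a complex pair is possible here).\n")
  cat(sprintf("Oscillation (complex-pair) threshold: omega1 < %g\n",
              x$oscillation_threshold))
  invisible(x)
}
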