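#' Bundle a model, input and feedback into a scenario
#'
#' @param model a [regulon_model()].
#' @param input an [input_signal()].
#' @param feedback optional [feedback_spec()].
#' @param label provenance string.
#' @param seed integer seed used to generate the scenario, or `NULL`.
#' @return An object of class `"regulon_scenario"`.
#' @export
regulon_scenario <- function(model, input, feedback = NULL,
                             label = "custom", seed = NULL) {
  stopifnot(inherits(model, "regulon_model"), inherits(input, "input_signal"))
  if (!is.null(feedback)) stopifnot(inherits(feedback, "feedback_spec"))
  structure(list(model = model, input = input, feedback = feedback,
                 label = label, seed = seed),
            class = "regulon_scenario")
}

#' @export
print.regulon_scenario <- function(x, ...) {
  cat(sprintf("Regulon scenario '%s'%s\n", x$label,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  print(x$model)
  print(x$input)
  if (!is.null(x$feedback)) print(x$feedback)
  invisible(x)
}

#' Canonical XlnR regulon scenario
#'
#' The three-gene XlnR regulon parameterization used throughout the
#' package's worked analyses: master xlnR gene plus two target genes, a
#' 50 mM D-xylose pulse consumed at rate `K = 0.3`, and (optionally) the
#' two-target feedback illustration in which gene 2's protein activates and
#' gene 3's protein represses the xlnR gene through the delayed
#' post-translational channel (`k_RL = k_AL = k_ls = 1`, `tau = 1` h, CreA
#' absent). Which target acts as activator is not biologically resolved;
#' the assignment here is a documented, configurable default.
#'
#' @param with_feedback include the feedback specification.
#' @return A `"regulon_scenario"` labelled `"xlnr-canonical"`.
#' @examples
#' xlnr_scenario()$model$k_d          # 0.5 0.4 0.3
#' @export
xlnr_scenario <- function(with_feedback = FALSE) {
  model <- regulon_model(
    rho = c(2e-3, 2.5e-3, 1e-3),
    k_s = c(NA, 5, 6),
    k_1 = c(NA, 0.1, 0.1),
    k_d = c(0.5, 0.4, 0.3),
    r   = c(0.5, 0.5, 0.5),
    eta = c(1, 1, 1),
    b   = c(1, 0, 0),
    h   = 1)
  input <- input_signal(u0 = 50, K = 0.3, beta = 1e-6)
  feedback <- if (with_feedback) {
    feedback_spec(S1 = 3L, S2 = 2L, k_RL = 1, k_AL = 1, k_ls = 1,
                  tau = 1, C_A = 0, creA_binary = TRUE)
  } else NULL
  regulon_scenario(model, input, feedback,
                   label = if (with_feedback) "xlnr-canonical+feedback"
                   else "xlnr-canonical")
}

#' Randomized plausible regulon scenario
#'
#' Draws a structurally valid n-gene scenario for property testing. Rates
#' are drawn log-uniformly from ranges bracketing the canonical values by
#' roughly an order of magnitude each way; basal transcription is kept far
#' below synthesis (leaky transcription at very low mRNA levels). The draw
#' is deterministic in `seed`.
#'
#' @param seed integer seed.
#' @param n number of genes (>= 2).
#' @param ranges optional named list overriding default ranges; each entry
#'   is `c(lo, hi)` with `0 < lo <= hi`. Names: `k_d`, `eta`, `k_s`, `k_1`,
#'   `r`, `rho`, `b1`, `u0`, `K`, `k_RL`, `k_AL`, `k_ls`.
#' @param with_feedback include a random feedback specification (each
#'   target assigned activator or repressor).
#' @return A `"regulon_scenario"` labelled `"randomized"`.
#' @export
random_scenario <- function(seed, n = 3L, ranges = NULL,
                            with_feedback = FALSE) {
  stopifnot(n >= 2L)
  defaults <- list(
    k_d = c(0.05, 5), eta = c(0.1, 10), k_s = c(0.5, 50),
    k_1 = c(0.01, 1), r = c(0.05, 5), rho = c(1e-4, 1e-2),
    b1 = c(0.1, 10), u0 = c(5, 500), K = c(0.03, 3),
    k_RL = c(0.1, 10), k_AL = c(0.1, 10), k_ls = c(0.1, 10))
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(defaults))
    if (length(bad)) {
      stop("unknown range names: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(ranges)) {
      rg <- ranges[[nm]]
      if (length(rg) != 2L || rg[1] <= 0 || rg[2] < rg[1]) {
        stop(sprintf("invalid range for '%s'", nm), call. = FALSE)
      }
      defaults[[nm]] <- rg
    }
  }
  set.seed(seed)
  runif_log <- function(m, rg) exp(stats::runif(m, log(rg[1]), log(rg[2])))
  model <- regulon_model(
    rho = runif_log(n, defaults$rho),
    k_s = c(NA, runif_log(n - 1L, defaults$k_s)),
    k_1 = c(NA, runif_log(n - 1L, defaults$k_1)),
    k_d = runif_log(n, defaults$k_d),
    r   = runif_log(n, defaults$r),
    eta = runif_log(n, defaults$eta),
    b   = c(runif_log(1L, defaults$b1), rep(0, n - 1L)),
    h   = 1)
  input <- input_signal(u0 = runif_log(1L, defaults$u0),
                        K = runif_log(1L, defaults$K))
  feedback <- NULL
  if (with_feedback) {
    targets <- 2:n
    act <- stats::runif(length(targets)) < 0.5
    if (all(act)) act[length(act)] <- FALSE      # keep both channels nonempty
    if (!any(act)) act[1] <- TRUE
    feedback <- feedback_spec(
      S1 = targets[!act], S2 = targets[act],
      k_RL = runif_log(1L, defaults$k_RL),
      k_AL = runif_log(1L, defaults$k_AL),
      k_ls = runif_log(1L, defaults$k_ls),
      tau = sample(0:5, 1L), C_A = 0, creA_binary = TRUE)
  }
  regulon_scenario(model, input, feedback, label = "randomized", seed = seed)
}

#' Edge-case scenarios
#'
#' Named degenerate variants of the canonical scenario that exercise
#' boundary behavior: a zero mRNA-degradation rate (critically stable
#' spectrum), zero basal transcription, a zero input (nothing perturbs the
#' basal state), a zero feedback delay, and CreA present (the feedback
#' channel silenced by the gate).
#'
#' @return Named list of `"regulon_scenario"` objects.
#' @export
degenerate_scenarios <- function() {
  base <- xlnr_scenario(with_feedback = TRUE)
  zero_kd <- base
  zero_kd$model$k_d[3] <- 0
  zero_kd$label <- "degenerate-zero-kd"
  zero_basal <- base
  zero_basal$model$rho[] <- 0
  zero_basal$label <- "degenerate-zero-basal"
  zero_input <- base
  zero_input$input <- input_signal(u0 = 0, K = 0.3)
  zero_input$label <- "degenerate-zero-input"
  zero_delay <- base
  zero_delay$feedback$tau <- 0
  zero_delay$label <- "degenerate-zero-delay"
  crea_present <- base
  crea_present$feedback$C_A <- 1
  crea_present$label <- "degenerate-creA-present"
  list(zero_kd = zero_kd, zero_basal = zero_basal, zero_input = zero_input,
       zero_delay = zero_delay, crea_present = crea_present)
}
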