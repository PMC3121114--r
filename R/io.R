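#' Serialize a scenario to a flat configuration file
#'
#' Writes the model, input and feedback parameters as a flat mapping with
#' keys `rho, k_s, k_1, k_d, r, eta, b, h, u0, K, beta, S1, S2, k_RL, k_AL,
#' k_ls, tau, C_A, k_A, creA_binary`. The dialect is chosen by extension:
#' `.yaml`/`.yml` or `.json`.
#'
#' @param scenario a `"regulon_scenario"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "regulon_scenario"))
  m <- scenario$model
  cfg <- list(rho = m$rho, k_s = m$k_s, k_1 = m$k_1, k_d = m$k_d,
              r = m$r, eta = m$eta, b = m$b, h = m$h,
              u0 = scenario$input$u0, K = scenario$input$K,
              beta = scenario$input$beta,
              label = scenario$label)
  fb <- scenario$feedback
  if (!is.null(fb)) {
    cfg <- c(cfg, list(S1 = fb$S1, S2 = fb$S2, k_RL = fb$k_RL,
                       k_AL = fb$k_AL, k_ls = fb$k_ls, tau = fb$tau,
                       C_A = fb$C_A, k_A = fb$k_A,
                       creA_binary = fb$creA_binary))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    stop("config extension must be .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' Read a scenario from a flat configuration file
#'
#' @param path a `.yaml`/`.yml` or `.json` file written by
#'   [write_scenario_config()] or authored by hand with the same keys.
#' @return A `"regulon_scenario"`.
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config extension must be .yaml, .yml or .json", call. = FALSE)
  }
  num <- function(x) {
    if (is.null(x)) return(NULL)
    vapply(x, function(v) if (is.null(v) || (is.character(v) && v == "NA"))
      NA_real_ else as.numeric(v), numeric(1))
  }
  model <- regulon_model(rho = num(cfg$rho), k_s = num(cfg$k_s),
                         k_1 = num(cfg$k_1), k_d = num(cfg$k_d),
                         r = num(cfg$r), eta = num(cfg$eta),
                         b = num(cfg$b), h = as.numeric(cfg$h))
  input <- input_signal(u0 = as.numeric(cfg$u0), K = as.numeric(cfg$K),
                        beta = as.numeric(cfg$beta))
  feedback <- NULL
  if (!is.null(cfg$k_ls)) {
    feedback <- feedback_spec(
      S1 = as.integer(unlist(cfg$S1)), S2 = as.integer(unlist(cfg$S2)),
      k_RL = as.numeric(cfg$k_RL), k_AL = as.numeric(cfg$k_AL),
      k_ls = as.numeric(cfg$k_ls), tau = as.numeric(cfg$tau),
      C_A = as.numeric(cfg$C_A), k_A = as.numeric(cfg$k_A),
      creA_binary = isTRUE(as.logical(cfg$creA_binary)))
  }
  regulon_scenario(model, input, feedback,
                   label = if (is.null(cfg$label)) "config" else cfg$label)
}

#' Write a trajectory as CSV
#'
#' One row per output time with header `t, u, x1..xn, z1..zn`.
#'
#' @param traj a `"regulon_trajectory"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "regulon_trajectory"))
  df <- data.frame(t = traj$times, u = traj$u_values, traj$states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV back into a data frame
#'
#' @param path CSV written by [write_trajectory()].
#' @return Data frame with columns `t`, `u`, `x1..xn`, `z1..zn`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "u")
  if (!all(need %in% names(df))) {
    stop("not a trajectory CSV: missing 't'/'u' columns", call. = FALSE)
  }
  df
}

#' Write a gain scan as CSV
#'
#' One row per scanned gain with header
#' `omega, stability_index, oscillation_index, max_re, max_im`.
#'
#' @param scan a `"gain_scan"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "gain_scan"))
  df <- data.frame(omega = scan$omega,
                   stability_index = scan$stability_index,
                   oscillation_index = scan$oscillation_index,
                   max_re = scan$max_re, max_im = scan$max_im)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a scan's threshold report as JSON
#'
#' Records the scanned Jacobian cell, every bisection-refined index flip,
#' the method, and the evaluation state (on which the located thresholds
#' for target-protein cells depend).
#'
#' @param scan a `"gain_scan"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(scan, path) {
  stopifnot(inherits(scan, "gain_scan"))
  rep <- list(
    position = c(1L, length(scan$eval_state$x) + scan$position),
    thresholds = scan$thresholds,
    method = "grid scan with bisection refinement",
    eval_state = list(x = scan$eval_state$x, z = scan$eval_state$z))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
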