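# Pipeline entry points: reproduce the package's headline analyses as files
# (trajectory/scan/promoter CSVs plus JSON summaries with provenance).

# internal: resolve a scenario argument (object, builtin name, or config path)
resolve_scenario <- function(scenario, with_feedback = FALSE) {
  if (inherits(scenario, "regulon_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    if (scenario %in% c("xlnr", "xlnr-canonical")) {
      return(xlnr_scenario(with_feedback = with_feedback))
    }
    if (file.exists(scenario)) return(read_scenario_config(scenario))
    stop(sprintf("unknown scenario '%s' (not a builtin, not a file)", scenario),
         call. = FALSE)
  }
  stop("'scenario' must be a regulon_scenario, builtin name or config path",
       call. = FALSE)
}

# internal: provenance record written beside every pipeline output
write_provenance <- function(out_dir, command, resolved) {
  rec <- c(list(command = command,
                package = "xlnrdyn",
                version = as.character(utils::packageVersion("xlnrdyn")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           resolved)
  jsonlite::write_json(rec, file.path(out_dir, paste0(command, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
}

#' Run the simulation pipeline
#'
#' Simulates the scenario open loop and (optionally) with feedback, writes
#' trajectory CSVs, and writes a JSON summary holding analytic and
#' empirical relaxation times, per-species peaks, the open-loop/feedback
#' pointwise difference summary, and a per-delay peak table when `tau_list`
#' is given.
#'
#' @param scenario a `"regulon_scenario"`, the builtin name `"xlnr"`, or a
#'   config file path.
#' @param out_dir output directory (created if missing).
#' @param t_end,dt_out simulation horizon and sampling (h).
#' @param with_feedback also run the feedback system and compare.
#' @param tau_list optional vector of delays for a sensitivity table.
#' @return Invisibly, a list with the summary and file paths.
#' @export
run_simulate <- function(scenario = "xlnr", out_dir = ".",
                         t_end = 50, dt_out = 0.1,
                         with_feedback = FALSE, tau_list = NULL) {
  sc <- resolve_scenario(scenario, with_feedback = with_feedback)
  if (with_feedback && is.null(sc$feedback)) {
    stop("feedback run requested but the scenario has no feedback spec",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  open_tr <- simulate_regulon(sc$model, sc$input, NULL,
                              t_end = t_end, dt_out = dt_out)
  files <- list(open = file.path(out_dir, "trajectory_open_loop.csv"))
  write_trajectory(open_tr, files$open)
  n <- sc$model$n
  summ <- list(
    relaxation_time_analytic = vapply(seq_len(n), function(i)
      relaxation_time(sc$model, i), numeric(1)),
    relaxation_time_empirical_master =
      empirical_relaxation_time(sc$model, gene_index = 1L,
                                u_const = sc$input$u0),
    peaks_open_loop = summary(open_tr))
  if (with_feedback) {
    fb_tr <- simulate_regulon(sc$model, sc$input, sc$feedback,
                              t_end = t_end, dt_out = dt_out)
    files$feedback <- file.path(out_dir, "trajectory_feedback.csv")
    write_trajectory(fb_tr, files$feedback)
    d <- fb_tr$states - open_tr$states
    summ$peaks_feedback <- summary(fb_tr)
    summ$feedback_minus_open <- list(
      max_abs = apply(abs(d), 2, max),
      mean = colMeans(d))
  }
  if (!is.null(tau_list)) {
    if (is.null(sc$feedback)) {
      stop("'tau_list' requires a feedback scenario", call. = FALSE)
    }
    summ$delay_sensitivity <- delay_sensitivity(
      sc$model, sc$input, sc$feedback, tau_grid = tau_list,
      t_end = t_end, dt_out = dt_out)
  }
  jsonlite::write_json(summ, file.path(out_dir, "simulate_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_provenance(out_dir, "simulate",
                   list(scenario = sc$label, t_end = t_end, dt_out = dt_out,
                        with_feedback = with_feedback, tau_list = tau_list))
  invisible(list(summary = summ, files = files))
}

#' Run the feedback-gain scan pipeline
#'
#' Scans one or more Jacobian cells `(1, n + position)`, writing per-cell
#' scan CSVs and threshold JSONs (every index flip, bisection-refined, plus
#' the evaluation state used).
#'
#' @inheritParams run_simulate
#' @param positions protein indices to scan (default all of `1..n`).
#' @param omega_grid gain grid.
#' @param u_eval sustained input defining the evaluation state (mM).
#' @return Invisibly, the list of `"gain_scan"` objects.
#' @export
run_scan <- function(scenario = "xlnr", out_dir = ".",
                     positions = NULL,
                     omega_grid = seq(-1000, 1000, length.out = 2001),
                     u_eval = 50) {
  sc <- resolve_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(positions)) positions <- seq_len(sc$model$n)
  eval_state <- steady_state(sc$model, u_const = u_eval)
  scans <- lapply(positions, function(p) {
    s <- scan_feedback_gain(sc$model, position = p, omega_grid = omega_grid,
                            eval_state = eval_state)
    write_scan(s, file.path(out_dir, sprintf("scan_omega%d.csv", p)))
    write_thresholds(s, file.path(out_dir, sprintf("thresholds_omega%d.json", p)))
    s
  })
  names(scans) <- paste0("omega", positions)
  write_provenance(out_dir, "scan",
                   list(scenario = sc$label, positions = positions,
                        grid = range(omega_grid), grid_n = length(omega_grid),
                        u_eval = u_eval))
  invisible(scans)
}

#' Run the promoter-activity pipeline
#'
#' Simulates the feedback scenario for each feedback synthesis strength in
#' `k_ls_values` and writes one CSV per value with columns
#' `t, Gamma_A, Gamma_R, combined`.
#'
#' @inheritParams run_simulate
#' @param k_ls_values feedback synthesis strengths to compare.
#' @return Invisibly, a named list of promoter-activity data frames.
#' @export
run_promoter <- function(scenario = "xlnr", out_dir = ".",
                         k_ls_values = c(1, 5), t_end = 50, dt_out = 0.1) {
  sc <- resolve_scenario(scenario, with_feedback = TRUE)
  if (is.null(sc$feedback)) {
    stop("promoter pipeline requires a feedback scenario", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(k_ls_values, function(kls) {
    sp <- sc$feedback
    sp$k_ls <- kls
    tr <- simulate_regulon(sc$model, sc$input, sp,
                           t_end = t_end, dt_out = dt_out)
    pa <- promoter_activity_trajectory(tr, sp)
    utils::write.csv(pa, file.path(out_dir, sprintf("promoter_kls%g.csv", kls)),
                     row.names = FALSE)
    pa
  })
  names(out) <- paste0("k_ls_", k_ls_values)
  write_provenance(out_dir, "promoter",
                   list(scenario = sc$label, k_ls_values = k_ls_values,
                        t_end = t_end, dt_out = dt_out))
  invisible(out)
}

#' Run the analysis report pipeline
#'
#' Writes a single JSON report with the analytic relaxation times, the
#' closed-form autoregulation thresholds, and the bifurcation report for
#' the scenario.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the report list.
#' @export
run_report <- function(scenario = "xlnr", out_dir = ".") {
  sc <- resolve_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cond <- omega1_conditions(sc$model)
  bif <- bifurcation_report(sc$model)
  rep <- list(
    scenario = sc$label,
    relaxation_times = vapply(seq_len(sc$model$n), function(i)
      relaxation_time(sc$model, i), numeric(1)),
    omega1_stability_threshold = cond$stability,
    omega1_oscillation_threshold = cond$oscillation,
    bifurcation = list(
      crossing = bif$crossing,
      eigenvalues_at_crossing = list(
        re = Re(bif$eigenvalues_at_crossing),
        im = Im(bif$eigenvalues_at_crossing)),
      crossing_type = bif$crossing_type,
      complex_pair_real_part = bif$complex_pair_real_part),
    open_loop_spectrum = Re(open_loop_spectrum(sc$model)$values))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, "report", list(scenario = sc$label))
  invisible(rep)
}
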