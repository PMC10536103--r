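# Known config blocks and their permitted keys. Defaults reproduce the
# reference acquisition and detection parameters (0.0005 uA threshold,
# 5 s minimum peak distance, the standard DPV program).
.config_schema <- list(
  top = c("seed", "out_dir", "stages", "log_level", "cohort", "detector",
          "coding", "network", "qsar", "input", "write_traces"),
  cohort = c("noise_sd", "spike_amplitude"),
  detector = c("threshold", "min_peak_distance"),
  coding = c("theta", "T_window", "learning_rate", "n_neurons", "n_columns"),
  network = c("tau_m", "v_th", "v_reset", "dt", "t_ref", "U", "pulse_width",
              "pulse_amplitude", "duration"),
  qsar = c("n_samples", "b0", "b1", "b2", "noise_sd"),
  input = c("trace_csv")
)

.known_stages <- c("simulate", "detect", "encode", "train", "network", "qsar")

#' Build and validate a pipeline run configuration
#'
#' A run configuration selects pipeline stages and carries one parameter
#' block per stage. Unknown keys are rejected (a typo must fail loudly,
#' not silently fall back to a default), a seed is mandatory so every run
#' is reproducible, and all defaults equal the reference parameters: a
#' detection threshold of 0.0005 signal units with a 5 s minimum peak
#' distance, and a noise-free cohort with 0.001-unit spikes.
#'
#' @param config A named list, or a path to a JSON file holding one.
#' @return A validated config list of class `run_config` with all
#'   defaults filled in.
#' @examples
#' cfg <- run_config(list(seed = 1, out_dir = tempdir(),
#'                        stages = c("simulate", "detect")))
#' cfg$detector$threshold
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("`config` must be a list or a JSON file path")
  unknown <- setdiff(names(config), .config_schema$top)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (block in intersect(names(config), names(.config_schema)[-1L])) {
    bad <- setdiff(names(config[[block]]), .config_schema[[block]])
    if (length(bad)) {
      stopf("unknown key(s) in `%s` block: %s", block,
            paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$seed)) {
    stopf("`seed` is mandatory: runs must be reproducible")
  }
  check_scalar(config$seed, "seed")
  defaults <- list(
    out_dir = ".",
    stages = c("simulate", "detect"),
    log_level = "info",
    write_traces = FALSE,
    cohort = list(noise_sd = 0, spike_amplitude = 0.001),
    detector = list(threshold = 0.0005, min_peak_distance = 5),
    coding = list(theta = 0.0005, T_window = 10, learning_rate = 0.1,
                  n_neurons = 10, n_columns = 500),
    network = list(tau_m = 1, v_th = 0.5, v_reset = 0, dt = 0.1, t_ref = 0,
                   U = 2, pulse_width = 2, pulse_amplitude = 1,
                   duration = 200),
    qsar = list(n_samples = 100, b0 = 100, b1 = 0.5, b2 = 10, noise_sd = 5),
    input = list(trace_csv = NULL)
  )
  out <- utils::modifyList(defaults, config)
  for (block in names(.config_schema)[-1L]) {
    out[[block]] <- utils::modifyList(defaults[[block]],
                                      as.list(config[[block]] %||% list()))
  }
  bad_stage <- setdiff(out$stages, .known_stages)
  if (length(bad_stage)) {
    stopf("unknown stage(s): %s (known: %s)",
          paste(bad_stage, collapse = ", "),
          paste(.known_stages, collapse = ", "))
  }
  structure(out, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order — simulate (synthetic cohort
#' generation), detect (spike detection + per-sample and cohort
#' statistics), encode (latency temporal codes), train (co-activation
#' weight updates and connectivity indices), network (spiking-network
#' response to the first detected train), qsar (descriptor generation and
#' linear-model fit) — writing one CSV/JSON artifact per stage into
#' `out_dir`. The run is end-to-end deterministic for a fixed seed: the
#' same config produces byte-identical artifacts.
#'
#' `detect` uses the simulated cohort when `simulate` is selected,
#' otherwise it reads `input$trace_csv` (a trace CSV file or a directory
#' of them).
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @return Invisibly, a list of per-stage results (`traces`, `report`,
#'   `codes`, `weights`, `indices`, `network`, `qsar` as applicable) plus
#'   `artifacts`, the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(artifacts = character(0))
  say <- function(fmt, ...) {
    if (identical(cfg$log_level, "info")) message(sprintf(fmt, ...))
  }
  emit <- function(obj, file, writer) {
    path <- file.path(cfg$out_dir, file)
    writer(obj, path)
    res$artifacts <<- c(res$artifacts, path)
    path
  }
  write_csv <- function(obj, path) {
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  }

  traces <- NULL
  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", {
      specs <- cohort_specs(noise_sd = cfg$cohort$noise_sd,
                            spike_amplitude = cfg$cohort$spike_amplitude,
                            seed = cfg$seed)
      traces <- lapply(specs, synth_trace)
      say("simulate: generated %d traces", length(traces))
      if (isTRUE(cfg$write_traces)) {
        for (tr in traces) {
          emit(tr, sprintf("trace_%s.csv", gsub("[^A-Za-z0-9]+", "_",
                                                tr$sample_id)),
               write_trace_csv)
        }
      }
      res$traces <- traces
    })
    traces <- res$traces
  }

  if ("detect" %in% cfg$stages) {
    run_stage("detect", {
      if (is.null(traces)) {
        src <- cfg$input$trace_csv
        if (is.null(src)) {
          stopf("no input: select the 'simulate' stage or set input$trace_csv")
        }
        files <- if (dir.exists(src)) {
          list.files(src, pattern = "\\.csv$", full.names = TRUE)
        } else src
        traces <- lapply(files, read_trace_csv)
      }
      report <- cohort_report(traces,
                              threshold = cfg$detector$threshold,
                              min_peak_distance = cfg$detector$min_peak_distance)
      say("detect: %d samples, cohort mean count %.1f",
          nrow(report), attr(report, "cohort_means")[["n_spikes"]])
      emit(report, "spike_report.csv", write_csv)
      res$report <- report
      res$trains <- lapply(traces, detect_spikes,
                           threshold = cfg$detector$threshold,
                           min_peak_distance = cfg$detector$min_peak_distance)
    })
  }

  if ("encode" %in% cfg$stages || "train" %in% cfg$stages) {
    run_stage("encode", {
      if (is.null(traces)) stopf("encode needs traces (select 'simulate')")
      N <- min(cfg$coding$n_neurons, length(traces))
      n_cols <- min(cfg$coding$n_columns,
                    min(vapply(traces[seq_len(N)], length, integer(1L))))
      p <- t(vapply(traces[seq_len(N)],
                    function(tr) tr$values[seq_len(n_cols)],
                    numeric(n_cols)))
      codes <- encode_matrix(p, theta = cfg$coding$theta,
                             T_window = cfg$coding$T_window)
      say("encode: %d x %d code matrix, %.1f%% nonzero",
          nrow(codes), ncol(codes), 100 * mean(codes > 0))
      emit(as.data.frame(codes), "temporal_codes.csv", write_csv)
      res$codes <- codes
    })
  }

  if ("train" %in% cfg$stages) {
    run_stage("train", {
      N <- nrow(res$codes)
      W0 <- if (N == 10L) load_initial_weights() else init_weights(N, cfg$seed)
      W <- train_weights(W0, res$codes, cfg$coding$learning_rate)
      act <- rowMeans(res$codes > 0)
      idx <- psi_ppi(W, act)
      say("train: weights in [%.3f, %.3f]", min(W), max(W))
      emit(as.data.frame(W), "trained_weights.csv", write_csv)
      emit(data.frame(neuron = seq_len(N), psi = idx$psi, ppi = idx$ppi,
                      mean_activity = act),
           "connectivity_indices.csv", write_csv)
      res$weights <- W
      res$indices <- idx
    })
  }

  if ("network" %in% cfg$stages) {
    run_stage("network", {
      if (is.null(res$trains)) stopf("network needs detected trains (select 'detect')")
      np <- cfg$network
      train <- res$trains[[1L]]
      keep <- train$spike_times <= np$duration
      train$spike_times <- train$spike_times[keep]
      train$spike_values <- train$spike_values[keep]
      params <- lif_params(N = 1, tau_m = np$tau_m, v_th = np$v_th,
                           v_reset = np$v_reset, dt = np$dt, t_ref = np$t_ref,
                           U = np$U, tau_s = np$tau_m / 2)
      summary <- drive_with_proteinoid(train, params,
                                       pulse_width = np$pulse_width,
                                       pulse_amplitude = np$pulse_amplitude,
                                       duration = np$duration)
      say("network: %d input -> %d output spikes",
          summary$n_input_spikes, summary$n_output_spikes)
      emit(data.frame(n_input_spikes = summary$n_input_spikes,
                      n_output_spikes = summary$n_output_spikes,
                      output_rate = summary$output_rate,
                      F_out_mean = summary$F_out_mean,
                      F_out_max = summary$F_out_max),
           "network_response.csv", write_csv)
      res$network <- summary[c("n_input_spikes", "n_output_spikes",
                               "output_rate", "F_out_mean", "F_out_max")]
    })
  }

  if ("qsar" %in% cfg$stages) {
    run_stage("qsar", {
      q <- cfg$qsar
      d <- generate_descriptor_table(q$n_samples, q$b0, q$b1, q$b2,
                                     q$noise_sd, seed = cfg$seed)
      model <- fit_qsar(d$firing_rate, d)
      pred <- predict(model, d)
      say("qsar: b = (%.4g, %.4g, %.4g), R^2 = %.4f",
          model$coefficients[1L], model$coefficients[2L],
          model$coefficients[3L], model$r_squared)
      emit(list(coefficients = as.list(model$coefficients),
                ci95 = list(lower = model$ci95[, 1L],
                            upper = model$ci95[, 2L]),
                r_squared = model$r_squared),
           "qsar_model.json",
           function(obj, path) jsonlite::write_json(obj, path,
                                                    auto_unbox = TRUE,
                                                    digits = NA))
      emit(cbind(d, predicted = as.numeric(pred),
                 percent_deviation = percent_deviation(as.numeric(pred),
                                                       d$firing_rate)),
           "qsar_predictions.csv", write_csv)
      res$qsar <- model
    })
  }

  invisible(res)
}
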