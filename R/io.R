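#' @title Serialization helpers
#'
#' @description
#' Plain-text interchange for every artifact: recordings and stimulus
#' matrices as CSV (metadata in `#`-prefixed header lines), normalization
#' statistics, training configuration and calibrated model parameters as
#' JSON, trial logs as per-sample CSV plus a JSON session manifest.
#'
#' @name serialization
NULL

#' Write / read a raw recording as CSV
#'
#' One column per channel; sampling rate, bit depth and ADC range are
#' stored in `#`-comment header lines.
#'
#' @param recording an [emg_recording].
#' @param path output file.
#' @return `write_recording_csv`: `path`, invisibly. `read_recording_csv`:
#'   an [emg_recording].
#' @export
write_recording_csv <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate=%g", recording$sampling_rate),
               sprintf("# bits=%d", recording$bits),
               sprintf("# v_range=%.17g", recording$v_range)), con)
  utils::write.table(t(recording$values), con, sep = ",", row.names = FALSE,
                     col.names = paste0("ch", seq_len(recording$n_channels)))
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- function(key) as.numeric(sub(paste0("# ", key, "="), "",
                                       grep(key, hdr, value = TRUE)[1]))
  x <- utils::read.csv(path, comment.char = "#")
  emg_recording(t(as.matrix(x)), meta("sampling_rate"), meta("bits"),
                meta("v_range"))
}

#' Write / read a stimulus encoding as CSV
#'
#' @param stimulus a [stimulus_encoding].
#' @param path file path.
#' @return The path (write) or a [stimulus_encoding] (read).
#' @export
write_stimulus_csv <- function(stimulus, path) {
  utils::write.table(t(stimulus$values), path, sep = ",", row.names = FALSE,
                     col.names = paste0("dof", seq_len(stimulus$n_dofs)))
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  stimulus_encoding(t(as.matrix(utils::read.csv(path))))
}

#' Serialize normalization statistics to JSON
#'
#' @param stats a `normalization_stats` object.
#' @param path file path.
#' @return The path (write) or `normalization_stats` (read).
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(list(p1 = stats$p1, p99 = stats$p99), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stats_json
#' @export
read_stats_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(p1 = x$p1, p99 = x$p99, n_channels = length(x$p1)),
            class = "normalization_stats")
}

#' Serialize calibrated network parameters to JSON
#'
#' Full-precision round-trip of the topology and every weight matrix and
#' bias vector.
#'
#' @param params an `mrl_parameters` object.
#' @param path file path.
#' @return The path (write) or `mrl_parameters` (read).
#' @export
write_model_json <- function(params, path) {
  tp <- params$topology
  obj <- list(
    topology = tp[c("n_inputs", "n_dofs", "first_layer_log2", "encoder_depth",
                    "decoder_hidden_log2", "activation_slope", "layernorm_eps")],
    encoder = lapply(params$encoder, function(l)
      list(W = l$W, b = l$b)),
    decoder = lapply(params$decoder, function(d)
      list(hidden = list(W = d$hidden$W, b = d$hidden$b),
           out = list(W = d$out$W, b = d$out$b)))
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  tp <- do.call(mrl_topology, as.list(x$topology))
  enc <- lapply(seq_len(tp$encoder_depth), function(l)
    list(W = as.matrix(x$encoder[[l]]$W), b = as.numeric(x$encoder[[l]]$b)))
  dec <- lapply(seq_len(tp$n_dofs), function(j)
    list(hidden = list(W = as.matrix(x$decoder[[j]]$hidden$W),
                       b = as.numeric(x$decoder[[j]]$hidden$b)),
         out = list(W = matrix(as.numeric(x$decoder[[j]]$out$W), nrow = 1),
                    b = as.numeric(x$decoder[[j]]$out$b))))
  structure(list(topology = tp, encoder = enc, decoder = dec),
            class = "mrl_parameters")
}

#' Write a trial log as per-sample CSV
#'
#' Rows: time (s from control grant), cursor x/y, in-target flag.
#'
#' @param log a `trial_log`.
#' @param path file path.
#' @param rate sampling rate used during the trial.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(log, path, rate = 200) {
  n <- nrow(log$trajectory)
  tgt <- c(log$target$x, log$target$y)
  inside <- sqrt(colSums((t(log$trajectory) - tgt)^2)) < log$target$radius
  utils::write.table(
    data.frame(t = (seq_len(n) - 1) / rate,
               x = log$trajectory[, 1], y = log$trajectory[, 2],
               inside = as.integer(inside)),
    path, sep = ",", row.names = FALSE)
  invisible(path)
}

#' Write a session manifest as JSON
#'
#' Targets, outcomes, completion times and overshoot counts of a full
#' session.
#'
#' @param logs list of `trial_log`s.
#' @param path file path.
#' @param seed seed used for the session (recorded for provenance).
#' @return The path, invisibly.
#' @export
write_session_json <- function(logs, path, seed = NULL) {
  obj <- list(
    seed = seed,
    trials = lapply(logs, function(l) list(
      x = l$target$x, y = l$target$y, radius = l$target$radius,
      distance = l$target$distance, id_bits = l$target$id_bits,
      outcome = l$outcome, completion_time = l$completion_time,
      overshoots = l$overshoots, path_length = l$path_length))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
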