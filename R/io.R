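# Plain-text (CSV) readers and writers for panels and simulation truth.

#' Write / read an ESM panel as CSV
#'
#' Columns: `patient_id, occasion, day, beep` followed by one column per
#' channel; missing cells are empty; UTF-8 with header. Numeric values
#' are written with full (17 significant digits) precision so a
#' write/read round trip reproduces values and missingness masks
#' bit-exactly.
#'
#' @param panel An ESM panel data frame.
#' @param path File path.
#' @param check_scale For `read_panel()`: reject observed scores outside
#'   `[1, 100]` (the ESM item scale). Disable for unclipped synthetic
#'   recovery data.
#' @return `read_panel()` returns the panel data frame.
#' @export
write_panel <- function(panel, path) {
  channels <- panel_channels(panel)
  out <- panel[, c("patient_id", "occasion", "day", "beep"), drop = FALSE]
  for (ch in channels) out[[ch]] <- format_full(panel[[ch]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, check_scale = TRUE) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "occasion", "day", "beep")
  if (!all(need %in% colnames(df)))
    stop("malformed panel CSV: required columns ", paste(need, collapse = ", "))
  channels <- setdiff(colnames(df), need)
  if (length(channels) == 0) stop("malformed panel CSV: no channel columns")
  for (ch in channels) df[[ch]] <- as.numeric(df[[ch]])
  if (check_scale) {
    y <- as.matrix(df[, channels, drop = FALSE])
    bad <- which(!is.na(y) & (y < 1 | y > 100), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("scores outside [1, 100] at rows: ",
           paste(utils::head(unique(bad[, 1]), 10), collapse = ", "),
           " (use check_scale = FALSE for unclipped synthetic data)")
  }
  df
}

#' Write simulation truth files
#'
#' Companion CSVs for a simulated panel: the true latent states
#' (`patient_id, occasion, state`) and the true patient-level parameters
#' in long format (`patient_id, parameter, state, column, value`).
#'
#' @param sim An `esm_sim` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$states, file.path(dir, "true_states.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(sim$subject_params, function(sp) {
    mu <- sp$emission_means
    G <- sp$transition
    rbind(
      data.frame(patient_id = sp$patient_id, parameter = "emission_mean",
                 state = rep(seq_len(sp$m), sp$K),
                 column = rep(colnames(mu) %||% seq_len(sp$K), each = sp$m),
                 value = as.numeric(mu)),
      data.frame(patient_id = sp$patient_id, parameter = "transition",
                 state = rep(seq_len(sp$m), sp$m),
                 column = rep(seq_len(sp$m), each = sp$m),
                 value = as.numeric(G))
    )
  }))
  write.csv(long, file.path(dir, "true_subject_params.csv"), row.names = FALSE)
  invisible(dir)
}
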