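## Text-based interchange formats: a delimited numeric table per recording
## plus a YAML sidecar holding the metadata (rate, labels, start time).
## Delimited tables round-trip doubles exactly (shortest round-trippable
## decimal representation on write).

#' Write a recording as a table + metadata sidecar
#'
#' Produces `<prefix>.tsv` (columns: `time`, `trigger` if present, then one
#' column per channel) and `<prefix>.meta.yaml` (sampling rate, start time,
#' channel labels, units).
#'
#' @param rec An [emg_recording()].
#' @param prefix Output path prefix (directories must exist).
#' @return The two file paths, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "ff_recording"))
  n <- ncol(rec$data)
  tab <- data.table::data.table(time = rec$t0 + (seq_len(n) - 1L) / rec$fs)
  if (!is.null(rec$trigger))
    data.table::set(tab, j = "trigger", value = rec$trigger)
  ## %.17g guarantees a bit-exact double round-trip through the text table
  m <- data.table::as.data.table(
    matrix(sprintf("%.17g", t(rec$data)), nrow = n))
  data.table::setnames(m, rec$labels)
  tab <- cbind(tab, m)
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".meta.yaml")
  data.table::fwrite(tab, data_path, sep = "\t")
  yaml::write_yaml(list(fs = rec$fs, t0 = rec$t0, unit = "uV",
                        n_channels = nrow(rec$data),
                        labels = as.list(rec$labels),
                        has_trigger = !is.null(rec$trigger)),
                   meta_path)
  invisible(c(data_path, meta_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix used at write time (or the `.tsv` path).
#' @param format Only `"table_sidecar"` is supported; `"edf_bdf"` raises an
#'   error (no EDF backend is bundled).
#' @return An [emg_recording()].
#' @export
read_recording <- function(prefix, format = c("table_sidecar", "edf_bdf")) {
  format <- match.arg(format)
  if (format == "edf_bdf")
    stop("edf_bdf is not supported by this build; use table_sidecar")
  prefix <- sub("\\.tsv$", "", prefix)
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".meta.yaml")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  if (!file.exists(data_path)) stop("missing data table: ", data_path)
  meta <- yaml::read_yaml(meta_path)
  for (field in c("fs", "labels", "n_channels"))
    if (is.null(meta[[field]])) stop("sidecar is missing field: ", field)
  labels <- unlist(meta$labels)
  tab <- data.table::fread(data_path, sep = "\t")
  miss <- setdiff(labels, names(tab))
  if (length(miss)) stop("data table is missing declared channels: ",
                         paste(miss, collapse = ", "))
  if (length(labels) != meta$n_channels)
    stop("sidecar field n_channels disagrees with labels")
  data <- t(as.matrix(tab[, labels, with = FALSE]))
  trig <- if (isTRUE(meta$has_trigger)) tab$trigger else NULL
  emg_recording(data, fs = meta$fs, labels = labels, trigger = trig,
                t0 = if (is.null(meta$t0)) 0 else meta$t0)
}

#' Write a phase schedule as a delimited table
#'
#' @param schedule An [phase_schedule()].
#' @param path Output `.tsv` path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "ff_schedule"))
  tab <- as.data.frame(schedule)
  tab$calibration_s <- attr(schedule, "calibration_s")
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read a phase schedule written by [write_schedule()]
#'
#' @param path Input `.tsv` path.
#' @return An [phase_schedule()].
#' @export
read_schedule <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  calib <- if ("calibration_s" %in% names(tab)) tab$calibration_s[1L] else 0
  tab$finger[tab$finger %in% c("", "NA")] <- NA_character_
  phase_schedule(tab[, c("start", "end", "kind", "finger")],
                 calibration_s = calib)
}

#' Serialize fitted model parameters to YAML
#'
#' Writes the parameter values with provenance (model kind, seed/restarts
#' for the MSM optimizer, package version).
#'
#' @param fit An `ff_model_fit` from [fit_msm()] or [fit_lrm()].
#' @param path Output `.yaml` path.
#' @export
write_model_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ff_model_fit"))
  p <- fit$params
  body <- if (fit$kind == "msm")
    list(a = p$a, k0 = p$k0, k1 = p$k1, l0 = p$l0, l1 = p$l1)
  else list(beta = p$beta, residual_sd = p$residual_sd,
            collinear = p$collinear)
  yaml::write_yaml(list(kind = fit$kind, params = body,
                        rmse_train = fit$rmse_train,
                        diagnostics = fit$diagnostics,
                        package_version =
                          as.character(utils::packageVersion("fingerflex"))),
                   path, precision = 15L)
  invisible(path)
}

#' Write an evaluation table
#'
#' @param tab EvalTable from [run_protocol()].
#' @param path Output `.tsv` path.
#' @export
write_eval_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
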