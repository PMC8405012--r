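# Plain-text I/O: RRI files (one ms value per line, '#' comments), ECG CSV
# (time,amplitude), cohort CSV, and a thin command-line front end.

#' Read an RR-interval file
#'
#' One interval in ms per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @param source_id Label (default: the file name).
#' @return An [rri_sequence()].
#' @export
read_rri <- function(path, source_id = basename(path)) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rri_sequence(as.numeric(lines), source_id = source_id)
}

#' Write an RR-interval file
#'
#' @param rri An [rri_sequence()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_rri <- function(rri, path) {
  stopifnot(inherits(rri, "rri_sequence"))
  writeLines(c(sprintf("# RRI sequence %s (ms per line)", rri$source_id),
               format(rri$intervals, trim = TRUE)), path)
  invisible(path)
}

#' Read an ECG CSV (time_s, amplitude)
#'
#' The sampling rate is inferred from the median time step.
#'
#' @param path CSV with columns `time_s` and `amplitude`.
#' @param record_id Label.
#' @return An `"ecg_record"`.
#' @export
read_ecg_csv <- function(path, record_id = basename(path)) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "amplitude") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(samples = d$amplitude, sampling_rate = round(fs),
                 record_id = record_id), class = "ecg_record")
}

#' Write an ECG CSV (time_s, amplitude)
#'
#' @param ecg An `"ecg_record"`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  n <- length(ecg$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / ecg$sampling_rate,
                              amplitude = ecg$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (tachogram / ECG / cohort from a JSON config),
#' `extract` (RRI file to a wide HRV/HRnV feature CSV), `analyze --baseline`
#' (two-group baseline table from a cohort CSV). Invoked by the
#' `inst/exec/hrnv` wrapper; model fitting and ROC evaluation are reachable
#' through the R API ([build_hrnv_model()], [compare_models()]).
#'
#' @param args Character vector of CLI arguments (default: the command line).
#' @return Exit status, invisibly.
#' @export
hrnv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hrnv <simulate|extract|analyze> [options]",
    "  simulate --config cfg.json --out-dir DIR",
    "  extract  --input rri.txt [--nmax 3] [--no-clean] --out features.csv",
    "  analyze  --baseline --input cohort.csv --out table.csv",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    args[i[1] + 1L]
  }
  has <- function(flag) flag %in% args
  cmd <- args[1]
  if (cmd == "simulate") {
    cfg <- jsonlite::read_json(opt("--config"), simplifyVector = TRUE)
    out_dir <- opt("--out-dir", ".")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (identical(cfg$type, "tachogram")) {
      spec <- do.call(tachogram_spec, cfg[setdiff(names(cfg), "type")])
      rri <- generate_rri(spec)
      write_rri(rri, file.path(out_dir, "rri.txt"))
      ecg <- generate_ecg(rri, seed = spec$seed)
      write_ecg_csv(ecg, file.path(out_dir, "ecg.csv"))
    } else if (identical(cfg$type, "cohort")) {
      spec <- do.call(cohort_spec, cfg[setdiff(names(cfg), "type")])
      utils::write.csv(generate_cohort(spec),
                       file.path(out_dir, "cohort.csv"), row.names = FALSE)
    } else stop("config `type` must be 'tachogram' or 'cohort'", call. = FALSE)
    return(invisible(0L))
  }
  if (cmd == "extract") {
    rri <- read_rri(opt("--input"))
    if (!has("--no-clean")) rri <- clean_rri(rri)
    n_max <- as.integer(opt("--nmax", "3"))
    row <- cbind(data.frame(record_id = rri$source_id),
                 hrnv_feature_row(rri, n_max))
    utils::write.csv(row, opt("--out", "features.csv"), row.names = FALSE)
    return(invisible(0L))
  }
  if (cmd == "analyze" && has("--baseline")) {
    cohort <- utils::read.csv(opt("--input"))
    tab <- baseline_table(median_impute(cohort))
    utils::write.csv(tab, opt("--out", "baseline.csv"), row.names = FALSE)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
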