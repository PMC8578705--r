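# Delimited trace files: first column time_s, one column per trace,
# "#"-prefixed metadata lines (annotations, calibration, seed) above the
# header row. Comma separator, "." decimal.

.format_meta_kv <- function(x) {
  paste(sprintf("%s=%s", names(x), vapply(x, format, "")), collapse = " ")
}

.parse_meta_kv <- function(line) {
  body <- sub("^#\\s*\\w+:\\s*", "", line)
  parts <- strsplit(trimws(body), "\\s+")[[1]]
  kv <- strsplit(parts, "=")
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Write fluorescence traces as delimited text
#'
#' Writes one or more traces sharing a common time base: `#` metadata lines
#' (annotations, calibration, optional seed), a header row, then
#' comma-separated columns `time_s`, one per trace.
#'
#' @param traces A [fluorescence_trace()] or a named list of them (shared
#'   times and annotations).
#' @param path Output path.
#' @param seed Optional integer seed to record in the metadata.
#' @param overwrite Allow overwriting an existing file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, seed = NULL, overwrite = FALSE) {
  if (inherits(traces, "fluor_trace")) traces <- list(trace = traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "fluor_trace")))
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; use overwrite = TRUE")
  }
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- paste0("trace", seq_along(traces))
  }
  first <- traces[[1L]]
  meta <- sprintf("# quantalCa traces v%s",
                  as.character(utils::packageVersion("quantalCa")))
  if (length(first$annotations)) {
    meta <- c(meta, paste("# annotations:",
                          .format_meta_kv(first$annotations)))
  }
  if (!is.null(first$calibration)) {
    meta <- c(meta, paste("# calibration:",
                          .format_meta_kv(as.list(first$calibration))))
  }
  if (!is.null(seed)) meta <- c(meta, sprintf("# seed: %d", seed))
  d <- data.frame(time_s = first$times)
  for (nm in names(traces)) d[[nm]] <- traces[[nm]]$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces from delimited text
#'
#' Inverse of [write_traces()]: annotations and calibration are restored
#' from the `#` metadata lines (or may be supplied/overridden here).
#'
#' @param path File path.
#' @param annotations Optional named list overriding file metadata.
#' @param calibration Optional `c(a = , b = )` overriding file metadata.
#' @return A named list of [fluorescence_trace()] objects.
#' @export
read_traces <- function(path, annotations = NULL, calibration = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  d <- utils::read.table(text = lines[!startsWith(lines, "#")],
                         header = TRUE, sep = ",")
  if (!"time_s" %in% names(d) || ncol(d) < 2L) {
    stop("trace file must have a 'time_s' column plus at least one trace ",
         "column")
  }
  if (is.null(annotations)) {
    ml <- grep("^#\\s*annotations:", meta, value = TRUE)
    annotations <- if (length(ml)) {
      as.list(vapply(.parse_meta_kv(ml[1]), as.numeric, 0))
    } else list()
  }
  if (is.null(calibration)) {
    ml <- grep("^#\\s*calibration:", meta, value = TRUE)
    if (length(ml)) {
      calibration <- vapply(.parse_meta_kv(ml[1]), as.numeric, 0)
    }
  }
  out <- lapply(setdiff(names(d), "time_s"), function(nm) {
    fluorescence_trace(d$time_s, d[[nm]], annotations = annotations,
                       calibration = calibration)
  })
  names(out) <- setdiff(names(d), "time_s")
  out
}

#' Write a ground-truth sidecar for a synthetic trace
#'
#' Stores the generating parameters and the true open-receptor and store
#' trajectories alongside a generated dataset, so recovery can be scored.
#'
#' @param trace A trace from [generate_trace()] (carries its ground truth).
#' @param path Output path.
#' @param overwrite Allow overwriting.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(trace, path, overwrite = FALSE) {
  gt <- attr(trace, "ground_truth")
  if (is.null(gt)) stop("trace carries no ground truth")
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; use overwrite = TRUE")
  }
  meta <- c(
    sprintf("# quantalCa ground truth v%s",
            as.character(utils::packageVersion("quantalCa"))),
    sprintf("# template: %s", gt$template_id),
    sprintf("# seed: %d", gt$seed),
    paste("# er_params:", .format_meta_kv(gt$er_params)),
    paste("# rates:", .format_meta_kv(gt$rates)),
    paste("# occupancy:", .format_meta_kv(gt$occupancy)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(gt$truth, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path File path.
#' @return A list with `truth` (data.frame `time_s`, `O4_true`,
#'   `C_ER_true_uM`), `seed`, `template_id`, and the parameter metadata as
#'   named character vectors.
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  truth <- utils::read.table(text = lines[!startsWith(lines, "#")],
                             header = TRUE, sep = ",")
  grab <- function(key) {
    ml <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (!length(ml)) return(NULL)
    .parse_meta_kv(ml[1])
  }
  list(truth = truth,
       seed = as.integer(sub("^#\\s*seed:\\s*", "",
                             grep("^#\\s*seed:", meta, value = TRUE)[1])),
       template_id = sub("^#\\s*template:\\s*", "",
                         grep("^#\\s*template:", meta, value = TRUE)[1]),
       er_params = grab("er_params"), rates = grab("rates"),
       occupancy = grab("occupancy"))
}
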