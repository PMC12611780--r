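#' Construct an annotated time course
#'
#' A single phase of a kinetic assay: sample times, signal, the phase start
#' time `t0`, and assay metadata. The unit of fitting for all exponential
#' models.
#'
#' @param times sample times (s), strictly increasing.
#' @param signal signal values (response units), same length as `times`.
#' @param t0 phase start time (s); defaults to the first sample time.
#' @param assay assay kind label (e.g. `"spr_dissociation"`, `"fp"`,
#'   `"fret"`, `"luminescence"`).
#' @param conc analyte concentration (M) associated with the course.
#' @param cycle optional SPR cycle index.
#' @param phase phase label, `"dissociation"` or `"association"`.
#' @return Object of class `time_course`.
#' @export
time_course <- function(times, signal, t0 = times[1], assay = NA_character_,
                        conc = NA_real_, cycle = NA_integer_,
                        phase = NA_character_) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("times and signal must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, signal = signal, t0 = as.numeric(t0),
                 assay = assay, conc = conc, cycle = cycle, phase = phase),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course: %d points, t in [%g, %g] s, t0 = %g",
              length(x$times), min(x$times), max(x$times), x$t0))
  if (!is.na(x$conc)) cat(sprintf(", conc = %g M", x$conc))
  if (!is.na(x$assay)) cat(sprintf(", assay = %s", x$assay))
  cat("\n")
  invisible(x)
}

# robust noise scale estimate from first differences
.noise_rms <- function(y) stats::sd(diff(y)) / sqrt(2)

#' Write / read a set of time courses as CSV
#'
#' Uses the package's CSV dialect: columns `time_s`, `signal`, `cycle`,
#' `phase`, `conc_M`. One file can hold many courses, distinguished by the
#' `cycle` column (or by `conc_M` when cycles are absent).
#'
#' @param courses a list of [time_course()] objects.
#' @param path CSV file path.
#' @return `write_time_courses_csv` returns `path` invisibly;
#'   `read_time_courses_csv` returns a list of `time_course` objects.
#' @export
write_time_courses_csv <- function(courses, path) {
  if (inherits(courses, "time_course")) courses <- list(courses)
  rows <- lapply(seq_along(courses), function(i) {
    tc <- courses[[i]]
    data.frame(time_s = tc$times, signal = tc$signal,
               cycle = if (is.na(tc$cycle)) i else tc$cycle,
               phase = ifelse(is.na(tc$phase), "dissociation", tc$phase),
               conc_M = tc$conc)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_courses_csv
#' @export
read_time_courses_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "signal", "cycle", "phase", "conc_M")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$cycle), function(d) {
    d <- d[order(d$time_s), ]
    time_course(d$time_s, d$signal, conc = d$conc_M[1],
                cycle = d$cycle[1], phase = d$phase[1])
  })
}
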