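#' Force-extension trace
#'
#' An ordered set of (force, extension) observations from one pull or one
#' relax half-cycle of a force-ramp experiment.
#'
#' @param force force values (pN), within [0, 60].
#' @param extension extension values (nm), same length.
#' @param direction `"stretch"` or `"relax"`.  A stretch trace must be in
#'   non-decreasing force order.
#' @param time optional time stamps (s).
#' @return a `data.frame` of class `fe_trace` with columns `force_pN`,
#'   `extension_nm` and optionally `time_s`, plus a `direction` attribute.
#' @export
fe_trace <- function(force, extension, direction = c("stretch", "relax"),
                     time = NULL) {
  direction <- match.arg(direction)
  if (length(force) != length(extension))
    stop("force and extension must have equal length")
  if (length(force) < 10) stop("a trace needs at least 10 points")
  if (any(!is.finite(force)) || any(force < 0) || any(force > 60))
    stop("forces must lie within [0, 60] pN")
  if (direction == "stretch" && is.unsorted(force))
    stop("a stretch trace must be in non-decreasing force order")
  df <- data.frame(force_pN = force, extension_nm = extension)
  if (!is.null(time)) {
    if (length(time) != length(force)) stop("time length mismatch")
    df$time_s <- time
  }
  structure(df, direction = direction,
            class = c("fe_trace", "data.frame"))
}

#' @export
print.fe_trace <- function(x, ...) {
  cat(sprintf("Force-extension trace (%s): %d points, %.3g-%.3g pN\n",
              attr(x, "direction"), nrow(x),
              min(x$force_pN), max(x$force_pN)))
  invisible(x)
}

#' Read / write force-extension traces as TSV
#'
#' The on-disk format is tab-separated with header columns `time_s`,
#' `force_pN`, `extension_nm`, `direction`; `time_s` may be `NA`.
#'
#' @param path file path.
#' @return `read_fe_trace`: a list of [fe_trace()] objects, one per
#'   direction present in the file (named `stretch` / `relax`).
#' @export
read_fe_trace <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("force_pN", "extension_nm", "direction")
  if (!all(need %in% names(df)))
    stop("trace file must have columns force_pN, extension_nm, direction")
  out <- lapply(split(df, df$direction), function(d) {
    tm <- if ("time_s" %in% names(d) && !all(is.na(d$time_s))) d$time_s
    fe_trace(d$force_pN, d$extension_nm, direction = d$direction[1],
             time = tm)
  })
  out
}

#' @param traces a single [fe_trace()] or a list of them.
#' @rdname read_fe_trace
#' @export
write_fe_trace <- function(traces, path) {
  if (inherits(traces, "fe_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(time_s = if ("time_s" %in% names(tr)) tr$time_s else NA,
               force_pN = tr$force_pN, extension_nm = tr$extension_nm,
               direction = attr(tr, "direction"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Force-jump trace
#'
#' Equal-length temporal records of force and extension sampled at a fixed
#' interval during a force-jump protocol.
#'
#' @param time time stamps (s), strictly increasing.
#' @param force force channel (pN).
#' @param extension extension channel (nm).
#' @param dt sampling interval (s); defaults to the median time step.
#' @return a `data.frame` of class `fj_trace` with a `dt` attribute.
#' @export
fj_trace <- function(time, force, extension, dt = stats::median(diff(time))) {
  n <- length(time)
  if (length(force) != n || length(extension) != n)
    stop("time, force and extension must have equal length")
  if (n < 2 || any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.finite(dt) || dt <= 0) stop("sampling interval must be > 0")
  structure(data.frame(time_s = time, force_pN = force,
                       extension_nm = extension),
            dt = dt, class = c("fj_trace", "data.frame"))
}

#' Read / write force-jump traces as TSV
#'
#' Columns `time_s`, `force_pN`, `extension_nm`.
#' @param path file path.
#' @return `read_fj_trace`: an [fj_trace()].
#' @export
read_fj_trace <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  need <- c("time_s", "force_pN", "extension_nm")
  if (!all(need %in% names(df)))
    stop("jump trace file must have columns time_s, force_pN, extension_nm")
  fj_trace(df$time_s, df$force_pN, df$extension_nm)
}

#' @param trace an [fj_trace()].
#' @rdname read_fj_trace
#' @export
write_fj_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[c("time_s", "force_pN",
                                            "extension_nm")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
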