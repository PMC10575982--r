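#' Write a parameter set to a flat config file
#'
#' Serialises a model object to plain text, one `name = value` per line,
#' with units noted in `#` comments.  All forces are pN, lengths nm,
#' energies pN nm.
#'
#' @param x a [wlc_params()], [spring_params()], [construct_model()] or
#'   [junction_geometry()] object, or a plain named list of numbers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  flat <- flatten_params(x)
  lines <- c("# nanospringr parameter file",
             "# units: force pN, length nm, energy pN nm",
             sprintf("%s = %.*g", names(flat), 15L, unlist(flat)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat config file written by [write_config()]
#'
#' @param path input file path.
#' @return a named list of numeric values.  If the names carry a
#'   `handles.` / `spring.` / `F0` structure, a [construct_model()] is
#'   reassembled instead.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  names(vals) <- trimws(vapply(kv, `[`, character(1), 1L))
  if (anyNA(vals)) stop("non-numeric config value")
  out <- as.list(vals)
  nm <- names(out)
  if (all(c("handles.Lp", "handles.L0", "handles.K0",
            "spring.k", "spring.x0", "F0") %in% nm)) {
    kBT <- if ("handles.kBT" %in% nm) out$handles.kBT else KBT_ROOM
    return(construct_model(
      wlc_params(out$handles.Lp, out$handles.L0, out$handles.K0, kBT),
      spring_params(out$spring.k, out$spring.x0),
      F0 = out$F0))
  }
  out
}

flatten_params <- function(x) {
  if (inherits(x, "construct_model")) {
    h <- unclass(x$handles); s <- unclass(x$spring)
    c(stats::setNames(h, paste0("handles.", names(h))),
      stats::setNames(s, paste0("spring.", names(s))),
      list(F0 = x$F0))
  } else if (inherits(x, c("wlc_params", "spring_params",
                           "junction_geometry"))) {
    unclass(x)
  } else if (is.list(x) && !is.null(names(x))) {
    x
  } else stop("cannot serialise object of class ", class(x)[1])
}
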