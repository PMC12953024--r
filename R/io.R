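#' Write a cell trace as CSV
#'
#' Column units are recorded in a leading comment line
#' (time ms, Vm mV, concentrations mM, currents pA/pF, fluxes mM/ms).
#'
#' @param trace A `cell_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# units: time_ms ms; Vm mV; concentrations mM; currents pA/pF; SR fluxes mM/ms; iso %g uM",
    attr(trace, "iso")), con)
  df <- as.data.frame(lapply(trace, function(col)
    if (is.numeric(col)) sprintf("%.12g", col) else col),
    check.names = FALSE)
  names(df) <- names(trace)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell trace written by [write_cell_trace()]
#'
#' @param path CSV path.
#' @return A `cell_trace` data.frame.
#' @export
read_cell_trace <- function(path) {
  hdr <- readLines(path, n = 1)
  iso <- as.numeric(sub(".*iso ([0-9.eE+-]+) uM.*", "\\1", hdr))
  tr <- read.csv(path, comment.char = "#", check.names = FALSE)
  attr(tr, "iso") <- iso
  class(tr) <- c("cell_trace", "data.frame")
  tr
}

#' Write an adrenergic-stimulation map as CSV
#'
#' One row per element (`element`, `flag`, `iso`), with the generation
#' metadata (density or gradient, seed, grid shape) in comment lines.
#'
#' @param map A `bars_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bars_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("# nx %d ny %d seed %d iso %g density %s delta %s",
                  map$nx, map$ny, map$seed, map$iso,
                  if (is.null(map$density)) "NA" else map$density,
                  if (is.null(map$delta)) "NA" else map$delta)
  writeLines(meta, con)
  df <- data.frame(element = seq_along(map$flag),
                   flag = as.integer(map$flag),
                   iso = ifelse(map$flag, map$iso, 0))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adrenergic-stimulation map written by [write_bars_map()]
#'
#' @param path CSV path.
#' @return A `bars_map`.
#' @export
read_bars_map <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1)), " ")[[1]]
  kv <- setNames(hdr[seq(2, length(hdr), 2)], hdr[seq(1, length(hdr), 2)])
  num <- function(k) suppressWarnings(as.numeric(kv[[k]]))
  df <- read.csv(path, comment.char = "#")
  structure(list(flag = df$flag == 1L, iso = num("iso"),
                 density = if (is.na(num("density"))) NULL else num("density"),
                 seed = as.integer(num("seed")),
                 delta = if (is.na(num("delta"))) NULL else num("delta"),
                 nx = as.integer(num("nx")), ny = as.integer(num("ny"))),
            class = "bars_map")
}

#' Write phase-singularity tracks as CSV
#'
#' @param tracks A `ps_tracks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ps_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track = i, time_ms = tr$time, x_mm = tr$x_mm,
               y_mm = tr$y_mm, chirality = tr$chirality)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
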