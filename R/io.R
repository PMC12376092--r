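## Plain-text spectral file dialects.
##
## 1D dialect: UTF-8 CSV, header `wavenumber_cm-1,value` (IR roles) or
## `wavelength_nm,ellipticity_mdeg` (role = cd), one axis/value pair per row,
## `#`-prefixed comment lines allowed anywhere.
##
## 2D dialect: CSV; cell (1,1) empty or `pump\probe`; first row = probe axis
## (cm^-1); first column = pump axis (cm^-1); body = Delta-OD matrix.

axis_header_for_role <- function(role) {
  if (role == "cd") "wavelength_nm,ellipticity_mdeg" else "wavenumber_cm-1,value"
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

#' Read a one-dimensional spectrum file
#'
#' Parses the two-column CSV dialect (see Details) and returns a validated
#' [axis_spectrum()] sorted by ascending axis.  Files whose header does not
#' carry the unit tag expected for `role` are rejected rather than guessed,
#' and duplicate axis values are an error, not averaged.
#'
#' @details The file must be UTF-8 CSV with header line `wavenumber_cm-1,value`
#' (or `wavelength_nm,ellipticity_mdeg` when `role = "cd"`), one
#' axis-value pair per row.  Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param role Role tag for the returned spectrum (see [axis_spectrum()]).
#' @return An [axis_spectrum()].
#' @export
read_axis_spectrum <- function(path, role = c("linear_od", "transmission",
                                              "pump", "tds", "cd")) {
  role <- match.arg(role)
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop("empty spectrum file: ", path)
  expected <- axis_header_for_role(role)
  header <- gsub("\\s", "", dat$lines[1])
  if (!identical(header, expected))
    stop("line ", dat$lineno[1], " of ", path, ": expected header '",
         expected, "' for role ", role, ", found '", dat$lines[1], "'")
  body <- dat$lines[-1]
  lineno <- dat$lineno[-1]
  if (length(body) < 2L)
    stop(path, ": a spectrum needs at least 2 data rows")
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path,
         ": expected 2 comma-separated fields, found ", length(parts[[bad[1]]]))
  ax <- parse_num(vapply(parts, `[[`, "", 1L))
  vl <- parse_num(vapply(parts, `[[`, "", 2L))
  bad <- which(is.na(ax) | is.na(vl))
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path, ": non-numeric cell in '",
         body[bad[1]], "'")
  o <- order(ax)
  ax <- ax[o]; vl <- vl[o]
  dup <- which(diff(ax) == 0)
  if (length(dup))
    stop(path, ": duplicated axis value ", format(ax[dup[1]]),
         " (duplicate axis points are rejected, not averaged)")
  axis_spectrum(ax, vl, role = role, meta = list(path = path))
}

#' Write a one-dimensional spectrum file
#'
#' Emits exactly the dialect read by [read_axis_spectrum()], at full double
#' precision so that read/write round trips are lossless.
#'
#' @param spectrum An [axis_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_axis_spectrum <- function(spectrum, path) {
  stopifnot_spectrum(spectrum)
  rows <- paste(format_full(spectrum$axis), format_full(spectrum$values),
                sep = ",")
  writeLines(c(axis_header_for_role(spectrum$role), rows), path,
             useBytes = TRUE)
  invisible(path)
}

format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Read a 2D IR spectrum file
#'
#' Parses the matrix CSV dialect: first row the probe axis, first column the
#' pump axis, cell (1,1) empty or `pump\probe`, body the Delta-OD matrix.
#' Axes are sorted ascending (the matrix is reordered consistently).
#'
#' @param path Path to the file.
#' @return A [grid2d_spectrum()].
#' @export
read_grid2d <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L) stop("empty or header-only 2D file: ", path)
  parts <- strsplit(dat$lines, ",", fixed = TRUE)
  hdr <- parts[[1]]
  corner <- gsub("\\s", "", hdr[1])
  if (!(corner == "" || corner == "pump\\probe"))
    stop("line ", dat$lineno[1], " of ", path,
         ": corner cell must be empty or 'pump\\probe', found '", hdr[1], "'")
  probe <- parse_num(hdr[-1])
  if (anyNA(probe))
    stop("line ", dat$lineno[1], " of ", path, ": non-numeric probe axis value")
  width <- length(hdr)
  body <- parts[-1]
  lineno <- dat$lineno[-1]
  bad <- which(lengths(body) != width)
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path, ": row has ",
         length(body[[bad[1]]]), " fields, header has ", width,
         " (ragged rows)")
  cells <- matrix(parse_num(unlist(body)), nrow = length(body), byrow = TRUE)
  if (anyNA(cells)) {
    bad_row <- which(apply(is.na(cells), 1, any))[1]
    stop("line ", lineno[bad_row], " of ", path, ": non-numeric cell")
  }
  grid2d_spectrum(pump_axis = cells[, 1], probe_axis = probe,
                  delta_od = cells[, -1, drop = FALSE],
                  meta = list(path = path))
}

#' Write a 2D IR spectrum file
#'
#' Emits exactly the dialect read by [read_grid2d()], at full double
#' precision.
#'
#' @param spec2d A [grid2d_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid2d <- function(spec2d, path) {
  if (!inherits(spec2d, "grid2d_spectrum"))
    stop("`spec2d` must be a grid2d_spectrum")
  hdr <- paste(c("pump\\probe", format_full(spec2d$probe_axis)),
               collapse = ",")
  rows <- vapply(seq_along(spec2d$pump_axis), function(i) {
    paste(c(format_full(spec2d$pump_axis[i]),
            format_full(spec2d$delta_od[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}
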