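# File dialect: plain CSV with a leading block of `# key=value` metadata
# lines, then exactly one header row, then data rows.  Values are written
# with 17 significant digits so read(write(x)) reproduces every double
# exactly.  No community standard exists for fluorometer exports, so this
# one dialect is used for every object the package reads or writes.

fmt_num <- function(x) sprintf("%.17g", x)

parse_meta_block <- function(lines) {
  meta <- list()
  n <- 0L
  for (i in seq_along(lines)) {
    if (!startsWith(lines[[i]], "#")) break
    n <- i
    body <- sub("^#\\s*", "", lines[[i]])
    if (!grepl("=", body, fixed = TRUE)) {
      stop_format(sprintf("line %d: metadata line is not of the form '# key=value'", i))
    }
    key <- trimws(sub("=.*$", "", body))
    val <- trimws(sub("^[^=]*=", "", body))
    if (!nzchar(key)) stop_format(sprintf("line %d: empty metadata key", i))
    meta[[key]] <- val
  }
  list(meta = meta, n_meta = n)
}

meta_num <- function(meta, key, line_hint, required = FALSE) {
  if (is.null(meta[[key]])) {
    if (required) stop_format(sprintf("missing required metadata '%s'", key))
    return(NULL)
  }
  val <- suppressWarnings(as.numeric(meta[[key]]))
  if (is.na(val)) {
    stop_format(sprintf("metadata '%s' is not numeric: '%s'", key, meta[[key]]))
  }
  val
}

parse_numeric_rows <- function(lines, offset, ncol_expected, what) {
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], ",", fixed = TRUE)[[1]]
    if (length(fields) != ncol_expected) {
      stop_format(sprintf("line %d: expected %d %s fields, found %d",
                          offset + i, ncol_expected, what, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_format(sprintf("line %d: non-numeric value in data row", offset + i))
    }
    vals
  })
  do.call(rbind, rows)
}

#' Read a spectral or titration object from a delimited-text file
#'
#' Reads the package's CSV dialect: a leading block of `# key=value`
#' metadata lines, one header row, then comma-separated numeric data.
#' All type invariants (strictly increasing wavelength axes, matching
#' lengths, non-negative intensities) are enforced; a file violating one
#' is rejected, never silently repaired.
#'
#' @param path Path to the file.
#' @param kind One of `"emission"`, `"absorbance"`, `"titration"`,
#'   `"eem"`, `"synchronous"`.
#' @return The corresponding object ([emission_spectrum()],
#'   [absorbance_spectrum()], [quench_titration()], [eem_matrix()], or a
#'   synchronous scan).
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance", "titration",
                                         "eem", "synchronous")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_format(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pm <- parse_meta_block(lines)
  meta <- pm$meta
  if (!is.null(meta$kind) && !identical(meta$kind, kind)) {
    stop_format(sprintf("file declares kind '%s' but '%s' was requested",
                        meta$kind, kind))
  }
  body <- if (pm$n_meta > 0) lines[-seq_len(pm$n_meta)] else lines
  if (length(body) < 2L) stop_format("file has no data rows")
  header_line <- pm$n_meta + 1L
  header <- trimws(strsplit(body[[1]], ",", fixed = TRUE)[[1]])
  data_lines <- body[-1L]

  expect_header <- function(expected) {
    if (length(header) != length(expected) || !all(header == expected)) {
      stop_format(sprintf("line %d: expected header '%s', found '%s'",
                          header_line, paste(expected, collapse = ","),
                          paste(header, collapse = ",")))
    }
  }

  label <- if (is.null(meta$label)) "" else meta$label

  switch(kind,
    emission = {
      expect_header(c("wavelength", "intensity"))
      m <- parse_numeric_rows(data_lines, header_line, 2L, "emission")
      emission_spectrum(m[, 1], m[, 2],
                        excitation = meta_num(meta, "excitation", required = TRUE),
                        temperature = meta_num(meta, "temperature"),
                        label = label)
    },
    absorbance = {
      expect_header(c("wavelength", "absorbance"))
      m <- parse_numeric_rows(data_lines, header_line, 2L, "absorbance")
      absorbance_spectrum(m[, 1], m[, 2],
                          concentration = meta_num(meta, "concentration", required = TRUE),
                          path_length = meta_num(meta, "path_length", required = TRUE),
                          label = label)
    },
    titration = {
      expect_header(c("concentration", "intensity"))
      m <- parse_numeric_rows(data_lines, header_line, 2L, "titration")
      ref <- meta_num(meta, "ref_wavelength")
      quench_titration(m[, 1], m[, 2],
                       F0 = meta_num(meta, "f0", required = TRUE),
                       temperature = meta_num(meta, "temperature") %||% 298,
                       ref_wavelength = ref %||% NA_real_,
                       label = label)
    },
    eem = {
      if (length(header) < 3L || header[1] != "excitation") {
        stop_format(sprintf(
          "line %d: EEM header must be 'excitation' followed by emission wavelengths",
          header_line))
      }
      emission <- suppressWarnings(as.numeric(header[-1]))
      if (any(is.na(emission))) {
        stop_format(sprintf("line %d: non-numeric emission wavelength in EEM header",
                            header_line))
      }
      m <- parse_numeric_rows(data_lines, header_line, length(header), "EEM")
      eem_matrix(m[, 1], emission, m[, -1, drop = FALSE], label = label)
    },
    synchronous = {
      expect_header(c("excitation", "intensity"))
      m <- parse_numeric_rows(data_lines, header_line, 2L, "synchronous")
      new_synchronous_scan(meta_num(meta, "delta_lambda", required = TRUE),
                           m[, 1], m[, 2])
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectral or titration object to a delimited-text file
#'
#' Serializes to the package's CSV dialect at full double precision, so
#' `read_spectrum(write_spectrum(x, path), kind)` reproduces `x` exactly.
#'
#' @param x An object created by this package's constructors.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @seealso [read_spectrum()]
#' @export
write_spectrum <- function(x, path) UseMethod("write_spectrum")

write_lines_qb <- function(lines, path) {
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_format(sprintf("cannot write to '%s'", path))
  invisible(path)
}

meta_line <- function(key, value) sprintf("# %s=%s", key, value)

#' @export
write_spectrum.emission_spectrum <- function(x, path) {
  lines <- c(meta_line("kind", "emission"),
             meta_line("excitation", fmt_num(x$excitation)))
  if (!is.null(x$temperature)) lines <- c(lines, meta_line("temperature", fmt_num(x$temperature)))
  if (nzchar(x$label)) lines <- c(lines, meta_line("label", x$label))
  lines <- c(lines, "wavelength,intensity",
             paste(fmt_num(x$wavelength), fmt_num(x$intensity), sep = ","))
  write_lines_qb(lines, path)
}

#' @export
write_spectrum.absorbance_spectrum <- function(x, path) {
  lines <- c(meta_line("kind", "absorbance"),
             meta_line("concentration", fmt_num(x$concentration)),
             meta_line("path_length", fmt_num(x$path_length)))
  if (nzchar(x$label)) lines <- c(lines, meta_line("label", x$label))
  lines <- c(lines, "wavelength,absorbance",
             paste(fmt_num(x$wavelength), fmt_num(x$absorbance), sep = ","))
  write_lines_qb(lines, path)
}

#' @export
write_spectrum.quench_titration <- function(x, path) {
  lines <- c(meta_line("kind", "titration"),
             meta_line("f0", fmt_num(x$F0)),
             meta_line("temperature", fmt_num(x$temperature)))
  if (!is.na(x$ref_wavelength)) {
    lines <- c(lines, meta_line("ref_wavelength", fmt_num(x$ref_wavelength)))
  }
  if (nzchar(x$label)) lines <- c(lines, meta_line("label", x$label))
  lines <- c(lines, "concentration,intensity",
             paste(fmt_num(x$concentration), fmt_num(x$intensity), sep = ","))
  write_lines_qb(lines, path)
}

#' @export
write_spectrum.eem_matrix <- function(x, path) {
  lines <- meta_line("kind", "eem")
  if (nzchar(x$label)) lines <- c(lines, meta_line("label", x$label))
  lines <- c(lines,
             paste(c("excitation", fmt_num(x$emission)), collapse = ","),
             vapply(seq_along(x$excitation), function(i) {
               paste(c(fmt_num(x$excitation[i]), fmt_num(x$intensity[i, ])),
                     collapse = ",")
             }, character(1)))
  write_lines_qb(lines, path)
}

#' @export
write_spectrum.synchronous_scan <- function(x, path) {
  lines <- c(meta_line("kind", "synchronous"),
             meta_line("delta_lambda", fmt_num(x$delta_lambda)),
             "excitation,intensity",
             paste(fmt_num(x$excitation), fmt_num(x$intensity), sep = ","))
  write_lines_qb(lines, path)
}
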