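#' Construct a UV-Vis absorbance spectrum
#'
#' A `uv_spectrum` is a tibble with columns `wavelength_nm` and `absorbance`
#' plus cell metadata: the optical path length and the dilution factor applied
#' to the measured solution. Rows are sorted by wavelength on construction and
#' the wavelength grid must be strictly increasing.
#'
#' @param data A data frame with numeric columns `wavelength_nm` (nm) and
#'   `absorbance` (AU), at least two rows.
#' @param path_length Optical path length in cm (default 1, the standard
#'   flow-cell geometry).
#' @param dilution_factor Dilution factor R applied to the sample before
#'   measurement; must be >= 1.
#' @param label Optional free-text label carried through printing.
#' @param components Optional tibble of per-source absorbance columns (one per
#'   analyte plus `byproduct`) summing to `absorbance`; attached by the
#'   synthetic generator so treatment models can act on each source separately.
#'
#' @return A tibble of class `uv_spectrum`.
#' @examples
#' s <- uv_spectrum(data.frame(wavelength_nm = c(266, 284),
#'                             absorbance    = c(0.5, 0.8)))
#' absorbance_at(s, 275)
#' @export
uv_spectrum <- function(data, path_length = 1, dilution_factor = 1,
                        label = NULL, components = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `wavelength_nm` and `absorbance`.")
  }
  missing_cols <- setdiff(c("wavelength_nm", "absorbance"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  wl <- data$wavelength_nm
  ab <- data$absorbance
  if (!is.numeric(wl) || !is.numeric(ab)) {
    abort("`wavelength_nm` and `absorbance` must be numeric.")
  }
  if (length(wl) < 2) abort("A spectrum needs at least 2 samples.")
  if (anyNA(wl) || anyNA(ab)) abort("Spectrum contains missing values.")
  ord <- order(wl)
  wl <- wl[ord]
  ab <- ab[ord]
  if (any(diff(wl) <= 0)) {
    abort("Wavelength grid must be strictly increasing (duplicate wavelengths found).")
  }
  if (!is.numeric(path_length) || length(path_length) != 1 || path_length <= 0) {
    abort("`path_length` must be a single positive number (cm).")
  }
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 ||
      dilution_factor < 1) {
    abort("`dilution_factor` must be a single number >= 1.")
  }
  if (!is.null(components)) {
    components <- as_tibble(components)[ord, , drop = FALSE]
  }
  out <- tibble(wavelength_nm = as.numeric(wl), absorbance = as.numeric(ab))
  structure(out,
            class = c("uv_spectrum", class(out)),
            path_length = as.numeric(path_length),
            dilution_factor = as.numeric(dilution_factor),
            label = label,
            components = components)
}

#' @export
print.uv_spectrum <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<uv_spectrum>",
      if (!is.null(lab)) paste0(" ", lab) else "", "\n", sep = "")
  cat(sprintf("  %d points, %.6g-%.6g nm | path %g cm | dilution x%g\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              path_length(x), dilution_factor(x)))
  print(as_tibble(unclass_spectrum(x)), ...)
  invisible(x)
}

unclass_spectrum <- function(x) {
  attr(x, "path_length") <- NULL
  attr(x, "dilution_factor") <- NULL
  attr(x, "label") <- NULL
  attr(x, "components") <- NULL
  class(x) <- setdiff(class(x), "uv_spectrum")
  x
}

#' Spectrum metadata accessors
#'
#' @param s A [uv_spectrum()].
#' @return `path_length()` the path length in cm; `dilution_factor()` the
#'   dilution factor R; `spectrum_components()` the per-source absorbance
#'   tibble attached by the synthetic generator, or `NULL`.
#' @export
path_length <- function(s) attr(s, "path_length") %||% 1

#' @rdname path_length
#' @export
dilution_factor <- function(s) attr(s, "dilution_factor") %||% 1

#' @rdname path_length
#' @export
spectrum_components <- function(s) attr(s, "components")

#' Read an absorbance spectrum from disk
#'
#' CSV files must carry exactly the header `wavelength_nm,absorbance`
#' (comma-separated, decimal point, UTF-8). A minimal JCAMP-DX reader covers
#' single-block files whose data section is `##XYDATA=(X++(Y..Y))`.
#' Rows are sorted by wavelength on load; no other processing is applied.
#'
#' @param path Path to the file.
#' @param format `"csv"` (default) or `"jcampdx"`.
#' @inheritParams uv_spectrum
#' @return A [uv_spectrum()].
#' @export
read_spectrum <- function(path, format = c("csv", "jcampdx"),
                          path_length = 1, dilution_factor = 1, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- switch(format,
                 csv = read_spectrum_csv(path),
                 jcampdx = read_spectrum_jcampdx(path))
  uv_spectrum(data, path_length = path_length,
              dilution_factor = dilution_factor,
              label = label %||% basename(path))
}

read_spectrum_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "wavelength_nm,absorbance")) {
    abort(paste0("Expected CSV header 'wavelength_nm,absorbance', got '",
                 header, "'."))
  }
  # base strtod parsing is correctly rounded, so shortest-representation
  # output from write_spectrum() round-trips bit-identically
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) abort(paste0("Malformed CSV in ", path, ": ",
                                     conditionMessage(e)))
  )
  parse_col <- function(txt, name) {
    vals <- suppressWarnings(as.numeric(trimws(txt)))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf("Malformed value in %s at line %d: expected a number in `%s`, got '%s'.",
                    path, bad[1] + 1L, name, txt[bad[1]]))
    }
    vals
  }
  tibble(wavelength_nm = parse_col(raw[["wavelength_nm"]], "wavelength_nm"),
         absorbance = parse_col(raw[["absorbance"]], "absorbance"))
}

# Minimal JCAMP-DX: single block, ##XYDATA=(X++(Y..Y)), AFFN numerals only.
read_spectrum_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    pat <- paste0("^##", name, "=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    suppressWarnings(as.numeric(trimws(sub(pat, "", hit[1], ignore.case = TRUE))))
  }
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines, ignore.case = TRUE)
  if (length(start) == 0) {
    abort("JCAMP-DX file lacks an '##XYDATA=(X++(Y..Y))' block (only format supported).")
  }
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end) > 0) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort("JCAMP-DX data block is empty.")
  xfactor <- get_field("XFACTOR"); if (is.na(xfactor)) xfactor <- 1
  yfactor <- get_field("YFACTOR"); if (is.na(yfactor)) yfactor <- 1
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  npoints <- get_field("NPOINTS"); deltax <- get_field("DELTAX")
  tokens <- lapply(body, function(line) {
    toks <- strsplit(trimws(line), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) abort(paste0("Non-numeric token in JCAMP-DX data line: '", line, "'"))
    vals
  })
  if (is.na(deltax)) {
    if (!is.na(firstx) && !is.na(lastx) && !is.na(npoints) && npoints > 1) {
      deltax <- (lastx - firstx) / (npoints - 1)
    } else if (length(tokens) > 1) {
      deltax <- (tokens[[2]][1] - tokens[[1]][1]) / (length(tokens[[1]]) - 1)
    } else {
      abort("Cannot infer DELTAX from JCAMP-DX header.")
    }
  }
  rows <- lapply(tokens, function(vals) {
    x0 <- vals[1] * xfactor
    ys <- vals[-1] * yfactor
    tibble(wavelength_nm = x0 + deltax * xfactor * (seq_along(ys) - 1),
           absorbance = ys)
  })
  dplyr::bind_rows(rows)
}

#' Write a spectrum to CSV
#'
#' Uses the fixed dialect read by [read_spectrum()] (header
#' `wavelength_nm,absorbance`); numbers are written with shortest
#' round-trip precision so read -> write -> read is bit-identical.
#'
#' @param s A [uv_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "uv_spectrum"))
  readr::write_csv(as_tibble(unclass_spectrum(s))[, c("wavelength_nm", "absorbance")],
                   path, progress = FALSE)
  invisible(path)
}

#' Interpolate absorbance at given wavelengths
#'
#' Linear interpolation between the bracketing grid samples; an exact grid hit
#' returns the stored value. Queries outside the measured range are an error —
#' no extrapolation is performed.
#'
#' @param s A [uv_spectrum()].
#' @param wavelength Numeric vector of query wavelengths (nm).
#' @return Numeric vector of absorbances (AU), one per query.
#' @export
absorbance_at <- function(s, wavelength) {
  stopifnot(inherits(s, "uv_spectrum"))
  if (!is.numeric(wavelength) || length(wavelength) == 0) {
    abort("`wavelength` must be a non-empty numeric vector.")
  }
  lo <- min(s$wavelength_nm); hi <- max(s$wavelength_nm)
  out_of_range <- wavelength < lo | wavelength > hi
  if (any(out_of_range)) {
    abort(sprintf("Wavelength %g nm outside measured range [%g, %g] nm; no extrapolation.",
                  wavelength[out_of_range][1], lo, hi))
  }
  stats::approx(s$wavelength_nm, s$absorbance, xout = wavelength,
                method = "linear", ties = "ordered")$y
}
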