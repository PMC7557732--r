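#' Write a spectral series as a wide CSV matrix plus metadata sidecar
#'
#' The main file has a `wavenumber_cm-1` first column and one column per
#' spectrum (named by `spectrum_id`); the sidecar (`<stem>_meta.csv`) holds
#' `spectrum_id, time_s, phase, applied_mass_g`. Intensities are written
#' with full double precision so a round-trip is exact to <= 1e-9 relative.
#'
#' @param series A [spectral_series()].
#' @param path Output CSV path.
#' @param meta_path Sidecar path; default replaces `.csv` with `_meta.csv`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(series, "spectral_series"))
  wide <- data.frame(series$axis, t(series$spectra), check.names = FALSE)
  names(wide) <- c("wavenumber_cm-1", series$info$spectrum_id)
  utils::write.csv(format(wide, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(series$info, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_meta_path <- function(path) {
  sub("\\.csv$", "_meta.csv", path)
}

#' Read a spectral series written by [write_series()]
#'
#' Validates rectangularity up front: a ragged row raises a parse error
#' naming the offending line. If the metadata sidecar is missing, spectra
#' are loaded with `NA` mass labels and `"spray"` phase.
#'
#' @param path Wide CSV path.
#' @param meta_path Sidecar path (default as in [write_series()]).
#' @param metadata Optional metadata list to attach.
#' @return A [spectral_series()].
#' @export
read_series <- function(path, meta_path = default_meta_path(path),
                        metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("parse error in ", path, ": line ", bad, " has ", nf[bad],
         " field(s), expected ", nf[1], call. = FALSE)
  }
  wide <- utils::read.csv(path, check.names = FALSE)
  if (names(wide)[1] != "wavenumber_cm-1") {
    stop("parse error in ", path,
         ": first column must be `wavenumber_cm-1`, found `",
         names(wide)[1], "`", call. = FALSE)
  }
  if (!all(vapply(wide, is.numeric, logical(1)))) {
    bad <- names(wide)[!vapply(wide, is.numeric, logical(1))][1]
    stop("parse error in ", path, ": non-numeric values in column `", bad,
         "`", call. = FALSE)
  }
  axis <- wide[[1]]
  spectra <- t(as.matrix(wide[-1]))
  ids <- names(wide)[-1]
  if (file.exists(meta_path)) {
    info <- tibble::as_tibble(utils::read.csv(meta_path))
    if (!identical(sort(info$spectrum_id), sort(ids))) {
      stop("parse error: sidecar ", meta_path,
           " does not list the same spectrum ids as ", path, call. = FALSE)
    }
    info <- info[match(ids, info$spectrum_id), ]
  } else {
    info <- tibble::tibble(spectrum_id = ids,
                           time_s = seq_along(ids) - 1,
                           phase = "spray",
                           applied_mass_g = NA_real_)
  }
  spectral_series(axis, spectra, info, metadata)
}

#' Export one spectrum of a series as JCAMP-DX
#'
#' Writes a minimal JCAMP-DX 4.24 record (XUNITS=1/CM,
#' YUNITS=ARBITRARY UNITS) with uncompressed `(XY..XY)` data pairs, for
#' interchange with spectroscopy software.
#'
#' @param series A [spectral_series()].
#' @param index Which spectrum to export (default 1).
#' @param path Output `.jdx` path.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(series, index = 1L, path) {
  stopifnot(inherits(series, "spectral_series"))
  y <- series$spectra[index, ]
  x <- series$axis
  info <- series$info[index, ]
  header <- c(
    paste0("##TITLE=", info$spectrum_id, " t=", info$time_s, "s mass=",
           info$applied_mass_g, "g"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    paste0("##FIRSTX=", format(x[1], digits = 15)),
    paste0("##LASTX=", format(x[length(x)], digits = 15)),
    paste0("##NPOINTS=", length(x)),
    "##XYDATA=(XY..XY)")
  body <- paste(format(x, digits = 15, trim = TRUE),
                format(y, digits = 15, trim = TRUE), sep = ", ")
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file written by [write_jcamp()]
#'
#' @param path `.jdx` path.
#' @return List with `axis`, `intensity` and `title`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) {
      stop("parse error in ", path, ": missing ##", key, "= record",
           call. = FALSE)
    }
    sub(paste0("^##", key, "="), "", hit[1])
  }
  if (get_field("XUNITS") != "1/CM") {
    stop("parse error in ", path, ": XUNITS must be 1/CM", call. = FALSE)
  }
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0L) {
    stop("parse error in ", path, ": no ##XYDATA record", call. = FALSE)
  }
  end <- grep("^##END=", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  body <- lines[(start + 1L):(end - 1L)]
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", start + bad[1],
         " is not an `x, y` pair", call. = FALSE)
  }
  m <- vapply(parts, function(p) as.numeric(trimws(p)), numeric(2))
  n <- as.integer(get_field("NPOINTS"))
  if (ncol(m) != n) {
    stop("parse error in ", path, ": NPOINTS=", n, " but ", ncol(m),
         " data pairs found", call. = FALSE)
  }
  list(axis = m[1, ], intensity = m[2, ], title = get_field("TITLE"))
}
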