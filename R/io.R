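# Plain-text columnar formats.  Instrument-native binary formats (FAST,
# JASCO) are proprietary; the exchange format here is 2-column
# tab-separated text with '# key: value' metadata headers, written with
# enough digits to round-trip doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      sprintf("%d", as.integer(min(max(v, -.Machine$integer.max),
                                   .Machine$integer.max)))
    else sprintf("%.17g", v)
  }, character(1))
  out
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

parse_two_columns <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx)) abort_format(sprintf("%s: no data rows", path))
  col1 <- numeric(length(data_idx))
  col2 <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    ln <- data_idx[i]
    parts <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || any(is.na(vals)))
      abort_format(sprintf("%s: line %d is not two numeric columns: '%s'",
                           path, ln, lines[ln]))
    col1[i] <- vals[1]; col2[i] <- vals[2]
  }
  list(meta = meta, x = col1, y = col2, lines = data_idx)
}

#' Read / write TCSPC decay histograms
#'
#' Two tab-separated columns (time in ns, counts) with `# key: value`
#' metadata headers; `wavelength_nm` is recognised specially.  Reading
#' validates grid uniformity and count non-negativity, reporting the
#' offending line number.
#'
#' @param path file path.
#' @return [read_decay_file()]: a [decay_curve()].
#' @export
read_decay_file <- function(path) {
  p <- parse_two_columns(path)
  neg <- which(p$y < 0)
  if (length(neg))
    abort_format(sprintf("%s: negative count on line %d",
                         path, p$lines[neg[1]]))
  if (length(p$x) >= 3) {
    d <- diff(p$x)
    if (max(d) - min(d) > 1e-9 * mean(d))
      abort_format(sprintf("%s: non-uniform time grid near line %d", path,
                           p$lines[which.max(abs(d - mean(d))) + 1]))
  }
  wl <- if (!is.null(p$meta$wavelength_nm))
    as.numeric(p$meta$wavelength_nm) else NA_real_
  meta <- p$meta[setdiff(names(p$meta),
                         c("wavelength_nm", "columns", "stackprobe_decay"))]
  decay_curve(p$x, p$y, wavelength = wl, metadata = meta)
}

#' @rdname read_decay_file
#' @param curve a [decay_curve()].
#' @export
write_decay_file <- function(curve, path) {
  hdr <- c("# stackprobe_decay: v1",
           if (is.finite(curve$wavelength))
             sprintf("# wavelength_nm: %s", fmt_num(curve$wavelength)),
           vapply(names(curve$metadata), function(k)
             sprintf("# %s: %s", k, as.character(curve$metadata[[k]])),
             character(1)),
           "# columns: time_ns counts")
  rows <- paste(fmt_num(curve$times), fmt_num(curve$counts), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write CD spectra
#'
#' Two tab-separated columns (wavelength in nm, signal) with a mandatory
#' `# units: mdeg|delta_epsilon` header.  The 0.5 nm grid convention is
#' enforced unless `spacing = NULL`.
#'
#' @param path file path.
#' @param spacing expected spacing in nm (`NULL` to accept any uniform
#'   grid).
#' @return [read_cd_file()]: a [cd_spectrum()].
#' @export
read_cd_file <- function(path, spacing = 0.5) {
  p <- parse_two_columns(path)
  if (is.null(p$meta$units))
    abort_format(sprintf("%s: missing '# units:' header", path))
  if (!p$meta$units %in% c("mdeg", "delta_epsilon"))
    abort_format(sprintf("%s: unknown units '%s'", path, p$meta$units))
  n_scans <- if (!is.null(p$meta$n_scans)) as.integer(p$meta$n_scans) else 1L
  meta <- p$meta[setdiff(names(p$meta),
                         c("units", "n_scans", "columns", "stackprobe_cd"))]
  cd_spectrum(p$x, p$y, units = p$meta$units, n_scans = n_scans,
              metadata = meta, spacing = spacing)
}

#' @rdname read_cd_file
#' @param spectrum a [cd_spectrum()].
#' @export
write_cd_file <- function(spectrum, path) {
  hdr <- c("# stackprobe_cd: v1",
           sprintf("# units: %s", spectrum$units),
           sprintf("# n_scans: %d", spectrum$n_scans),
           vapply(names(spectrum$metadata), function(k)
             sprintf("# %s: %s", k, as.character(spectrum$metadata[[k]])),
             character(1)),
           "# columns: wavelength_nm value")
  rows <- paste(fmt_num(spectrum$wavelengths), fmt_num(spectrum$values),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# TSV writer with deterministic numeric formatting (no scientific-digit
# drift between runs).
write_tsv_table <- function(df, path) {
  df2 <- df
  for (k in names(df2))
    if (is.numeric(df2[[k]])) df2[[k]] <- vapply(df2[[k]], function(v)
      if (is.na(v)) "NA" else sprintf("%.10g", v), character(1))
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
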