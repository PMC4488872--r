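#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix in log(1/T) units with its
#' wavelength grid (nm) and per-sample metadata. The grid must be strictly
#' increasing with constant spacing; every absorbance value must be finite.
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector of wavelengths in nm, one per column.
#' @param meta optional `data.frame` of per-sample metadata. Recognised
#'   columns: `sample_id`, `class_label`, `dna_conc` (uM), `uvc_dose`
#'   (kJ/m2), `tt_conc` (uM), `batch`. Missing `sample_id`s are generated.
#' @return an object of class `spectra_set` with elements `absorbance`,
#'   `wavelengths` and `meta`.
#' @export
spectra_set <- function(absorbance, wavelengths, meta = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  validate_wavelength_grid(wavelengths)
  if (ncol(absorbance) != length(wavelengths))
    .stop2("aquaphot_shape_error",
           "absorbance has %d columns but grid has %d wavelengths",
           ncol(absorbance), length(wavelengths))
  if (nrow(absorbance) > 0 && any(!is.finite(absorbance)))
    .stop2("aquaphot_value_error", "non-finite absorbance values present")
  n <- nrow(absorbance)
  if (is.null(meta)) meta <- data.frame(sample_id = character(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    .stop2("aquaphot_shape_error",
           "metadata has %d rows but absorbance has %d samples", nrow(meta), n)
  if (is.null(meta$sample_id) || all(meta$sample_id == ""))
    meta$sample_id <- if (n > 0) sprintf("S%03d", seq_len(n)) else character(0)
  if (anyDuplicated(meta$sample_id))
    .stop2("aquaphot_value_error", "sample_id values must be unique")
  for (col in intersect(.META_NUMERIC, names(meta))) {
    meta[[col]] <- as.numeric(meta[[col]])
    bad <- !is.na(meta[[col]]) & meta[[col]] < 0
    if (any(bad))
      .stop2("aquaphot_value_error", "metadata column '%s' has negative values", col)
  }
  dimnames(absorbance) <- NULL
  structure(list(absorbance = absorbance, wavelengths = wavelengths,
                 meta = meta),
            class = "spectra_set")
}

# strictly increasing, positive, constant spacing within 1e-9 nm
validate_wavelength_grid <- function(w) {
  if (length(w) == 0 || any(!is.finite(w)) || any(w <= 0))
    .stop2("aquaphot_grid_error", "wavelengths must be finite and positive")
  if (length(w) > 1) {
    d <- diff(w)
    if (any(d <= 0))
      .stop2("aquaphot_grid_error", "wavelength grid must be strictly increasing")
    if (max(d) - min(d) > 1e-9)
      .stop2("aquaphot_grid_error",
             "wavelength grid spacing is irregular (range of steps %.3g nm)",
             max(d) - min(d))
  }
  invisible(w)
}

#' Wavelength step of a spectra set
#' @param set a `spectra_set`.
#' @return step in nm (NA for a single-wavelength grid).
#' @export
grid_step <- function(set) {
  w <- set$wavelengths
  if (length(w) < 2) return(NA_real_)
  (w[length(w)] - w[1]) / (length(w) - 1)
}

#' @export
print.spectra_set <- function(x, ...) {
  w <- x$wavelengths
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm, step %.3g nm)\n",
              nrow(x$absorbance), length(w),
              if (length(w)) w[1] else NA, if (length(w)) w[length(w)] else NA,
              grid_step(x)))
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

.detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a delimited spectra table
#'
#' Reads a plain delimited text file (comma default, tab accepted) holding a
#' sample x wavelength absorbance table. With `samples_as_rows` the header
#' row holds metadata column names followed by wavelengths in nm; with
#' `samples_as_columns` the layout is transposed (first column holds the
#' names/wavelengths). Metadata fields absent from the file are left unset.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"samples_as_columns"`.
#' @return a validated [spectra_set()].
#' @export
read_spectra_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "samples_as_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    .stop2("aquaphot_io_error", "file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0)
    .stop2("aquaphot_parse_error", "empty file: %s", path)
  sep <- .detect_sep(lines[1])
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncells <- lengths(cells)
  if (length(unique(ncells)) != 1)
    .stop2("aquaphot_parse_error", "ragged rows in %s (widths %s)",
           path, paste(unique(ncells), collapse = "/"))
  m <- do.call(rbind, cells)
  if (orientation == "samples_as_columns") m <- t(m)
  header <- m[1, ]
  body <- m[-1, , drop = FALSE]
  is_meta <- header %in% .META_COLUMNS
  wl <- suppressWarnings(as.numeric(header[!is_meta]))
  if (any(is.na(wl)))
    .stop2("aquaphot_parse_error", "non-numeric wavelength header entries: %s",
           paste(utils::head(header[!is_meta][is.na(wl)], 3), collapse = ", "))
  validate_wavelength_grid(wl)
  spec_cols <- which(!is_meta)
  abs_chr <- body[, spec_cols, drop = FALSE]
  abs_num <- suppressWarnings(matrix(as.numeric(abs_chr), nrow = nrow(abs_chr),
                                     ncol = ncol(abs_chr)))
  if (length(abs_num) && any(is.na(abs_num))) {
    bad <- which(is.na(abs_num), arr.ind = TRUE)[1, ]
    .stop2("aquaphot_parse_error",
           "non-numeric absorbance value '%s' at sample row %d, wavelength %g nm",
           abs_chr[bad[1], bad[2]], bad[1], wl[bad[2]])
  }
  meta <- NULL
  if (any(is_meta)) {
    meta <- as.data.frame(body[, is_meta, drop = FALSE],
                          stringsAsFactors = FALSE)
    names(meta) <- header[is_meta]
    for (col in intersect(.META_NUMERIC, names(meta))) {
      v <- meta[[col]]
      v[v == ""] <- NA_character_
      meta[[col]] <- as.numeric(v)
    }
  }
  spectra_set(abs_num, wl, meta)
}

#' Write a spectra table
#'
#' Emits the delimited dialect accepted by [read_spectra_table()] at full
#' floating precision (17 significant digits), samples as rows.
#'
#' @param set a `spectra_set`.
#' @param path destination path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return invisibly, `path`.
#' @export
write_spectra_table <- function(set, path, sep = ",") {
  stopifnot(inherits(set, "spectra_set"))
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  }
  meta_cols <- intersect(.META_COLUMNS, names(set$meta))
  header <- c(meta_cols, sprintf("%.17g", set$wavelengths))
  rows <- character(nrow(set$absorbance))
  for (i in seq_len(nrow(set$absorbance))) {
    mvals <- vapply(meta_cols, function(col) {
      v <- set$meta[[col]][i]
      if (is.numeric(v)) fmt(v) else if (is.na(v)) "" else as.character(v)
    }, character(1))
    rows[i] <- paste(c(mvals, fmt(set$absorbance[i, ])), collapse = sep)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) .stop2("aquaphot_io_error",
                                             "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(c(paste(header, collapse = sep), rows), con)
  invisible(path)
}

#' Subset a spectra set to a wavelength window
#'
#' Keeps the columns with `lo <= lambda <= hi` (closed interval; on-grid
#' endpoints are included). Metadata is unchanged.
#'
#' @param set a `spectra_set`.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return a `spectra_set` restricted to the window.
#' @export
select_wavelength_range <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectra_set"))
  if (!(lo < hi))
    .stop2("aquaphot_range_error", "need lo < hi (got %g, %g)", lo, hi)
  keep <- which(set$wavelengths >= lo - 1e-9 & set$wavelengths <= hi + 1e-9)
  if (length(keep) == 0)
    .stop2("aquaphot_range_error",
           "range [%g, %g] nm does not intersect the grid (%g-%g nm)",
           lo, hi, min(set$wavelengths), max(set$wavelengths))
  spectra_set(set$absorbance[, keep, drop = FALSE], set$wavelengths[keep],
              set$meta)
}
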