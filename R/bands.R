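#' Water absorbance band table (C1-C12, W1-W3)
#'
#' The curated table of water absorbance bands in the first overtone
#' region used to interpret regression vectors and discriminating power:
#' twelve C bands spanning 1336-1516 nm (including the water species
#' S0-S4, i.e. water molecules with 0-4 hydrogen bonds) and three further
#' W bands. Band intervals are closed and may overlap (C1/W1; C10 and C11
#' share the 1482 nm boundary), so a peak can belong to several bands.
#'
#' @return a `data.frame` of class `band_table` with columns `name`,
#'   `lo` (nm), `hi` (nm), `assignment`.
#' @export
default_band_table <- function() {
  tab <- data.frame(
    name = c(paste0("C", 1:12), paste0("W", 1:3)),
    lo = c(1336, 1360, 1370, 1380, 1398, 1421, 1432, 1448, 1458, 1472,
           1482, 1506, 1342, 1536, 1565),
    hi = c(1348, 1366, 1376, 1388, 1418, 1430, 1444, 1454, 1468, 1482,
           1495, 1516, 1360, 1546, 1586),
    assignment = c(
      "nu3, H2O asymmetric stretching vibration",
      "water solvation shell, OH-(H2O)1,2,4",
      "nu1 + nu3, symmetrical stretching fundamental vibration and H2O asymmetric stretching vibration",
      "water solvation shell, OH-(H2O)1,4 and superoxide, O2-(H2O)4",
      "S0, free water and free OH-",
      "H-OH bend and O...O",
      "S1",
      "water solvation shell, OH-(H2O)4,5",
      "S2",
      "S3",
      "S4",
      "nu1, nu2, symmetrical stretching fundamental vibration, and doubly degenerate bending fundamental",
      "H15O7, H13O6, H11O5 + free OH stretch",
      "H2O intermolecular bend angling",
      "H15O7 + H-bonded OH stretch"),
    stringsAsFactors = FALSE)
  class(tab) <- c("band_table", "data.frame")
  tab
}

.validate_band_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "lo", "hi", "assignment") %in% names(tab)))
  if (anyDuplicated(tab$name))
    .stop2("aquaphot_value_error", "band names must be unique")
  if (any(tab$lo >= tab$hi))
    .stop2("aquaphot_value_error", "band intervals need lo < hi")
  tab
}

#' Band midpoints
#' @param tab a band table (default [default_band_table()]).
#' @return named numeric vector of interval midpoints in nm.
#' @export
band_midpoints <- function(tab = default_band_table()) {
  stats::setNames((tab$lo + tab$hi) / 2, tab$name)
}

#' Read / write a band table as 4-column delimited text
#'
#' Columns `name, lo_nm, hi_nm, assignment`, comma separated (tab
#' accepted on read).
#'
#' @param path file path.
#' @return `read_band_table` returns a validated `band_table`.
#' @export
read_band_table <- function(path) {
  lines <- readLines(path)
  sep <- .detect_sep(lines[1])
  cells <- strsplit(lines[-1], sep, fixed = TRUE)
  tab <- data.frame(
    name = vapply(cells, `[`, "", 1),
    lo = as.numeric(vapply(cells, `[`, "", 2)),
    hi = as.numeric(vapply(cells, `[`, "", 3)),
    assignment = vapply(cells, function(x) paste(x[-(1:3)], collapse = sep), ""),
    stringsAsFactors = FALSE)
  class(tab) <- c("band_table", "data.frame")
  .validate_band_table(tab)
}

#' @rdname read_band_table
#' @param tab a band table.
#' @export
write_band_table <- function(tab, path) {
  .validate_band_table(tab)
  lines <- c("name,lo_nm,hi_nm,assignment",
             sprintf("%s,%g,%g,%s", tab$name, tab$lo, tab$hi, tab$assignment))
  writeLines(lines, path)
  invisible(path)
}

# topographic prominence of a local maximum at index i of signal s:
# height above the higher of the two key cols (minima between the peak
# and the nearest higher terrain, or the signal ends)
.prominence <- function(s, i) {
  left_min <- s[i]
  j <- i - 1
  while (j >= 1 && s[j] <= s[i]) {
    left_min <- min(left_min, s[j])
    j <- j - 1
  }
  right_min <- s[i]
  j <- i + 1
  while (j <= length(s) && s[j] <= s[i]) {
    right_min <- min(right_min, s[j])
    j <- j + 1
  }
  s[i] - max(left_min, right_min)
}

.local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  idx
}

#' Detect signed peaks in a per-wavelength vector
#'
#' Finds local extrema of a signed vector (a regression vector or a
#' discriminating-power trace): maxima of the values and of their
#' negation. Each extremum's topographic prominence is computed and
#' extrema with prominence below `min_prominence * max(abs(values))` are
#' dropped. An optional moving-average pre-smoothing can be applied.
#'
#' @param values numeric vector, one value per wavelength.
#' @param wavelengths matching wavelength grid in nm.
#' @param min_prominence prominence threshold as a fraction of the largest
#'   absolute value, in (0, 1] (default 0.1).
#' @param smoothing_window optional odd window for moving-average
#'   pre-smoothing.
#' @return a `data.frame` with columns `wavelength`, `amplitude` (signed
#'   value at the peak), `prominence`, `sign` (`"positive"`/`"negative"`),
#'   sorted by wavelength. Constant input yields zero rows.
#' @export
detect_peaks <- function(values, wavelengths, min_prominence = 0.1,
                         smoothing_window = NULL) {
  if (length(values) != length(wavelengths))
    .stop2("aquaphot_shape_error", "values and wavelengths differ in length")
  if (min_prominence <= 0 || min_prominence > 1)
    .stop2("aquaphot_parameter_error", "min_prominence must be in (0, 1]")
  v <- as.numeric(values)
  if (!is.null(smoothing_window)) {
    kern <- smoothing_kernel(smoothing_window, "moving_average")
    v <- .smooth_row(v, kern)
  }
  vmax <- max(abs(v))
  empty <- data.frame(wavelength = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (vmax < 1e-300) return(empty)
  rows <- list()
  for (direction in c(1, -1)) {
    s <- direction * v
    for (i in .local_maxima(s)) {
      prom <- .prominence(s, i)
      if (prom >= min_prominence * vmax) {
        rows[[length(rows) + 1]] <- data.frame(
          wavelength = wavelengths[i], amplitude = v[i], prominence = prom,
          sign = if (direction > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$wavelength), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate peaks with water bands
#'
#' Maps each detected peak to every band whose closed interval contains
#' its wavelength. Because bands overlap, a peak can carry several band
#' names; a peak outside all bands gets an empty list.
#'
#' @param peaks a `data.frame` from [detect_peaks()] (needs a `wavelength`
#'   column).
#' @param band_table a band table (default [default_band_table()]).
#' @return the `peaks` data frame with a list column `bands` of band-name
#'   character vectors.
#' @export
annotate_peaks <- function(peaks, band_table = default_band_table()) {
  .validate_band_table(band_table)
  peaks$bands <- lapply(peaks$wavelength, function(wl) {
    band_table$name[band_table$lo - 1e-9 <= wl & wl <= band_table$hi + 1e-9]
  })
  peaks
}
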