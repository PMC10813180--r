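CLASS_LEVELS <- c("FM", "NONFM", "NC", "UNKNOWN")

#' Single Raman/SERS spectrum
#'
#' Constructs a single spectrum: an intensity trace on a strictly increasing
#' wavenumber axis (cm^-1), with sample metadata.
#'
#' @param wavenumber numeric vector of positions in cm^-1, strictly increasing,
#'   length >= 3.
#' @param intensity numeric vector of intensities (arbitrary units), finite,
#'   same length as `wavenumber`.
#' @param sample_id sample identifier string.
#' @param replicate non-negative integer replicate index (0 = averaged/unique).
#' @param label class label, one of `"FM"`, `"NONFM"`, `"NC"`, `"UNKNOWN"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumber, intensity, sample_id = "", replicate = 0L,
                     label = "UNKNOWN") {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) < 3L)
    stop("a spectrum needs at least 3 points")
  if (length(intensity) != length(wavenumber))
    stop("wavenumber and intensity lengths differ")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  label <- match.arg(label, CLASS_LEVELS)
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate = as.integer(replicate), label = label),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s (rep %d, %s): %d points, %.0f-%.0f cm-1\n",
              x$sample_id, x$replicate, x$label, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Aligned set of spectra
#'
#' A cohort of spectra sharing one wavenumber grid: an n_samples x n_points
#' intensity matrix plus per-row metadata (sample id, replicate index, class
#' label).
#'
#' @param grid shared wavenumber axis (strictly increasing).
#' @param X numeric matrix, one row per spectrum, `length(grid)` columns.
#' @param sample_id character vector, one per row.
#' @param replicate integer vector, one per row.
#' @param label character vector of class labels, one per row.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(grid, X, sample_id = NULL, replicate = NULL,
                        label = NULL) {
  grid <- as.numeric(grid)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (ncol(X) != length(grid)) stop("ncol(X) must equal length(grid)")
  if (!all(is.finite(X))) stop("intensities must be finite")
  n <- nrow(X)
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(0L, n)
  if (is.null(label)) label <- rep("UNKNOWN", n)
  if (length(sample_id) != n || length(replicate) != n || length(label) != n)
    stop("metadata length must match number of rows")
  if (!all(label %in% CLASS_LEVELS))
    stop("labels must be one of: ", paste(CLASS_LEVELS, collapse = ", "))
  colnames(X) <- format(grid, trim = TRUE)
  structure(
    list(grid = grid, X = X, sample_id = as.character(sample_id),
         replicate = as.integer(replicate), label = as.character(label)),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = CLASS_LEVELS))
  cat(sprintf("<spectra_set> %d spectra x %d points (%.0f-%.0f cm-1)\n",
              nrow(x$X), length(x$grid), min(x$grid), max(x$grid)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$grid, x$X[i, , drop = FALSE], x$sample_id[i],
              x$replicate[i], x$label[i])
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$X

#' Extract one spectrum from a set
#' @param set a `spectra_set`.
#' @param i row index.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"), length(i) == 1L)
  spectrum(set$grid, set$X[i, ], set$sample_id[i], set$replicate[i],
           set$label[i])
}

#' Number of spectra in a set
#' @param set a `spectra_set`.
#' @export
n_spectra <- function(set) nrow(set$X)

parse_colname_meta <- function(nm) {
  # column-name convention "<id>_<replicate>_<label>"; anything else becomes
  # (name, 0, UNKNOWN)
  parts <- strsplit(nm, "_", fixed = TRUE)
  out <- lapply(seq_along(nm), function(i) {
    p <- parts[[i]]
    if (length(p) >= 3L && p[length(p)] %in% CLASS_LEVELS &&
        !is.na(suppressWarnings(as.integer(p[length(p) - 1L])))) {
      list(id = paste(p[seq_len(length(p) - 2L)], collapse = "_"),
           rep = as.integer(p[length(p) - 1L]), lab = p[length(p)])
    } else {
      list(id = nm[i], rep = 0L, lab = "UNKNOWN")
    }
  })
  list(sample_id = vapply(out, `[[`, "", "id"),
       replicate = vapply(out, `[[`, 0L, "rep"),
       label = vapply(out, `[[`, "", "lab"))
}

#' Read spectra from CSV or JCAMP-DX
#'
#' CSV is a wide table: first column the wavenumber axis, one column per
#' spectrum. Per-spectrum metadata comes from a sidecar CSV with columns
#' `sample_id`, `replicate`, `label` (one row per spectrum column, in file
#' order), or, as a fallback, from column names following the
#' `"<id>_<replicate>_<label>"` convention. JCAMP-DX files (single block,
#' AFFN-encoded `(X++(Y..Y))` or `(XY..XY)` data, with `XFACTOR`/`YFACTOR`
#' scaling) yield one spectrum.
#'
#' @param path file path.
#' @param format `"csv"` or `"jcamp"`.
#' @param metadata optional path of the sidecar metadata CSV (csv format only).
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, format = c("csv", "jcamp"), metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_spectra_csv(path, metadata) else read_jcamp(path)
}

read_spectra_csv <- function(path, metadata = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L) stop("wide-table CSV needs a wavenumber column plus at least one spectrum")
  if (anyNA(d)) stop("ragged or non-numeric columns in ", path)
  grid <- as.numeric(d[[1L]])
  if (any(diff(grid) <= 0))
    stop("non-monotone wavenumber axis in ", path)
  X <- t(as.matrix(d[, -1L, drop = FALSE]))
  if (!is.null(metadata)) {
    md <- utils::read.csv(metadata, stringsAsFactors = FALSE)
    need <- c("sample_id", "replicate", "label")
    if (!all(need %in% names(md)))
      stop("metadata CSV must have columns: ", paste(need, collapse = ", "))
    if (nrow(md) != nrow(X))
      stop("metadata rows (", nrow(md), ") do not match spectra (", nrow(X), ")")
    spectra_set(grid, X, md$sample_id, md$replicate, md$label)
  } else {
    m <- parse_colname_meta(rownames(X))
    spectra_set(grid, X, m$sample_id, m$replicate, m$label)
  }
}

#' Write spectra to a wide-table CSV (plus metadata sidecar)
#'
#' Values are written at full double precision so that write/read round-trips
#' are exact.
#'
#' @param set a `spectra_set`.
#' @param path output CSV path.
#' @param metadata optional path for the sidecar metadata CSV.
#' @export
write_spectra <- function(set, path, metadata = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  cols <- apply(set$X, 1L, function(y) sprintf("%.17g", y))
  hdr <- sprintf("%s_%d_%s", set$sample_id, set$replicate, set$label)
  tab <- cbind(sprintf("%.17g", set$grid), cols)
  colnames(tab) <- c("wavenumber", hdr)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    utils::write.csv(
      data.frame(sample_id = set$sample_id, replicate = set$replicate,
                 label = set$label),
      metadata, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)           # strip comments
  ldr <- grepl("^##", lines)
  get_field <- function(key, default = NA_character_) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  num_field <- function(key, default = NA_real_) {
    v <- get_field(key)
    if (is.na(v)) default else as.numeric(v)
  }
  xf <- num_field("XFACTOR", 1)
  yf <- num_field("YFACTOR", 1)
  title <- get_field("TITLE", "jcamp")
  start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no XYDATA/XYPOINTS block in ", path)
  start <- start[1L]
  form <- toupper(get_field("XYDATA", get_field("XYPOINTS", "")))
  stop_at <- which(ldr & seq_along(lines) > start)
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[(start + 1L):end]
  body <- body[nzchar(trimws(body))]
  toks <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), as.numeric)
  if (any(vapply(toks, anyNA, TRUE)))
    stop("non-AFFN (compressed) JCAMP data not supported in ", path)
  if (grepl("XY\\.\\.XY", form) || grepl("XYPOINTS", toupper(lines[start]))) {
    v <- unlist(toks)
    x <- v[seq(1L, length(v), 2L)] * xf
    y <- v[seq(2L, length(v), 2L)] * yf
  } else {
    # (X++(Y..Y)): each line starts with an X value followed by Y values
    npt <- num_field("NPOINTS")
    firstx <- num_field("FIRSTX")
    lastx <- num_field("LASTX")
    y <- unlist(lapply(toks, function(v) v[-1L])) * yf
    if (!is.na(npt) && length(y) != npt)
      stop("NPOINTS mismatch in ", path)
    if (is.na(firstx) || is.na(lastx)) {
      # fall back to per-line X with uniform spacing within lines
      stop("FIRSTX/LASTX required for (X++(Y..Y)) data in ", path)
    }
    x <- seq(firstx, lastx, length.out = length(y)) * xf
  }
  if (any(diff(x) < 0)) { x <- rev(x); y <- rev(y) }
  if (any(diff(x) <= 0)) stop("non-monotone axis in ", path)
  spectra_set(x, matrix(y, nrow = 1L), sample_id = title)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto `grid`; the grid must lie within the spectrum's
#' support (no extrapolation). Grid points that coincide with input points are
#' reproduced exactly.
#'
#' @param s a `spectrum`.
#' @param grid target wavenumber axis.
#' @return A `spectrum` on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavenumber) || max(grid) > max(s$wavenumber))
    stop("resampling grid extends beyond the spectrum's support (extrapolation refused)")
  y <- stats::approx(s$wavenumber, s$intensity, xout = grid, method = "linear",
                     ties = "ordered")$y
  spectrum(grid, y, s$sample_id, s$replicate, s$label)
}

#' Resample every spectrum of a set onto a new grid
#' @param set a `spectra_set`.
#' @param grid target axis.
#' @return A `spectra_set` on `grid`.
#' @export
resample_set <- function(set, grid) {
  stopifnot(inherits(set, "spectra_set"))
  grid <- as.numeric(grid)
  if (min(grid) < min(set$grid) || max(grid) > max(set$grid))
    stop("resampling grid extends beyond the spectra's support (extrapolation refused)")
  X <- t(apply(set$X, 1L, function(y)
    stats::approx(set$grid, y, xout = grid, ties = "ordered")$y))
  spectra_set(grid, X, set$sample_id, set$replicate, set$label)
}

#' Average replicate spectra per sample
#'
#' Collapses all rows sharing a `sample_id` to their pointwise arithmetic
#' mean, the per-sample spectrum used for modelling. Labels must agree within
#' a sample.
#'
#' @param set a `spectra_set` with replicate rows.
#' @return A `spectra_set` with one row per sample (replicate index 0).
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$sample_id)
  X <- matrix(0, length(ids), length(set$grid))
  lab <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- which(set$sample_id == ids[k])
    labs <- unique(set$label[rows])
    if (length(labs) != 1L)
      stop("conflicting labels within sample ", ids[k], ": ",
           paste(labs, collapse = ", "))
    lab[k] <- labs
    X[k, ] <- colMeans(set$X[rows, , drop = FALSE])
  }
  spectra_set(set$grid, X, ids, rep(0L, length(ids)), lab)
}
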