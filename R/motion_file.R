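#' Write a motion file (.mot/.sto dialect)
#'
#' Plain-text motion file: a key=value header (version, nRows, nColumns,
#' inDegrees) terminated by `endheader`, then a tab-separated block with a
#' `time` column followed by one column per dof. Values are printed with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param time numeric vector of times (s), strictly increasing.
#' @param angles matrix of joint angles, columns named by dof (degrees when
#'   `in_degrees`, radians otherwise).
#' @param path output file path.
#' @param in_degrees logical; recorded in the header. When FALSE the values
#'   are written in radians.
#' @param name dataset name written on the first header line.
#' @return `path`, invisibly.
#' @export
write_motion_file <- function(time, angles, path, in_degrees = TRUE,
                              name = "motion") {
  A <- as.matrix(angles)
  stopifnot(length(time) == nrow(A), !is.null(colnames(A)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(name,
               "version=1",
               sprintf("nRows=%d", nrow(A)),
               sprintf("nColumns=%d", ncol(A) + 1L),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(c("time", colnames(A)), collapse = "\t")), con)
  block <- cbind(time, A)
  writeLines(apply(block, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a motion file (.mot/.sto dialect)
#'
#' Validates the header keys and the row/column counts. Angle columns of
#' radian-mode files (`inDegrees=no`) are converted to degrees on read.
#'
#' @param path motion file path.
#' @return list with `time` (s), `angles` (matrix, degrees), `in_degrees`
#'   (the file's native unit flag) and `name`.
#' @export
read_motion_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed motion file: ", path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stop("motion file missing 'endheader': ", path)
  hdr <- lines[seq_len(end - 1)]
  kv <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- sub("=.*", "", kv); vals <- sub("^[^=]*=", "", kv)
  h <- stats::setNames(trimws(vals), trimws(keys))
  for (need in c("nRows", "nColumns", "inDegrees"))
    if (!(need %in% names(h))) stop("motion file header missing ", need)
  n_rows <- as.integer(h[["nRows"]]); n_cols <- as.integer(h[["nColumns"]])
  in_degrees <- tolower(h[["inDegrees"]]) %in% c("yes", "true")
  cols <- strsplit(trimws(lines[end + 1]), "\t", fixed = TRUE)[[1]]
  if (cols[1] != "time") stop("first data column must be 'time'")
  if (length(cols) != n_cols)
    stop(sprintf("nColumns=%d but %d column names found", n_cols, length(cols)))
  body <- lines[seq(end + 2, length.out = length(lines) - end - 1)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows)
    stop(sprintf("nRows=%d but %d data rows found", n_rows, length(body)))
  mat <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]]))
    if (length(v) != n_cols || anyNA(v))
      stop(sprintf("malformed data row %d of %s", i, path))
    v
  }))
  angles <- mat[, -1, drop = FALSE]
  colnames(angles) <- cols[-1]
  if (!in_degrees) angles <- angles * 180 / pi
  list(time = mat[, 1], angles = angles, in_degrees = in_degrees,
       name = trimws(lines[1]))
}

#' Export a Fourier motion to a motion file
#'
#' Samples the motion uniformly (first sample at t = 0) and writes it in the
#' motion-file dialect of [write_motion_file()].
#'
#' @param motion `fourier_motion`.
#' @param path output path.
#' @param n_samples number of rows (default 100).
#' @param cycles number of cycles covered (default 1).
#' @param in_degrees write degrees (default) or radians.
#' @return `path`, invisibly.
#' @export
export_motion_file <- function(motion, path, n_samples = 100, cycles = 1,
                               in_degrees = TRUE) {
  stopifnot(n_samples > 0)
  t <- seq(0, cycles * motion$period_s, length.out = n_samples + 1)[seq_len(n_samples)]
  ang <- evaluate_motion(motion, t)$angles
  if (!in_degrees) ang <- ang * pi / 180
  write_motion_file(t, ang, path, in_degrees = in_degrees, name = "wingflap motion")
}
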