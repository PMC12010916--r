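#' Read a point cloud (ascii PLY, XYZ or CSV)
#'
#' Format is chosen by file extension: `.ply` for ascii PLY (comment lines
#' ignored; only vertex x/y/z properties are read), anything else is parsed
#' as whitespace- or comma-separated x y z rows (a `x,y,z` header line is
#' allowed). Malformed rows are reported with their line number.
#'
#' @param path input file.
#' @return Nx3 numeric matrix (mm), columns x, y, z.
#' @export
read_point_cloud <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !any(nzchar(trimws(lines))))
    stop("empty point cloud file: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(read_ply_ascii(lines, path))
  start <- 1L
  first <- trimws(lines[1])
  if (grepl("^[a-zA-Z]", first)) start <- 2L   # header line
  rows <- lines[seq(start, length(lines))]
  keep <- nzchar(trimws(rows))
  idx <- seq(start, length(lines))[keep]
  rows <- rows[keep]
  pts <- t(vapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "[,[:space:]]+")[[1]]))
    if (length(v) < 3 || anyNA(v[1:3]))
      stop(sprintf("non-numeric point cloud row at line %d of %s", idx[i], path))
    v[1:3]
  }, numeric(3)))
  colnames(pts) <- c("x", "y", "z")
  pts
}

read_ply_ascii <- function(lines, path) {
  if (trimws(lines[1]) != "ply") stop("malformed PLY header (missing 'ply'): ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY header (missing 'end_header'): ", path)
  hdr <- trimws(lines[2:(end - 1)])
  hdr <- hdr[!grepl("^comment", hdr)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ascii PLY is supported: ", path)
  ev <- grep("^element\\s+vertex\\s+\\d+", hdr, value = TRUE)
  if (length(ev) != 1) stop("malformed PLY header (vertex element): ", path)
  n <- as.integer(sub(".*vertex\\s+", "", ev))
  body <- lines[seq(end + 1, length.out = length(lines) - end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop(sprintf("PLY body has %d rows, header says %d", length(body), n))
  pts <- t(vapply(seq_len(n), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) < 3 || anyNA(v[1:3]))
      stop(sprintf("non-numeric PLY vertex at data row %d of %s", i, path))
    v[1:3]
  }, numeric(3)))
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Write a point cloud (ascii PLY, XYZ or CSV)
#'
#' Values are written with 17 significant digits so the [read_point_cloud()]
#' round trip is lossless at printed precision.
#'
#' @param points Nx3 numeric matrix (mm).
#' @param path output path; `.ply` selects ascii PLY, `.csv` comma-separated
#'   with header, anything else whitespace-separated XYZ.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3)
  fmt <- function(row) paste(sprintf("%.17g", row), collapse = " ")
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 "comment written by wingflap",
                 sprintf("element vertex %d", nrow(pts)),
                 "property double x", "property double y", "property double z",
                 "end_header"), con)
    writeLines(apply(pts, 1, fmt), con)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("x,y,z", con)
    writeLines(apply(pts, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")), con)
  } else {
    writeLines(apply(pts, 1, fmt), path)
  }
  invisible(path)
}
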