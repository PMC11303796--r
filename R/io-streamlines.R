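# Streamline file IO. Both tractography dialects are read into, and written
# from, world-space RAS mm coordinates (the package-wide convention).
#
# TRK (TrackVis) stores points in "voxmm" with a corner-based origin:
#   rasmm = vox_to_ras %*% (p / voxel_size - 0.5)
# TCK (MRtrix) stores RAS mm directly (text header + Float32LE triples,
# NaN-delimited, Inf-terminated).

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

#' Write streamlines to a TRK file
#'
#' @param streamlines List of n x 3 world-mm point matrices, or a
#'   [bundle()].
#' @param file Output path.
#' @param affine 4 x 4 voxel-to-world matrix of the reference grid.
#' @param dim Reference grid dimensions (3 integers).
#' @param voxel_size Voxel edge lengths, mm.
#' @return `file`, invisibly.
#' @export
write_trk <- function(streamlines, file, affine = diag(4), dim = c(1, 1, 1),
                      voxel_size = c(1, 1, 1)) {
  if (inherits(streamlines, "bundle")) streamlines <- streamlines$streamlines
  inv <- solve(affine)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(pad_raw("TRACK", 6), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)                                      # scalar names
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)                                      # property names
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  writeBin(pad_raw("RAS", 4), con)                             # voxel_order
  writeBin(raw(4), con)                                        # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")       # orientation
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert/swap
  writeBin(length(streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (p in streamlines) {
    vox <- (cbind(p, 1) %*% t(inv))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2, voxel_size, `*`)
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(file)
}

#' Read streamlines from a TRK file
#'
#' @param file Path to a little-endian TRK v1/v2 file without per-point
#'   scalars; the header's `vox_to_ras` matrix must be filled in.
#' @return List with `streamlines` (world-mm matrices) and `header`
#'   (`dim, voxel_size, affine, n_count`).
#' @export
read_trk <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(id, "TRACK")) stop("not a TRK file", call. = FALSE)
  dim <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")      # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  affine <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 1000L)) {
    stop("unsupported TRK header (expected little-endian, hdr_size 1000)",
         call. = FALSE)
  }
  if (all(affine == 0)) stop("TRK header has an empty vox_to_ras matrix", call. = FALSE)
  if (n_scalars > 0 || n_props > 0) {
    stop("TRK files with scalars/properties are not supported", call. = FALSE)
  }
  out <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0) break
    pts <- matrix(readBin(con, "numeric", 3 * np, size = 4, endian = "little"),
                  np, 3, byrow = TRUE)
    vox <- sweep(pts, 2, voxel_size, `/`) - 0.5
    world <- (cbind(vox, 1) %*% t(affine))[, 1:3, drop = FALSE]
    out[[length(out) + 1]] <- world
  }
  if (n_count > 0 && length(out) != n_count) {
    warning(sprintf("TRK header advertised %d streamlines, found %d",
                    n_count, length(out)), call. = FALSE)
  }
  list(streamlines = out,
       header = list(dim = dim, voxel_size = voxel_size, affine = affine,
                     n_count = length(out)))
}

#' Write streamlines to a TCK file
#'
#' @param streamlines List of n x 3 world-mm matrices, or a [bundle()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tck <- function(streamlines, file) {
  if (inherits(streamlines, "bundle")) streamlines <- streamlines$streamlines
  base <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 length(streamlines), "\nfile: . ")
  tail <- "\nEND\n"
  offset <- nchar(base) + 1 + nchar(tail)   # at least one offset digit
  repeat {
    hdr <- paste0(base, offset, tail)
    if (nchar(hdr) == offset) break
    offset <- nchar(paste0(base, offset, tail))
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (p in streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(file)
}

#' Read streamlines from a TCK file
#'
#' @param file Path to an MRtrix TCK file (Float32LE or Float64LE).
#' @return List with `streamlines` (world-mm matrices) and `header` (named
#'   character vector of the raw fields).
#' @export
read_tck <- function(file) {
  raw_all <- readBin(file, "raw", file.info(file)$size)
  if (!identical(rawToChar(raw_all[1:13]), "mrtrix tracks")) {
    stop("not a TCK file", call. = FALSE)
  }
  end_pos <- grepRaw("\nEND\n", raw_all, fixed = TRUE)
  if (length(end_pos) == 0) stop("TCK header END marker not found", call. = FALSE)
  head_txt <- rawToChar(raw_all[seq_len(end_pos[1] - 1)])
  hdr_lines <- strsplit(head_txt, "\n")[[1]][-1]
  kv <- strsplit(hdr_lines, ": ", fixed = TRUE)
  header <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = ": "),
                                   character(1)),
                            vapply(kv, `[[`, character(1), 1))
  datatype <- header[["datatype"]]
  size <- switch(datatype, Float32LE = 4L, Float64LE = 8L,
                 stop("unsupported TCK datatype: ", datatype, call. = FALSE))
  offset <- as.integer(sub("^\\S+\\s+", "", header[["file"]]))
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "numeric",
                  n = (length(raw_all) - offset) / size,
                  size = size, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) == 3
  is_inf <- rowSums(is.infinite(m)) == 3
  stop_row <- which(is_inf)[1]
  if (!is.na(stop_row)) m <- m[seq_len(stop_row - 1), , drop = FALSE]
  breaks <- which(rowSums(is.na(m)) == 3)
  starts <- c(1, breaks + 1)
  ends <- c(breaks - 1, nrow(m))
  out <- list()
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    out[[length(out) + 1]] <- m[starts[i]:ends[i], , drop = FALSE]
  }
  list(streamlines = out, header = header)
}

#' Read a bundle from TRK or TCK
#'
#' Dispatches on the file extension and wraps the streamlines in a
#' [bundle()].
#'
#' @param file `.trk` or `.tck` path.
#' @param name Bundle label (default: file base name).
#' @return A [bundle()].
#' @export
read_bundle <- function(file, name = NULL) {
  ext <- tolower(tools::file_ext(file))
  sl <- switch(ext,
               trk = read_trk(file)$streamlines,
               tck = read_tck(file)$streamlines,
               stop("unsupported streamline format: .", ext, call. = FALSE))
  if (is.null(name)) name <- sub("\\.(trk|tck)$", "", basename(file),
                                 ignore.case = TRUE)
  bundle(name, sl)
}
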