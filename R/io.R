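# grayscale conversion by Rec.601 luminance for RGB(A) arrays
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    if (ch >= 3L) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    return(img[, , 1])
  }
  stop("unsupported image layout", call. = FALSE)
}

# numeric-aware file ordering: sort by the last integer in the file name
numeric_sort <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)(?!.*\\d).*", "\\1",
                                         base, perl = TRUE)))
  ord <- order(is.na(num), num, base)
  files[ord]
}

read_one_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported frame format: '%s'", ext), call. = FALSE)
  )
  to_gray(img)
}

#' Read a grayscale image sequence
#'
#' Accepts either a multi-page TIFF stack or a directory of PNG/TIFF frames
#' ordered by the number embedded in their file names. 8- and 16-bit
#' integer images are rescaled to \[0, 1\]; RGB frames are converted to
#' luminance.
#'
#' @param path Path to a multi-page TIFF file or a directory of frames.
#' @param frame_interval_s Optional seconds between frames (metadata).
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, frame_interval_s = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) < 2L) {
      stop("directory must contain at least 2 PNG/TIFF frames", call. = FALSE)
    }
    frames <- lapply(numeric_sort(files), read_one_frame)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  } else {
    stop(sprintf("no such file or directory: '%s'", path), call. = FALSE)
  }
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  image_sequence(frames, frame_interval_s = frame_interval_s)
}

#' Write an image sequence as a multi-page TIFF
#'
#' @param seq An [image_sequence()].
#' @param path Output `.tif` path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, bits = 16L) {
  stopifnot(inherits(seq, "image_sequence"), bits %in% c(8L, 16L))
  tiff::writeTIFF(seq$frames, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

FLO_MAGIC <- 202021.25

#' Write a flow field in Middlebury .flo format
#'
#' Little-endian binary: float32 magic 202021.25, int32 width, int32
#' height, then row-major interleaved float32 (u, v) per pixel.
#'
#' @param flow A [flow_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flo <- function(flow, path) {
  stopifnot(inherits(flow, "flow_field"))
  h <- nrow(flow$u); w <- ncol(flow$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4L, endian = "little")
  writeBin(c(as.integer(w), as.integer(h)), con, size = 4L, endian = "little")
  # row-major interleaved: for each row, (u, v) across columns
  inter <- rbind(as.vector(t(flow$u)), as.vector(t(flow$v)))
  writeBin(as.vector(inter), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo flow field
#'
#' @param path Path to a `.flo` file written as by [write_flo()].
#' @return A [flow_field()].
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "double", n = 1L, size = 4L, endian = "little")
  if (length(magic) != 1L || !is.finite(magic) ||
      abs(magic - FLO_MAGIC) > 0.01) {
    stop("not a .flo file (bad magic number)", call. = FALSE)
  }
  dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(dims) != 2L || any(dims < 1)) {
    stop("truncated or corrupt .flo header", call. = FALSE)
  }
  w <- dims[1]; h <- dims[2]
  vals <- readBin(con, "double", n = 2L * w * h, size = 4L, endian = "little")
  if (length(vals) != 2L * w * h) {
    stop("truncated .flo payload", call. = FALSE)
  }
  inter <- matrix(vals, nrow = 2L)
  u <- matrix(inter[1, ], nrow = h, ncol = w, byrow = TRUE)
  v <- matrix(inter[2, ], nrow = h, ncol = w, byrow = TRUE)
  flow_field(u, v)
}
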