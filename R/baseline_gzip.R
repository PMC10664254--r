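# The comparison baseline: rounded-coordinate text (the size denominator
# for every compression ratio) and gzip over an integer-encoded binary
# stream (x10 rounding, per-axis delta + zigzag + varint packing).

#' Rounded-coordinates text rendering
#'
#' One line per atom: the three Cartesian coordinates rounded to one
#' decimal (ties away from zero), space-separated, newline-terminated, in
#' minimal decimal form (`"1.0 -2.3 0.0"`). Its size is the reference
#' against which both gzip and PIC compression ratios are measured.
#'
#' @param points numeric matrix (n x 3) in Angstrom.
#' @return raw vector of text bytes.
#' @export
rounded_text <- function(points) {
  points <- as_points(points)
  if (nrow(points) == 0L) stop("cannot render an empty point list")
  tenths <- round_half_away(points * 10)
  tenths[tenths == 0] <- 0  # normalize -0
  txt <- matrix(sprintf("%.1f", tenths / 10), nrow(points), 3)
  charToRaw(paste0(txt[, 1], " ", txt[, 2], " ", txt[, 3], "\n",
                   collapse = ""))
}

#' Integer-encode coordinates into a packed binary stream
#'
#' Each coordinate is multiplied by 10 and rounded to the nearest integer
#' (ties away from zero), then per-axis delta encoded in file order, zigzag
#' mapped to non-negative integers, and packed as LEB128 varints; the three
#' axis streams follow a small header carrying the atom count. The stream
#' is losslessly invertible to the x10 integers via [integer_unpack()].
#'
#' @param points numeric matrix (n x 3) in Angstrom.
#' @return raw vector.
#' @export
integer_pack <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  if (n == 0L) stop("cannot pack an empty point list")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("PICB"), con)
  writeBin(n, con, size = 4, endian = "little")
  for (k in 1:3) {
    v <- as.integer(round_half_away(points[, k] * 10))
    d <- diff(c(0L, v))
    zz <- ifelse(d >= 0L, 2L * d, -2L * d - 1L)
    writeBin(cpp_varint_pack(zz), con)
  }
  rawConnectionValue(con)
}

#' @rdname integer_pack
#' @param bytes raw vector from [integer_pack()].
#' @return `integer_unpack`: integer matrix (n x 3) of the x10 coordinates.
#' @export
integer_unpack <- function(bytes) {
  if (length(bytes) < 8 || !identical(bytes[1:4], charToRaw("PICB")))
    stop("not an integer-packed coordinate stream (bad magic)")
  n <- readBin(bytes[5:8], "integer", 1, size = 4, endian = "little")
  out <- matrix(0L, n, 3)
  pos <- 8L
  for (k in 1:3) {
    st <- cpp_varint_unpack(bytes, n, pos)
    zz <- st$values
    d <- ifelse(zz %% 2L == 0L, zz %/% 2L, -((zz + 1L) %/% 2L))
    out[, k] <- cumsum(d)
    pos <- st$position
  }
  out
}

#' Gzip a payload at maximum compression
#'
#' Standard RFC 1952 gzip member at level 9; decompresses to the payload
#' exactly.
#'
#' @param payload raw vector.
#' @return raw vector of gzip bytes.
#' @export
gzip_bytes <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  con <- gzfile(tmp, "wb", compression = 9)
  writeBin(payload, con)
  close(con)
  readBin(tmp, "raw", n = file.size(tmp))
}

#' Compression ratio
#'
#' Reference size divided by compressed size; both in the same unit.
#'
#' @param reference_size,compressed_size positive sizes in bytes.
#' @return the ratio.
#' @export
compression_ratio <- function(reference_size, compressed_size) {
  if (any(reference_size <= 0) || any(compressed_size <= 0))
    stop("sizes must be positive")
  reference_size / compressed_size
}

#' Baseline sizes for a point cloud
#'
#' Computes the three sizes of the gzip baseline in one call: rounded text,
#' packed binary, and gzipped binary.
#'
#' @param points numeric matrix (n x 3) in Angstrom.
#' @return list with `text_size_bytes`, `binary_size_bytes`,
#'   `gzip_size_bytes`.
#' @export
baseline_sizes <- function(points) {
  txt <- rounded_text(points)
  bin <- integer_pack(points)
  list(text_size_bytes = length(txt),
       binary_size_bytes = length(bin),
       gzip_size_bytes = length(gzip_bytes(bin)))
}
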