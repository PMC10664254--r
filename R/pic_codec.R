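#' Codec configuration
#'
#' The single tunable of the codec is `epsilon`, the number of pixels
#' allotted per degree of azimuth along the image's vertical axis. It
#' controls the image height (360*epsilon pixel rows, i.e. 2880*epsilon bits
#' per column) and thereby the collision rate: small epsilon gives small
#' images but more collisions (pointers, overflow images); large epsilon the
#' reverse. Legal values satisfy `epsilon >= 1.25` with `0.8*epsilon` and
#' `360*epsilon` integers, i.e. epsilon in {1.25, 2.5, 3.75, 5, ...};
#' `m = 0.8*epsilon` is the number of bits per tenth of an azimuth degree
#' (the azimuth bin width) and is the integer actually serialized.
#'
#' @param epsilon pixels per azimuth degree; default 2.5.
#' @return a `pic_config` with derived constants: `m`, column height
#'   `H = 2880*epsilon` bits, image height `rows_px = 360*epsilon` pixels,
#'   and the pointer width `ceil(log2(H))` bits.
#' @export
#' @examples
#' codec_config(2.5)
codec_config <- function(epsilon = 2.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon))
    stop("epsilon must be a single finite number")
  m <- 0.8 * epsilon
  if (epsilon < 1.25 || abs(m - round(m)) > 1e-9 ||
      abs(360 * epsilon - round(360 * epsilon)) > 1e-9)
    stop("illegal epsilon ", epsilon,
         ": need epsilon >= 1.25 with 0.8*epsilon and 360*epsilon integers")
  m <- as.integer(round(m))
  H <- 3600L * m
  w <- 0L
  while (2^w < H) w <- w + 1L
  structure(list(epsilon = epsilon, m = m, H = H, rows_px = H %/% 8L,
                 ptr_width = w),
            class = "pic_config")
}

#' @export
print.pic_config <- function(x, ...) {
  cat("<pic_config> epsilon =", x$epsilon, "(m =", x$m,
      "bits/bin), column =", x$H, "bits, image height =", x$rows_px,
      "px, pointer width =", x$ptr_width, "bits\n")
  invisible(x)
}

as_config <- function(config) {
  if (inherits(config, "pic_config")) config else codec_config(config)
}

#' Map a quantized spherical triple to its target image position
#'
#' The positional encoding (x, y) = (10r, epsilon*phi): the column index is
#' the radial component in tenths of an Angstrom and the target bit index
#' within the column is `0.8*epsilon` times the azimuth in tenths of a
#' degree (an integer by the epsilon constraint).
#'
#' @param q integer matrix with columns `r_decit`, `phi_decideg`,
#'   `theta_decideg` (rows are atoms), or a single triple.
#' @param config a [codec_config()] or an epsilon value.
#' @return integer matrix with columns `x` (column index) and `b` (bit
#'   index in \[0, 2880*epsilon)).
#' @export
map_position <- function(q, config = codec_config()) {
  cfg <- as_config(config)
  if (is.null(dim(q))) q <- matrix(as.integer(q), ncol = 3)
  cbind(x = as.integer(q[, 1]), b = as.integer(cfg$m * q[, 2]))
}

#' Pack one atom record into its self-delimiting bit string
#'
#' A record is `1` (start bit), a pointer flag, an optional pointer of
#' `ceil(log2(2880*epsilon))` bits, and the 11-bit big-endian elevation
#' payload `10*theta` — 13 bits without pointer, 13 + pointer width with.
#'
#' @param theta_code integer in \[0, 1800\]: the elevation angle in tenths
#'   of a degree.
#' @param p pointer (offset in bits back to the record's azimuth bin), an
#'   integer in \[1, 2880*epsilon), or `NULL` for a pointer-free record.
#' @param config a [codec_config()] or an epsilon value.
#' @return integer vector of bits (0/1).
#' @export
#' @examples
#' paste(pack_record(900), collapse = "")
pack_record <- function(theta_code, p = NULL, config = codec_config()) {
  cfg <- as_config(config)
  cpp_pack_record(as.integer(theta_code),
                  if (is.null(p)) -1L else as.integer(p), cfg$m)
}

#' Unpack a record from the head of a bit string
#'
#' Exact inverse of [pack_record()]; the bit string may be longer than the
#' record (trailing bits are ignored).
#'
#' @param bits integer vector of bits whose first bit starts a record.
#' @param config a [codec_config()] or an epsilon value.
#' @return list with `theta_code`, `p` (integer or `NULL`), and the record
#'   length `length` in bits.
#' @export
unpack_record <- function(bits, config = codec_config()) {
  cfg <- as_config(config)
  out <- cpp_unpack_record(as.integer(bits), cfg$m)
  list(theta_code = out$theta_code,
       p = if (length(out$p)) out$p[[1]] else NULL,
       length = out$length)
}

#' Find the slot for a record in one canvas column
#'
#' Scans candidates b = (b_target + i) mod 2880*epsilon for i = 0, 1, ...:
#' a candidate inside the azimuth bin \[b_target, b_target + 0.8*epsilon)
#' takes a pointer-free 13-bit record, any other candidate a pointered one;
#' it is accepted iff the whole record fits above the column bottom and all
#' its bits are unwritten. On acceptance outside the bin the pointer is
#' p = (b_star - b') mod 2880*epsilon with b' = b_target + 0.8*epsilon - 1,
#' the last bit of the intended bin.
#'
#' @param occupied logical vector of length 2880*epsilon: which bits of the
#'   column have been written.
#' @param b_target target bit index (`0.8*epsilon * phi_decideg`).
#' @param config a [codec_config()] or an epsilon value.
#' @return `NULL` when the column has no space; otherwise a list with
#'   `b_star` (chosen start bit) and `p` (pointer, or `NULL` inside the
#'   bin).
#' @export
find_slot <- function(occupied, b_target, config = codec_config()) {
  cfg <- as_config(config)
  out <- cpp_find_slot(as.logical(occupied), as.integer(b_target), cfg$m)
  if (isTRUE(out$no_space)) return(NULL)
  list(b_star = out$b_star, p = if (length(out$p)) out$p[[1]] else NULL)
}

#' Compress a point cloud into a PIC archive
#'
#' The full forward pipeline: centre on the global centroid, convert to
#' spherical coordinates, quantize to one decimal, positionally encode each
#' atom (in file order) into the first canvas with space — opening a fresh
#' full-size canvas when every existing one is full at that column — then
#' crop all-black margins and PNG-encode each canvas.
#'
#' @param points numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom, in file order.
#' @param config a [codec_config()] or an epsilon value.
#' @param keep_log if `TRUE`, attach the encoder's write log as component
#'   `log`: one row per atom in file order with the image, column, start
#'   bit, pointer (`NA` when pointer-free) and bit length of its record —
#'   the instrumentation against which the scanning decoder can be
#'   checked.
#' @return a `pic_archive`: PNG bytes per image, crop offsets, centroid
#'   `mu`, maximal quantized radius `r_star_decit`, the scan-order ->
#'   file-order permutation, per-image fill fractions, and (optionally,
#'   see [pic_compress()]) the non-coordinate file content.
#' @export
pic_encode <- function(points, config = codec_config(), keep_log = FALSE) {
  cfg <- as_config(config)
  points <- as_points(points)
  n <- nrow(points)
  if (n < 1L) stop("cannot encode an empty point cloud")
  mu <- centroid(points)
  q <- quantize_spherical(cart_to_spherical(sweep(points, 2, mu)))
  enc <- cpp_encode(q, cfg$m)
  perm <- order(enc$image, enc$column, enc$bit) - 1L  # scan order -> file index
  images <- vector("list", length(enc$rasters))
  crops <- matrix(0L, length(images), 2,
                  dimnames = list(NULL, c("top", "left")))
  for (i in seq_along(images)) {
    cr <- crop_raster(enc$rasters[[i]])
    crops[i, ] <- c(cr$top, cr$left)
    images[[i]] <- render_png(cr$raster)
  }
  cols <- enc$r_star + 1L
  out <- structure(list(config = cfg, mu = mu, r_star_decit = enc$r_star,
                        n = n, images = images, crops = crops,
                        permutation = perm,
                        fill = enc$bits_written / (as.double(cfg$H) * cols),
                        metadata = NULL),
                   class = "pic_archive")
  if (keep_log)
    out$log <- tibble::tibble(image = enc$image, column = enc$column,
                              bit = enc$bit,
                              pointer = ifelse(enc$pointer < 0, NA_integer_,
                                               enc$pointer),
                              length = enc$length)
  out
}

#' @export
print.pic_archive <- function(x, ...) {
  cat("<pic_archive> ", x$n, " atoms, epsilon = ", x$config$epsilon, ", ",
      length(x$images), " image(s), ",
      sum(vapply(x$images, length, 0L)), " PNG bytes, fill ",
      paste(sprintf("%.1f%%", 100 * x$fill), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Decompress a PIC archive back to Cartesian coordinates
#'
#' Exact inverse of [pic_encode()] up to quantization: each image is PNG-
#' decoded and uncropped to full size, every column is scanned top to
#' bottom with a bit cursor (a 1 bit opens a self-delimiting record, a 0
#' bit advances by one), the azimuth is recovered from the record start bit
#' minus its pointer, the stored permutation restores original atom order,
#' and coordinates are mapped back to Cartesian and translated by +mu.
#'
#' @param archive a `pic_archive`.
#' @param quantized if `TRUE`, return the integer matrix of recovered
#'   spherical triples (tenths) instead of Cartesian coordinates.
#' @return numeric matrix (n x 3) of coordinates in original file order (or
#'   the quantized triples when `quantized = TRUE`).
#' @export
pic_decode <- function(archive, quantized = FALSE) {
  stopifnot(inherits(archive, "pic_archive"))
  cfg <- archive$config
  if (length(archive$images) == 0L) stop("archive contains no images")
  cols <- archive$r_star_decit + 1L
  recs <- lapply(seq_along(archive$images), function(i) {
    raster <- uncrop_raster(read_png(archive$images[[i]]),
                            archive$crops[i, 1], archive$crops[i, 2],
                            cfg$rows_px, cols)
    cpp_decode_raster(raster, cfg$m)
  })
  column <- unlist(lapply(recs, `[[`, "column"))
  bit <- unlist(lapply(recs, `[[`, "bit"))
  p <- unlist(lapply(recs, `[[`, "pointer"))
  theta <- unlist(lapply(recs, `[[`, "theta_code"))
  perm <- archive$permutation
  if (length(theta) != length(perm))
    stop("decoded ", length(theta), " records but the permutation lists ",
         length(perm), " atoms")
  if (!identical(sort(perm), seq_along(perm) - 1L))
    stop("stored permutation is not a bijection on 0..n-1")
  if (any(theta > 1800L)) stop("corrupt record: elevation code above 1800")
  bprime <- (bit - pmax(p, 0L)) %% cfg$H
  phi <- bprime %/% cfg$m
  q <- cbind(r_decit = column, phi_decideg = phi, theta_decideg = theta)
  q[perm + 1L, ] <- q  # scan order -> original file order
  if (quantized) return(q)
  sweep(spherical_to_cart(q), 2, archive$mu, `+`)
}

#' Crop all-black margins from a raster
#'
#' Removes maximal all-zero rows and columns from every edge; the top and
#' left offsets (the two cropping parameters stored per image) suffice to
#' reverse the crop because the full image dimensions are known from
#' epsilon and the maximal radius.
#'
#' @param raster integer matrix of 8-bit pixel values.
#' @return list with the cropped `raster` and the `top` and `left` offsets
#'   (counts of removed rows/columns).
#' @export
crop_raster <- function(raster) {
  nz_row <- which(rowSums(raster != 0) > 0)
  nz_col <- which(colSums(raster != 0) > 0)
  if (length(nz_row) == 0L) stop("cannot crop an all-black raster")
  r <- range(nz_row)
  cl <- range(nz_col)
  list(raster = raster[r[1]:r[2], cl[1]:cl[2], drop = FALSE],
       top = r[1] - 1L, left = cl[1] - 1L)
}

#' Reverse a crop given the full image dimensions
#'
#' @param cropped integer matrix from [crop_raster()].
#' @param top,left offsets stored with the image.
#' @param rows,cols full (uncropped) dimensions.
#' @return integer matrix `rows` x `cols`.
#' @export
uncrop_raster <- function(cropped, top, left, rows, cols) {
  if (top + nrow(cropped) > rows || left + ncol(cropped) > cols)
    stop("cropped raster does not fit the stated full dimensions")
  full <- matrix(0L, rows, cols)
  full[top + seq_len(nrow(cropped)), left + seq_len(ncol(cropped))] <- cropped
  full
}

#' PNG encode / decode a greyscale raster
#'
#' 8-bit single-channel non-interlaced PNG via libpng; the lossless layer of
#' the codec — decoding returns the raster pixel-exactly.
#'
#' @param raster integer matrix of pixel values in \[0, 255\].
#' @return `render_png`: raw vector of PNG bytes. `read_png`: integer
#'   matrix.
#' @export
render_png <- function(raster) {
  png::writePNG(raster / 255, target = raw())
}

#' @rdname render_png
#' @param bytes raw vector of PNG bytes.
#' @export
read_png <- function(bytes) {
  img <- png::readPNG(bytes)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
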