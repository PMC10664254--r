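# On-disk archive: one little-endian binary sidecar (.pic) plus one PNG per
# image next to it. Sidecar layout:
#   magic "PIC1" | version u8 | m = 0.8*epsilon u8 | mu 3 x f64 |
#   r*_decit u32 | image count u16 | per image: crop_top u16, crop_left u32 |
#   atom count u32 | permutation u32[n] | metadata length u32 |
#   gzip member: masked structure file + record template + dialect tag
PIC_MAGIC <- charToRaw("PIC1")
PIC_VERSION <- 1L

#' Write a PIC archive to disk
#'
#' Writes the binary sidecar at `path` and the cropped PNG images as
#' `<path minus .pic>_<i>.png` alongside it.
#'
#' @param archive a `pic_archive` from [pic_encode()].
#' @param path sidecar file path (conventionally ending in `.pic`).
#' @return invisibly, the character vector of all files written (sidecar
#'   first).
#' @export
write_pic_archive <- function(archive, path) {
  stopifnot(inherits(archive, "pic_archive"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(PIC_MAGIC, con)
  writeBin(as.raw(c(PIC_VERSION, archive$config$m)), con)
  writeBin(as.double(archive$mu), con, size = 8, endian = "little")
  writeBin(as.integer(archive$r_star_decit), con, size = 4, endian = "little")
  writeBin(length(archive$images), con, size = 2, endian = "little")
  for (i in seq_along(archive$images)) {
    writeBin(as.integer(archive$crops[i, 1]), con, size = 2, endian = "little")
    writeBin(as.integer(archive$crops[i, 2]), con, size = 4, endian = "little")
  }
  writeBin(archive$n, con, size = 4, endian = "little")
  writeBin(as.integer(archive$permutation), con, size = 4, endian = "little")
  blob <- if (is.null(archive$metadata)) raw(0) else archive$metadata
  writeBin(length(blob), con, size = 4, endian = "little")
  writeBin(blob, con)
  png_paths <- png_paths_for(path, length(archive$images))
  for (i in seq_along(archive$images))
    writeBin(archive$images[[i]], png_paths[i])
  invisible(c(path, png_paths))
}

png_paths_for <- function(sidecar, k) {
  prefix <- sub("\\.pic$", "", sidecar)
  paste0(prefix, "_", seq_len(k) - 1L, ".png")
}

#' Read a PIC archive from disk
#'
#' @param path sidecar file path; the PNG images are expected next to it
#'   under the names [write_pic_archive()] uses.
#' @return a `pic_archive`.
#' @export
read_pic_archive <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readBin(con, "raw", 4), PIC_MAGIC))
    stop("'", path, "' is not a PIC sidecar (bad magic)")
  version <- as.integer(readBin(con, "raw", 1))
  if (version != PIC_VERSION) stop("unsupported PIC sidecar version ", version)
  m <- as.integer(readBin(con, "raw", 1))
  cfg <- codec_config(m / 0.8)
  mu <- readBin(con, "double", 3, size = 8, endian = "little")
  r_star <- readBin(con, "integer", 1, size = 4, endian = "little")
  k <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  crops <- matrix(0L, k, 2, dimnames = list(NULL, c("top", "left")))
  for (i in seq_len(k)) {
    crops[i, 1] <- readBin(con, "integer", 1, size = 2, endian = "little",
                           signed = FALSE)
    crops[i, 2] <- readBin(con, "integer", 1, size = 4, endian = "little")
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  perm <- readBin(con, "integer", n, size = 4, endian = "little")
  blob_len <- readBin(con, "integer", 1, size = 4, endian = "little")
  blob <- if (blob_len > 0) readBin(con, "raw", blob_len) else NULL
  png_paths <- png_paths_for(path, k)
  missing <- png_paths[!file.exists(png_paths)]
  if (length(missing))
    stop("sidecar references missing image file(s): ",
         paste(missing, collapse = ", "))
  images <- lapply(png_paths, function(p)
    readBin(p, "raw", n = file.size(p)))
  structure(list(config = cfg, mu = mu, r_star_decit = r_star, n = n,
                 images = images, crops = crops, permutation = perm,
                 fill = rep(NA_real_, k), metadata = blob),
            class = "pic_archive")
}

# gzip member holding everything outside the coordinate values: the masked
# file bytes plus the per-atom field positions/decimals and the dialect
serialize_metadata <- function(model) {
  masked <- mask_structure(model)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(model$dialect == "mmcif"), con, size = 1)
  n <- length(model$atom_line)
  writeBin(n, con, size = 4, endian = "little")
  writeBin(as.integer(model$atom_line), con, size = 4, endian = "little")
  writeBin(as.integer(model$field_start), con, size = 4, endian = "little")
  writeBin(as.integer(model$field_end), con, size = 4, endian = "little")
  writeBin(as.integer(model$field_dec), con, size = 1)
  bytes <- charToRaw(paste(masked$lines, collapse = ""))
  writeBin(length(bytes), con, size = 4, endian = "little")
  writeBin(bytes, con)
  memCompress(rawConnectionValue(con), type = "gzip")
}

deserialize_metadata <- function(blob) {
  con <- rawConnection(memDecompress(blob, type = "gzip"))
  on.exit(close(con), add = TRUE)
  mmcif <- readBin(con, "integer", 1, size = 1)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  atom_line <- readBin(con, "integer", n, size = 4, endian = "little")
  fs <- matrix(readBin(con, "integer", 3 * n, size = 4, endian = "little"), n, 3)
  fe <- matrix(readBin(con, "integer", 3 * n, size = 4, endian = "little"), n, 3)
  fd <- matrix(readBin(con, "integer", 3 * n, size = 1), n, 3)
  blen <- readBin(con, "integer", 1, size = 4, endian = "little")
  lines <- split_keep_newlines(rawToChar(readBin(con, "raw", blen)))
  structure(list(lines = lines, coords = matrix(NA_real_, n, 3),
                 atom_line = atom_line, field_start = fs, field_end = fe,
                 field_dec = fd, dialect = if (mmcif) "mmcif" else "pdb"),
            class = "pic_structure")
}

#' Compress a structure file with PIC
#'
#' Reads a PDB/mmCIF file, compresses its atomic point cloud into PNG
#' images, and writes the sidecar plus images into `output_dir`. The
#' sidecar carries everything needed to rebuild the file byte-identically
#' outside the coordinate fields.
#'
#' @param input path to a PDB or mmCIF file.
#' @param output_dir directory for the archive files (created if absent).
#' @param epsilon pixels per azimuth degree (see [codec_config()]).
#' @param name basename for the archive; defaults to the input filename
#'   without extension.
#' @param quiet suppress the per-structure summary message.
#' @return invisibly, a list with the `archive`, the sidecar path
#'   (`sidecar`), and all written `files`.
#' @export
pic_compress <- function(input, output_dir, epsilon = 2.5, name = NULL,
                         quiet = FALSE) {
  cfg <- as_config(epsilon)
  model <- read_structure(input)
  archive <- pic_encode(model$coords, cfg)
  archive$metadata <- serialize_metadata(model)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(input))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  sidecar <- file.path(output_dir, paste0(name, ".pic"))
  files <- write_pic_archive(archive, sidecar)
  if (!quiet)
    message(sprintf("%s: %d atoms -> %d image(s), fill %s, %d PNG bytes + %d sidecar bytes",
                    name, archive$n, length(archive$images),
                    paste(sprintf("%.1f%%", 100 * archive$fill), collapse = "/"),
                    sum(vapply(archive$images, length, 0L)),
                    file.size(sidecar)))
  invisible(list(archive = archive, sidecar = sidecar, files = files))
}

#' Decompress a PIC archive back to a structure file
#'
#' @param sidecar path to the `.pic` sidecar (images must sit next to it).
#' @param output path for the reconstructed structure file; `NULL` to skip
#'   writing.
#' @param original optional path to the original file: when given, the RMSD
#'   between original and reconstructed coordinates is reported.
#' @return invisibly, a list with the decoded `coords`, the reconstructed
#'   file `bytes` (or `NULL` when the archive holds no metadata), and
#'   `rmsd` (or `NA`).
#' @export
pic_decompress <- function(sidecar, output = NULL, original = NULL,
                           quiet = FALSE) {
  archive <- read_pic_archive(sidecar)
  coords <- pic_decode(archive)
  bytes <- NULL
  if (!is.null(archive$metadata)) {
    model <- deserialize_metadata(archive$metadata)
    bytes <- write_structure(model, coords)
    if (!is.null(output)) writeBin(bytes, output)
  } else if (!is.null(output)) {
    stop("archive holds no file metadata; cannot write a structure file")
  }
  dev <- NA_real_
  if (!is.null(original)) {
    dev <- rmsd(read_structure(original)$coords, coords)
    if (!quiet) message(sprintf("RMSD vs original: %.3f A", dev))
  }
  invisible(list(coords = coords, bytes = bytes, rmsd = dev))
}
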