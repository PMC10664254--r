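# Shared fixture builders: everything is generated in code at test time.

# quantized spherical triples of a cloud after centering — the reference
# the codec round trip must reproduce exactly
quantized_of <- function(points) {
  unname(quantize_spherical(cart_to_spherical(sweep(points, 2,
                                                    centroid(points)))))
}

write_fixture <- function(bytes, ext) {
  path <- tempfile(fileext = ext)
  writeBin(bytes, path)
  path
}

# a minimal mmCIF with an _atom_site loop (mixed decimal widths on purpose)
toy_mmcif_text <- function(points = NULL) {
  if (is.null(points))
    points <- rbind(c(1, 2, 3), c(-4.25, 0.125, 10.5), c(7.77, -8.88, 9.99))
  rows <- sprintf("%s %d C %s %s %s 1.00",
                  c("ATOM", "ATOM", "HETATM")[(seq_len(nrow(points)) - 1) %% 3 + 1],
                  seq_len(nrow(points)),
                  format(points[, 1], trim = TRUE, nsmall = 3),
                  format(points[, 2], trim = TRUE, nsmall = 3),
                  format(points[, 3], trim = TRUE, nsmall = 2))
  paste0("data_toy\n#\nloop_\n_atom_site.group_PDB\n_atom_site.id\n",
         "_atom_site.type_symbol\n_atom_site.Cartn_x\n_atom_site.Cartn_y\n",
         "_atom_site.Cartn_z\n_atom_site.occupancy\n",
         paste(rows, collapse = "\n"), "\n#\n")
}

one_atom_pdb_line <- function() {
  paste0("ATOM      1  N   ALA A   1       1.000   2.000   3.000",
         "  1.00  0.00           N\n")
}

# blank the coordinate fields of PDB atom records so files can be compared
# outside coordinates
mask_pdb_coords <- function(bytes) {
  lines <- strsplit(rawToChar(bytes), "(?<=\n)", perl = TRUE)[[1]]
  is_atom <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  lines[is_atom] <- paste0(substr(lines[is_atom], 1, 30), strrep(" ", 24),
                           substring(lines[is_atom], 55))
  paste(lines, collapse = "")
}

# Independent decoder oracle written in plain R on top of the exported
# record primitives: converts each image back to column bit strings and
# walks them with a cursor, collecting every record it meets in scan order.
decode_scan_log <- function(archive) {
  cfg <- archive$config
  cols <- archive$r_star_decit + 1L
  out <- list()
  for (i in seq_along(archive$images)) {
    raster <- uncrop_raster(read_png(archive$images[[i]]),
                            archive$crops[i, 1], archive$crops[i, 2],
                            cfg$rows_px, cols)
    for (x in seq_len(cols)) {
      vals <- raster[, x]
      bitm <- vapply(7:0, function(s) bitwAnd(bitwShiftR(vals, s), 1L),
                     integer(length(vals)))
      bits <- as.vector(t(bitm))
      b <- 0L
      while (b < cfg$H) {
        if (bits[b + 1L] == 0L) { b <- b + 1L; next }
        rec <- unpack_record(bits[(b + 1L):min(b + 40L, cfg$H)], cfg)
        out[[length(out) + 1L]] <-
          data.frame(image = i - 1L, column = x - 1L, bit = b,
                     pointer = if (is.null(rec$p)) NA_integer_ else rec$p,
                     theta = rec$theta_code)
        b <- b + rec$length
      }
    }
  }
  do.call(rbind, out)
}
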