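#' Read a PDB or mmCIF structure file into an ordered atom model
#'
#' Extracts every coordinate-bearing atom record (ATOM and HETATM, all models
#' and chains) in file order, and keeps everything else in the file verbatim
#' so that a decompressed file can be rebuilt byte-identically outside the
#' coordinate fields.
#'
#' @param path path to a structure file.
#' @param dialect `"pdb"`, `"mmcif"`, or `NULL` to guess from the file
#'   extension and content.
#' @return an object of class `pic_structure` with components
#'   \describe{
#'     \item{lines}{character vector of the file's lines, terminators
#'       included}
#'     \item{dialect}{`"pdb"` or `"mmcif"`}
#'     \item{coords}{numeric matrix (n x 3) of Cartesian coordinates in
#'       Angstrom, in file order}
#'     \item{atom_line, field_start, field_end, field_dec}{per-atom record
#'       template: which line holds the atom and where its three coordinate
#'       fields sit (1-based substring positions) with how many printed
#'       decimals}
#'   }
#' @export
read_structure <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  content <- rawToChar(readBin(path, "raw", n = file.size(path)))
  if (is.null(dialect)) dialect <- guess_dialect(path, content)
  dialect <- match.arg(dialect, c("pdb", "mmcif"))
  lines <- split_keep_newlines(content)
  model <- if (dialect == "pdb") parse_pdb(lines) else parse_mmcif(lines)
  if (nrow(model$coords) == 0L)
    stop("no atoms: '", path, "' contains no ATOM/HETATM records")
  model$dialect <- dialect
  class(model) <- "pic_structure"
  model
}

#' @export
print.pic_structure <- function(x, ...) {
  cat("<pic_structure> ", nrow(x$coords), " atoms (", x$dialect, "), ",
      length(x$lines), " lines\n", sep = "")
  invisible(x)
}

# split into lines, each keeping its trailing "\n" (a final unterminated
# line is kept as-is), so paste(collapse = "") reproduces the file
split_keep_newlines <- function(content) {
  if (nchar(content) == 0L) return(character(0))
  strsplit(content, "(?<=\n)", perl = TRUE)[[1]]
}

guess_dialect <- function(path, content) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (grepl("_atom_site.", content, fixed = TRUE)) "mmcif" else "pdb"
}

parse_pdb <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_line <- which(rec == "ATOM  " | rec == "HETATM")
  n <- length(atom_line)
  coords <- matrix(numeric(0), 0, 3)
  fs <- fe <- fd <- matrix(integer(0), 0, 3)
  if (n > 0L) {
    fs <- matrix(rep(c(31L, 39L, 47L), each = n), n, 3)
    fe <- fs + 7L
    fd <- matrix(3L, n, 3)
    coords <- vapply(1:3, function(k) {
      v <- suppressWarnings(as.numeric(substr(lines[atom_line], fs[, k], fe[, k])))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop("malformed coordinate field on line ", atom_line[bad[1]])
      v
    }, numeric(n))
    coords <- matrix(coords, n, 3)
  }
  list(lines = lines, coords = coords, atom_line = atom_line,
       field_start = fs, field_end = fe, field_dec = fd)
}

# _atom_site loop: tag lines give the column order; data rows are plain
# whitespace-separated tokens (quoted/multi-line values are not expected in
# coordinate rows and are rejected)
parse_mmcif <- function(lines) {
  stripped <- sub("[ \t\r\n]+$", "", lines)
  atom_line <- integer(0)
  fs <- fe <- matrix(integer(0), 0, 3)
  fd <- matrix(integer(0), 0, 3)
  xs <- ys <- zs <- numeric(0)
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    if (stripped[i] == "loop_") {
      tags <- character(0)
      j <- i + 1L
      while (j <= nl && startsWith(stripped[j], "_")) {
        tags <- c(tags, stripped[j])
        j <- j + 1L
      }
      if (any(grepl("^_atom_site\\.", tags))) {
        names_only <- sub("^_atom_site\\.", "", tags)
        kx <- match("Cartn_x", names_only)
        ky <- match("Cartn_y", names_only)
        kz <- match("Cartn_z", names_only)
        if (any(is.na(c(kx, ky, kz))))
          stop("_atom_site loop lacks Cartn_x/y/z columns")
        while (j <= nl && !startsWith(stripped[j], "_") &&
               !(stripped[j] %in% c("loop_", "#")) &&
               !startsWith(stripped[j], "data_") && nzchar(stripped[j])) {
          toks <- gregexpr("\\S+", stripped[j])[[1]]
          if (toks[1] == -1L || length(toks) != length(tags))
            stop("malformed _atom_site row on line ", j)
          tlen <- attr(toks, "match.length")
          pos <- function(k) c(toks[k], toks[k] + tlen[k] - 1L)
          px <- pos(kx); py <- pos(ky); pz <- pos(kz)
          tok3 <- substring(stripped[j], c(px[1], py[1], pz[1]),
                            c(px[2], py[2], pz[2]))
          val3 <- suppressWarnings(as.numeric(tok3))
          if (any(!is.finite(val3)))
            stop("malformed coordinate field on line ", j)
          dec3 <- ifelse(grepl("\\.", tok3),
                         nchar(sub(".*\\.", "", tok3)), 0L)
          atom_line <- c(atom_line, j)
          fs <- rbind(fs, c(px[1], py[1], pz[1]))
          fe <- rbind(fe, c(px[2], py[2], pz[2]))
          fd <- rbind(fd, as.integer(dec3))
          xs <- c(xs, val3[1]); ys <- c(ys, val3[2]); zs <- c(zs, val3[3])
          j <- j + 1L
        }
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  list(lines = lines, coords = cbind(xs, ys, zs), atom_line = atom_line,
       field_start = fs, field_end = fe, field_dec = fd)
}

#' Render a structure with replacement coordinates
#'
#' Produces file bytes identical to the original file except the coordinate
#' fields, which render `new_positions`: fixed 8.3 columns for PDB, and the
#' same number of decimals as the source field for mmCIF.
#'
#' @param model a `pic_structure` from [read_structure()].
#' @param new_positions numeric matrix (n x 3), one row per atom in file
#'   order.
#' @return raw vector of file bytes.
#' @export
write_structure <- function(model, new_positions) {
  stopifnot(inherits(model, "pic_structure"))
  new_positions <- as_points(new_positions)
  n <- length(model$atom_line)
  if (nrow(new_positions) != n)
    stop("new_positions has ", nrow(new_positions), " rows but the model has ",
         n, " atoms")
  lines <- model$lines
  for (a in seq_len(n)) {
    li <- model$atom_line[a]
    line <- lines[li]
    # replace right-to-left so earlier substring positions stay valid
    for (k in 3:1) {
      width <- model$field_end[a, k] - model$field_start[a, k] + 1L
      txt <- sprintf(paste0("%.", model$field_dec[a, k], "f"),
                     new_positions[a, k])
      if (model$dialect == "pdb") {
        if (nchar(txt) > width)
          stop("coordinate ", txt, " overflows the ", width,
               "-character PDB field (atom ", a, ")")
        txt <- formatC(txt, width = width)
      }
      line <- paste0(substr(line, 1, model$field_start[a, k] - 1L), txt,
                     substring(line, model$field_end[a, k] + 1L))
    }
    lines[li] <- line
  }
  charToRaw(paste(lines, collapse = ""))
}

# model with coordinate fields blanked, for the archive sidecar: everything
# needed to rebuild the file once coordinates are known again
mask_structure <- function(model) {
  blank <- model
  n <- length(model$atom_line)
  for (a in seq_len(n)) {
    li <- model$atom_line[a]
    line <- blank$lines[li]
    for (k in 3:1) {
      width <- model$field_end[a, k] - model$field_start[a, k] + 1L
      line <- paste0(substr(line, 1, model$field_start[a, k] - 1L),
                     strrep(" ", width),
                     substring(line, model$field_end[a, k] + 1L))
    }
    blank$lines[li] <- line
  }
  blank$coords <- matrix(NA_real_, n, 3)
  blank
}
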