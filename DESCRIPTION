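Package: picr
Title: Image-Centric Compression of Protein Structure Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lossy compressor for the atomic point clouds stored in PDB and
    mmCIF protein structure files. Atom coordinates are centred on their
    global centroid, converted to spherical coordinates, quantized to one
    decimal (0.1 Angstrom / 0.1 degree), positionally encoded into the bit
    planes of 8-bit greyscale images with a scan-and-pointer collision
    scheme, and entropy coded with the lossless PNG image compressor.
    Decompression exactly inverts the pipeline up to the quantization loss
    and restores the original atom order, so the reconstructed file is
    byte-identical to the original outside the coordinate fields. Includes a
    gzip-after-integer-encoding baseline, a deterministic synthetic
    point-cloud generator, a benchmarking harness, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
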