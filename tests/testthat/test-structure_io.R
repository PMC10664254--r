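test_that("a single PDB ATOM line parses to one atom with its coordinates", {
  f <- write_fixture(charToRaw(one_atom_pdb_line()), ".pdb")
  m <- read_structure(f)
  expect_s3_class(m, "pic_structure")
  expect_equal(nrow(m$coords), 1L)
  expect_equal(unname(m$coords[1, ]), c(1, 2, 3))
  expect_equal(m$dialect, "pdb")
})

test_that("a file without atom records is rejected", {
  f <- write_fixture(charToRaw("HEADER    TOY PROTEIN\nEND\n"), ".pdb")
  expect_error(read_structure(f), "no atoms")
  expect_error(read_structure(tempfile(), "pdb"), "no such file")
})

test_that("malformed coordinate fields are reported with their line", {
  bad <- sub("   1.000", "   x.000", one_atom_pdb_line(), fixed = TRUE)
  f <- write_fixture(charToRaw(bad), ".pdb")
  expect_error(read_structure(f), "malformed coordinate field on line 1")
})

test_that("PDB and mmCIF files round trip byte-for-byte with original coordinates", {
  pts <- generate_cloud(50, 20, "uniform_ball", seed = 7)
  pdb <- make_toy_pdb(pts)
  f <- write_fixture(pdb, ".pdb")
  m <- read_structure(f)
  expect_identical(write_structure(m, m$coords), pdb)

  cif <- charToRaw(toy_mmcif_text())
  fc <- write_fixture(cif, ".cif")
  mc <- read_structure(fc)
  expect_equal(mc$dialect, "mmcif")
  expect_equal(nrow(mc$coords), 3L)
  expect_equal(unname(mc$coords[2, ]), c(-4.25, 0.125, 10.5))
  expect_identical(write_structure(mc, mc$coords), cif)
})

test_that("atom order and count are stable across repeated reads", {
  f <- write_fixture(make_toy_pdb(generate_cloud(30, 10, seed = 2)), ".pdb")
  m1 <- read_structure(f)
  m2 <- read_structure(f)
  expect_identical(m1$coords, m2$coords)
  expect_identical(m1$atom_line, m2$atom_line)
})

test_that("writing replaces only the requested coordinate fields", {
  f <- write_fixture(charToRaw(one_atom_pdb_line()), ".pdb")
  m <- read_structure(f)
  out <- rawToChar(write_structure(m, cbind(1, 2.1, 3)))
  expect_equal(substr(out, 31, 54), "   1.000   2.100   3.000")
  expect_equal(substr(out, 1, 30), substr(one_atom_pdb_line(), 1, 30))
  expect_equal(substring(out, 55), substring(one_atom_pdb_line(), 55))
})

test_that("writing validates position count and field width", {
  f <- write_fixture(make_toy_pdb(generate_cloud(5, 10, seed = 1)), ".pdb")
  m <- read_structure(f)
  expect_error(write_structure(m, m$coords[1:3, ]), "3 rows")
  expect_error(write_structure(m, m$coords * 1e5), "overflows")
})

test_that("both ATOM and HETATM records are read, in file order", {
  txt <- paste0("ATOM      1  CA  GLY A   1       1.000   0.000   0.000",
                "  1.00  0.00           C\n",
                "HETATM    2  O   HOH A   2       2.000   0.000   0.000",
                "  1.00  0.00           O\n", "END\n")
  m <- read_structure(write_fixture(charToRaw(txt), ".pdb"))
  expect_equal(m$coords[, 1], c(1, 2))
})
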