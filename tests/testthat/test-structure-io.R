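test_that("PDB round trip preserves atom keys, coordinates and B-factors", {
  m <- make_claudin_like(25)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_structure(path)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  key <- function(a) paste(a$chain, a$resno, a$ins, a$elety, a$alt)
  expect_identical(key(m2$atoms), key(m$atoms))
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                    as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_lt(max(abs(m2$atoms$b - m$atoms$b)), 0.01)
})

test_that("reading a generated helix fixture yields the constructed atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_ideal_helix(helix_spec(20)), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(sum(m$atoms$elety == "CA"), 20)
})

test_that("the same fixture read from PDB and mmCIF gives identical C-alphas", {
  pdb <- system.file("extdata", "synthetic_helix.pdb", package = "cldngeom")
  cif <- system.file("extdata", "synthetic_helix.cif", package = "cldngeom")
  a <- read_structure(pdb)
  b <- suppressWarnings(read_structure(cif))
  ca <- select_calpha(a, "A", c(1, 20))
  cb <- select_calpha(b, "A", c(1, 20))
  expect_equal(ca$resno, cb$resno)
  expect_equal(as.matrix(ca[, c("x", "y", "z")]),
               as.matrix(cb[, c("x", "y", "z")]), tolerance = 1e-6)
  expect_equal(a$atoms$b, b$atoms$b, tolerance = 1e-6)
})

test_that("read errors are informative", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", bad)
  expect_error(read_structure(bad), "cannot infer format")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(suppressWarnings(read_structure(empty)))
})

test_that("select_calpha handles ranges, gaps and unknown chains", {
  m <- make_ideal_helix(helix_spec(10))
  sel <- select_calpha(m, "A", c(1, 10))
  expect_equal(nrow(sel), 10)
  expect_equal(sel$resno, 1:10)
  expect_error(select_calpha(m, "B", c(1, 10)), "unknown chain")
  expect_error(select_calpha(m, "A", c(40, 50)), "empty")
  # deletion: drop residue 5 -> 9 entries and the gap reported
  m_gap <- m
  m_gap$atoms <- m_gap$atoms[m_gap$atoms$resno != 5, ]
  sel <- select_calpha(m_gap, "A", c(1, 10))
  expect_equal(nrow(sel), 9)
  expect_equal(attr(sel, "missing_residues"), 5)
})

test_that("altloc selection takes the highest-occupancy conformer", {
  at <- data.frame(chain = "A", resno = c(1, 1, 2), ins = "",
                   resid = "ALA", elety = "CA", alt = c("A", "B", ""),
                   occ = c(0.3, 0.7, 1), b = 10,
                   x = c(0, 5, 1), y = 0, z = c(0, 0, 3.8))
  m <- structure_model("altloc_test", at)
  sel <- select_calpha(m, "A", c(1, 2))
  expect_equal(sel$x[sel$resno == 1], 5)  # the 0.7-occupancy conformer
  # tie -> lexicographically first altloc
  m$atoms$occ[1:2] <- 0.5
  sel <- select_calpha(m, "A", c(1, 2))
  expect_equal(sel$x[sel$resno == 1], 0)  # altloc "A"
})

test_that("structure_model enforces key uniqueness and finite coordinates", {
  at <- data.frame(chain = "A", resno = 1, ins = "", resid = "ALA",
                   elety = "CA", alt = "", occ = 1, b = 10,
                   x = 0, y = 0, z = 0)
  expect_error(structure_model("dup", rbind(at, at)), "duplicate")
  at$x <- NaN
  expect_error(structure_model("nan", at), "finite")
})

test_that("insertion codes in a geometry range are rejected", {
  at <- data.frame(chain = "A", resno = c(1, 2, 2, 3), ins = c("", "", "A", ""),
                   resid = "ALA", elety = "CA", alt = "", occ = 1, b = 10,
                   x = c(0, 1, 2, 3), y = 0, z = c(0, 3.8, 7.6, 11.4))
  m <- structure_model("ins", at)
  expect_error(select_calpha(m, "A", c(1, 3)), "insertion")
})
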