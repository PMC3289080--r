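# Hand-written mzXML snippets (built in code) exercise the reader edge
# cases; the synthetic writer covers the realistic path.

mini_mzxml <- function(path, scans) {
  enc <- function(mz, int) {
    jsonlite::base64_enc(writeBin(as.numeric(rbind(mz, int)), raw(),
                                  size = 8, endian = "big"))
  }
  body <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    sprintf(paste0(
      '  <scan num="%d" msLevel="%d" peaksCount="%d" retentionTime="%s">\n',
      '   <peaks precision="64" byteOrder="network" contentType="m/z-int"',
      ' compressionType="none" compressedLen="0">%s</peaks>\n  </scan>'),
      i, s$level, length(s$mz), s$rt, enc(s$mz, s$int))
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', length(scans)),
    body,
    ' </msRun>', ' <index name="scan"></index>',
    ' <indexOffset>0</indexOffset>', '</mzXML>'), path)
  path
}

test_that("the reader keeps MS1 scans only and parses ISO-8601 times", {
  path <- mini_mzxml(tempfile(fileext = ".mzXML"), list(
    list(level = 1, rt = "PT60S", mz = c(400.1, 402.2), int = c(1e5, 2e5)),
    list(level = 2, rt = "PT90S", mz = 150.1, int = 5e3),
    list(level = 1, rt = "PT120S", mz = c(400.1, 402.2), int = c(3e5, 4e5))))
  sc <- read_mzxml(path)
  expect_s3_class(sc, "scan_collection")
  expect_length(sc$times, 2L)
  expect_equal(sc$times, c(60, 120))
  expect_equal(sc$intensity[[2]], c(3e5, 4e5))
  expect_equal(sc$mz[[1]], c(400.1, 402.2), tolerance = 1e-9)
})

test_that("reader errors name the failure mode", {
  expect_error(read_mzxml(tempfile()), "not found")
  bad <- tempfile(fileext = ".mzXML")
  writeLines(c("<mzXML><msRun>", "<scan oops"), bad)
  expect_error(read_mzxml(bad), "malformed")
  ms2only <- mini_mzxml(tempfile(fileext = ".mzXML"), list(
    list(level = 2, rt = "PT10S", mz = 100.5, int = 1)))
  expect_error(read_mzxml(ms2only), "no MS1")
})

test_that("mzXML written by the synthetic module round-trips its peaks", {
  rp <- generate_run_pair(run_spec(n_peptides = 3, n_scans = 60,
                                   apex_range = c(1e5, 1e6),
                                   use_theoretical_r = TRUE, seed = 5))
  for (prec in c(32, 64)) {
    path <- tempfile(fileext = ".mzXML")
    write_mzxml_fixture(rp$run1, path, precision = prec)
    sc <- read_mzxml(path)
    expect_length(sc$times, 60L)
    tol <- if (prec == 32) 1e-4 else 1e-6
    for (k in seq_along(rp$run1)) {
      p <- rp$run1[[k]]
      xic <- extract_xic(sc, p$peptide$mz1, tol_ppm = 10)
      nz <- p$y1$intensities > 0
      expect_equal(xic$intensities[nz], p$y1$intensities[nz],
                   tolerance = tol)
      xic2 <- extract_xic(sc, p$peptide$mz2, tol_ppm = 10)
      nz2 <- p$y2$intensities > 0
      expect_equal(xic2$intensities[nz2], p$y2$intensities[nz2],
                   tolerance = tol)
    }
  }
  # zlib-compressed peaks decode identically
  pz <- tempfile(fileext = ".mzXML")
  write_mzxml_fixture(rp$run1, pz, precision = 64, compression = "zlib")
  scz <- read_mzxml(pz)
  expect_equal(scz$intensity, read_mzxml(path)$intensity, tolerance = 1e-12)
  expect_error(write_mzxml_fixture(list(), tempfile()), "empty run")
})

test_that("co-eluting peptides with separated m/z do not cross-contaminate", {
  rp <- generate_run_pair(run_spec(n_peptides = 2, n_scans = 50,
                                   apex_range = c(9e5, 1.1e6),
                                   use_theoretical_r = TRUE, seed = 2))
  path <- tempfile(fileext = ".mzXML")
  write_mzxml_fixture(rp$run1, path, precision = 64)
  sc <- read_mzxml(path)
  p1 <- rp$run1[[1]]; p2 <- rp$run1[[2]]
  xic1 <- extract_xic(sc, p1$peptide$mz1, tol_ppm = 10)
  nz <- p1$y1$intensities > 0
  expect_equal(xic1$intensities[nz], p1$y1$intensities[nz],
               tolerance = 1e-6)
  expect_gt(abs(p1$peptide$mz1 - p2$peptide$mz1), 0.04)
})

test_that("peptide lists validate their schema and rows", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(sequence = c("PEPTIDEK", "GASPR"), charge = c(2L, 3L),
                   elution_time = c(100.5, 220), probability = c(0.99, 0.8),
                   extra = c("x", "y"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_peptide_list(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$sequence, c("PEPTIDEK", "GASPR"))
  expect_type(rec$charge, "integer")

  bad <- df; bad$charge[2] <- 0L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_list(path), "row 2.*charge")

  bad <- df; bad$sequence[1] <- "PEPTIDEX1"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_list(path), "row 1.*non-residue")

  bad <- df; bad$elution_time[2] <- "soon"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_list(path), "row 2.*unparsable")

  write.table(df[, -3], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_list(path), "lacks column")
})

test_that("result tables round-trip at six significant digits", {
  res <- data.frame(sequence = c("PEPTIDEK", "GASPR"),
                    abundance_before_1 = c(1234567.1, 2.5e5),
                    abundance_before_2 = c(1534567.9, 2.5e5),
                    correctable = c(TRUE, FALSE),
                    abundance_after_1 = c(1834567.2, 2.5e5),
                    abundance_after_2 = c(2034167.8, 2.5e5),
                    fold_change = c(1.1088, 1.0),
                    p_value = c(0.2345678, 1))
  path <- tempfile(fileext = ".tsv")
  write_results(res, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("sequence", "abundance_before", "correctable",
                      "abundance_after", "fold_change", "p_value"))
  back <- read_results(path)
  for (col in setdiff(names(res), c("sequence", "correctable"))) {
    expect_equal(back[[col]], res[[col]], tolerance = 1e-5)
  }
  expect_equal(back$correctable, res$correctable)
  # uncorrectable rows carry identical before/after abundances
  expect_equal(back$abundance_after_2[2], back$abundance_before_2[2])
  expect_error(write_results(res[0, ], tempfile()), "non-empty")
})
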