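# MGF / mzML / mzXML readers and the inline CSV peak representation.

test_that("MGF blocks parse into spectra with title, pepmass and charge", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan one", "PEPMASS=500.25 12345",
               "CHARGE=2+", "100 10", "200 20", "300 30", "END IONS"), f)
  sp <- read_mgf(f)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$precursor_mz, 500.25)
  expect_equal(sp[[1]]$precursor_charge, 2L)
  expect_equal(sp[[1]]$native_id, "scan one")
  expect_equal(nrow(sp[[1]]$peaks), 3)
})

test_that("MGF reader handles empty files, absent charge and charge lists", {
  f <- tempfile(fileext = ".mgf")
  writeLines(character(0), f)
  expect_length(read_mgf(f), 0)
  writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=400", "100 1", "END IONS"), f)
  expect_true(is.na(read_mgf(f)[[1]]$precursor_charge))
  writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=400", "CHARGE=2+ and 3+",
               "100 1", "END IONS"), f)
  expect_warning(sp <- read_mgf(f), "ambiguous")
  expect_true(is.na(sp[[1]]$precursor_charge))
})

test_that("MGF reader reports truncation and bad peak lines precisely", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=t", "100 1"), f)
  expect_error(read_mgf(f), "truncation error: block 1")
  writeLines(c("BEGIN IONS", "TITLE=t", "100 notanumber", "END IONS"), f)
  expect_error(read_mgf(f), "line 3")
})

test_that("MGF reader agrees with pyteomics on a generated fixture", {
  fx <- fixture_spec(seed = 5, n_spectra = 3)
  truth <- generate_ground_truth(fx)
  f <- tempfile(fileext = ".mgf")
  write_mgf(lapply(truth$records, `[[`, "spectrum"), f)
  ours <- read_mgf(f)
  py <- system2("python", c("-c", shQuote(paste0(
    "from pyteomics import mgf\n",
    "import json\n",
    "out=[]\n",
    "for s in mgf.read('", f, "'):\n",
    "    out.append({'title': s['params']['title'],",
    " 'pepmass': s['params']['pepmass'][0],",
    " 'n': len(s['m/z array']), 'mzsum': float(s['m/z array'].sum())})\n",
    "print(json.dumps(out))"))), stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(py, collapse = ""), simplifyVector = FALSE)
  expect_length(ours, length(ref))
  for (k in seq_along(ours)) {
    expect_equal(ours[[k]]$native_id, ref[[k]]$title)
    expect_equal(ours[[k]]$precursor_mz, ref[[k]]$pepmass, tolerance = 1e-9)
    expect_equal(nrow(ours[[k]]$peaks), ref[[k]]$n)
    expect_equal(sum(ours[[k]]$peaks$mz), ref[[k]]$mzsum, tolerance = 1e-6)
  }
})

test_that("mzML reader yields MS2 scans only, with native ids and precursors", {
  s1 <- spectrum(500.25, 2, peaks = three_peaks(), native_id = "scan=1")
  s2 <- spectrum(600.5, 3, peaks = three_peaks(), native_id = "scan=2")
  f <- tempfile(fileext = ".mzML")
  write_mzml(list(s1, s2), f, ms1_stub = TRUE)  # file contains 1 MS1 + 2 MS2
  sp <- read_mzml(f)
  expect_length(sp, 2)
  expect_equal(sp[[1]]$native_id, "scan=1")
  expect_equal(sp[[1]]$precursor_mz, 500.25)
  expect_equal(sp[[2]]$precursor_charge, 3L)
})

test_that("64-bit little-endian peak arrays decode to the exact input floats", {
  set.seed(9)
  pk <- data.frame(mz = sort(stats::runif(40, 100, 2000)),
                   intensity = 10^stats::runif(40, 0, 6))
  s <- spectrum(900.123456789, 2, peaks = pk, native_id = "scan=7")
  f <- tempfile(fileext = ".mzML")
  write_mzml(list(s), f)
  back <- read_mzml(f)[[1]]
  expect_identical(back$peaks$mz, pk$mz)          # bit-exact
  expect_identical(back$peaks$intensity, pk$intensity)
})

test_that("malformed XML and missing precursors are handled", {
  f <- tempfile(fileext = ".mzML")
  writeLines("<mzML><run>", f)
  expect_error(read_mzml(f), "parse error")
  writeLines(paste0(
    '<mzML xmlns="http://psi.hupo.org/ms/mzml"><run id="r"><spectrumList count="1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="1">',
    '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
    '<binaryDataArrayList count="2"><binaryDataArray>',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000514" name="m/z array"/>',
    '<binary>', dnmso:::encode_doubles_b64(123.4), '</binary></binaryDataArray>',
    '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000515" name="intensity array"/>',
    '<binary>', dnmso:::encode_doubles_b64(1), '</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum></spectrumList></run></mzML>'), f)
  expect_warning(sp <- read_mzml(f), "precursor")
  expect_true(is.na(sp[[1]]$precursor_mz))
  expect_equal(sp[[1]]$peaks$mz, 123.4)
})

test_that("mzXML network-byte-order pairs round-trip and MS1 scans are skipped", {
  set.seed(10)
  pk <- data.frame(mz = sort(stats::runif(25, 100, 1500)),
                   intensity = stats::runif(25, 0, 1e6))
  s <- spectrum(777.7, 2, peaks = pk, retention_time_s = 12.5)
  f <- tempfile(fileext = ".mzXML")
  write_mzxml(list(s), f)
  back <- read_mzxml(f)
  expect_length(back, 1)
  expect_identical(back[[1]]$peaks$mz, pk$mz)
  expect_identical(back[[1]]$peaks$intensity, pk$intensity)
  expect_equal(back[[1]]$retention_time_s, 12.5)
  expect_equal(back[[1]]$native_id, "scan=1")
})

test_that("the same scan written to MGF, mzML and mzXML reads back identically", {
  fx <- fixture_spec(seed = 12, n_spectra = 4)
  truth <- generate_ground_truth(fx)
  d <- withr::local_tempdir()
  paths <- write_tool_outputs(truth, fx, d)
  a <- read_mgf(paths$mgf); b <- read_mzml(paths$mzml); x <- read_mzxml(paths$mzxml)
  expect_length(b, length(a))
  expect_length(x, length(a))
  for (k in seq_along(a)) {
    expect_equal(a[[k]]$peaks, b[[k]]$peaks, tolerance = 1e-12)
    expect_equal(a[[k]]$peaks, x[[k]]$peaks, tolerance = 1e-12)
    expect_equal(a[[k]]$precursor_mz, b[[k]]$precursor_mz)
    expect_equal(a[[k]]$precursor_charge, x[[k]]$precursor_charge)
  }
})

test_that("CSV representation is bit-exact and normalizing", {
  set.seed(11)
  for (k in 1:100) {
    s <- random_spectrum(sample(1:50, 1))
    s$id <- paste0("sp", k)
    back <- csv_to_spectrum(spectrum_to_csv(s))
    expect_identical(back$peaks$mz, s$peaks$mz)
    expect_identical(back$peaks$intensity, s$peaks$intensity)
    expect_identical(back$id, s$id)
    expect_identical(back$precursor_mz, s$precursor_mz)
    expect_identical(back$precursor_charge, s$precursor_charge)
  }
  # unsorted rows are sorted on ingestion
  txt <- "#id=x\n#precursor_mz=500\n#charge=2\n300,3\n100,1\n200,2\n"
  expect_equal(csv_to_spectrum(txt)$peaks$mz, c(100, 200, 300))
  expect_error(csv_to_spectrum("#id=x\n100,1,9\n"), "ragged CSV row 1")
  expect_error(csv_to_spectrum("#id=x\n100,-5\n"), "negative intensity")
})

test_that("format dispatch reads by extension", {
  fx <- fixture_spec(seed = 13, n_spectra = 2)
  truth <- generate_ground_truth(fx)
  d <- withr::local_tempdir()
  paths <- write_tool_outputs(truth, fx, d)
  expect_length(read_spectra(paths$mgf), 2)
  expect_length(read_spectra(paths$mzml), 2)
  expect_length(read_spectra(paths$mzxml), 2)
  expect_error(read_spectra("x.unknown"), "detect")
})
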