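test_that("flow_sample validates its matrix and marker names", {
  m <- matrix(1:6, 3, 2)
  fs <- flow_sample(m, c("CD3", "CD19"))
  expect_equal(n_cells(fs), 3L)
  expect_equal(n_markers(fs), 2L)
  expect_equal(fs$marker_names, c("CD3", "CD19"))

  expect_error(flow_sample(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(flow_sample(matrix(c(1, Inf, 3, 4), 2, 2)), "non-finite")
  expect_error(flow_sample(m, c("only_one")), "marker_names")
  expect_error(flow_sample(matrix(character(4), 2, 2)), "numeric")
  # default names
  expect_equal(flow_sample(m)$marker_names, c("M1", "M2"))
})

test_that("CSV reading handles headers, positions of errors, and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2", "3,4", "5,6"), path)
  fs <- read_csv_matrix(path)
  expect_equal(fs$marker_names, c("A", "B"))
  expect_equal(dim(fs$values), c(3L, 2L))
  expect_equal(fs$values[, "A"], c(1, 3, 5))  # order preserved

  writeLines(c("1,2", "3,4"), path)
  fs2 <- read_csv_matrix(path, has_header = FALSE)
  expect_equal(fs2$marker_names, c("M1", "M2"))
  expect_equal(fs2$values[1, ], c(M1 = 1, M2 = 2))

  # ragged row
  writeLines(c("A,B", "1,2", "3"), path)
  expect_error(read_csv_matrix(path), "ragged.*row 3", ignore.case = TRUE)
  # non-numeric cell names its location
  writeLines(c("A,B", "1,2", "3,oops"), path)
  expect_error(read_csv_matrix(path), "'oops' at row 3, column 2")
  # empty file
  writeLines(character(0), path)
  expect_error(read_csv_matrix(path), "empty")
  expect_error(read_csv_matrix("no/such/file.csv"), "not found")

  # write -> read round trip
  sim <- two_blob_sample(50)
  out <- withr::local_tempfile(fileext = ".csv")
  write_csv_matrix(sim$sample, out)
  back <- read_csv_matrix(out)
  expect_equal(back$values, sim$sample$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("arcsinh transform matches its closed form and is monotone", {
  fs <- flow_sample(matrix(c(0, sinh(1) * 5, 2, 7), 2, 2), c("A", "B"))
  tr <- transform_arcsinh(fs, cofactor = 5)
  expect_equal(unname(tr$values[1, 1]), 0)
  expect_equal(unname(tr$values[2, 1]), 1)
  expect_equal(tr$marker_names, fs$marker_names)

  v <- sort(runif(50, 0, 100))
  fs2 <- flow_sample(matrix(v, ncol = 1))
  expect_false(is.unsorted(transform_arcsinh(fs2, 5)$values[, 1]))
  expect_error(transform_arcsinh(fs, cofactor = 0), "positive")
  expect_error(transform_arcsinh(fs, cofactor = -1), "positive")
})

test_that("FCS write/read round-trips events, channel names and order", {
  sim <- gen_mixture_sample(
    mixture_spec(rbind(c(100, 200, 50)), n_cells = 100L,
                 marker_names = c("CD3", "CD5", "CD19")),
    seed = 3)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(sim$sample, path)
  back <- read_fcs(path)
  expect_equal(n_cells(back), 100L)
  expect_equal(n_markers(back), 3L)
  expect_equal(back$marker_names, c("CD3", "CD5", "CD19"))
  # float32 storage: relative agreement to 1e-6
  expect_equal(back$values, sim$sample$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  # FCS -> CSV -> flow_sample preserves values
  csv <- withr::local_tempfile(fileext = ".csv")
  write_csv_matrix(back, csv)
  again <- read_csv_matrix(csv)
  expect_equal(again$values, back$values, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("FCS reader raises distinct named errors", {
  expect_error(read_fcs("no/such/file.fcs"), class = "fcs_file_missing")

  bad <- withr::local_tempfile(fileext = ".fcs")
  writeLines("this is not an fcs file, just some text padding to 58+ bytes",
             bad)
  expect_error(read_fcs(bad), class = "fcs_header_error")

  # valid file, truncated data segment
  sim <- two_blob_sample(30)
  good <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(sim$sample, good)
  bytes <- readBin(good, "raw", file.info(good)$size)
  trunc <- withr::local_tempfile(fileext = ".fcs")
  writeBin(bytes[seq_len(length(bytes) - 50L)], trunc)
  expect_error(read_fcs(trunc), class = "fcs_truncated")

  # zero events: hand-built header + TEXT with $TOT 0
  text <- "/$PAR/1/$TOT/0/$MODE/L/$DATATYPE/F/$BYTEORD/1,2,3,4/$P1N/CD3/"
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", 58L,
                    58L + nchar(text) - 1L, 0L, 0L, 0L, 0L)
  empty <- withr::local_tempfile(fileext = ".fcs")
  con <- file(empty, "wb")
  writeChar(paste0(header, text), con, eos = NULL)
  close(con)
  expect_error(read_fcs(empty), class = "fcs_empty")
})

test_that("label CSV round-trips", {
  labels <- c(1L, 1L, 2L, 3L, 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(labels, path)
  expect_equal(read_labels_csv(path), labels)
})
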