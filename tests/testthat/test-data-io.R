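test_that("annotation JSON files are read with validation", {
  # hand-built JSON (independent of write_annotations)
  mk_scan <- function(i) sprintf(
    '{"scan_index": %d, "bmo": [[0, 0], [1500, 10]], "lc": [[400, 350], [750, 465]]}', i)
  doc <- sprintf(
    '{"eye_id": "OD-1", "axial_positive_is_posterior": true, "scans": [%s]}',
    paste(vapply(0:11, mk_scan, ""), collapse = ", "))
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(doc, path)
  ann <- read_annotations(path)
  expect_length(ann, 12L)
  expect_identical(attr(ann, "eye_id"), "OD-1")
  expect_identical(ann[[3]]$scan_index, 2L)
  expect_equal(ann[[1]]$lc[2, ], c(lateral_um = 750, axial_um = 465))

  # one scan with a single BMO point: validation error naming the scan
  bad <- sub('"bmo": \\[\\[0, 0\\], \\[1500, 10\\]\\], "lc": \\[\\[400, 350\\], \\[750, 465\\]\\]}]',
             '"bmo": [[0, 0]], "lc": [[400, 350]]}]', doc)
  writeLines(bad, path)
  expect_error(read_annotations(path), "scan 11.*2 BMO points")

  writeLines("{not json", path)
  expect_error(read_annotations(path), "malformed")
})

test_that("annotation write/read round-trips losslessly on random fixtures", {
  set.seed(42)
  for (rep in 1:10) {
    scans <- lapply(seq_len(sample(3:16, 1)), function(i) random_annotation())
    scans <- lapply(seq_along(scans), function(i) {
      s <- scans[[i]]; s$scan_index <- i - 1L; s
    })
    eye <- eye_annotations(scans, eye_id = sprintf("eye-%d", rep),
                           axial_positive_is_posterior = rep %% 2 == 0)
    path <- withr::local_tempfile(fileext = ".json")
    write_annotations(eye, path)
    back <- read_annotations(path)
    expect_identical(attr(back, "eye_id"), attr(eye, "eye_id"))
    expect_length(back, length(eye))
    for (i in seq_along(eye)) {
      expect_identical(back[[i]]$scan_index, eye[[i]]$scan_index)
      expect_equal(back[[i]]$bmo, eye[[i]]$bmo)
      expect_equal(back[[i]]$lc, eye[[i]]$lc)
    }
  }
})

test_that("landmark validation enforces the annotation invariants", {
  bmo <- rbind(c(0, 0), c(1000, 0))
  expect_error(bscan_annotation(0, rbind(c(5, 5), c(5, 5)), rbind(c(1, 1))),
               "coincident")
  expect_error(bscan_annotation(0, bmo, matrix(numeric(0), 0, 2)), "1 to 8")
  expect_error(bscan_annotation(0, bmo, matrix(1, 9, 2)), "1 to 8")
  expect_error(bscan_annotation(0, bmo, rbind(c(Inf, 1))), "finite")
  expect_error(bscan_annotation(-1, bmo, rbind(c(1, 1))), "non-negative")
})

test_that("cohort CSV reading builds ordered, validated subject series", {
  sim <- generate_cohort(cohort_config(), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  cohort <- read_cohort(path)
  expect_s3_class(cohort, "lcd_cohort")
  expect_length(cohort, 29L)
  expect_true(all(vapply(cohort, function(s) nrow(s$visits) == 5L,
                         logical(1))))
  expect_true(all(vapply(cohort, function(s) all(s$complete), logical(1))))

  # permutation invariance: shuffled rows and columns give identical output
  df <- sim$data
  set.seed(1)
  shuffled <- df[sample(nrow(df)), sample(ncol(df))]
  expect_identical(cohort_frame(as_lcd_cohort(shuffled)),
                   cohort_frame(cohort))
})

test_that("missing follow-up is flagged incomplete, schedule errors are hard", {
  sim <- generate_cohort(cohort_config(), seed = 3)
  df <- sim$data
  drop <- df$subject_id == "S01" & df$visit_label == "FUpv"
  cohort <- as_lcd_cohort(df[!drop, ])
  s01 <- cohort[[which(vapply(cohort, `[[`, "", "subject_id") == "S01")]]
  expect_false(s01$complete[["FUpv"]])
  expect_true(all(s01$complete[c("base", "1pv", "3pv", "6pv")]))

  dup <- rbind(df, df[df$subject_id == "S02" & df$visit_label == "3pv", ])
  expect_error(as_lcd_cohort(dup), "duplicate")

  bad <- df
  bad$t_months[bad$subject_id == "S03" & bad$visit_label == "FUpv"] <- 5
  expect_error(as_lcd_cohort(bad), "non-monotone|not strictly increasing")

  bad2 <- df
  bad2$t_months[bad2$subject_id == "S04" & bad2$visit_label == "base"] <- 0.5
  expect_error(as_lcd_cohort(bad2), "baseline visit")
})

test_that("supplementary XLSX ingestion matches the CSV path via a mapping", {
  sim <- generate_cohort(cohort_config(n_subjects = 8L), seed = 11)
  csv_cohort <- sim$cohort

  # spreadsheet mimic with renamed, reordered columns
  alien_names <- c(subject_id = "Patient ID", visit_label = "Visit",
                   t_months = "Months after surgery", iop_mmHg = "IOP",
                   rnfl_G = "RNFL G", rnfl_TS = "RNFL TS", rnfl_T = "RNFL T",
                   rnfl_TI = "RNFL TI", rnfl_NS = "RNFL NS",
                   rnfl_N = "RNFL N", rnfl_NI = "RNFL NI",
                   lcd_um = "LCD [um]", age_years = "Age",
                   surgery = "Procedure")
  df <- sim$data[, names(alien_names)]
  df <- df[, sample(ncol(df))]
  renamed <- alien_names[names(df)]
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_xlsx_via_python(df, xlsx, colnames = unname(renamed))

  mapping <- stats::setNames(unname(alien_names), names(alien_names))
  got <- suppressMessages(ingest_supplementary(xlsx, mapping))
  keep <- names(alien_names)
  expect_equal(cohort_frame(got)[, keep], cohort_frame(csv_cohort)[, keep],
               tolerance = 1e-8)

  # mapping file in key=value form works the same
  map_file <- withr::local_tempfile(fileext = ".cfg")
  writeLines(paste0(names(mapping), "=", mapping), map_file)
  got2 <- suppressMessages(ingest_supplementary(xlsx, map_file))
  expect_equal(cohort_frame(got2), cohort_frame(got))

  # unmappable required column: error listing the sheet's candidates
  expect_error(
    ingest_supplementary(xlsx, c(subject_id = "No Such Column",
                                 visit_label = "Visit",
                                 t_months = "Months after surgery")),
    "subject_id.*Patient ID")

  # empty sheet: empty cohort plus warning
  empty_xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_xlsx_via_python(df[0, ], empty_xlsx, colnames = unname(renamed))
  expect_warning(got3 <- ingest_supplementary(empty_xlsx, mapping), "empty")
  expect_length(got3, 0L)
})
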