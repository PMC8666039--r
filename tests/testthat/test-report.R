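# A small fully processed plate shared by the report tests.
processed_result <- local({
  sim <- NULL
  res <- NULL
  function() {
    if (is.null(res)) {
      sim <<- small_sim(seed = 303)
      qc <- qc_plate(sim$curves, signal_threshold = 50)
      processed <- preprocess_plate(qc$accepted)
      fits <- fit_plate(processed)
      fits_ann <- dplyr::left_join(fits,
                                   sim$map[, c("well", "compound_id", "role")],
                                   by = "well")
      cs <- control_stats(fits_ann)
      hits <- call_hits(aggregate_replicates(
        fits_ann[fits_ann$role == "sample", ]), cs)
      res <<- plate_result("10001", sim$map, qc$report, fits, hits, cs)
    }
    list(result = res, sim = sim)
  }
})

test_that("plate_result accounts for every mapped well exactly once", {
  pr <- processed_result()$result
  expect_equal(nrow(pr$wells), 96)
  expect_equal(anyDuplicated(pr$wells$well), 0)
  fitted <- sum(pr$wells$converged, na.rm = TRUE)
  flagged <- sum(!pr$wells$accepted, na.rm = TRUE)
  expect_equal(fitted + flagged, 96)
})

test_that("results SDF carries the added properties and round-trips", {
  pr <- processed_result()$result
  path <- tempfile(fileext = ".sdf")
  write_results_sdf(pr, path)
  back <- read_sdf_platemap(path, geometry = "96")
  expect_equal(nrow(back), 96)
  expect_true(all(c("Tm", "RSE", "dTm", "abs_dTm", "hit", "QC_flags") %in%
                    names(back)))
  # numeric fidelity through the text round trip
  expect_equal(as.numeric(back$Tm), pr$wells$tm, tolerance = 1e-12)
  expect_equal(as.numeric(back$dTm), pr$wells$delta_tm, tolerance = 1e-12)
  expect_equal(ifelse(back$hit == "", NA, back$hit == "true"),
               pr$wells$hit)
})

test_that("the CSV twin matches the SDF contents", {
  pr <- processed_result()$result
  sp <- tempfile(fileext = ".sdf")
  cp <- tempfile(fileext = ".csv")
  write_results_sdf(pr, sp)
  write_results_csv(pr, cp)
  from_sdf <- read_sdf_platemap(sp, geometry = "96")
  from_csv <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(nrow(from_csv), 96)
  expect_equal(from_csv$Compound_ID, from_sdf$compound_id)
  expect_equal(from_csv$Tm, as.numeric(from_sdf$Tm), tolerance = 1e-12)
})

test_that("flagged wells appear in results with empty fit fields", {
  sim <- small_sim(seed = 404, anomalies = list(
    list(well = "A3", kind = "flat")))
  qc <- qc_plate(sim$curves, signal_threshold = 50)
  processed <- preprocess_plate(qc$accepted)
  fits <- fit_plate(processed)
  fits_ann <- dplyr::left_join(fits,
                               sim$map[, c("well", "compound_id", "role")],
                               by = "well")
  cs <- control_stats(fits_ann)
  hits <- call_hits(aggregate_replicates(
    fits_ann[fits_ann$role == "sample", ]), cs)
  pr <- plate_result("10001", sim$map, qc$report, fits, hits, cs)
  rec <- pr$wells[pr$wells$well == "A3", ]
  expect_equal(rec$flags, "LOW_SIGNAL")
  expect_true(is.na(rec$tm))
  path <- tempfile(fileext = ".sdf")
  write_results_sdf(pr, path)
  back <- read_sdf_platemap(path, geometry = "96")
  a3 <- back[back$well == "A3", ]
  expect_equal(a3$QC_flags, "LOW_SIGNAL")
  expect_equal(a3$Tm, "")
})

test_that("original plate-map properties pass through to the results SDF", {
  map <- toy_map()
  sdf_path <- tempfile(fileext = ".sdf")
  write_platemap_sdf(map, sdf_path, control_smiles = "CS(C)=O")
  map2 <- read_sdf_platemap(sdf_path)
  qc_report <- tibble::tibble(well = map2$well, row = map2$row,
                              column = map2$column, flags = "",
                              accepted = TRUE, signal_range = 1000,
                              max_step_ratio = 2, t_at_min = 30,
                              t_at_max = 90)
  fits <- tibble::tibble(well = map2$well, row = map2$row,
                         column = map2$column, tm = c(51, 50.2, 50, 50.1),
                         rse = 0.01, converged = TRUE,
                         compound_id = map2$compound_id)
  cs <- control_stats(fits)
  hits <- call_hits(aggregate_replicates(fits[fits$compound_id != "DMSO", ]),
                    cs)
  pr <- plate_result("10001", map2, qc_report, fits, hits, cs)
  out <- tempfile(fileext = ".sdf")
  write_results_sdf(pr, out)
  back <- read_sdf_platemap(out)
  expect_equal(back$Batch, c("B-7", "B-8", "", ""))
})

test_that("workbook has the five sheets with faithful numeric cells", {
  skip_if_not_installed("readxl")
  pr <- processed_result()$result
  path <- tempfile(fileext = ".xlsx")
  write_workbook(pr, path)
  sheets <- readxl::excel_sheets(path)
  expect_identical(sheets, c("Plate Heatmap",
                             "Fit Results with hits annotated",
                             "DMSO mean and SD",
                             "Fitted Melting Curves",
                             "Melting Curves"))
  heat <- readxl::read_excel(path, sheet = "Plate Heatmap")
  expect_equal(dim(heat), c(8, 13))  # 96-well: 8 rows x (row label + 12)
  # heatmap cell (r, c) equals the fitted Tm of well (r, c)
  w <- pr$wells
  expect_equal(heat[[as.character(5)]][2],
               w$tm[w$row == 2 & w$column == 5])
  fitres <- readxl::read_excel(path, sheet = 2)
  expect_equal(nrow(fitres), 96)
  expect_equal(fitres$tm, w$tm)
  expect_equal(fitres$hit, as.logical(w$hit))
  dmso <- readxl::read_excel(path, sheet = 3)
  expect_equal(dmso$control_tm, pr$controls$mean_tm)
  # threshold identity: absolute variant = mean + 3 x SD variant
  expect_equal(dmso$hit_threshold_abs,
               dmso$control_tm + dmso$hit_threshold_3sd)
  fitted_sheet <- readxl::read_excel(path, sheet = 4)
  expect_equal(nrow(fitted_sheet), sum(pr$fits$converged))
  curves_sheet <- readxl::read_excel(path, sheet = 5)
  expect_equal(nrow(curves_sheet), 6)
})

test_that("heatmaps render at plate and screen level with hit overlays", {
  pr <- processed_result()$result
  p1 <- render_heatmap(pr, "plate")
  expect_s3_class(p1, "ggplot")
  n_hit_wells <- sum(pr$wells$hit, na.rm = TRUE)
  overlay <- p1$layers[[2]]$data
  expect_equal(nrow(overlay), n_hit_wells)

  p2 <- render_heatmap(list(pr, pr), "screen")
  built <- ggplot2::ggplot_build(p2)
  expect_equal(length(unique(built$layout$layout$PANEL)), 1)

  pr2 <- pr
  pr2$plate_id <- "10002"
  pr2$wells$plate_id <- "10002"
  p3 <- render_heatmap(list(pr, pr2), "screen")
  built3 <- ggplot2::ggplot_build(p3)
  expect_equal(length(unique(built3$layout$layout$PANEL)), 2)

  f <- tempfile(fileext = ".png")
  render_heatmap(pr, "plate", file = f)
  expect_true(file.size(f) > 0)
})

test_that("consolidation sums record counts and is idempotent", {
  pr <- processed_result()$result
  root <- tempfile()
  results_dir <- file.path(root, "Results")
  dir.create(results_dir, recursive = TRUE)
  write_results_sdf(pr, file.path(results_dir, "plate1.sdf"))
  pr2 <- pr
  pr2$wells$plate_id <- "10002"
  pr2$map$plate_id <- "10002"
  pr2$plate_id <- "10002"
  write_results_sdf(pr2, file.path(results_dir, "plate2.sdf"))

  combined <- consolidate(results_dir, format = "sdf")
  expect_equal(nrow(combined), 192)
  expect_setequal(unique(combined$source_file),
                  c("plate1.sdf", "plate2.sdf"))
  out_files <- list.files(file.path(root, "Consolidated"))
  expect_setequal(out_files, c("consolidated.sdf", "consolidated.xlsx"))
  # outputs live outside the scanned folder: re-running is identical
  combined2 <- consolidate(results_dir, format = "sdf")
  expect_equal(tibble::as_tibble(combined), tibble::as_tibble(combined2))
})

test_that("consolidation unites disjoint columns and guards bad folders", {
  root <- tempfile()
  rd <- file.path(root, "Results")
  dir.create(rd, recursive = TRUE)
  readr::write_csv(tibble::tibble(Compound_ID = "A", Tm = 50, Extra1 = "x"),
                   file.path(rd, "a.csv"))
  readr::write_csv(tibble::tibble(Compound_ID = "B", Tm = 51, Extra2 = "y"),
                   file.path(rd, "b.csv"))
  combined <- consolidate(rd, format = "csv")
  expect_equal(nrow(combined), 2)
  expect_true(all(c("Extra1", "Extra2") %in% names(combined)))
  expect_true(is.na(combined$Extra2[combined$Compound_ID == "A"]))

  empty <- file.path(root, "Empty")
  dir.create(empty)
  expect_error(consolidate(empty, format = "csv"), "no .csv")
  writeLines("x", file.path(rd, "stray.sdf"))
  expect_error(consolidate(rd), "mixes")
})

test_that("workbook writer stores exact numbers and escapes strings", {
  skip_if_not_installed("readxl")
  df <- data.frame(name = c("a<b", "c&d"), value = c(pi, 1 / 3),
                   ok = c(TRUE, FALSE))
  path <- tempfile(fileext = ".xlsx")
  write_xlsx_workbook(list("S1" = df), path)
  back <- readxl::read_excel(path)
  expect_equal(back$name, c("a<b", "c&d"))
  expect_identical(back$value, c(pi, 1 / 3))
  expect_error(write_xlsx_workbook(
    list("this sheet name is way too long for the xlsx format" = df),
    tempfile(fileext = ".xlsx")), "31")
})
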