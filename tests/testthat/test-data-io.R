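toyDir <- system.file("extdata", "toy_dta", package = "dtafuse")

test_that("toy benchmark loads with one record per measured cell", {
  ds <- suppressMessages(loadDTADataset(toyDir, transform = "none"))
  expect_s4_class(ds, "DTADataset")
  expect_length(ligands(ds), 2)
  expect_length(proteins(ds), 2)
  expect_equal(nrow(affinityRecords(ds)), 3)   # 2x2 grid, one NA cell
  expect_true(is.na(affinityMatrix(ds)["D001", "T002"]))
  expect_equal(
    affinityRecords(ds)$affinity[
      affinityRecords(ds)$drug_id == "D002" &
      affinityRecords(ds)$target_id == "T001"], 6.8)
})

test_that("missing files and unresolvable IDs raise named errors", {
  expect_error(loadDTADataset(tempdir()), "ligands.json")
  bad <- file.path(tempdir(), "badds")
  dir.create(bad, showWarnings = FALSE)
  file.copy(list.files(toyDir, full.names = TRUE), bad, overwrite = TRUE)
  aff <- read.csv(file.path(bad, "affinity.csv"), row.names = 1,
                  check.names = FALSE)
  rownames(aff) <- c("D001", "DXXX")
  write.csv(aff, file.path(bad, "affinity.csv"))
  expect_error(suppressMessages(loadDTADataset(bad)), "resolve")
})

test_that("the nM -> pKd transform is applied for Davis-style data", {
  d <- file.path(tempdir(), "davis_toy")
  dir.create(d, showWarnings = FALSE)
  jsonlite::write_json(list(D1 = "CCO"), file.path(d, "ligands.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(T1 = "ACDEF"), file.path(d, "proteins.json"),
                       auto_unbox = TRUE)
  write.csv(matrix(10000, 1, 1, dimnames = list("D1", "T1")),
            file.path(d, "affinity.csv"))
  ds <- suppressMessages(loadDTADataset(d, name = "davis"))
  expect_equal(affinityRecords(ds)$affinity, 5)  # -log10(1e4 / 1e9)
})

test_that("write + reload round-trips the record set exactly", {
  ds <- generateSyntheticBenchmark(
    synthConfig(nDrugs = 8L, nProteins = 5L, missingFrac = 0.2, seed = 3))
  d <- file.path(tempdir(), "roundtrip")
  writeDTADataset(ds, d)
  ds2 <- suppressMessages(loadDTADataset(d, transform = "none"))
  expect_equal(ligands(ds2), ligands(ds))
  expect_equal(proteins(ds2), proteins(ds))
  r1 <- affinityRecords(ds); r2 <- affinityRecords(ds2)
  expect_equal(r2[order(r2$drug_id, r2$target_id), ],
               r1[order(r1$drug_id, r1$target_id), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("DPI pairs load and subsample to the requested class ratio", {
  path <- system.file("extdata", "toy_dpi.tsv", package = "dtafuse")
  df <- loadDPIPairs(path)
  expect_equal(nrow(df), 6)
  expect_equal(sum(df$label == 1), 2)

  # 2 pos + 4 neg at 1:1 -> keep 2 of each
  df11 <- loadDPIPairs(path, negRatio = 1, seed = 4)
  expect_equal(sum(df11$label == 0), 2)
  expect_equal(sum(df11$label == 1), 2)
  # 1:2 keeps all four negatives
  df12 <- loadDPIPairs(path, negRatio = 2, seed = 4)
  expect_equal(sum(df12$label == 0), 4)
  expect_error(loadDPIPairs(path, negRatio = 5), "only 4 negatives")
})

test_that("DPI pairs convert to a dataset driving the shared machinery", {
  path <- system.file("extdata", "toy_dpi.tsv", package = "dtafuse")
  ds <- dpiToDataset(loadDPIPairs(path))
  expect_s4_class(ds, "DTADataset")
  expect_equal(nrow(affinityRecords(ds)), 6)
  expect_true(all(affinityRecords(ds)$affinity %in% c(0, 1)))
})
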