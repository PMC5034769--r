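test_that("reading a 3-row file yields the hand-computed totals", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(data.frame(species = c("a", "b", "c"),
                           leaf_mass_g = c(1, 10, 0.5),
                           stem_mass_g = c(2, 20, 0.1),
                           root_mass_g = c(3, 30, 0.4)), path)
  ds <- read_biomass(path)
  expect_s3_class(ds, "biomass_data")
  expect_equal(nrow(ds), 3L)
  expect_equal(total_mass(ds), c(6, 60, 1.0))
})

test_that("nonpositive masses are fatal in strict mode, skipped otherwise", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(data.frame(species = c("a", "b"),
                           leaf_mass_g = c(1, 2),
                           stem_mass_g = c(1, 2),
                           root_mass_g = c(0, 2)), path)
  expect_error(read_biomass(path, biomass_dialect(strict = TRUE)), "row 1")
  ds <- read_biomass(path)
  expect_equal(nrow(ds), 1L)
  rep <- validation_report(ds)
  expect_equal(rep$n_rejected, 1L)
  expect_equal(rep$errors[[1]]$row, 1L)
})

test_that("a missing mandatory column is reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(data.frame(species = "a", leaf_mass_g = 1,
                           stem_mass_g = 1), path)
  expect_error(read_biomass(path), "root_mass_g")
})

test_that("column mapping and unit factor adapt a foreign layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(taxon = "x", lf = 1, st = 2, rt = 3),
                     path, sep = "\t", row.names = FALSE)
  ds <- read_biomass(path, biomass_dialect(
    sep = "\t",
    col_map = c(species = "taxon", leaf_mass_g = "lf",
                stem_mass_g = "st", root_mass_g = "rt"),
    unit_factor = 1000))  # masses in kg
  expect_equal(ds$leaf_mass_g, 1000)
  expect_equal(total_mass(ds), 6000)
})

test_that("write -> read round trip reproduces every field exactly", {
  ds <- generate_fixed(100, noise_sd = 0.2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_biomass(ds, path)
  back <- read_biomass(path)
  for (col in c("record_id", "species", "family", "leaf_mass_g",
                "stem_mass_g", "root_mass_g")) {
    expect_identical(back[[col]], ds[[col]], label = col)
  }
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_biomass(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("group label vocabulary and exclusivity are enforced", {
  df <- data.frame(species = "a", leaf_mass_g = 1, stem_mass_g = 1,
                   root_mass_g = 1, group_labels = "evergreen;deciduous")
  expect_error(biomass_data(df), "mutually exclusive")
  df$group_labels <- "everblue"
  expect_error(biomass_data(df), "unknown group label")
  df$group_labels <- "evergreen;gymnosperm"
  expect_s3_class(biomass_data(df), "biomass_data")
})

test_that("filter atoms remove the right records and report counts", {
  df <- data.frame(
    species = c(rep("A", 5), rep("B", 3)),
    family = c(rep("famA", 5), rep("famB", 3)),
    leaf_mass_g = 1:8, stem_mass_g = 1:8, root_mass_g = 1:8)
  ds <- biomass_data(df)
  kept <- filter_records(ds, min_records_per_species = 4)
  expect_equal(unique(kept$species), "A")
  expect_equal(unname(attr(kept, "filter_counts")["min_records_per_species"]),
               3L)

  # mass filter: totals are 3 * (1:8); keep > 9 g
  kept2 <- filter_records(ds, mass_range = c(9.0001, Inf))
  expect_equal(nrow(kept2), 5L)

  expect_error(filter_records(ds, min_records_per_specis = 4),
               "unknown filter atom")
})

test_that("family filter counts only species passing the record threshold", {
  # famA: 2 qualifying species; famB: 2 species but only 1 qualifies;
  # famC: 1 species
  df <- data.frame(
    species = c(rep("a1", 4), rep("a2", 4), rep("b1", 4), rep("b2", 2),
                rep("c1", 6)),
    family = c(rep("famA", 8), rep("famB", 6), rep("famC", 6)),
    leaf_mass_g = 1, stem_mass_g = 1, root_mass_g = 1)
  df$leaf_mass_g <- seq_len(nrow(df))  # unique masses
  ds <- biomass_data(df)
  kept <- filter_records(ds, min_records_per_species = 4,
                         min_species_per_family = 2)
  expect_setequal(unique(kept$family), "famA")
})

test_that("filters are idempotent and a no-op filter keeps every record", {
  ds <- generate_fixed(200, seed = 3, n_species = 20)
  expect_equal(nrow(filter_records(ds)), 200L)
  df <- data.frame(species = c(rep("A", 5), rep("B", 3)),
                   leaf_mass_g = 1:8, stem_mass_g = 1, root_mass_g = 1)
  ds2 <- biomass_data(df)
  once <- filter_records(ds2, min_records_per_species = 4)
  twice <- filter_records(once, min_records_per_species = 4)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_true(all(attr(twice, "filter_counts") == 0L))
  expect_equal(unname(attr(once, "filter_counts")["min_records_per_species"]),
               3L)
})

test_that("outlier diagnostic flags a planted deviant record but keeps it", {
  ds <- generate_fixed(500, noise_sd = 0.05, seed = 9)
  ds$leaf_mass_g[250] <- ds$leaf_mass_g[250] * 1e4  # gross deviation
  ds2 <- biomass_data(as.data.frame(ds))
  flags <- flag_outlier_records(ds2, "leaf", "stem", threshold = 4)
  expect_true(flags$flagged[250])
  expect_lt(sum(flags$flagged), 5L)
  expect_equal(nrow(flags), 500L)  # nothing removed
})
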