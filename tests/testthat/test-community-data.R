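test_that("taxon set has unique ids and exactly five key species", {
  tx <- guild_taxa()
  expect_equal(anyDuplicated(tx$taxon_id), 0L)
  expect_setequal(key_taxa(tx), c("AlotL1", "AlotL2", "Tgut", "Tsept",
                                  "Tspe"))
  expect_equal(sum(tx$is_key), 5L)
})

test_that("loading colony tables builds records with empty assemblages", {
  paths <- write_mini_tables()
  cs <- load_colony_tables(paths$colonies, paths$occupancy)
  expect_s3_class(cs, "colony_set")
  expect_equal(cs$colonies$colony_id, c("c1", "c2"))
  expect_equal(nrow(cs$occupancy), 1L)
  # c2 has an empty assemblage but keeps its row
  m <- to_incidence(cs, taxa = key_taxa())
  expect_equal(unname(rowSums(m)), c(1, 0))
  expect_equal(abundance(m)["c1", "Tgut"], 2L)
  expect_equal(m["c1", "Tgut"], 1L)
})

test_that("header-only colony table gives an empty colony set", {
  dir <- tempfile(); dir.create(dir)
  colony_csv <- file.path(dir, "colonies.csv")
  occ_csv <- file.path(dir, "occupancy.csv")
  writeLines("colony_id,region,site,stage,host_type,L_cm,l_cm", colony_csv)
  writeLines("colony_id,taxon_id,count", occ_csv)
  cs <- load_colony_tables(colony_csv, occ_csv)
  expect_equal(nrow(cs$colonies), 0L)
  expect_equal(nrow(cs$occupancy), 0L)
})

test_that("validation rejects unknown taxa, duplicates and bad counts", {
  paths <- write_mini_tables()
  bad_occ <- file.path(dirname(paths$occupancy), "bad.csv")

  writeLines(c("colony_id,taxon_id,count", "c1,NOPE,1"), bad_occ)
  expect_error(load_colony_tables(paths$colonies, bad_occ),
               "unknown taxon_id 'NOPE'.*row 1")

  writeLines(c("colony_id,taxon_id,count", "c1,Tgut,0"), bad_occ)
  expect_error(load_colony_tables(paths$colonies, bad_occ),
               "count must be >= 1")

  dup_col <- file.path(dirname(paths$colonies), "dup.csv")
  writeLines(c("colony_id,region,site,stage,host_type,L_cm,l_cm",
               "c1,RI,LI,adult,beta,,", "c1,RI,LI,adult,beta,,"), dup_col)
  expect_error(load_colony_tables(dup_col, paths$occupancy),
               "duplicate colony_id")
})

test_that("implausible sizes for a stage warn but do not fail", {
  dir <- tempfile(); dir.create(dir)
  colony_csv <- file.path(dir, "colonies.csv")
  occ_csv <- file.path(dir, "occupancy.csv")
  writeLines(c("colony_id,region,site,stage,host_type,L_cm,l_cm",
               "j1,RI,LI,juvenile,beta,12,8"), colony_csv)
  writeLines("colony_id,taxon_id,count", occ_csv)
  expect_warning(load_colony_tables(colony_csv, occ_csv),
                 "juvenile colonies with diameter > 5 cm")
})

test_that("planar area is the ellipse formula with argument checks", {
  expect_equal(planar_area(30, 20), pi * 30 * 20 / 4)
  expect_equal(planar_area(30, 20), 471.238898, tolerance = 1e-8)
  d <- 7
  expect_equal(planar_area(d, d), pi * d^2 / 4)   # circle
  expect_equal(planar_area(0, 0), 0)
  expect_error(planar_area(10, 20), "cannot exceed")
  expect_error(planar_area(-1, -2), "non-negative")
})

test_that("stratum selection reproduces the analysis strata of the survey", {
  s <- coral_survey()
  expect_equal(nrow(s$colonies), 234L)
  expect_equal(nrow(select_stratum(s, region = "RI",
                                   stage = "adult")$colonies), 61L)
  expect_equal(nrow(select_stratum(s, region = "NC", stage = "adult",
                                   host_type = "alpha")$colonies), 48L)
  expect_equal(nrow(select_stratum(s, region = "NC", stage = "adult",
                                   host_type = "beta")$colonies), 11L)
  expect_equal(nrow(select_stratum(s, region = "RI",
                                   stage = "juvenile")$colonies), 56L)
  expect_equal(nrow(select_stratum(s, region = "NC", stage = "juvenile",
                                   host_type = "alpha")$colonies), 40L)
  # no selectors: identity
  expect_identical(select_stratum(s)$colonies, s$colonies)
  # empty result allowed
  expect_equal(nrow(select_stratum(s, region = "RI", stage = "adult",
                                   host_type = "alpha")$colonies), 0L)
  expect_error(select_stratum(s, region = "XX"), "region must be in")
})

test_that("incidence matrices respect drop_empty and column order", {
  s <- coral_survey()
  ri <- select_stratum(s, region = "RI", stage = "adult")
  m <- to_incidence(ri, taxa = key_taxa(), drop_empty = FALSE)
  expect_equal(dim(m), c(61L, 5L))
  expect_equal(colnames(m), c("AlotL1", "AlotL2", "Tgut", "Tsept", "Tspe"))
  m_drop <- to_incidence(ri, taxa = key_taxa(), drop_empty = TRUE)
  expect_equal(nrow(m_drop), sum(rowSums(m) > 0))
  # order of `taxa` argument does not matter; declaration order wins
  m_shuffled <- to_incidence(ri, taxa = rev(key_taxa()))
  expect_identical(unclass(m_shuffled), unclass(m))
  expect_error(to_incidence(ri, taxa = character(0)), "non-empty")
})

test_that("write/load round trip reproduces the fixture tables", {
  s <- coral_survey()
  dir <- tempfile(); dir.create(dir)
  out_c <- file.path(dir, "colonies.csv")
  out_o <- file.path(dir, "occupancy.csv")
  write_colony_tables(s, out_c, out_o)
  s2 <- load_colony_tables(out_c, out_o)
  expect_equal(s2$colonies, s$colonies)
  expect_equal(s2$occupancy, s$occupancy)
  # cell-identical files against the packaged originals
  orig <- system.file("extdata", c("colonies.csv", "occupancy.csv"),
                      package = "coralguild")
  expect_identical(readLines(out_c), readLines(orig[1]))
  expect_identical(readLines(out_o), readLines(orig[2]))
})
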