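test_that("a single-record mpa file parses to a 1x1 species-level table", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#Classification\tS1",
               paste0(strep_lineage("Streptococcus sanguinis"), "\t10")), f)
  tab <- read_mpa_table(f)
  expect_equal(dim(tab), c(1L, 1L))
  expect_equal(tab$rank, "species")
  expect_equal(unname(tab$counts[1, 1]), 10)
})

test_that("species-level subsetting keeps exactly the s__ rows, counts intact", {
  f <- write_mpa_fixture()
  tab <- read_mpa_table(f)
  sp <- species_level(tab)
  # independent oracle: count lineage lines ending at species rank in the file
  raw <- readLines(f)[-1]
  lin <- sub("\t.*", "", raw)
  n_species <- sum(grepl("s__", lin, fixed = TRUE))
  expect_equal(nrow(sp$counts), n_species)
  expect_equal(nrow(sp$counts), 3L)
  expect_equal(sp$counts, tab$counts[tab$rank == "species", , drop = FALSE])
})

test_that("duplicate lineages and non-numeric cells are hard errors", {
  f <- tempfile(fileext = ".tsv")
  lin <- strep_lineage("Streptococcus mitis")
  writeLines(c("#Classification\tS1",
               paste0(lin, "\t1"), paste0(lin, "\t2")), f)
  expect_error(read_mpa_table(f), "duplicate lineage")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("#Classification\tS1\tS2",
               paste0(lin, "\t3\tx")), f2)
  expect_error(read_mpa_table(f2), "non-numeric.*S2")
})

test_that("k__ prefixes are accepted as domain aliases", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#Classification\tS1", "k__Bacteria\t7"), f)
  tab <- read_mpa_table(f)
  expect_equal(tab$rank, "domain")
})

test_that("mpa write/read round-trips counts exactly", {
  tab <- arith_table()
  f <- tempfile(fileext = ".tsv")
  write_mpa_table(tab, f)
  back <- read_mpa_table(f)
  expect_identical(back$lineage, tab$lineage)
  expect_equal(back$counts, tab$counts)
})

test_that("ANI matrices read symmetric with forced diagonal", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome\tg1\tg2", "g1\t100\t96.3", "g2\t96.3\t100"), f)
  m <- read_ani_matrix(f)
  expect_equal(diag(unclass(m)), c(g1 = 100, g2 = 100))
  expect_equal(m["g1", "g2"], 96.3)
  expect_equal(unclass(m), t(unclass(m)))
})

test_that("asymmetry beyond tolerance is rejected with the offending pair", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome\tg1\tg2", "g1\t100\t96.3", "g2\t91.0\t100"), f)
  expect_error(read_ani_matrix(f), "asymmetric.*g1/g2")
})

test_that("missing ANI pairs are imputed at the floor with a warning", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome\tg1\tg2", "g1\t100\tNA", "g2\tNA\t100"), f)
  expect_warning(m <- read_ani_matrix(f), "imputed")
  expect_equal(m["g1", "g2"], 70)
})

test_that("a planted ANI matrix round-trips bit-identically", {
  fx <- block_ani_fixture()
  f <- tempfile(fileext = ".tsv")
  write_ani_matrix(fx$ani, f)
  back <- read_ani_matrix(f)
  expect_identical(unclass(back), unclass(fx$ani))
})

test_that("long-result writer is deterministic and round-trips", {
  f <- tempfile(fileext = ".tsv")
  # empty collection: header-only file
  write_long_results(data.frame(a = character(0), b = numeric(0)), f)
  expect_equal(length(readLines(f)), 1L)
  # two records sort by key regardless of insertion order
  r1 <- data.frame(a = c("z", "b"), v = c(1.5, 2.5))
  r2 <- data.frame(a = c("b", "z"), v = c(2.5, 1.5))
  f1 <- tempfile(); f2 <- tempfile()
  write_long_results(r1, f1, sort_by = "a")
  write_long_results(r2, f2, sort_by = "a")
  expect_identical(readLines(f1), readLines(f2))
  # clade-profile round trip to 1e-12
  sim <- generate_cohort(cohort_config(), seed = 11, groups = "modern_calculus")
  long <- as.data.frame(clade_shares(sim$table, sim$clade_map))
  f3 <- tempfile()
  write_long_results(long, f3, sort_by = c("layer", "clade", "sample"))
  back <- read_long_results(f3)
  expect_equal(back$value, long$value, tolerance = 1e-12)
})

test_that("metadata requires unique sample ids", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thost", "s1\thuman", "s1\thuman"), f)
  expect_error(read_metadata(f), "duplicate sample_id")
})
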