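test_that("the three abundance layers follow their denominators", {
  prof <- clade_shares(arith_table(), ref_map())
  l1 <- prof$clade_share_of_genus["S1", ]
  expect_equal(unname(l1[c("Sanguinis", "Mitis", "Anginosus")]),
               c(0.3, 0.6, 0.1))
  expect_equal(unname(prof$genus_share["S1"]), 0.1)
  expect_equal(unname(prof$clade_share_of_species["S1", "Sanguinis"]), 0.03)
})

test_that("a single-clade sample has share 1 and zero-read samples go NA", {
  lin <- c(strep_lineage("Streptococcus mitis"),
           other_lin("Neisseria", "Neisseria subflava"))
  counts <- matrix(c(50, 0, 0, 0), nrow = 2,
                   dimnames = list(NULL, c("S1", "S2")))
  tab <- species_table(counts, lin)
  expect_message(prof <- clade_shares(tab, ref_map()), "zero species-level")
  expect_equal(unname(prof$clade_share_of_genus["S1", "Mitis"]), 1)
  expect_true(all(is.na(prof$clade_share_of_genus["S2", ])))
  expect_equal(unname(prof$dominance["S2"]), "none")
})

test_that("layer sums satisfy their invariants on a random cohort", {
  sim <- generate_cohort(cohort_config(), seed = 5, groups = "modern_calculus")
  prof <- clade_shares(sim$table, sim$clade_map)
  expect_equal(unname(rowSums(prof$clade_share_of_genus)),
               rep(1, 18), tolerance = 1e-12)
  expect_equal(unname(rowSums(prof$clade_share_of_species)),
               unname(prof$genus_share), tolerance = 1e-12)
  expect_true(all(prof$genus_share >= 0 & prof$genus_share <= 1))
})

test_that("layers are invariant to per-sample depth scaling", {
  tab <- arith_table()
  scaled <- species_table(tab$counts * 7, tab$lineage)
  p1 <- clade_shares(tab, ref_map())
  p2 <- clade_shares(scaled, ref_map())
  expect_equal(p1$clade_share_of_genus, p2$clade_share_of_genus)
  expect_equal(p1$genus_share, p2$genus_share)
  expect_equal(p1$clade_share_of_species, p2$clade_share_of_species)
})

test_that("removing a non-focal genus leaves layer 1 unchanged", {
  tab <- arith_table()
  keep <- !grepl("Neisseria", tab$lineage)
  smaller <- species_table(tab$counts[keep, , drop = FALSE],
                           tab$lineage[keep])
  p1 <- clade_shares(tab, ref_map())
  p2 <- clade_shares(smaller, ref_map())
  expect_equal(p1$clade_share_of_genus, p2$clade_share_of_genus)
})

test_that("log10p1 maps percents as documented and round-trips", {
  expect_equal(log10p1(0), 0)
  expect_equal(log10p1(99), 2)
  set.seed(2)
  m <- matrix(runif(30, 0, 100), 5)
  expect_equal(10^log10p1(m) - 1, m, tolerance = 1e-10)
  expect_error(log10p1(-0.1), "non-negative")
})

test_that("dominance uses plurality with fixed-precedence tie breaking", {
  lin <- c(strep_lineage("Streptococcus sanguinis"),
           strep_lineage("Streptococcus anginosus"),
           strep_lineage("Streptococcus mitis"))
  counts <- matrix(c(60, 10, 30,   50, 50, 0), nrow = 3,
                   dimnames = list(NULL, c("S1", "S2")))
  prof <- clade_shares(species_table(counts, lin), ref_map())
  expect_equal(unname(dominant_clade(prof)["S1"]), "Sanguinis")
  # exact Sanguinis/Anginosus tie resolves to Sanguinis
  expect_equal(unname(dominant_clade(prof)["S2"]), "Sanguinis")
})

test_that("cohort summaries count every sample and ignore sample order", {
  labels <- c(rep("Sanguinis", 6), rep("Anginosus", 3), "none")
  s1 <- cohort_summary(labels)
  expect_equal(sum(s1$n), 10)
  expect_equal(sum(s1$fraction), 1)
  s2 <- cohort_summary(rev(labels))
  expect_identical(s1, s2)
  expect_equal(s1$percent[s1$clade == "Anginosus"], 30)
})

test_that("top species picks the maximum with lexicographic tie flagging", {
  lin <- c(strep_lineage("Streptococcus sanguinis"),
           strep_lineage("Streptococcus gordonii"))
  counts <- matrix(c(5, 7,  5, 5), nrow = 2,
                   dimnames = list(NULL, c("S1", "S2")))
  prof <- clade_shares(species_table(counts, lin), ref_map())
  ts <- top_species(prof, "Sanguinis", restrict = "all")
  expect_equal(ts$per_sample$species[ts$per_sample$sample == "S1"],
               "Streptococcus gordonii")
  s2 <- ts$per_sample[ts$per_sample$sample == "S2", ]
  expect_equal(s2$species, "Streptococcus gordonii")  # lexicographic first
  expect_true(s2$tie)
  expect_error(top_species(prof, "Downei"), "no species")
})

test_that("the cohort top-species mode matches the largest generator weight", {
  # Monte-Carlo oracle: in non-industrial plaque the generator gives
  # S. sinensis the largest Sanguinis-clade weight
  sim <- generate_cohort(cohort_config(), seed = 31,
                         groups = "plaque_nonindustrial")
  prof <- clade_shares(sim$table, sim$clade_map)
  ts <- top_species(prof, "Sanguinis", restrict = "all")
  expect_equal(ts$tally$species[1], "Streptococcus sinensis")
})
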