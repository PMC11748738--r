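two_genome_ani <- function(ani_val) {
  m <- matrix(c(100, ani_val, ani_val, 100), 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  ani_matrix(m)
}

test_that("the 95% ANI species boundary splits and merges as expected", {
  expect_equal(length(cluster_species(two_genome_ani(96))$members), 1L)
  expect_equal(length(cluster_species(two_genome_ani(94))$members), 2L)
  # boundary value: >= 95 means 95.0 itself joins
  expect_equal(length(cluster_species(two_genome_ani(95))$members), 1L)
})

test_that("a single genome forms one singleton cluster", {
  m <- ani_matrix(matrix(100, 1, 1, dimnames = list("g1", "g1")))
  cl <- cluster_species(m)
  expect_equal(unname(cl$partition), 1L)
})

test_that("planted blocks are recovered and match the threshold-graph oracle", {
  fx <- block_ani_fixture()
  cl <- cluster_species(fx$ani, 95)
  oracle <- threshold_components(fx$ani, 95)
  # same partition up to relabeling
  expect_equal(length(unique(cl$partition)), length(unique(oracle)))
  expect_true(all(tapply(oracle, cl$partition[names(oracle)],
                         function(v) length(unique(v)) == 1)))
  expect_equal(length(cl$members), 3L)
})

test_that("NaN in the matrix is rejected", {
  m <- two_genome_ani(96)
  m[1, 2] <- NaN; m[2, 1] <- NaN
  class(m) <- "matrix"
  expect_error(cluster_species(structure(m, class = c("ani_matrix", "matrix"))),
               "NA")
})

test_that("clustering is invariant to genome order and monotone in threshold", {
  set.seed(7)
  pl <- generate_ani(n_clades = 3, species_per_clade = 2,
                     genomes_per_species = 2, n_unplaced = 1, seed = 5)
  cl1 <- cluster_species(pl$ani, 95)
  perm <- sample(rownames(pl$ani))
  ani2 <- ani_matrix(unclass(pl$ani)[perm, perm])
  cl2 <- cluster_species(ani2, 95)
  expect_identical(cl1$partition[sort(names(cl1$partition))],
                   cl2$partition[sort(names(cl2$partition))])
  # raising the threshold never merges clusters: the coarser partition is
  # refined by the finer one
  for (thr in c(90, 95, 98)) {
    lo <- cluster_species(pl$ani, thr)$partition
    hi <- cluster_species(pl$ani, thr + 1)$partition
    expect_true(all(tapply(lo, hi, function(v) length(unique(v)) == 1)))
  }
})

test_that("named clusters inherit their reference clade", {
  pl <- generate_ani(n_clades = 2, species_per_clade = 2,
                     genomes_per_species = 3, n_unplaced = 0, n_other = 0,
                     seed = 3)
  cl <- cluster_species(pl$ani)
  cm <- assign_clades(cl, pl$named_labels)
  merged <- merge(cm, pl$planted, by = "genome")
  expect_equal(merged$clade.x, merged$clade.y)
  expect_true(all(cm$provenance %in% c("named_reference", "propagated")))
})

test_that("dendrogram placement labels Other inside and Unknown at the root", {
  pl <- generate_ani(n_clades = 3, species_per_clade = 2,
                     genomes_per_species = 2, n_unplaced = 2, n_other = 2,
                     seed = 9)
  cl <- cluster_species(pl$ani)
  cm <- assign_clades(cl, pl$named_labels)
  merged <- merge(cm, pl$planted, by = "genome")
  expect_equal(merged$clade.x, merged$clade.y)
  expect_true(all(cm$provenance[cm$clade == "Unknown"] == "unknown_rule"))
  expect_true(all(cm$provenance[cm$clade == "Other"] == "other_rule"))
})

test_that("placement agrees with an explicit LCA search on the phylogeny", {
  pl <- generate_ani(n_clades = 3, species_per_clade = 2,
                     genomes_per_species = 2, n_unplaced = 1, n_other = 2,
                     seed = 21)
  cl <- cluster_species(pl$ani)
  cm <- assign_clades(cl, pl$named_labels)
  phy <- ape::as.phylo(cl$tree)
  root <- ape::Ntip(phy) + 1L
  named_tips <- intersect(phy$tip.label, pl$named_labels$species)
  clade_size <- function(node) {
    length(ape::extract.clade(phy, node)$tip.label)
  }
  for (cid in names(cl$members)) {
    mem <- cl$members[[cid]]
    if (any(mem %in% named_tips)) next
    # oracle: smallest MRCA of the cluster plus one named tip
    nodes <- vapply(named_tips, function(g)
      ape::getMRCA(phy, c(mem, g)), numeric(1))
    sizes <- vapply(nodes, clade_size, numeric(1))
    best <- nodes[which.min(sizes)]
    want <- if (best == root) "Unknown" else "Other"
    got <- unique(cm$clade[cm$genome %in% mem])
    expect_equal(got, want)
  }
})

test_that("conflicting named labels error by default and downgrade on request", {
  # two named species of different clades forced into one cluster
  g <- c("Streptococcus sanguinis", "Streptococcus mitis")
  m <- matrix(c(100, 97, 97, 100), 2, dimnames = list(g, g))
  cl <- cluster_species(ani_matrix(m))
  refs <- strep_clade_reference()
  expect_error(assign_clades(cl, refs), "conflicting clades")
  expect_warning(cm <- assign_clades(cl, refs, conflict = "majority"),
                 "majority")
  expect_equal(length(unique(cm$clade)), 1L)
  expect_error(assign_clades(cl, refs[0, ]), "empty")
})
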