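# Small fixtures built in code; every test file regenerates what it needs.

strep_lineage <- function(sp) {
  paste0("d__Bacteria|p__Firmicutes|c__Bacilli|o__Lactobacillales|",
         "f__Streptococcaceae|g__Streptococcus|s__", sp)
}

other_lin <- function(genus, sp) {
  paste0("d__Bacteria|p__Proteobacteria|c__Gammaproteobacteria|",
         "o__Xanthomonadales|f__", genus, "aceae|g__", genus, "|s__", sp)
}

# a 5-lineage mpa fixture with 3 species-level rows, written to a temp file
write_mpa_fixture <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "#Classification\tS1\tS2",
    paste0("d__Bacteria\t100\t200"),
    paste0("d__Bacteria|p__Firmicutes\t90\t150"),
    paste0(strep_lineage("Streptococcus sanguinis"), "\t30\t5"),
    paste0(strep_lineage("Streptococcus mitis"), "\t60\t10"),
    paste0(other_lin("Neisseria", "Neisseria subflava"), "\t900\t85"))
  writeLines(lines, path)
  path
}

# minimal three-clade table: Sanguinis 30, Mitis 60, Anginosus 10 focal
# reads plus 900 reads in another genus (single sample)
arith_table <- function() {
  lin <- c(strep_lineage("Streptococcus sanguinis"),
           strep_lineage("Streptococcus mitis"),
           strep_lineage("Streptococcus anginosus"),
           other_lin("Neisseria", "Neisseria subflava"))
  counts <- matrix(c(30, 60, 10, 900), ncol = 1,
                   dimnames = list(NULL, "S1"))
  species_table(counts, lin)
}

ref_map <- function() strep_clade_reference()

# block ANI matrix with 3 planted species (2 genomes each), deterministic
block_ani_fixture <- function(seed = 42) {
  set.seed(seed)
  g <- c("A.1", "A.2", "B.1", "B.2", "C.1", "C.2")
  blk <- rep(c("A", "B", "C"), each = 2)
  m <- matrix(NA_real_, 6, 6, dimnames = list(g, g))
  for (i in 1:6) for (j in 1:6) {
    if (j <= i) next
    v <- if (blk[i] == blk[j]) runif(1, 97, 99) else runif(1, 80, 85)
    m[i, j] <- v; m[j, i] <- v
  }
  diag(m) <- 100
  list(ani = ani_matrix(m), blocks = setNames(blk, g))
}

# connected components of the >= threshold ANI graph (independent oracle
# for well-separated planted blocks)
threshold_components <- function(ani, threshold) {
  adj <- unclass(ani) >= threshold
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  setNames(comp, rownames(ani))
}
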