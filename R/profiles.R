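# Fixed precedence for dominance tie-breaking: the two clades of the
# ancient-calculus dichotomy first, then the remaining oral clades, then the
# catch-all labels.
CLADE_PRECEDENCE <- c("Sanguinis", "Mitis", "Anginosus", "Salivarius",
                      "Mutans", "Bovis", "Pyogenic", "Downei",
                      "Other", "Unknown")

#' Per-sample clade abundance layers
#'
#' Computes, for every sample, the three relative-abundance layers used
#' throughout clade profiling. All denominators count species-level
#' assignments only; genus-level reads that were never resolved to a species
#' do not enter any layer.
#'
#' \describe{
#'   \item{clade_share_of_genus}{reads of focal-genus species in each clade,
#'     divided by all focal-genus species reads (sums to 1 per sample when
#'     the genus was observed).}
#'   \item{genus_share}{focal-genus species reads divided by all
#'     species-level reads in the sample.}
#'   \item{clade_share_of_species}{reads of focal-genus species in each
#'     clade divided by all species-level reads (sums to `genus_share`).}
#' }
#'
#' @param table a [species_table] (only its species-level rows are used).
#' @param clades clade map: anything accepted by [clade_lookup()], covering
#'   the focal-genus species. Species without an entry are assigned
#'   "Unknown" with a warning.
#' @param focal_genus genus whose clades are profiled.
#' @return `clade_profile`: list with matrices `clade_share_of_genus` and
#'   `clade_share_of_species` (samples x clades), vector `genus_share`,
#'   character vector `dominance`, and `focal_species_counts` (samples x
#'   focal species) kept for species-level queries.
#' @export
clade_shares <- function(table, clades, focal_genus = "Streptococcus") {
  sp <- species_level(table)
  if (nrow(sp$counts) == 0) stop("no species-level rows in table")
  nm <- taxon_names(sp)
  lookup <- clade_lookup(clades)
  focal <- !is.na(nm$genus) & nm$genus == focal_genus
  clade <- rep(NA_character_, nrow(sp$counts))
  clade[focal] <- unname(lookup[nm$species[focal]])
  if (any(focal & is.na(clade))) {
    warning("focal species without clade entry set to Unknown: ",
            paste(utils::head(nm$species[focal & is.na(clade)], 5),
                  collapse = ", "))
    clade[focal & is.na(clade)] <- "Unknown"
  }

  counts <- sp$counts
  total_species <- colSums(counts)
  focal_total <- colSums(counts[focal, , drop = FALSE])

  clade_f <- factor(clade[focal], levels = CLADE_PRECEDENCE)
  by_clade <- rowsum(counts[focal, , drop = FALSE], clade_f)
  full <- matrix(0, nrow = length(CLADE_PRECEDENCE), ncol = ncol(counts),
                 dimnames = list(CLADE_PRECEDENCE, colnames(counts)))
  full[rownames(by_clade), ] <- by_clade

  layer1 <- t(full) / ifelse(focal_total > 0, focal_total, NA)
  genus_share <- ifelse(total_species > 0, focal_total / total_species, NA)
  layer3 <- t(full) / ifelse(total_species > 0, total_species, NA)

  zero <- total_species == 0
  if (any(zero)) {
    message(sum(zero), " sample(s) with zero species-level reads: ",
            "all layers set NA")
    layer1[zero, ] <- NA
    layer3[zero, ] <- NA
  }

  dominance <- rep("none", ncol(counts))
  names(dominance) <- colnames(counts)
  has_focal <- !zero & focal_total > 0
  if (any(has_focal)) {
    idx <- apply(layer1[has_focal, , drop = FALSE], 1, which.max)
    dominance[has_focal] <- CLADE_PRECEDENCE[idx]
  }

  structure(list(clade_share_of_genus = layer1,
                 genus_share = genus_share,
                 clade_share_of_species = layer3,
                 dominance = dominance,
                 focal_genus = focal_genus,
                 focal_species_counts = {
                   fc <- t(counts[focal, , drop = FALSE])
                   colnames(fc) <- nm$species[focal]
                   fc
                 },
                 focal_species_clade =
                   stats::setNames(clade[focal], nm$species[focal])),
            class = "clade_profile")
}

#' @export
print.clade_profile <- function(x, ...) {
  cat(sprintf("clade_profile: %d samples, genus %s (mean genus share %.3f)\n",
              length(x$genus_share), x$focal_genus,
              mean(x$genus_share, na.rm = TRUE)))
  invisible(x)
}

#' Long-format view of a clade profile
#'
#' @param x a `clade_profile`.
#' @param ... unused.
#' @return data.frame with columns `sample`, `layer`, `clade`, `value`,
#'   sorted for deterministic output. The `genus_share` layer repeats the
#'   focal genus in the `clade` column.
#' @export
as.data.frame.clade_profile <- function(x, ...) {
  samples <- names(x$genus_share)
  if (is.null(samples)) samples <- rownames(x$clade_share_of_genus)
  long <- function(m, layer) data.frame(
    sample = rep(rownames(m), times = ncol(m)),
    layer = layer, clade = rep(colnames(m), each = nrow(m)),
    value = as.vector(m), stringsAsFactors = FALSE)
  out <- rbind(
    long(x$clade_share_of_genus, "clade_share_of_genus"),
    long(x$clade_share_of_species, "clade_share_of_species"),
    data.frame(sample = samples, layer = "genus_share",
               clade = x$focal_genus, value = unname(x$genus_share),
               stringsAsFactors = FALSE))
  out[order(out$layer, out$clade, out$sample), , drop = FALSE]
}

#' Heatmap transform: log10 of percent + 1
#'
#' Applied to percent-scale (0-100) relative abundances before heatmap
#' display, compressing the dynamic range while mapping absence to exactly
#' zero: 0 -> 0, 99 -> 2.
#'
#' @param percent_matrix numeric, values >= 0 on the percent scale.
#' @return log10(x + 1), same shape.
#' @export
log10p1 <- function(percent_matrix) {
  if (any(percent_matrix < 0, na.rm = TRUE))
    stop("log10p1 expects non-negative percent values")
  log10(percent_matrix + 1)
}

#' Dominant clade per sample
#'
#' The clade holding the plurality of the sample's focal-genus reads
#' (argmax of the clade_share_of_genus layer). Ties are broken by the fixed
#' clade precedence (Sanguinis first, then Mitis, Anginosus, Salivarius,
#' Mutans, Bovis, Pyogenic, Downei, Other, Unknown). Samples without focal
#' reads are "none".
#'
#' @param profile a `clade_profile`.
#' @return named character vector of clade labels per sample.
#' @export
dominant_clade <- function(profile) profile$dominance

#' Cohort dominance summary
#'
#' @param labels dominance labels as returned by [dominant_clade()].
#' @param group optional grouping vector parallel to `labels`; one summary
#'   per group.
#' @return data.frame `group`, `clade`, `n`, `fraction`, `percent`;
#'   fractions sum to 1 within each group.
#' @export
cohort_summary <- function(labels, group = NULL) {
  if (is.null(group)) group <- rep("all", length(labels))
  levels_ <- c(CLADE_PRECEDENCE, "none")
  out <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    lab <- labels[group == g]
    tab <- table(factor(lab, levels = levels_))
    data.frame(group = g, clade = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(lab),
               stringsAsFactors = FALSE)
  }))
  out$percent <- 100 * out$fraction
  rownames(out) <- NULL
  out
}

#' Most abundant species of a clade per sample
#'
#' For every sample, the focal-genus species of the requested clade with
#' the most reads (ties resolved to the lexicographically first species and
#' flagged). The cohort tally reports, for each species, the fraction of
#' samples in which it is the clade's top species; by default the tally is
#' restricted to samples where that clade is dominant.
#'
#' @param profile a `clade_profile` from [clade_shares()].
#' @param clade clade label to interrogate.
#' @param restrict `"dominant"` (tally only clade-dominant samples) or
#'   `"all"`.
#' @return list with `per_sample` (sample, species, reads, tie) and `tally`
#'   (species, n, fraction).
#' @export
top_species <- function(profile, clade, restrict = c("dominant", "all")) {
  restrict <- match.arg(restrict)
  in_clade <- names(profile$focal_species_clade)[
    profile$focal_species_clade == clade]
  if (!length(in_clade))
    stop("clade has no species in the profile: ", clade)
  m <- profile$focal_species_counts[, in_clade, drop = FALSE]
  m <- m[, order(colnames(m)), drop = FALSE]   # lexicographic tie-break
  top_idx <- apply(m, 1, which.max)
  top <- colnames(m)[top_idx]
  reads <- m[cbind(seq_len(nrow(m)), top_idx)]
  tie <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] == reads[i]) > 1 & reads[i] > 0, logical(1))
  per_sample <- data.frame(sample = rownames(m), species = top,
                           reads = reads, tie = tie,
                           stringsAsFactors = FALSE)
  keep <- if (restrict == "dominant") profile$dominance == clade
          else rep(TRUE, nrow(per_sample))
  keep <- keep & reads > 0
  tally_tab <- table(per_sample$species[keep])
  tally <- data.frame(species = names(tally_tab), n = as.integer(tally_tab),
                      fraction = as.numeric(tally_tab) / max(1, sum(keep)),
                      stringsAsFactors = FALSE)
  tally <- tally[order(-tally$n, tally$species), , drop = FALSE]
  rownames(tally) <- NULL
  list(per_sample = per_sample, tally = tally)
}
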