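# Polynomial rolling hash of a string, folded into a 31-bit integer; used
# for the config fingerprint and stable per-stage seed derivation.
fnv1a31 <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% (2^31 - 1)
  as.integer(h)
}

#' Derive a per-stage seed from a master seed
#'
#' Stable, documented derivation: FNV-1a hash of the stage name combined
#' with the master seed, reduced below 2^31 so it is a valid R seed.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((fnv1a31(stage) + as.numeric(master) * 7919) %% (2^31 - 1))
}

default_run_config <- function() {
  list(seed = 1, outdir = "strepclades_results", simulate = TRUE,
       groups = NULL, focal_genus = "Streptococcus",
       qc = list(enabled = TRUE, burn_in_rank = 10,
                 min_percent = c(ancient = 50, industrial = 65,
                                 `non-industrial` = 65, nhp = 65)),
       assign = list(enabled = TRUE, threshold_ani = 95),
       profile = list(enabled = TRUE),
       correlate = list(enabled = TRUE, pseudocount = 1),
       enrich = list(enabled = TRUE, min_prevalence = 0.30),
       inputs = list(mpa = NULL, metadata = NULL, ani = NULL,
                     clade_refs = NULL))
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full clade-profiling pipeline
#'
#' Executes the stages in fixed order — simulate/ingest, preservation QC,
#' clade assignment, clade profiling, compositional correlations,
#' group enrichment — writing deterministic long-format TSVs plus a JSON
#' run manifest into `outdir`. All randomness derives from the single
#' master seed via [derive_seed()], so a rerun with the same config is
#' numerically identical. Logging goes to standard error; results only to
#' files.
#'
#' @param config path to a YAML config file, or a config list; omitted
#'   entries fall back to defaults (`simulate: true` with the default
#'   synthetic cohort).
#' @return the run manifest (invisibly), also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  record <- function(stage, files, n) {
    stages[[stage]] <<- list(stage = stage, files = as.list(files),
                             records = n)
  }

  # -- data: simulate or ingest
  if (isTRUE(cfg$simulate)) {
    log_stage("simulate", "generating synthetic cohort")
    cc <- cohort_config(cfg$groups)
    sim <- generate_cohort(cc, seed = derive_seed(cfg$seed, "simulate"))
    table <- sim$table
    metadata <- sim$metadata
    clade_map <- sim$clade_map
    f_mpa <- file.path(cfg$outdir, "cohort_mpa.tsv")
    f_md <- file.path(cfg$outdir, "cohort_metadata.tsv")
    write_mpa_table(table, f_mpa)
    write_long_results(metadata, f_md, sort_by = "sample_id")
    record("simulate", c(f_mpa, f_md), ncol(table$counts))
  } else {
    log_stage("ingest", "reading input tables")
    table <- read_mpa_table(cfg$inputs$mpa)
    metadata <- read_metadata(cfg$inputs$metadata)
    clade_map <- if (!is.null(cfg$inputs$clade_refs))
      read_clade_reference(cfg$inputs$clade_refs) else strep_clade_reference()
    record("ingest", unlist(cfg$inputs[!vapply(cfg$inputs, is.null,
                                               logical(1))]),
           ncol(table$counts))
  }
  rownames(metadata) <- metadata$sample_id
  group_of <- stats::setNames(metadata$group, metadata$sample_id)

  # -- preservation QC
  if (isTRUE(cfg$qc$enabled)) {
    log_stage("qc", "cumulative-percent-decay preservation screen")
    qc <- screen_preservation(table, oral_reference_species(),
                              groups = group_of,
                              burn_in_rank = cfg$qc$burn_in_rank,
                              min_percent = cfg$qc$min_percent)
    f_qc <- file.path(cfg$outdir, "preservation.tsv")
    write_long_results(qc, f_qc, sort_by = "sample")
    keep <- qc$sample[qc$pass]
    table <- species_table(table$counts[, keep, drop = FALSE],
                           table$lineage)
    metadata <- metadata[keep, , drop = FALSE]
    record("qc", f_qc, nrow(qc))
  }

  # -- clade assignment from an ANI matrix, when one is provided/simulated
  if (isTRUE(cfg$assign$enabled)) {
    if (!is.null(cfg$inputs$ani)) {
      log_stage("assign", "clustering provided ANI matrix")
      ani <- read_ani_matrix(cfg$inputs$ani)
      refs <- if (!is.null(cfg$inputs$clade_refs))
        read_clade_reference(cfg$inputs$clade_refs)
      else strep_clade_reference()
      cl <- cluster_species(ani, cfg$assign$threshold_ani)
      cm <- assign_clades(cl, refs)
      clade_map <- data.frame(species = cm$genome, clade = cm$clade,
                              stringsAsFactors = FALSE)
    } else if (isTRUE(cfg$simulate)) {
      log_stage("assign", "clustering planted ANI matrix")
      pl <- generate_ani(seed = derive_seed(cfg$seed, "assign"))
      cl <- cluster_species(pl$ani, cfg$assign$threshold_ani)
      cm <- assign_clades(cl, pl$named_labels)
    } else cm <- NULL
    if (!is.null(cm)) {
      f_as <- file.path(cfg$outdir, "clade_assignments.tsv")
      write_long_results(cm, f_as, sort_by = "genome")
      record("assign", f_as, nrow(cm))
    }
  }

  # -- clade profiles and dominance
  profile <- clade_shares(table, clade_map, cfg$focal_genus)
  if (isTRUE(cfg$profile$enabled)) {
    log_stage("profile", "computing clade abundance layers")
    long <- as.data.frame(profile)
    f_pr <- file.path(cfg$outdir, "clade_profile.tsv")
    write_long_results(long, f_pr, sort_by = c("layer", "clade", "sample"))
    dom <- dominant_clade(profile)
    summ <- cohort_summary(dom, group = metadata[names(dom), "cohort"])
    f_dom <- file.path(cfg$outdir, "dominance_summary.tsv")
    write_long_results(summ, f_dom, sort_by = c("group", "clade"))
    record("profile", c(f_pr, f_dom), nrow(long))
  }

  # -- compositional correlations between clades (ancient calculus)
  if (isTRUE(cfg$correlate$enabled)) {
    log_stage("correlate", "CLR correlations between clades")
    anc <- metadata$sample_id[metadata$group == "ancient"]
    use <- if (length(anc) >= 3) anc else metadata$sample_id
    clade_counts <- clade_read_counts(table, clade_map, cfg$focal_genus)
    clade_counts <- clade_counts[use, , drop = FALSE]
    keep_cl <- colSums(clade_counts) > 0
    y <- clr_transform(clade_counts[, keep_cl, drop = FALSE],
                       cfg$correlate$pseudocount)
    pear <- clr_pearson(y)
    prho <- proportionality_rho(y)
    prop_long <- data.frame(
      feature1 = rep(rownames(prho), times = ncol(prho)),
      feature2 = rep(colnames(prho), each = nrow(prho)),
      method = "proportionality", rho = as.vector(prho),
      stringsAsFactors = FALSE)
    prop_long <- prop_long[prop_long$feature1 < prop_long$feature2, ]
    f_cor <- file.path(cfg$outdir, "clade_correlations.tsv")
    both <- rbind(pear[, c("feature1", "feature2", "method", "rho")],
                  prop_long)
    write_long_results(both, f_cor,
                       sort_by = c("method", "feature1", "feature2"))
    record("correlate", f_cor, nrow(both))
  }

  # -- enrichment between industrial and non-industrial groups
  if (isTRUE(cfg$enrich$enabled)) {
    ok <- metadata$group %in% c("industrial", "non-industrial")
    types <- split(metadata$sample_id[ok], metadata$sample_type[ok])
    res <- list()
    for (ty in names(types)) {
      ids <- types[[ty]]
      gr <- factor(metadata[ids, "group"])
      if (nlevels(gr) == 2 && all(table(gr) >= 2)) {
        gs <- profile$genus_share[ids]
        r <- wilcoxon_enrichment(matrix(gs, ncol = 1,
                                        dimnames = list(NULL, "genus_share")),
                                 gr)
        r$sample_type <- ty
        res[[ty]] <- r
      }
    }
    if (length(res)) {
      log_stage("enrich", "industrial vs non-industrial genus-share tests")
      res <- do.call(rbind, res)
      f_en <- file.path(cfg$outdir, "enrichment.tsv")
      write_long_results(res, f_en, sort_by = c("sample_type", "feature"))
      record("enrich", f_en, nrow(res))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("strepclades")),
    config_hash = fnv1a31(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           force = TRUE)),
    seed = cfg$seed,
    stages = unname(stages))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", paste("manifest written to",
                          file.path(cfg$outdir, "manifest.json")))
  invisible(manifest)
}

#' Aggregate species counts to clade counts
#'
#' Sums the focal-genus species reads of each clade per sample, giving the
#' samples x clades count matrix used for CLR-based clade correlations.
#'
#' @param table a [species_table].
#' @param clades clade map accepted by [clade_lookup()].
#' @param focal_genus focal genus.
#' @return samples x clades numeric matrix (clades in fixed order).
#' @export
clade_read_counts <- function(table, clades, focal_genus = "Streptococcus") {
  sp <- species_level(table)
  nm <- taxon_names(sp)
  lookup <- clade_lookup(clades)
  focal <- !is.na(nm$genus) & nm$genus == focal_genus
  clade <- unname(lookup[nm$species[focal]])
  clade[is.na(clade)] <- "Unknown"
  by_clade <- rowsum(sp$counts[focal, , drop = FALSE],
                     factor(clade, levels = CLADE_PRECEDENCE))
  full <- matrix(0, nrow = length(CLADE_PRECEDENCE), ncol = ncol(sp$counts),
                 dimnames = list(CLADE_PRECEDENCE, colnames(sp$counts)))
  full[rownames(by_clade), ] <- by_clade
  t(full)
}
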