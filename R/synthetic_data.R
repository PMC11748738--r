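# ---- distribution helpers ---------------------------------------------

#' Dirichlet draws
#'
#' @param n number of draws.
#' @param alpha concentration vector (> 0).
#' @return n x length(alpha) matrix of simplex draws.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be positive")
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

logitnorm_moments <- function(mu, sigma, k = 2001) {
  z <- mu + sigma * stats::qnorm(seq(0.5 / k, 1 - 0.5 / k, length.out = k))
  p <- stats::plogis(z)
  c(mean = mean(p), sd = stats::sd(p))
}

#' Logit-normal parameters matching a target mean and SD
#'
#' Group-level relative abundances are modeled as logit-normal (bounded in
#' (0,1), right-skewed at small means); this solves numerically for the
#' latent normal (mu, sigma) whose logistic transform has the requested
#' moments.
#'
#' @param mean,sd target moments on the proportion scale (0 < mean < 1).
#' @return named vector c(mu, sigma).
#' @export
fit_logitnorm <- function(mean, sd) {
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)")
  if (sd <= 0) stop("sd must be positive")
  obj <- function(par) {
    mm <- logitnorm_moments(par[1], exp(par[2]))
    (mm["mean"] - mean)^2 / mean^2 + (mm["sd"] - sd)^2 / sd^2
  }
  init <- c(stats::qlogis(mean), log(sd / (mean * (1 - mean))))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])))
}

rlogitnorm <- function(n, mu, sigma) stats::plogis(stats::rnorm(n, mu, sigma))

# ---- species inventory -------------------------------------------------

STREP_LINEAGE_HEAD <- paste0("d__Bacteria|p__Firmicutes|c__Bacilli|",
                             "o__Lactobacillales|f__Streptococcaceae|",
                             "g__Streptococcus|s__")

# unnamed focal species used to exercise the Other/Unknown rules
EXTRA_FOCAL <- data.frame(
  species = c("Streptococcus sp002361075", "Streptococcus sp902361515",
              "Streptococcus sp903001234", "Streptococcus sp903005678"),
  clade = c("Other", "Other", "Unknown", "Unknown"),
  stringsAsFactors = FALSE)

#' The generator's focal species inventory
#'
#' Named Streptococcus species of the eight clades (the bundled reference)
#' plus unnamed GTDB-style species carrying the "Other" and "Unknown"
#' labels.
#'
#' @return data.frame `species`, `clade`.
#' @export
focal_species_inventory <- function() {
  rbind(strep_clade_reference(), EXTRA_FOCAL)
}

# background oral genera: genus, representative species, phylum; weights
# loosely follow typical oral-community rank structure with the early
# colonizers and biofilm structurers prominent.
background_inventory <- function() {
  x <- rbind(
    c("Actinomyces",       "Actinomyces oris",               "Actinobacteriota", 6),
    c("Schaalia",          "Schaalia odontolytica",          "Actinobacteriota", 2),
    c("Rothia",            "Rothia dentocariosa",            "Actinobacteriota", 5),
    c("Corynebacterium",   "Corynebacterium matruchotii",    "Actinobacteriota", 5),
    c("Atopobium",         "Atopobium parvulum",             "Actinobacteriota", 1),
    c("Olsenella",         "Olsenella uli",                  "Actinobacteriota", 1),
    c("Bifidobacterium",   "Bifidobacterium dentium",        "Actinobacteriota", 1),
    c("Pseudopropionibacterium", "Pseudopropionibacterium propionicum", "Actinobacteriota", 1),
    c("Neisseria",         "Neisseria subflava",             "Proteobacteria", 6),
    c("Eikenella",         "Eikenella corrodens",            "Proteobacteria", 1.5),
    c("Kingella",          "Kingella oralis",                "Proteobacteria", 1),
    c("Lautropia",         "Lautropia mirabilis",            "Proteobacteria", 1),
    c("Haemophilus",       "Haemophilus parainfluenzae",     "Proteobacteria", 5),
    c("Aggregatibacter",   "Aggregatibacter aphrophilus",    "Proteobacteria", 1.5),
    c("Cardiobacterium",   "Cardiobacterium hominis",        "Proteobacteria", 1),
    c("Campylobacter",     "Campylobacter gracilis",         "Campylobacterota", 2),
    c("Desulfobulbus",     "Desulfobulbus oralis",           "Desulfobacterota", 1),
    c("Veillonella",       "Veillonella parvula",            "Firmicutes", 6),
    c("Gemella",           "Gemella haemolysans",            "Firmicutes", 2),
    c("Granulicatella",    "Granulicatella adiacens",        "Firmicutes", 2),
    c("Abiotrophia",       "Abiotrophia defectiva",          "Firmicutes", 1),
    c("Parvimonas",        "Parvimonas micra",               "Firmicutes", 1.5),
    c("Peptostreptococcus","Peptostreptococcus stomatis",    "Firmicutes", 1),
    c("Filifactor",        "Filifactor alocis",              "Firmicutes", 1),
    c("Mogibacterium",     "Mogibacterium timidum",          "Firmicutes", 1),
    c("Oribacterium",      "Oribacterium sinus",             "Firmicutes", 1),
    c("Lachnoanaerobaculum", "Lachnoanaerobaculum saburreum","Firmicutes", 1),
    c("Stomatobaculum",    "Stomatobaculum longum",          "Firmicutes", 1),
    c("Selenomonas",       "Selenomonas sputigena",          "Firmicutes", 1.5),
    c("Dialister",         "Dialister invisus",              "Firmicutes", 1),
    c("Megasphaera",       "Megasphaera micronuciformis",    "Firmicutes", 1),
    c("Lactobacillus",     "Lactobacillus gasseri",          "Firmicutes", 1),
    c("Capnocytophaga",    "Capnocytophaga gingivalis",      "Bacteroidota", 4),
    c("Prevotella",        "Prevotella melaninogenica",      "Bacteroidota", 5),
    c("Porphyromonas",     "Porphyromonas gingivalis",       "Bacteroidota", 2),
    c("Tannerella",        "Tannerella forsythia",           "Bacteroidota", 1.5),
    c("Alloprevotella",    "Alloprevotella tannerae",        "Bacteroidota", 1),
    c("Bergeyella",        "Bergeyella zoohelcum",           "Bacteroidota", 1),
    c("Fusobacterium",     "Fusobacterium nucleatum",        "Fusobacteriota", 4),
    c("Leptotrichia",      "Leptotrichia buccalis",          "Fusobacteriota", 2),
    c("Treponema",         "Treponema denticola",            "Spirochaetota", 1.5),
    c("Ottowia",           "Ottowia oryzae",                 "Proteobacteria", 1),
    c("Fretibacterium",    "Fretibacterium fastidiosum",     "Synergistota", 1),
    c("Methanobrevibacter","Methanobrevibacter oralis",      "Methanobacteriota", 1)
  )
  data.frame(genus = x[, 1], species = x[, 2], phylum = x[, 3],
             weight = as.numeric(x[, 4]), stringsAsFactors = FALSE)
}

# non-oral (soil/environmental) taxa used for contaminated QC-fail samples
contaminant_inventory <- function() {
  data.frame(
    genus = c("Bradyrhizobium", "Streptomyces", "Mycobacterium",
              "Nocardioides", "Sphingomonas", "Pseudomonas", "Bacillus",
              "Burkholderia", "Micromonospora", "Rhodopseudomonas"),
    species = c("Bradyrhizobium japonicum", "Streptomyces griseus",
                "Mycobacterium smegmatis", "Nocardioides albus",
                "Sphingomonas paucimobilis", "Pseudomonas fluorescens",
                "Bacillus subtilis", "Burkholderia cepacia",
                "Micromonospora aurantiaca", "Rhodopseudomonas palustris"),
    phylum = c("Proteobacteria", "Actinobacteriota", "Actinobacteriota",
               "Actinobacteriota", "Proteobacteria", "Proteobacteria",
               "Firmicutes", "Proteobacteria", "Actinobacteriota",
               "Proteobacteria"),
    weight = rep(1, 10), stringsAsFactors = FALSE)
}

other_lineage <- function(genus, species, phylum) {
  domain <- ifelse(phylum == "Methanobacteriota", "Archaea", "Bacteria")
  paste0("d__", domain, "|p__", phylum, "|c__", phylum, "_c|o__", phylum,
         "_o|f__", genus, "aceae|g__", genus, "|s__", species)
}

#' The oral reference species set of the generator
#'
#' All focal and background species; contaminant species are excluded, so
#' decay curves of contaminated samples dip.
#'
#' @return character vector of species names.
#' @export
oral_reference_species <- function() {
  c(focal_species_inventory()$species, background_inventory()$species)
}

# ---- default configuration --------------------------------------------

# base within-clade species weights, shared by all groups unless overridden
base_species_weights <- function() list(
  Sanguinis = c("Streptococcus sanguinis" = 0.35,
                "Streptococcus sinensis" = 0.30,
                "Streptococcus cristatus" = 0.20,
                "Streptococcus gordonii" = 0.15),
  Mitis = c("Streptococcus mitis" = 0.25, "Streptococcus oralis" = 0.25,
            "Streptococcus infantis" = 0.13,
            "Streptococcus parasanguinis" = 0.15,
            "Streptococcus pneumoniae" = 0.05,
            "Streptococcus pseudopneumoniae" = 0.03,
            "Streptococcus lactarius" = 0.02,
            "Streptococcus australis" = 0.05,
            "Streptococcus peroris" = 0.02,
            "Streptococcus oralis_S" = 0.05),
  Salivarius = c("Streptococcus salivarius" = 0.6,
                 "Streptococcus vestibularis" = 0.3,
                 "Streptococcus thermophilus" = 0.1),
  Anginosus = c("Streptococcus anginosus" = 0.45,
                "Streptococcus constellatus" = 0.30,
                "Streptococcus intermedius" = 0.25),
  Bovis = c("Streptococcus equinus" = 0.3, "Streptococcus gallolyticus" = 0.3,
            "Streptococcus infantarius" = 0.2,
            "Streptococcus alactolyticus" = 0.2),
  Pyogenic = c("Streptococcus pyogenes" = 0.25,
               "Streptococcus agalactiae" = 0.2,
               "Streptococcus dysgalactiae" = 0.2,
               "Streptococcus uberis" = 0.15, "Streptococcus canis" = 0.1,
               "Streptococcus iniae" = 0.1),
  Mutans = c("Streptococcus mutans" = 0.6, "Streptococcus sobrinus" = 0.2,
             "Streptococcus ratti" = 0.1, "Streptococcus macacae" = 0.1),
  Downei = c("Streptococcus downei" = 1),
  Other = c("Streptococcus sp002361075" = 0.5,
            "Streptococcus sp902361515" = 0.5),
  Unknown = c("Streptococcus sp903001234" = 0.6,
              "Streptococcus sp903005678" = 0.4))

clade_vec <- function(Sanguinis, Mitis, Anginosus, Salivarius, Mutans,
                      Bovis, Pyogenic, Downei, Other, Unknown) {
  v <- c(Sanguinis = Sanguinis, Mitis = Mitis, Anginosus = Anginosus,
         Salivarius = Salivarius, Mutans = Mutans, Bovis = Bovis,
         Pyogenic = Pyogenic, Downei = Downei, Other = Other,
         Unknown = Unknown)
  if (abs(sum(v) - 1) > 1e-8)
    stop("clade means must sum to 1, got ", sum(v))
  v[CLADE_PRECEDENCE]
}

group_spec <- function(n, host, sample_type, group_label, genus_mean,
                       genus_sd, clade_mean, clade_conc = 10,
                       species_overrides = NULL, anginosus_weight = 0,
                       angdom = NULL, n_contaminated = 0,
                       contam_fraction = 0.8, genus_support = c(0, 1)) {
  # genus_support narrows the logit-normal onto (lo, hi) while keeping the
  # target mean and SD: a floor concentrates the group away from low
  # values, a ceiling truncates its upper tail. Used where a group's
  # printed rank separation from its counterpart exceeds what the moments
  # alone reproduce under a full-support family.
  lo <- genus_support[1]; hi <- genus_support[2]
  if (!(lo < genus_mean && genus_mean < hi))
    stop("genus_mean must lie inside genus_support")
  ln <- fit_logitnorm((genus_mean - lo) / (hi - lo), genus_sd / (hi - lo))
  spec <- list(n = n, host = host, sample_type = sample_type,
               group_label = group_label,
               genus_mean = genus_mean, genus_sd = genus_sd,
               genus_support = c(lo, hi),
               genus_mu = ln[["mu"]], genus_sigma = ln[["sigma"]],
               clade_mean = clade_mean, clade_conc = clade_conc,
               species_overrides = species_overrides,
               anginosus_weight = anginosus_weight, angdom = angdom,
               n_contaminated = n_contaminated,
               contam_fraction = contam_fraction)
  if (!is.null(angdom)) {
    ln2 <- fit_logitnorm(angdom$genus_mean, angdom$genus_sd)
    spec$angdom$genus_mu <- ln2[["mu"]]
    spec$angdom$genus_sigma <- ln2[["sigma"]]
  }
  spec
}

#' Default synthetic cohort configuration
#'
#' Encodes the study conditions the generator emulates: per-group sample
#' sizes, genus-share means and SDs, clade mixtures, the two-component
#' Sanguinis/Anginosus dominance mixture of ancient calculus (14.7%
#' minority weight, realized as an exact stratified count), and the
#' group-specific species splits (notably the S. sinensis / S. sanguinis
#' exchange between non-industrial and industrial plaque). See the package
#' vignette for the provenance of each default.
#'
#' @param groups optional character vector restricting which sample groups
#'   the config describes.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(groups = NULL) {
  g <- list(
    ancient_calculus = group_spec(
      n = 483, host = "human", sample_type = "ancient_calculus",
      group_label = "ancient",
      genus_mean = 0.05, genus_sd = 0.03,
      clade_mean = clade_vec(Sanguinis = 0.55, Mitis = 0.135,
                             Anginosus = 0.012, Salivarius = 0.07,
                             Mutans = 0.03, Bovis = 0.02, Pyogenic = 0.03,
                             Downei = 0.01, Other = 0.093, Unknown = 0.05),
      clade_conc = 16,
      species_overrides = list(
        Sanguinis = c("Streptococcus sinensis" = 0.50,
                      "Streptococcus sanguinis" = 0.22,
                      "Streptococcus cristatus" = 0.16,
                      "Streptococcus gordonii" = 0.12)),
      anginosus_weight = 71 / 483,
      angdom = list(
        genus_mean = 0.015, genus_sd = 0.012,
        clade_mean = clade_vec(Sanguinis = 0.025, Mitis = 0.10,
                               Anginosus = 0.55, Salivarius = 0.08,
                               Mutans = 0.03, Bovis = 0.02, Pyogenic = 0.04,
                               Downei = 0.01, Other = 0.095, Unknown = 0.05),
        species_overrides = list(
          Anginosus = c("Streptococcus constellatus" = 0.72,
                        "Streptococcus anginosus" = 0.16,
                        "Streptococcus intermedius" = 0.12)))),
    modern_calculus = group_spec(
      n = 18, host = "human", sample_type = "modern_calculus",
      group_label = "industrial",
      genus_mean = 0.05, genus_sd = 0.03,
      clade_mean = clade_vec(Sanguinis = 0.45, Mitis = 0.19,
                             Anginosus = 0.04, Salivarius = 0.08,
                             Mutans = 0.03, Bovis = 0.02, Pyogenic = 0.02,
                             Downei = 0.01, Other = 0.10, Unknown = 0.06)),
    plaque_industrial = group_spec(
      n = 120, host = "human", sample_type = "plaque",
      group_label = "industrial",
      genus_mean = 0.07, genus_sd = 0.06,
      clade_mean = clade_vec(Sanguinis = 0.12, Mitis = 0.43,
                             Anginosus = 0.05, Salivarius = 0.10,
                             Mutans = 0.02, Bovis = 0.01, Pyogenic = 0.01,
                             Downei = 0.005, Other = 0.155, Unknown = 0.10),
      species_overrides = list(
        Sanguinis = c("Streptococcus sanguinis" = 0.625,
                      "Streptococcus sinensis" = 0.0358,
                      "Streptococcus cristatus" = 0.0733,
                      "Streptococcus gordonii" = 0.2659),
        Mitis = c("Streptococcus mitis" = 0.28,
                  "Streptococcus oralis" = 0.28,
                  "Streptococcus oralis_S" = 0.0512,
                  "Streptococcus infantis" = 0.14,
                  "Streptococcus parasanguinis" = 0.14,
                  "Streptococcus pneumoniae" = 0.05,
                  "Streptococcus pseudopneumoniae" = 0.02,
                  "Streptococcus lactarius" = 0.01,
                  "Streptococcus australis" = 0.02,
                  "Streptococcus peroris" = 0.0088),
        Anginosus = c("Streptococcus anginosus" = 0.45,
                      "Streptococcus constellatus" = 0.25,
                      "Streptococcus intermedius" = 0.30))),
    plaque_nonindustrial = group_spec(
      n = 100, host = "human", sample_type = "plaque",
      group_label = "non-industrial",
      genus_mean = 0.04, genus_sd = 0.03,
      clade_mean = clade_vec(Sanguinis = 0.22, Mitis = 0.27,
                             Anginosus = 0.04, Salivarius = 0.07,
                             Mutans = 0.06, Bovis = 0.02, Pyogenic = 0.02,
                             Downei = 0.005, Other = 0.175, Unknown = 0.12),
      species_overrides = list(
        Sanguinis = c("Streptococcus sinensis" = 0.50,
                      "Streptococcus cristatus" = 0.1045,
                      "Streptococcus sanguinis" = 0.1227,
                      "Streptococcus gordonii" = 0.2728),
        Mitis = c("Streptococcus mitis" = 0.29,
                  "Streptococcus oralis" = 0.29,
                  "Streptococcus oralis_S" = 0.0126,
                  "Streptococcus infantis" = 0.14,
                  "Streptococcus parasanguinis" = 0.14,
                  "Streptococcus pneumoniae" = 0.05,
                  "Streptococcus pseudopneumoniae" = 0.02,
                  "Streptococcus lactarius" = 0.01,
                  "Streptococcus australis" = 0.03,
                  "Streptococcus peroris" = 0.0174),
        Anginosus = c("Streptococcus anginosus" = 0.55,
                      "Streptococcus constellatus" = 0.3725,
                      "Streptococcus intermedius" = 0.0775))),
    buccal_industrial = group_spec(
      n = 28, host = "human", sample_type = "buccal_mucosa",
      group_label = "industrial",
      genus_mean = 0.39, genus_sd = 0.19, genus_support = c(0.25, 1),
      clade_mean = clade_vec(Sanguinis = 0.10, Mitis = 0.60,
                             Anginosus = 0.04, Salivarius = 0.13,
                             Mutans = 0.01, Bovis = 0.01, Pyogenic = 0.01,
                             Downei = 0.005, Other = 0.065, Unknown = 0.03)),
    buccal_nonindustrial = group_spec(
      n = 28, host = "human", sample_type = "buccal_mucosa",
      group_label = "non-industrial",
      genus_mean = 0.16, genus_sd = 0.08,
      clade_mean = clade_vec(Sanguinis = 0.10, Mitis = 0.60,
                             Anginosus = 0.04, Salivarius = 0.13,
                             Mutans = 0.01, Bovis = 0.01, Pyogenic = 0.01,
                             Downei = 0.005, Other = 0.065, Unknown = 0.03)),
    saliva_industrial = group_spec(
      n = 135, host = "human", sample_type = "saliva",
      group_label = "industrial",
      genus_mean = 0.14, genus_sd = 0.03,
      clade_mean = clade_vec(Sanguinis = 0.08, Mitis = 0.52,
                             Anginosus = 0.04, Salivarius = 0.22,
                             Mutans = 0.01, Bovis = 0.01, Pyogenic = 0.01,
                             Downei = 0.005, Other = 0.075, Unknown = 0.03)),
    saliva_nonindustrial = group_spec(
      n = 132, host = "human", sample_type = "saliva",
      group_label = "non-industrial",
      genus_mean = 0.19, genus_sd = 0.07,
      clade_mean = clade_vec(Sanguinis = 0.08, Mitis = 0.52,
                             Anginosus = 0.04, Salivarius = 0.22,
                             Mutans = 0.01, Bovis = 0.01, Pyogenic = 0.01,
                             Downei = 0.005, Other = 0.075, Unknown = 0.03)),
    chimp_calculus = group_spec(
      n = 20, host = "chimpanzee", sample_type = "ancient_calculus",
      group_label = "nhp",
      genus_mean = 0.0033, genus_sd = 0.0023,
      clade_mean = clade_vec(Sanguinis = 0.04, Mitis = 0.10,
                             Anginosus = 0.04, Salivarius = 0.05,
                             Mutans = 0.03, Bovis = 0.05, Pyogenic = 0.12,
                             Downei = 0.02, Other = 0.30, Unknown = 0.25)),
    chimp_swab = group_spec(
      n = 20, host = "chimpanzee", sample_type = "oral_swab",
      group_label = "nhp",
      genus_mean = 0.031, genus_sd = 0.016,
      clade_mean = clade_vec(Sanguinis = 0.02, Mitis = 0.08,
                             Anginosus = 0.03, Salivarius = 0.06,
                             Mutans = 0.02, Bovis = 0.05, Pyogenic = 0.08,
                             Downei = 0.01, Other = 0.35, Unknown = 0.30)),
    vervet_swab = group_spec(
      n = 16, host = "vervet_monkey", sample_type = "oral_swab",
      group_label = "nhp",
      genus_mean = 0.59, genus_sd = 0.20,
      clade_mean = clade_vec(Sanguinis = 0.01, Mitis = 0.05,
                             Anginosus = 0.02, Salivarius = 0.04,
                             Mutans = 0.01, Bovis = 0.08, Pyogenic = 0.10,
                             Downei = 0.01, Other = 0.40, Unknown = 0.28)),
    gorilla_calculus = group_spec(
      n = 15, host = "gorilla", sample_type = "ancient_calculus",
      group_label = "nhp",
      genus_mean = 0.01, genus_sd = 0.008,
      clade_mean = clade_vec(Sanguinis = 0.03, Mitis = 0.09,
                             Anginosus = 0.04, Salivarius = 0.05,
                             Mutans = 0.03, Bovis = 0.06, Pyogenic = 0.10,
                             Downei = 0.02, Other = 0.33, Unknown = 0.25)),
    baboon_calculus = group_spec(
      n = 20, host = "baboon", sample_type = "ancient_calculus",
      group_label = "nhp",
      genus_mean = 0.05, genus_sd = 0.03,
      clade_mean = clade_vec(Sanguinis = 0.40, Mitis = 0.25,
                             Anginosus = 0.04, Salivarius = 0.07,
                             Mutans = 0.03, Bovis = 0.03, Pyogenic = 0.04,
                             Downei = 0.01, Other = 0.08, Unknown = 0.05)),
    howler_calculus = group_spec(
      n = 12, host = "howler_monkey", sample_type = "ancient_calculus",
      group_label = "nhp",
      genus_mean = 0.02, genus_sd = 0.015,
      clade_mean = clade_vec(Sanguinis = 0.05, Mitis = 0.12,
                             Anginosus = 0.05, Salivarius = 0.06,
                             Mutans = 0.04, Bovis = 0.08, Pyogenic = 0.10,
                             Downei = 0.02, Other = 0.28, Unknown = 0.20)),
    howler_swab = group_spec(
      n = 12, host = "howler_monkey", sample_type = "oral_swab",
      group_label = "nhp",
      genus_mean = 0.08, genus_sd = 0.05,
      clade_mean = clade_vec(Sanguinis = 0.02, Mitis = 0.10,
                             Anginosus = 0.04, Salivarius = 0.05,
                             Mutans = 0.02, Bovis = 0.07, Pyogenic = 0.12,
                             Downei = 0.02, Other = 0.32, Unknown = 0.24)))
  if (!is.null(groups)) {
    missing <- setdiff(groups, names(g))
    if (length(missing)) stop("unknown group(s): ",
                              paste(missing, collapse = ", "))
    g <- g[groups]
  }
  structure(list(groups = g,
                 species_weights = base_species_weights(),
                 species_conc = 3,
                 background_conc = 25,
                 depth_meanlog = log(1e5), depth_sdlog = 0.5),
            class = "cohort_config")
}

# ---- cohort generation -------------------------------------------------

draw_species_probs <- function(clade_props, weights, overrides, conc) {
  unlist(lapply(names(clade_props), function(cl) {
    w <- if (!is.null(overrides) && cl %in% names(overrides))
      overrides[[cl]] else weights[[cl]]
    if (abs(sum(w) - 1) > 1e-6)
      stop("species weights for clade ", cl, " must sum to 1")
    p <- as.vector(rdirichlet(1, conc * w))
    stats::setNames(clade_props[[cl]] * p, names(w))
  }))
}

#' Generate a synthetic oral-metagenome cohort
#'
#' Draws, per sample: a dominance state (ancient calculus only; the
#' Anginosus-dominant minority count is fixed at round(n * weight) and
#' assigned to random samples), a genus share from the group's logit-normal,
#' a clade composition from a Dirichlet centered on the group/state clade
#' mixture, within-clade species splits, a background-genus composition, a
#' sequencing depth, and finally multinomial read counts over all species.
#' Fully reproducible given `seed`.
#'
#' @param config a `cohort_config` (see [cohort_config()]).
#' @param seed integer seed.
#' @param groups optional subset of group names to generate.
#' @return list: `table` ([species_table], species-level mpa lineages),
#'   `metadata` (data.frame), `clade_map` (data.frame species/clade for all
#'   focal species).
#' @export
generate_cohort <- function(config, seed = 1, groups = NULL) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  specs <- config$groups
  if (!is.null(groups)) {
    missing <- setdiff(groups, names(specs))
    if (length(missing)) stop("unknown group(s): ",
                              paste(missing, collapse = ", "))
    specs <- specs[groups]
  }
  set.seed(seed)

  focal <- focal_species_inventory()
  bg <- background_inventory()
  contam <- contaminant_inventory()
  all_species <- c(focal$species, bg$species, contam$species)
  lineages <- c(paste0(STREP_LINEAGE_HEAD, focal$species),
                other_lineage(bg$genus, bg$species, bg$phylum),
                other_lineage(contam$genus, contam$species, contam$phylum))
  bg_w <- bg$weight / sum(bg$weight)
  contam_w <- contam$weight / sum(contam$weight)

  counts <- NULL
  meta <- NULL
  for (gname in names(specs)) {
    s <- specs[[gname]]
    n <- s$n
    if (n == 0) next
    states <- rep("sanguinis", n)
    k <- round(n * s$anginosus_weight)
    if (k > 0) states[sample.int(n, k)] <- "anginosus"
    contaminated <- rep(FALSE, n)
    if (s$n_contaminated > 0)
      contaminated[sample.int(n, min(n, s$n_contaminated))] <- TRUE
    gm <- matrix(0L, nrow = length(all_species), ncol = n)
    for (i in seq_len(n)) {
      ang <- states[i] == "anginosus"
      mu <- if (ang) s$angdom$genus_mu else s$genus_mu
      sg <- if (ang) s$angdom$genus_sigma else s$genus_sigma
      cm <- if (ang) s$angdom$clade_mean else s$clade_mean
      ov <- if (ang && !is.null(s$angdom$species_overrides))
        utils::modifyList(as.list(s$species_overrides %||% list()),
                          as.list(s$angdom$species_overrides))
      else s$species_overrides
      sup <- if (ang) c(0, 1) else s$genus_support
      g <- sup[1] + (sup[2] - sup[1]) * rlogitnorm(1, mu, sg)
      clade_props <- stats::setNames(
        as.vector(rdirichlet(1, s$clade_conc * cm)), names(cm))
      sp_probs <- draw_species_probs(clade_props, config$species_weights,
                                     ov, config$species_conc)
      bgp <- as.vector(rdirichlet(1, config$background_conc * bg_w))
      p <- c(g * sp_probs[focal$species],
             (1 - g) * bgp,
             rep(0, nrow(contam)))
      if (contaminated[i]) {
        f <- s$contam_fraction
        cp <- as.vector(rdirichlet(1, 10 * contam_w))
        p <- c(p[seq_len(length(p) - nrow(contam))] * (1 - f), f * cp)
      }
      depth <- max(1000, round(stats::rlnorm(1, config$depth_meanlog,
                                             config$depth_sdlog)))
      gm[, i] <- stats::rmultinom(1, depth, p)
    }
    ids <- sprintf("%s_%03d", gname, seq_len(n))
    colnames(gm) <- ids
    counts <- if (is.null(counts)) gm else cbind(counts, gm)
    meta_g <- data.frame(
      sample_id = ids, host = s$host, sample_type = s$sample_type,
      group = s$group_label, cohort = gname,
      age_bp = if (s$sample_type == "ancient_calculus" &&
                   s$host == "human")
        round(stats::runif(n, 100, 5000)) else NA_integer_,
      sim_dominance = ifelse(states == "anginosus", "Anginosus",
                             "Sanguinis"),
      sim_contaminated = contaminated,
      stringsAsFactors = FALSE)
    meta <- if (is.null(meta)) meta_g else rbind(meta, meta_g)
  }
  if (is.null(counts)) {
    counts <- matrix(integer(0), nrow = length(all_species), ncol = 0,
                     dimnames = list(NULL, character(0)))
    meta <- data.frame(sample_id = character(0), host = character(0),
                       sample_type = character(0), group = character(0),
                       cohort = character(0), age_bp = integer(0),
                       sim_dominance = character(0),
                       sim_contaminated = logical(0))
  }
  list(table = species_table(counts, lineages), metadata = meta,
       clade_map = focal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- planted ANI matrices ---------------------------------------------

#' Generate a block-structured ANI matrix with planted clades
#'
#' Builds a symmetric ANI matrix whose blocks mirror the clade/species
#' hierarchy: genomes of the same species share high identity, species of
#' the same clade intermediate identity, different clades lower identity,
#' and `n_unplaced` basal genomes are distant from everything (they form
#' their own outgroup and should resolve to "Unknown"). `n_other` unnamed
#' species are inserted inside random clades at within-clade identity (they
#' should resolve to "Other"). The first genome of every named species
#' carries the species name so reference labels can be matched.
#'
#' @param n_clades number of named clades to plant (taken in fixed clade
#'   order from the bundled reference).
#' @param species_per_clade named species per clade (limited by the
#'   reference inventory).
#' @param genomes_per_species genomes per named species.
#' @param n_unplaced basal genomes planted as "Unknown".
#' @param seed integer seed.
#' @param n_other unnamed within-clade species planted as "Other".
#' @param ranges list of ANI ranges `within_species`, `within_clade`,
#'   `between_clade`, `basal`; must be disjoint and decreasing.
#' @return list: `ani` (an `ani_matrix`), `planted` (data.frame `genome`,
#'   `species`, `clade`), `named_labels` (reference table for
#'   [assign_clades()]).
#' @export
generate_ani <- function(n_clades = 4, species_per_clade = 3,
                         genomes_per_species = 2, n_unplaced = 2, seed = 1,
                         n_other = 1,
                         ranges = list(within_species = c(96.5, 99.9),
                                       within_clade = c(85, 94),
                                       between_clade = c(75, 84),
                                       basal = c(70, 74))) {
  stopifnot(n_clades >= 1, species_per_clade >= 1, genomes_per_species >= 1,
            n_unplaced >= 0, n_other >= 0)
  r <- ranges
  lims <- rbind(r$basal, r$between_clade, r$within_clade, r$within_species)
  if (any(diff(as.vector(t(lims))) <= 0))
    stop("ANI ranges must be disjoint and increasing from basal to species")
  set.seed(seed)

  ref <- strep_clade_reference()
  clades <- CLADE_PRECEDENCE[seq_len(min(n_clades, 8))]
  genomes <- character(0)
  species <- character(0)
  clade_of <- character(0)
  for (cl in clades) {
    sp <- utils::head(ref$species[ref$clade == cl], species_per_clade)
    if (length(sp) < species_per_clade)
      sp <- c(sp, sprintf("Streptococcus %s_extra%d", tolower(cl),
                          seq_len(species_per_clade - length(sp))))
    for (s in sp) {
      ids <- c(s, if (genomes_per_species > 1)
        sprintf("%s g%d", s, seq_len(genomes_per_species - 1)))
      genomes <- c(genomes, ids)
      species <- c(species, rep(s, length(ids)))
      clade_of <- c(clade_of, rep(cl, length(ids)))
    }
  }
  if (n_other > 0) {
    host_clade <- sample(clades, n_other, replace = TRUE)
    for (i in seq_len(n_other)) {
      s <- sprintf("Streptococcus sp%06d", 900000 + i)
      ids <- c(s, if (genomes_per_species > 1)
        sprintf("%s g%d", s, seq_len(genomes_per_species - 1)))
      genomes <- c(genomes, ids)
      species <- c(species, rep(s, length(ids)))
      clade_of <- c(clade_of, rep(paste0("other:", host_clade[i]),
                                  length(ids)))
    }
  }
  if (n_unplaced > 0) {
    for (i in seq_len(n_unplaced)) {
      s <- sprintf("Streptococcus sp%06d", 990000 + i)
      genomes <- c(genomes, s)
      species <- c(species, s)
      clade_of <- c(clade_of, "basal")
    }
  }

  ng <- length(genomes)
  m <- matrix(NA_real_, ng, ng, dimnames = list(genomes, genomes))
  runifr <- function(n, rr) stats::runif(n, rr[1], rr[2])
  # basal genomes cluster with one another just above their range so the
  # outgroup attaches to the rest of the tree strictly last (at the root)
  basal_internal <- c(max(r$basal) + 0.1 * (min(r$between_clade) -
                                              max(r$basal)),
                      max(r$basal) + 0.4 * (min(r$between_clade) -
                                              max(r$basal)))
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      if (j <= i) next
      bi <- clade_of[i] == "basal"; bj <- clade_of[j] == "basal"
      host_i <- sub("^other:", "", clade_of[i])
      host_j <- sub("^other:", "", clade_of[j])
      v <- if (bi && bj) runifr(1, basal_internal)
      else if (bi || bj) runifr(1, r$basal)
      else if (species[i] == species[j]) runifr(1, r$within_species)
      else if (host_i == host_j) runifr(1, r$within_clade)
      else runifr(1, r$between_clade)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  diag(m) <- 100
  planted_clade <- ifelse(clade_of == "basal", "Unknown",
                          ifelse(startsWith(clade_of, "other:"), "Other",
                                 clade_of))
  named <- ref[ref$clade %in% clades &
                 ref$species %in% species, , drop = FALSE]
  list(ani = ani_matrix(m),
       planted = data.frame(genome = genomes, species = species,
                            clade = planted_clade, stringsAsFactors = FALSE),
       named_labels = named)
}
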