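#' Cumulative percent decay curve
#'
#' Preservation QC for (ancient) oral metagenomes: taxa are ranked by
#' decreasing abundance and, at each rank k, the curve reports the percent
#' of the top-k taxa that belong to a reference set of known oral taxa.
#' Well-preserved oral samples stay near 100 at the top ranks; samples
#' overwhelmed by environmental (soil, skin) taxa decay quickly.
#'
#' @param abundances named numeric vector of taxon abundances for one
#'   sample (any scale; only ranks matter). Ties rank lexicographically.
#' @param oral_reference character vector of oral taxon names.
#' @return `decay_curve`: data.frame `rank`, `taxon`, `in_reference`,
#'   `percent`.
#' @export
decay_curve <- function(abundances, oral_reference) {
  if (!length(abundances)) stop("empty abundance vector")
  if (!length(oral_reference)) stop("empty oral reference set")
  if (is.null(names(abundances))) stop("abundances must be named by taxon")
  ord <- order(-abundances, names(abundances))
  taxa <- names(abundances)[ord]
  inref <- taxa %in% oral_reference
  out <- data.frame(rank = seq_along(taxa), taxon = taxa,
                    in_reference = inref,
                    percent = 100 * cumsum(inref) / seq_along(taxa),
                    stringsAsFactors = FALSE)
  class(out) <- c("decay_curve", class(out))
  out
}

#' Assess preservation from a decay curve
#'
#' A sample passes when its cumulative-percent-decay curve stays at or
#' above `min_percent` at every rank from `burn_in_rank` onward. The first
#' ranks are excluded because a handful of highly abundant contaminants can
#' distort the head of the curve even in well-preserved samples. Cutoffs
#' are intended to be set per sample group (ancient vs modern).
#'
#' @param curve a `decay_curve`.
#' @param burn_in_rank first rank at which the threshold applies (>= 1).
#' @param min_percent minimum acceptable percent of oral taxa.
#' @return logical: TRUE when the sample passes.
#' @export
assess_preservation <- function(curve, burn_in_rank = 10, min_percent = 50) {
  if (burn_in_rank < 1) stop("burn_in_rank must be >= 1")
  if (burn_in_rank > nrow(curve))
    stop("burn_in_rank exceeds the curve length")
  all(curve$percent[curve$rank >= burn_in_rank] >= min_percent)
}

#' Preservation screen for a whole species table
#'
#' Runs [decay_curve()] and [assess_preservation()] on every sample, with
#' group-specific thresholds.
#'
#' @param table a [species_table]; species-level rows are used.
#' @param oral_reference character vector of oral species names.
#' @param groups optional named vector (by sample) of group labels.
#' @param burn_in_rank rank at which thresholds start to apply.
#' @param min_percent single threshold or named vector by group label.
#' @return data.frame `sample`, `group`, `min_percent`, `pass`.
#' @export
screen_preservation <- function(table, oral_reference, groups = NULL,
                                burn_in_rank = 10, min_percent = 50) {
  sp <- species_level(table)
  nm <- taxon_names(sp)$species
  out <- lapply(sp$sample_ids, function(s) {
    v <- stats::setNames(sp$counts[, s], nm)
    v <- v[v > 0]
    g <- if (is.null(groups)) "all" else unname(groups[s])
    thr <- if (!is.null(names(min_percent))) {
      if (!g %in% names(min_percent))
        stop("no preservation threshold for group: ", g)
      min_percent[[g]]
    } else min_percent
    pass <- if (!length(v)) FALSE else {
      cv <- decay_curve(v, oral_reference)
      assess_preservation(cv, burn_in_rank = min(burn_in_rank, nrow(cv)),
                          min_percent = thr)
    }
    data.frame(sample = s, group = g, min_percent = thr, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
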