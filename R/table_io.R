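#' @keywords internal
"_PACKAGE"

RANK_PREFIXES <- c(d = "d__", p = "p__", c = "c__", o = "o__", f = "f__",
                   g = "g__", s = "s__")
RANK_NAMES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

CLADE_LABELS <- c("Sanguinis", "Mitis", "Salivarius", "Anginosus", "Bovis",
                  "Pyogenic", "Mutans", "Downei", "Other", "Unknown")

#' Construct a species table
#'
#' A `species_table` holds a taxa-by-samples matrix of read counts together
#' with the full rank-prefixed lineage string of every taxon, as produced by
#' joining per-sample Kraken-style metaphlan ("mpa") reports. Lineage strings
#' are pipe-separated paths from domain to the terminal rank
#' (`d__...|p__...|...|s__Genus species`); a leading `k__` is accepted as an
#' alias for `d__`.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; must be
#'   non-negative and will be stored as-is (integers are preserved exactly).
#' @param lineage character vector of lineage strings, one per row of
#'   `counts`.
#' @return An object of class `species_table` with elements `counts`,
#'   `lineage`, `rank` (terminal rank name per taxon), `sample_ids`.
#' @export
species_table <- function(counts, lineage) {
  counts <- as.matrix(counts)
  if (length(lineage) != nrow(counts))
    stop("lineage length must equal nrow(counts)")
  if (ncol(counts) > 0 &&
      (is.null(colnames(counts)) || any(!nzchar(colnames(counts)))))
    stop("species_table requires named sample columns")
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(lineage))
    stop("duplicate lineage string(s): ",
         paste(unique(lineage[duplicated(lineage)]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  lineage <- gsub("^k__", "d__", lineage)
  rank <- vapply(strsplit(lineage, "|", fixed = TRUE), function(p) {
    last <- p[length(p)]
    pref <- substr(last, 1, 3)
    i <- match(pref, RANK_PREFIXES)
    if (is.na(i)) stop("unrecognized rank prefix in lineage: ", last)
    RANK_NAMES[i]
  }, character(1))
  # every species-rank lineage must carry a genus component
  sp <- rank == "species"
  if (any(sp & !grepl("g__", lineage, fixed = TRUE)))
    stop("species-rank lineage without a genus component: ",
         lineage[which(sp & !grepl("g__", lineage, fixed = TRUE))[1]])
  rownames(counts) <- lineage
  structure(list(counts = counts, lineage = lineage, rank = unname(rank),
                 sample_ids = colnames(counts)),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("species_table: %d taxa (%d species-level) x %d samples\n",
              length(x$lineage), sum(x$rank == "species"),
              length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.species_table <- function(x) dim(x$counts)

#' Read a combined mpa-format taxonomy table
#'
#' Reads the tab-separated output of joining per-sample mpa reports (e.g.
#' KrakenTools `combine_mpa.py`): one lineage column (named
#' `#Classification` or unnamed/first) followed by one integer count column
#' per sample. Duplicate lineages and non-numeric count cells are hard
#' errors.
#'
#' @param path path to the TSV file.
#' @return a [species_table].
#' @export
read_mpa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("mpa table has no sample columns: ", path)
  lineage <- df[[1]]
  samples <- df[, -1, drop = FALSE]
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(samples[[j]]))
    bad <- which(is.na(v) & !is.na(samples[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric count at row %d, column '%s': '%s'",
                   bad[1], colnames(samples)[j], samples[[bad[1], j]]))
    samples[[j]] <- v
  }
  m <- as.matrix(samples)
  species_table(m, lineage)
}

#' Write a species table in mpa format
#'
#' @param x a [species_table].
#' @param path output path.
#' @export
write_mpa_table <- function(x, path) {
  df <- data.frame(`#Classification` = x$lineage, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a species table to its species-level rows
#'
#' Filters rows to the requested terminal rank; counts are untouched.
#'
#' @param x a [species_table].
#' @param rank terminal rank to keep (default `"species"`).
#' @return a [species_table] with only the matching rows.
#' @export
species_level <- function(x, rank = "species") {
  keep <- x$rank == rank
  species_table(x$counts[keep, , drop = FALSE], x$lineage[keep])
}

#' Extract the genus and species names of each taxon
#'
#' The genus is always taken from the `g__` component of the lineage itself,
#' never parsed out of the species name, so GTDB suffixed names such as
#' "Streptococcus oralis_S" stay distinct species of genus Streptococcus.
#'
#' @param x a [species_table].
#' @return data.frame with columns `lineage`, `genus`, `species` (NA where a
#'   rank is absent from the lineage).
#' @export
taxon_names <- function(x) {
  comp <- function(lin, pref) {
    parts <- strsplit(lin, "|", fixed = TRUE)
    vapply(parts, function(p) {
      hit <- p[startsWith(p, pref)]
      if (length(hit)) sub(pref, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  data.frame(lineage = x$lineage,
             genus = comp(x$lineage, "g__"),
             species = comp(x$lineage, "s__"),
             stringsAsFactors = FALSE)
}

#' Read a symmetric pairwise ANI matrix
#'
#' Expects a square labeled TSV of average-nucleotide-identity percentages.
#' The diagonal is forced to 100. Missing pairs (empty or NA cells) are
#' imputed at `floor_value` with a warning, mirroring ANI tools that omit
#' pairs below their reporting threshold. Asymmetric entries beyond
#' `tol` ANI points are an error; smaller asymmetries are averaged.
#'
#' @param path path to the square TSV (row and column genome labels).
#' @param floor_value ANI percentage used for missing pairs (default 70).
#' @param tol allowed row/column asymmetry in ANI points (default 0.5).
#' @return an `ani_matrix`: symmetric numeric matrix, diagonal 100.
#' @export
read_ani_matrix <- function(path, floor_value = 70, tol = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("ANI matrix is not square: %d rows, %d columns",
                 nrow(m), ncol(m)))
  if (!identical(rownames(m), colnames(m)))
    stop("ANI matrix row labels do not match column labels")
  ani_matrix(m, floor_value = floor_value, tol = tol)
}

#' Validate and finalize an ANI matrix
#'
#' @param m square numeric matrix with matching dimnames; values in
#'   \[0, 100\] or NA.
#' @inheritParams read_ani_matrix
#' @return matrix of class `ani_matrix`.
#' @export
ani_matrix <- function(m, floor_value = 70, tol = 0.5) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("ANI matrix must be square")
  if (is.null(rownames(m))) stop("ANI matrix must be labeled")
  if (!identical(rownames(m), colnames(m)))
    stop("ANI matrix row labels must match column labels")
  if (any(is.na(m))) {
    warning(sprintf("%d missing ANI pair(s) imputed at floor %.1f",
                    sum(is.na(m) & upper.tri(m, diag = FALSE)) +
                      sum(is.na(m) & lower.tri(m)), floor_value))
    m[is.na(m)] <- floor_value
  }
  if (any(m < 0 | m > 100)) stop("ANI values must lie in [0, 100]")
  d <- abs(m - t(m))
  if (any(d > tol)) {
    idx <- which(d > tol & upper.tri(d), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(ij)
      paste0(rownames(m)[ij[1]], "/", colnames(m)[ij[2]]))
    stop("asymmetric ANI beyond tolerance for pair(s): ",
         paste(utils::head(pairs, 5), collapse = ", "))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 100
  class(m) <- c("ani_matrix", class(m))
  m
}

#' Write an ANI matrix TSV
#'
#' @param m `ani_matrix` (or plain labeled square matrix).
#' @param path output path.
#' @export
write_ani_matrix <- function(m, path) {
  # %.17g round-trips IEEE doubles exactly
  ch <- apply(unclass(m), 2, function(v) sprintf("%.17g", v))
  df <- data.frame(genome = rownames(m), ch, check.names = FALSE)
  colnames(df) <- c("genome", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path TSV with at least a `sample_id` column; sample ids must be
#'   unique.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(md)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1])
  md
}

#' Read a named-species clade reference table
#'
#' @param path TSV with columns `species` and `clade`.
#' @return data.frame with columns `species`, `clade`.
#' @export
read_clade_reference <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("species", "clade") %in% colnames(df)))
    stop("clade reference needs 'species' and 'clade' columns")
  bad <- setdiff(unique(df$clade), CLADE_LABELS)
  if (length(bad)) stop("unrecognized clade label(s): ",
                        paste(bad, collapse = ", "))
  df[, c("species", "clade")]
}

#' The bundled Streptococcus clade reference
#'
#' Named oral and pathogenic Streptococcus species mapped to the eight
#' phylogenetically supported clades (Sanguinis, Mitis, Salivarius,
#' Anginosus, Bovis, Pyogenic, Mutans, Downei).
#'
#' @return data.frame with columns `species`, `clade`.
#' @export
strep_clade_reference <- function() {
  read_clade_reference(system.file("extdata", "streptococcus_clades.tsv",
                                   package = "strepclades", mustWork = TRUE))
}

#' Write a long-format result table
#'
#' Deterministic TSV writer used for every result artifact: UTF-8,
#' tab-separated, header always present, rows sorted by the given key
#' columns so that identical results are byte-identical files.
#'
#' @param records data.frame (may have zero rows).
#' @param path output path.
#' @param sort_by character vector of key columns for the row order
#'   (default: all non-numeric columns left to right, then numeric ones).
#' @export
write_long_results <- function(records, path, sort_by = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(sort_by)) {
    isnum <- vapply(records, is.numeric, logical(1))
    sort_by <- c(colnames(records)[!isnum], colnames(records)[isnum])
  }
  if (nrow(records) > 1 && length(sort_by)) {
    ord <- do.call(order, unname(records[, sort_by, drop = FALSE]))
    records <- records[ord, , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format result table back
#'
#' @param path TSV written by [write_long_results()].
#' @return data.frame.
#' @export
read_long_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
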