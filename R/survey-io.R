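#' Write a tree-level survey table to CSV
#'
#' Writes the canonical tree-level layout (`site,tree,region,oak_type,
#' girth_m,tmax_c,lat,lon,n_samples,n_sp_positive,other_yeast_freq`);
#' missing girth becomes an empty field.
#'
#' @param trees data frame as produced by [simulate_survey()] or
#'   [aggregate_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(trees, path) {
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.tree_cols <- c("site", "tree", "region", "oak_type", "girth_m", "tmax_c",
                "lat", "lon", "n_samples", "n_sp_positive",
                "other_yeast_freq")

#' Read a tree-level survey table from CSV
#'
#' Reads and validates the canonical tree-level layout. Empty girth fields
#' become `NA` (the row is retained: girth is the only covariate allowed to
#' be missing). Malformed rows are reported with their line numbers.
#'
#' @param path CSV path with the header written by [write_survey()].
#' @return validated tree-level data frame.
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(.tree_cols, names(d))
  if (length(missing_cols))
    stop("survey file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- d[, .tree_cols]
  # line number in the file = data row + 1 (header)
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop(what, " at line(s) ",
           paste(which(cond) + 1L, collapse = ", "), call. = FALSE)
  }
  for (col in c("girth_m", "tmax_c", "lat", "lon", "n_samples",
                "n_sp_positive", "other_yeast_freq"))
    if (!is.numeric(d[[col]]))
      stop("column '", col, "' is not numeric", call. = FALSE)
  bad(d$lat < -90 | d$lat > 90, "latitude outside [-90, 90]")
  bad(d$lon < -180 | d$lon > 180, "longitude outside [-180, 180]")
  bad(!is.na(d$girth_m) & d$girth_m <= 0, "non-positive girth")
  bad(is.na(d$n_samples) | d$n_samples < 1, "missing or zero sample count")
  bad(is.na(d$n_sp_positive) | d$n_sp_positive < 0 |
        d$n_sp_positive > d$n_samples,
      "positive count outside [0, n_samples]")
  bad(!is.na(d$other_yeast_freq) &
        (d$other_yeast_freq < 0 | d$other_yeast_freq > 1),
      "other-yeast frequency outside [0, 1]")
  d
}

#' Aggregate raw sample records to tree-level observations
#'
#' Collapses one-row-per-sample records to one row per tree, applying the
#' survey's modelling filters *before* counting: only the chosen substrate
#' is retained (default oak bark, which drops soil samples collected at tree
#' bases) and pilot samples incubated at an excluded temperature (default
#' 10 degC) are removed. Trials are the retained samples per tree; successes
#' are retained samples whose species list contains the target species.
#'
#' @param samples data frame with columns `sample_id`, `site`, `tree_id`,
#'   `substrate`, `species_found` (semicolon-separated species names; empty
#'   for no yeast), `lat`, `lon`, and optionally `incubation_temp_c` and
#'   `collection_date`.
#' @param target species counted as a success.
#' @param substrate_keep substrates retained (exact match).
#' @param exclude_incubation_c incubation temperatures excluded as pilot
#'   conditions (ignored when the column is absent).
#' @return tree-level data frame: `tree_id`, `site`, `lat`, `lon`,
#'   `n_samples`, `n_sp_positive`, `other_yeast_freq` (fraction of retained
#'   samples yielding a non-target yeast).
#' @export
aggregate_tree <- function(samples,
                           target = "Saccharomyces paradoxus",
                           substrate_keep = "oak bark",
                           exclude_incubation_c = 10) {
  need <- c("sample_id", "site", "tree_id", "substrate", "species_found",
            "lat", "lon")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- samples$substrate %in% substrate_keep
  if ("incubation_temp_c" %in% names(samples))
    keep <- keep & !(samples$incubation_temp_c %in% exclude_incubation_c)
  s <- samples[keep, , drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(tree_id = character(), site = character(),
                      lat = numeric(), lon = numeric(),
                      n_samples = integer(), n_sp_positive = integer(),
                      other_yeast_freq = numeric(),
                      stringsAsFactors = FALSE))
  species <- strsplit(ifelse(is.na(s$species_found), "", s$species_found),
                      ";", fixed = TRUE)
  species <- lapply(species, trimws)
  hit <- vapply(species, function(x) target %in% x, logical(1))
  other <- vapply(species, function(x) any(nzchar(x) & x != target),
                  logical(1))
  key <- paste(s$site, s$tree_id, sep = "\r")
  agg <- data.frame(
    tree_id = tapply(s$tree_id, key, `[`, 1L),
    site = tapply(s$site, key, `[`, 1L),
    lat = as.numeric(tapply(s$lat, key, `[`, 1L)),
    lon = as.numeric(tapply(s$lon, key, `[`, 1L)),
    n_samples = as.integer(tapply(rep(1L, nrow(s)), key, sum)),
    n_sp_positive = as.integer(tapply(hit, key, sum)),
    other_yeast_freq = as.numeric(tapply(other, key, mean)),
    stringsAsFactors = FALSE)
  agg <- agg[order(agg$site, agg$tree_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-site summaries of a tree-level survey
#'
#' Reproduces the site-level summary layout of the survey: tree and sample
#' counts, means of Tmax and girth weighted by the number of bark samples
#' per tree, the count of positive samples and the isolation frequency
#' (positives / samples). Sites with zero samples report a missing
#' frequency.
#'
#' @param trees tree-level data frame (columns `site`, `n_samples`,
#'   `n_sp_positive`, and optionally `tmax_c`, `girth_m`).
#' @return data frame with one row per site: `site`, `n_trees`,
#'   `n_samples`, `weighted_mean_tmax`, `weighted_mean_girth`, `n_sp`,
#'   `sp_freq`.
#' @export
summarize_site <- function(trees) {
  stopifnot(all(c("site", "n_samples", "n_sp_positive") %in% names(trees)))
  split_idx <- split(seq_len(nrow(trees)), trees$site)
  wmean <- function(x, w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  rows <- lapply(split_idx, function(ix) {
    t <- trees[ix, , drop = FALSE]
    ns <- sum(t$n_samples)
    data.frame(
      site = t$site[1L],
      n_trees = nrow(t),
      n_samples = ns,
      weighted_mean_tmax = if ("tmax_c" %in% names(t))
        wmean(t$tmax_c, t$n_samples) else NA_real_,
      weighted_mean_girth = if ("girth_m" %in% names(t))
        wmean(t$girth_m, t$n_samples) else NA_real_,
      n_sp = sum(t$n_sp_positive),
      sp_freq = if (ns > 0) sum(t$n_sp_positive) / ns else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read a strain-location table
#'
#' CSV layout mirroring a worldwide strain collection: `strain_id`,
#' `species`, `genotype_class` (wild / human-associated / mosaic / unknown),
#' `lat`, `lon`, `substrate`, `source_study`.
#'
#' @param strains strain data frame (e.g. from [simulate_strains()]).
#' @param path CSV path.
#' @return `path` invisibly (write) or a validated data frame (read).
#' @export
write_strains <- function(strains, path) {
  utils::write.csv(strains, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_strains
#' @export
read_strains <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("strain_id", "species", "genotype_class", "lat", "lon")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("strain file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  vocab <- c("wild", "human-associated", "mosaic", "unknown")
  badv <- !d$genotype_class %in% vocab
  if (any(badv))
    stop("unknown genotype_class at line(s) ",
         paste(which(badv) + 1L, collapse = ", "),
         " (expected: ", paste(vocab, collapse = ", "), ")", call. = FALSE)
  if (any(d$lat < -90 | d$lat > 90 | d$lon < -180 | d$lon > 180,
          na.rm = TRUE))
    stop("strain coordinates outside WGS84 bounds", call. = FALSE)
  d
}
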