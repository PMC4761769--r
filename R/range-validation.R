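#' Classify strain locations against a temperature envelope
#'
#' For each strain, extracts Tmax from the single raster pixel containing
#' its location, flags whether that temperature lies inside the interval,
#' and for out-of-range strains computes the great-circle distance to the
#' nearest in-range cell center. Strains whose pixel is nodata (or that fall
#' off the raster) are flagged unclassifiable and carry `NA` temperature and
#' distance; their count is reported via a message so exclusions stay
#' auditable.
#'
#' @param strains strain data frame (see [read_strains()]).
#' @param grid a [tmax_raster()].
#' @param interval numeric `c(T_lo, T_hi)` degrees C defining "in range".
#' @return the input with added columns `tmax_c`, `in_range`,
#'   `distance_km`, `classifiable`.
#' @export
classify_strains <- function(strains, grid, interval) {
  stopifnot(inherits(grid, "tmax_raster"))
  mask <- in_range_mask(grid, interval)
  n <- nrow(strains)
  tmax <- rep(NA_real_, n)
  inr <- rep(NA, n)
  dist <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    v <- tryCatch(value_at(grid, strains$lat[i], strains$lon[i]),
                  error = function(e) NA_real_)
    if (is.na(v)) next
    ok[i] <- TRUE
    tmax[i] <- v
    inr[i] <- v >= interval[1] && v <= interval[2]
    dist[i] <- if (inr[i]) 0 else
      distance_to_range(grid, interval, strains$lat[i], strains$lon[i],
                        mask = mask)
  }
  if (any(!ok))
    message(sum(!ok), " strain(s) on nodata cells or off the raster; ",
            "excluded from in-range fractions")
  out <- strains
  out$tmax_c <- tmax
  out$in_range <- inr
  out$distance_km <- dist
  out$classifiable <- ok
  out
}

#' Summarise classified strains by genotype class
#'
#' @param classified output of [classify_strains()].
#' @param by grouping column, default `genotype_class`.
#' @return data frame per group: `n_total`, `n_classifiable`, `n_in_range`,
#'   `n_out_of_range`, `n_nodata`, `fraction_in_range` (of classifiable
#'   strains; `NA` for empty groups), `median_distance_km` and
#'   `max_distance_km` over out-of-range strains (`NA` when none).
#' @export
summarize_validation <- function(classified, by = "genotype_class") {
  stopifnot(by %in% names(classified))
  groups <- split(classified, classified[[by]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    cl <- d[d$classifiable, , drop = FALSE]
    outr <- cl[!cl$in_range, , drop = FALSE]
    data.frame(
      group = g,
      n_total = nrow(d),
      n_classifiable = nrow(cl),
      n_in_range = sum(cl$in_range),
      n_out_of_range = nrow(outr),
      n_nodata = nrow(d) - nrow(cl),
      fraction_in_range = if (nrow(cl) > 0) mean(cl$in_range) else NA_real_,
      median_distance_km = if (nrow(outr) > 0)
        stats::median(outr$distance_km) else NA_real_,
      max_distance_km = if (nrow(outr) > 0)
        max(outr$distance_km) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}

#' Drop strains whose substrate indicates wine or vineyard origin
#'
#' Range validation must exclude strains whose locations reflect human
#' transport rather than climate (sink populations); the default filter
#' removes substrates mentioning wine or grape. Whether vineyard *soil*
#' counts is genuinely ambiguous, so the match patterns are configurable.
#'
#' @param strains strain data frame.
#' @param patterns case-insensitive substrings of `substrate` to drop.
#' @return filtered data frame.
#' @export
filter_vineyard_strains <- function(strains, patterns = c("wine", "grape")) {
  if (!"substrate" %in% names(strains)) return(strains)
  sub <- tolower(ifelse(is.na(strains$substrate), "", strains$substrate))
  drop <- Reduce(`|`, lapply(patterns, function(p) grepl(p, sub, fixed = TRUE)))
  strains[!drop, , drop = FALSE]
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the two-sided probability-mass convention
#' (all tables with the observed margins whose probability does not exceed
#' the observed table's, within a small relative tolerance), i.e. the
#' convention of [stats::fisher.test()], which this wraps. Used for the
#' between-region and between-study comparisons of isolation rates.
#'
#' @param table2x2 2x2 matrix of counts `rbind(c(a, b), c(c, d))` with rows
#'   as groups and columns as success/failure, or a numeric vector
#'   `c(a, b, c, d)` in row-major order.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table2x2) {
  if (is.numeric(table2x2) && is.null(dim(table2x2)) &&
      length(table2x2) == 4L)
    table2x2 <- matrix(table2x2, 2L, 2L, byrow = TRUE)
  if (!is.matrix(table2x2) || !all(dim(table2x2) == 2L))
    stop("'table2x2' must be a 2x2 matrix or length-4 vector", call. = FALSE)
  if (any(table2x2 < 0) || any(table2x2 != round(table2x2)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table2x2) == 0) || any(colSums(table2x2) == 0))
    stop("degenerate margins: every row and column needs a positive total",
         call. = FALSE)
  stats::fisher.test(table2x2, alternative = "two.sided")$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two samples of distances (e.g. distance-to-range of wild versus
#' human-associated strains). Uses the exact null distribution when both
#' samples are small (`min(n) <= 10`) and untied; otherwise the normal
#' approximation with tie and continuity corrections. Wraps
#' [stats::wilcox.test()].
#'
#' @param x,y numeric samples (non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= 10L && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}
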