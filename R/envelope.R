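#' Temperature envelope for a species
#'
#' A pair of closed Tmax intervals: the `optimum` range where predicted
#' isolation frequency peaks, and the wider `occurrence` range where the
#' species is found at all. For *S. paradoxus* the survey analysis gives an
#' optimum of 22-28 degC and occurrence of 18-31 degC.
#'
#' @param species species label.
#' @param optimum numeric `c(T_lo, T_hi)` degrees C.
#' @param occurrence numeric `c(T_lo, T_hi)` degrees C; must contain
#'   `optimum`.
#' @return object of class `temp_envelope`.
#' @export
temp_envelope <- function(species, optimum, occurrence) {
  stopifnot(is.numeric(optimum), length(optimum) == 2L,
            is.numeric(occurrence), length(occurrence) == 2L)
  if (optimum[1] >= optimum[2] || occurrence[1] >= occurrence[2])
    stop("interval bounds must satisfy T_lo < T_hi", call. = FALSE)
  if (optimum[1] < occurrence[1] || optimum[2] > occurrence[2])
    stop("'optimum' must be contained in 'occurrence'", call. = FALSE)
  structure(list(species = species,
                 optimum = unname(optimum),
                 occurrence = unname(occurrence)),
            class = "temp_envelope")
}

#' @export
print.temp_envelope <- function(x, ...) {
  cat(sprintf("<temp_envelope> %s\n  optimum:    [%g, %g] degC\n  occurrence: [%g, %g] degC\n",
              x$species, x$optimum[1], x$optimum[2],
              x$occurrence[1], x$occurrence[2]))
  invisible(x)
}

#' Predicted isolation-frequency response curve over Tmax
#'
#' Evaluates a fitted model's predicted probability of isolation on a grid of
#' summer temperatures, holding girth and region fixed — the conditioning
#' used to draw response curves at the lower-quartile (0.8 m), median
#' (1.3 m), and upper-quartile (1.9 m) girths.
#'
#' @param fit a [binom_glm()] fit whose formula uses `girth_m`, `tmax_c`,
#'   and `region`.
#' @param girth_m conditioning trunk girth in meters.
#' @param region conditioning region level (must be a level seen by the
#'   fit).
#' @param tmax_grid strictly increasing numeric vector of Tmax values
#'   (degrees C).
#' @return data frame of class `response_curve` with columns `tmax_c`,
#'   `predicted_p`, `girth_m`, `region`.
#' @export
predict_curve <- function(fit, girth_m, region, tmax_grid) {
  stopifnot(inherits(fit, "binom_glm"))
  if (is.unsorted(tmax_grid, strictly = TRUE))
    stop("'tmax_grid' must be strictly increasing", call. = FALSE)
  if (!fit$converged)
    warning("fit did not converge; predictions may be unreliable",
            call. = FALSE)
  vars <- all.vars(stats::delete.response(stats::terms(fit$formula)))
  nd <- data.frame(tmax_c = tmax_grid)
  if ("girth_m" %in% vars) nd$girth_m <- girth_m
  if ("region" %in% vars) {
    seen <- unique(as.character(fit$data_used$region))
    if (!region %in% seen)
      stop("region level '", region, "' was not seen by the fit",
           call. = FALSE)
    nd$region <- factor(region, levels = sort(seen))
  }
  missing_vars <- setdiff(vars, names(nd))
  if (length(missing_vars))
    stop("cannot condition on model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  tt <- stats::delete.response(stats::terms(fit$formula))
  X <- stats::model.matrix(tt, nd,
                           xlev = list(region = levels(nd$region)))
  eta <- drop(X %*% fit$coefficients[colnames(X)])
  out <- data.frame(tmax_c = tmax_grid, predicted_p = stats::plogis(eta),
                    girth_m = if ("girth_m" %in% vars) girth_m else NA_real_,
                    region = if ("region" %in% vars) region else NA_character_)
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Derive optimum and occurrence envelopes from response curves
#'
#' Two policies are offered. The survey analysis read its optimum (22-28
#' degC) and occurrence (18-31 degC) bounds off the fitted curves by
#' inspection rather than by a stated rule, so the default `"fixed"` policy
#' takes explicitly configured bounds. The `"threshold"` policy is a
#' reproducible alternative: the optimum is the Tmax interval where the
#' pooled predicted response is at least `theta` times its maximum, with
#' endpoints located by linear interpolation between grid points and then
#' rounded outward to whole degrees; the occurrence interval defaults to the
#' span of the curve grid rounded outward.
#'
#' @param curves a `response_curve` or list of them (the pointwise maximum
#'   across curves is used under the threshold policy).
#' @param policy `"fixed"` or `"threshold"`.
#' @param species species label for the envelope.
#' @param optimum,occurrence configured bounds, used by the `"fixed"` policy
#'   (occurrence also serves as the fallback under `"threshold"` when the
#'   curves are absent).
#' @param theta relative-height threshold in (0, 1) for the `"threshold"`
#'   policy.
#' @return a [temp_envelope()].
#' @export
derive_ranges <- function(curves = NULL, policy = c("fixed", "threshold"),
                          species = "Saccharomyces paradoxus",
                          optimum = c(22, 28), occurrence = c(18, 31),
                          theta = 0.5) {
  policy <- match.arg(policy)
  if (policy == "fixed")
    return(temp_envelope(species, optimum, occurrence))
  if (is.null(curves)) stop("'threshold' policy needs response curves",
                            call. = FALSE)
  if (inherits(curves, "response_curve")) curves <- list(curves)
  grid <- curves[[1L]]$tmax_c
  p <- do.call(pmax, lapply(curves, `[[`, "predicted_p"))
  cut <- theta * max(p)
  above <- p >= cut
  if (!any(above))
    stop("no grid point reaches theta * max(p); empty optimum interval",
         call. = FALSE)
  i1 <- which(above)[1L]
  i2 <- which(above)[sum(above)]
  lo <- if (i1 == 1L) grid[1L] else
    grid[i1 - 1L] + (cut - p[i1 - 1L]) / (p[i1] - p[i1 - 1L]) *
      (grid[i1] - grid[i1 - 1L])
  hi <- if (i2 == length(grid)) grid[length(grid)] else
    grid[i2] + (p[i2] - cut) / (p[i2] - p[i2 + 1L]) *
      (grid[i2 + 1L] - grid[i2])
  occ <- c(floor(min(grid)), ceiling(max(grid)))
  temp_envelope(species, c(floor(lo), ceiling(hi)), occ)
}

# interpolated crossings of p = cut, exported for reuse in tests via the
# threshold policy itself; kept internal.

#' Shift an envelope between species
#'
#' Translates both intervals by a fixed temperature offset — the
#' between-species difference in laboratory optimal growth temperature
#' (+7 degC from *S. paradoxus* to *S. cerevisiae*). Widths are preserved.
#'
#' @param env a [temp_envelope()].
#' @param offset_c offset in degrees C.
#' @param species label for the shifted envelope.
#' @return a new [temp_envelope()].
#' @export
shift_envelope <- function(env, offset_c = 7,
                           species = "Saccharomyces cerevisiae") {
  stopifnot(inherits(env, "temp_envelope"))
  temp_envelope(species, env$optimum + offset_c, env$occurrence + offset_c)
}

#' Intersection of two closed temperature intervals
#'
#' @param a,b numeric `c(T_lo, T_hi)` intervals in degrees C.
#' @return the intersection as `c(T_lo, T_hi)`, or `numeric(0)` when the
#'   intervals are disjoint.
#' @export
overlap_range <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 2L, is.numeric(b), length(b) == 2L)
  lo <- max(a[1], b[1])
  hi <- min(a[2], b[2])
  if (lo > hi) numeric(0) else c(lo, hi)
}

#' Serialise an envelope to a JSON file
#'
#' @param env a [temp_envelope()].
#' @param path output path.
#' @param provenance optional free-form list recorded alongside the bounds
#'   (e.g. the offset and source envelope used to derive it).
#' @return `path`, invisibly.
#' @export
write_envelope_json <- function(env, path, provenance = NULL) {
  stopifnot(inherits(env, "temp_envelope"))
  obj <- list(species = env$species, optimum = env$optimum,
              occurrence = env$occurrence)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an envelope from a JSON file
#'
#' @param path file written by [write_envelope_json()].
#' @return a [temp_envelope()].
#' @export
read_envelope_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  temp_envelope(obj$species, as.numeric(obj$optimum),
                as.numeric(obj$occurrence))
}
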