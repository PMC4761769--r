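#' Weighted binomial GLM by iteratively reweighted least squares
#'
#' Fits a logistic regression for grouped binomial data (per-tree successes
#' out of trials) by maximum likelihood. The response in `formula` must be a
#' two-column matrix `cbind(successes, failures)`. The algorithm is standard
#' IRLS: at each step, weighted least squares with working weights
#' `n * p * (1 - p)` and working response `eta + (y/n - p) / (p * (1 - p))`.
#'
#' Iteration starts from a flat fit (intercept at the logit of the pooled
#' positive rate, all slopes zero) and stops when the relative change in
#' deviance falls below `tol` or after `max_iter` iterations. Deviance uses
#' the saturated-model convention with `0 * log(0) = 0`.
#'
#' Rows with missing values in any model variable are dropped (and recorded
#' in the result), mirroring the survey analysis where trees without a girth
#' measurement are excluded from any model that uses girth. A warning is
#' issued when any coefficient exceeds 10 in absolute value on the logit
#' scale, the usual symptom of (quasi-)separation in small site-level data.
#'
#' @param formula model formula with `cbind(successes, failures)` response.
#' @param data data frame of tree-level observations.
#' @param tol relative deviance-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `binom_glm`, a list with elements
#'   `coefficients`, `se`, `vcov`, `null_deviance`, `deviance`,
#'   `df_residual`, `df_null`, `fitted_p`, `linear_predictor`,
#'   `prior_trials`, `successes`, `irls_weights`, `rank`, `n_iterations`,
#'   `converged`, `formula`, `model_frame`, `x`, `dropped_rows`.
#' @examples
#' d <- data.frame(g = c(0.5, 1, 1.5, 2), pos = c(0, 1, 2, 3), n = 4)
#' fit <- binom_glm(cbind(pos, n - pos) ~ g, d)
#' coef(fit)
#' @export
binom_glm <- function(formula, data, tol = 1e-8, max_iter = 25L) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  y2 <- stats::model.response(mf)
  if (is.null(dim(y2)) || ncol(y2) != 2L)
    stop("response must be a two-column matrix cbind(successes, failures)",
         call. = FALSE)
  y <- y2[, 1L]
  n <- y2[, 1L] + y2[, 2L]
  if (any(n < 1)) stop("every observation needs at least one trial",
                       call. = FALSE)
  if (any(y < 0 | y > n)) stop("successes must lie in [0, trials]",
                               call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  pooled <- sum(y) / sum(n)
  pooled <- min(max(pooled, 1e-6), 1 - 1e-6)
  eta <- rep(stats::qlogis(pooled), length(y))
  dev <- binom_deviance(y, n, stats::plogis(eta))
  beta <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- stats::plogis(eta)
    # keep fitted probabilities off the boundary so the working response
    # stays finite under (quasi-)separation
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    w <- n * p * (1 - p)
    z <- eta + (y / n - p) / (p * (1 - p))
    wfit <- lm.wfit.stable(X, z, w)
    beta <- wfit$beta
    eta <- drop(X %*% beta)
    dev_new <- binom_deviance(y, n, stats::plogis(eta))
    if (!is.finite(dev_new)) {
      converged <- FALSE
      break
    }
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
    if (iter >= max_iter) break
  }
  if (any(abs(beta) > 10))
    warning("coefficient(s) beyond 10 on the logit scale; ",
            "possible separation in the data", call. = FALSE)

  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  w <- n * p * (1 - p)
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(XtWX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(XtWX_inv))

  # null deviance at the pooled (intercept-only MLE) rate
  null_dev <- binom_deviance(y, n, rep(sum(y) / sum(n), length(y)))

  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = XtWX_inv,
    null_deviance = null_dev,
    deviance = dev,
    df_residual = length(y) - ncol(X),
    df_null = length(y) - 1L,
    fitted_p = p,
    linear_predictor = eta,
    prior_trials = n,
    successes = y,
    irls_weights = w,
    rank = ncol(X),
    n_iterations = iter,
    converged = converged,
    formula = formula,
    model_frame = mf,
    data_used = {
      used <- setdiff(seq_len(nrow(data)), as.integer(dropped))
      data[used, , drop = FALSE]
    },
    x = X,
    dropped_rows = as.integer(dropped)
  ), class = "binom_glm")
}

# weighted least squares via QR on the square-root-weighted design
lm.wfit.stable <- function(X, z, w) {
  sw <- sqrt(w)
  fit <- qr.solve(X * sw, z * sw)
  list(beta = fit)
}

# binomial deviance vs the saturated model, with 0*log(0) = 0
binom_deviance <- function(y, n, p) {
  xlogy <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  2 * sum(xlogy(y, n * p) + xlogy(n - y, n * (1 - p)))
}

#' @export
print.binom_glm <- function(x, ...) {
  cat("Binomial GLM (logit link, IRLS)\n")
  cat(deparse(x$formula), "\n\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  cat(sprintf("\nNull deviance: %.3f on %d df\n", x$null_deviance, x$df_null))
  cat(sprintf("Residual deviance: %.3f on %d df (%.1f%% explained)\n",
              x$deviance, x$df_residual, percent_deviance_explained(x)))
  cat(sprintf("Converged: %s after %d IRLS iterations\n",
              x$converged, x$n_iterations))
  invisible(x)
}

#' @export
coef.binom_glm <- function(object, ...) object$coefficients

#' @export
vcov.binom_glm <- function(object, ...) object$vcov

#' Percent of null deviance explained by a fit
#'
#' `(null_deviance - residual_deviance) / null_deviance * 100`, the summary
#' used to report how much tree-to-tree variation in isolation frequency the
#' model captures.
#'
#' @param fit a [binom_glm()] fit.
#' @return a percentage (0 for the null model, 100 for a saturated fit).
#' @export
percent_deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "binom_glm"))
  (fit$null_deviance - fit$deviance) / fit$null_deviance * 100
}

#' Likelihood-ratio (deviance) test between nested binomial GLMs
#'
#' Compares a reduced model against a full model fitted to the same rows.
#' The difference in residual deviances is referred to a chi-square
#' distribution with the difference in residual degrees of freedom.
#'
#' @param fit_reduced,fit_full [binom_glm()] fits; `fit_reduced` must be
#'   nested in `fit_full` and share its data rows.
#' @return a list of class `binom_lrt`: `delta_deviance`, `delta_df`,
#'   `p_value`, and `percent_null_deviance` (deviance change as a percentage
#'   of the full model's null deviance, the scale used to report term
#'   contributions).
#' @export
binom_lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "binom_glm"), inherits(fit_full, "binom_glm"))
  if (length(fit_reduced$successes) != length(fit_full$successes) ||
      !all(fit_reduced$successes == fit_full$successes) ||
      !all(fit_reduced$prior_trials == fit_full$prior_trials))
    stop("models were not fitted to the same data rows", call. = FALSE)
  if (fit_reduced$df_residual < fit_full$df_residual)
    stop("'fit_reduced' has more parameters than 'fit_full'; not nested",
         call. = FALSE)
  dd <- fit_reduced$deviance - fit_full$deviance
  ddf <- fit_reduced$df_residual - fit_full$df_residual
  if (dd < -1e-6)
    stop("reduced model has smaller deviance than full model; ",
         "models do not look nested", call. = FALSE)
  dd <- max(dd, 0)
  p <- if (ddf == 0L) 1 else stats::pchisq(dd, ddf, lower.tail = FALSE)
  structure(list(delta_deviance = dd, delta_df = ddf, p_value = p,
                 percent_null_deviance = dd / fit_full$null_deviance * 100),
            class = "binom_lrt")
}

#' @export
print.binom_lrt <- function(x, ...) {
  cat(sprintf("LRT: delta deviance %.4f on %d df, p = %.4g (%.2f%% of null)\n",
              x$delta_deviance, x$delta_df, x$p_value,
              x$percent_null_deviance))
  invisible(x)
}

#' Stepwise model simplification by deviance tests
#'
#' Starting from an initial (typically fully interacted) model, repeatedly
#' tests the deletion of every currently removable term — those whose removal
#' respects marginality, so interactions go before their main effects — and
#' deletes the candidate with the largest p-value provided `p > alpha`.
#' Stops when every remaining removable term is significant at `alpha`.
#' Among candidates, higher-order terms are considered first; equal-order
#' ties go to the largest p.
#'
#' All candidate fits are made on one fixed data subset: the complete cases
#' of every variable appearing in the *initial* formula, so that every
#' deviance comparison along the path is between models fitted to identical
#' rows.
#'
#' @param formula initial model formula (`cbind(successes, failures)`
#'   response).
#' @param data tree-level data frame.
#' @param alpha retention threshold: a term is kept when its deletion
#'   p-value is `<= alpha`.
#' @return list with `formula` (final), `fit` (final [binom_glm()]), and
#'   `log`: a data frame recording every tested deletion (step, term, term
#'   order, delta deviance, delta df, p, percent of null deviance, whether
#'   deleted).
#' @export
stepwise_simplify <- function(formula, data, alpha = 0.05) {
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, intersect(vars, names(data)),
                                     drop = FALSE])
  d <- data[keep, , drop = FALSE]

  current <- formula
  fit_cur <- binom_glm(current, d)
  log_rows <- list()
  step <- 0L
  repeat {
    cand <- stats::drop.scope(stats::terms(current))
    if (length(cand) == 0L) break
    step <- step + 1L
    tt <- stats::terms(current)
    ord <- attr(tt, "order")[match(cand, attr(tt, "term.labels"))]
    tests <- lapply(cand, function(trm) {
      red <- stats::update(current, paste("~ . -", trm))
      binom_lrt(binom_glm(red, d), fit_cur)
    })
    res <- data.frame(
      step = step,
      term = cand,
      order = ord,
      delta_deviance = vapply(tests, `[[`, 0, "delta_deviance"),
      delta_df = vapply(tests, `[[`, 0L, "delta_df"),
      p_value = vapply(tests, `[[`, 0, "p_value"),
      percent_null_deviance =
        vapply(tests, `[[`, 0, "percent_null_deviance"),
      deleted = FALSE,
      stringsAsFactors = FALSE)
    # highest order first, then largest p
    res <- res[order(-res$order, -res$p_value), ]
    hit <- which(res$p_value > alpha)[1]
    if (is.na(hit)) {
      log_rows[[length(log_rows) + 1L]] <- res
      break
    }
    res$deleted[hit] <- TRUE
    log_rows[[length(log_rows) + 1L]] <- res
    current <- stats::update(current, paste("~ . -", res$term[hit]))
    fit_cur <- binom_glm(current, d)
  }
  list(formula = current, fit = fit_cur,
       log = do.call(rbind, c(log_rows, list(make.row.names = FALSE))))
}

#' Test collapsing a multi-level factor to a coarser grouping
#'
#' Refits a model with a factor replaced by a coarser factor (e.g. three oak
#' host types collapsed to a northern/southern classification) everywhere it
#' appears — main effect and interactions — and compares the two fits by a
#' deviance test. The collapsed model is nested in the original, because the
#' coarse factor is a linear restriction of the fine one; the reported
#' `delta_df` is the number of parameters actually freed by the collapse in
#' the supplied model, which depends on how many interactions involve the
#' factor.
#'
#' @param formula model formula containing `factor_name`.
#' @param data tree-level data frame.
#' @param factor_name name of the factor column to collapse.
#' @param grouping named character vector mapping every level of the fine
#'   factor to a coarse level, e.g.
#'   `c("robur-like" = "north", "frainetto-like" = "south", "ilex" = "south")`.
#' @return list with `lrt` (a `binom_lrt`), `fit_full`, `fit_collapsed`, and
#'   `formula_collapsed`.
#' @export
collapse_factor <- function(formula, data, factor_name, grouping) {
  if (!factor_name %in% all.vars(formula))
    stop("'", factor_name, "' does not appear in the model formula",
         call. = FALSE)
  lv <- unique(as.character(data[[factor_name]]))
  if (!all(lv %in% names(grouping)))
    stop("grouping must map every level of '", factor_name, "'; missing: ",
         paste(setdiff(lv, names(grouping)), collapse = ", "), call. = FALSE)
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, intersect(vars, names(data)),
                                     drop = FALSE])
  d <- data[keep, , drop = FALSE]

  collapsed_name <- paste0(".collapsed_", factor_name)
  d[[collapsed_name]] <- factor(unname(
    grouping[as.character(d[[factor_name]])]))
  f_str <- deparse1(formula)
  f_col <- stats::as.formula(
    gsub(paste0("\\b", factor_name, "\\b"), collapsed_name, f_str),
    env = environment(formula))
  fit_full <- binom_glm(formula, d)
  fit_col <- binom_glm(f_col, d)
  list(lrt = binom_lrt(fit_col, fit_full),
       fit_full = fit_full, fit_collapsed = fit_col,
       formula_collapsed = f_col)
}

#' One-step Cook's distance for a binomial GLM fit
#'
#' Approximate per-observation influence on the coefficient vector, computed
#' from the hat values of the final weighted least-squares step and the
#' Pearson residuals:
#' `D_i = r_i^2 h_i / (p (1 - h_i)^2)` with `r_i` the Pearson residual, `h_i`
#' the leverage, and `p` the number of model parameters. This is the usual
#' one-step approximation; [refit_without()] gives the exact leave-one-out
#' answer.
#'
#' @param fit a [binom_glm()] fit.
#' @return numeric vector of Cook's distances, one per fitted row.
#' @export
cooks_distance <- function(fit) {
  stopifnot(inherits(fit, "binom_glm"))
  w <- fit$irls_weights
  Xw <- fit$x * sqrt(w)
  h <- rowSums((Xw %*% fit$vcov) * Xw)
  r <- (fit$successes - fit$prior_trials * fit$fitted_p) /
    sqrt(fit$prior_trials * fit$fitted_p * (1 - fit$fitted_p))
  (r / (1 - h))^2 * h / fit$rank
}

#' Exact leave-one-out refit
#'
#' Drops one fitted row and refits the same model, for sensitivity checks on
#' high-influence trees identified by [cooks_distance()].
#'
#' @param fit a [binom_glm()] fit.
#' @param i row index (into the rows the fit actually used).
#' @return a new [binom_glm()] fit.
#' @export
refit_without <- function(fit, i) {
  stopifnot(inherits(fit, "binom_glm"))
  d <- fit$data_used
  if (i < 1L || i > nrow(d)) stop("row index out of range", call. = FALSE)
  binom_glm(fit$formula, d[-i, , drop = FALSE])
}
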