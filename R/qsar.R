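# Censoring-aware log-transformation and linear QSAR models: logIC50
# regressed per cell line on the expression-weighted binding energy BE_w
# and, separately, on standard physicochemical descriptors (TPSA, MlogP,
# HBD, POL). Right-censored potencies (">100 uM") carry no point value;
# they are excluded by default or, optionally, imputed at the bound.

#' Log-transform a cell line's potencies under a censoring policy
#'
#' @param potencies a [potency_table].
#' @param cell_line cell-line label present in the table.
#' @param policy `"exclude"` drops right-censored entries (the default —
#'   it avoids fabricating values for compounds whose IC50 is only known to
#'   exceed the bound); `"at_bound"` includes them at `log(bound)`.
#' @param base logarithm base, default 10.
#' @return list with `log_ic50` (named numeric, compounds used) and
#'   `excluded` (data frame of compound/reason).
#' @export
log_transform <- function(potencies, cell_line,
                          policy = c("exclude", "at_bound"), base = 10) {
  stopifnot(inherits(potencies, "potency_table"))
  policy <- match.arg(policy)
  if (base <= 1) stop("log base must exceed 1", call. = FALSE)
  sel <- potencies$cell_line == cell_line
  if (!any(sel)) stop(sprintf("cell line '%s' not present", cell_line), call. = FALSE)
  sub <- potencies[sel, , drop = FALSE]
  censored <- sub$status == "censored"
  if (policy == "exclude") {
    use <- !censored
    excluded <- data.frame(compound = sub$compound[censored],
                           reason = sprintf("right-censored at %g uM", sub$value[censored]),
                           stringsAsFactors = FALSE)
  } else {
    use <- rep(TRUE, nrow(sub))
    excluded <- data.frame(compound = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  }
  list(log_ic50 = stats::setNames(log(sub$value[use], base = base), sub$compound[use]),
       excluded = excluded)
}

.regression_result <- function(fit, x_names, n, excluded) {
  # summary.lm warns on noiseless fits ("essentially perfect fit"); those are
  # legitimate here (synthetic zero-noise data)
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  out <- list(coefficients = stats::coef(fit),
              se = co[, "Std. Error"],
              intercept = unname(stats::coef(fit)[1L]),
              slopes = stats::coef(fit)[-1L],
              r_squared = sm$r.squared,
              n_used = n,
              excluded = excluded,
              residuals = stats::residuals(fit),
              fitted = stats::fitted(fit),
              lm = fit)
  class(out) <- "bw_regression"
  out
}

#' @export
print.bw_regression <- function(x, ...) {
  cat(sprintf("Linear model (n = %d): R^2 = %.4f\n", x$n_used, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Univariate ordinary least squares with R-squared
#'
#' Plain OLS of `y` on `x`; `r_squared = 1 - SS_res / SS_tot`, equal to the
#' squared Pearson correlation in this univariate case.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param excluded optional exclusion record carried into the result.
#' @return a `bw_regression` object (coefficients, standard errors,
#'   `r_squared`, `n_used`, residuals, fitted values).
#' @export
fit_linear <- function(x, y, excluded = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("insufficient data: n < 3", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate fit: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  .regression_result(fit, "x", length(x), excluded)
}

#' Two-predictor ordinary least squares
#'
#' OLS of `y` on two predictors (typically BE_w and TPSA). Nested above the
#' univariate model, so its R-squared can never be lower than
#' `fit_linear(x1, y)` on the same rows.
#'
#' @param x1,x2,y equal-length numeric vectors, `n >= 4`.
#' @param excluded optional exclusion record.
#' @return a `bw_regression` object.
#' @export
fit_bivariate <- function(x1, x2, y, excluded = NULL) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n) stop("predictor lengths differ", call. = FALSE)
  if (n < 4L) stop("insufficient data: n < 4", call. = FALSE)
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) stop("degenerate fit: collinear predictors", call. = FALSE)
  fit <- stats::lm(y ~ x1 + x2)
  .regression_result(fit, c("x1", "x2"), n, excluded)
}

#' Per-cell-line R-squared panel
#'
#' For every cell line, fits logIC50 on the cell line's BE_w column and on
#' each supplied descriptor (a cell-line-independent predictor against the
#' cell-line-specific response), assembling the coefficients of
#' determination into a descriptor-by-cell-line matrix. Cells with fewer
#' than three usable compounds are reported `NA` with a reason, never
#' silently zero. No multiple-testing correction is applied; the values are
#' descriptive.
#'
#' @param bw a [weighted_energy_table].
#' @param potencies a [potency_table].
#' @param descriptors optional data frame with a `compound` column plus one
#'   numeric column per descriptor (e.g. TPSA, MlogP, HBD, POL).
#' @param policy,base censoring policy and log base, see [log_transform()].
#' @return an object of class `r2_panel`: the R-squared matrix with
#'   attributes `n_used` (matrix), `excluded` (per-cell-line lists),
#'   `missing_reasons`.
#' @export
r2_panel <- function(bw, potencies, descriptors = NULL,
                     policy = c("exclude", "at_bound"), base = 10) {
  stopifnot(inherits(bw, "weighted_energy_table"))
  policy <- match.arg(policy)
  cell_lines <- colnames(bw)
  desc_names <- character(0)
  if (!is.null(descriptors)) {
    stopifnot(is.data.frame(descriptors), "compound" %in% names(descriptors))
    desc_names <- setdiff(names(descriptors), "compound")
  }
  rows_ids <- c("BE_w", desc_names)
  panel <- matrix(NA_real_, nrow = length(rows_ids), ncol = length(cell_lines),
                  dimnames = list(rows_ids, cell_lines))
  n_used <- panel
  excluded <- stats::setNames(vector("list", length(cell_lines)), cell_lines)
  reasons <- list()
  for (cl in cell_lines) {
    lt <- log_transform(potencies, cl, policy = policy, base = base)
    excluded[[cl]] <- lt$excluded
    y_all <- lt$log_ic50
    common <- intersect(rownames(bw), names(y_all))
    for (rid in rows_ids) {
      if (rid == "BE_w") {
        xv <- stats::setNames(unclass(bw)[common, cl], common)
        yv <- y_all[common]
      } else {
        dv <- stats::setNames(descriptors[[rid]], descriptors$compound)
        cc <- intersect(names(y_all), names(dv)[!is.na(dv)])
        xv <- dv[cc]
        yv <- y_all[cc]
      }
      if (length(yv) < 3L) {
        reasons[[paste(rid, cl, sep = "|")]] <-
          sprintf("only %d usable compounds", length(yv))
        next
      }
      if (stats::var(xv) == 0) {
        reasons[[paste(rid, cl, sep = "|")]] <- "constant predictor"
        next
      }
      f <- fit_linear(as.numeric(xv), as.numeric(yv))
      panel[rid, cl] <- f$r_squared
      n_used[rid, cl] <- f$n_used
    }
  }
  structure(panel, class = c("r2_panel", class(panel)),
            n_used = n_used, excluded = excluded, missing_reasons = reasons,
            policy = policy, base = base)
}

#' @export
print.r2_panel <- function(x, digits = 3, ...) {
  cat(sprintf("R^2 panel (censor policy '%s', log base %g):\n",
              attr(x, "policy"), attr(x, "base")))
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  print(signif(m, digits), ...)
  rs <- attr(x, "missing_reasons")
  if (length(rs) > 0L) {
    cat("missing entries:\n")
    for (k in names(rs)) cat("  ", k, ": ", rs[[k]], "\n", sep = "")
  }
  invisible(x)
}

# The model object ------------------------------------------------------------

#' Fit the expression-weighted binding-energy QSAR model
#'
#' The package's central fitting function. From a compound-by-isotype
#' binding-energy matrix, a panel of cell-line isotype-abundance profiles
#' and a (possibly right-censored) IC50 table it:
#' \enumerate{
#'   \item computes the expression-weighted binding energy
#'     \eqn{BE_w(c, \ell) = \sum_i w_{i\ell} E(c, i)} for every compound
#'     and cell line;
#'   \item fits, per cell line, the linear model
#'     \eqn{\log IC_{50} = \alpha + \beta \, BE_w + \varepsilon} after
#'     applying the censoring policy;
#'   \item fits each supplied descriptor univariately and, when a TPSA
#'     column is present, the bivariate \eqn{BE_w + TPSA} model;
#'   \item assembles the \eqn{R^2} panel and, when a reference weighted
#'     table is supplied instead of an expression panel, consistency
#'     diagnostics.
#' }
#'
#' @param binding a [binding_matrix].
#' @param expression an `expression_panel`, or a precomputed
#'   [weighted_energy_table] to use directly (in which case the weighting
#'   step is skipped and [diagnose()] is run against `binding`).
#' @param potencies a [potency_table].
#' @param descriptors optional compound descriptor data frame (see
#'   [r2_panel()]).
#' @param censor_policy `"exclude"` or `"at_bound"`.
#' @param log_base base for the logIC50 transform.
#' @param restrict passed to [weighted_energy_panel()].
#' @param tolerance feasibility tolerance (kcal/mol) for diagnostics.
#' @return an object of class `bw_qsar` with components `bw_table`,
#'   `fits` (per-cell-line `bw_regression` on BE_w), `bivariate` (per-cell-line
#'   BE_w + TPSA fits, if TPSA supplied), `r2`, `diagnosis` (when applicable)
#'   and `settings`.
#' @seealso [predict.bw_qsar()], [simulate.bw_qsar()], [plot.bw_qsar()]
#' @export
bw_qsar <- function(binding, expression, potencies, descriptors = NULL,
                    censor_policy = c("exclude", "at_bound"), log_base = 10,
                    restrict = FALSE, tolerance = 0.02) {
  stopifnot(inherits(binding, "binding_matrix"), inherits(potencies, "potency_table"))
  censor_policy <- match.arg(censor_policy)
  diagnosis <- NULL
  if (inherits(expression, "expression_panel")) {
    bw <- weighted_energy_panel(binding, expression, restrict = restrict)
  } else if (inherits(expression, "weighted_energy_table")) {
    bw <- expression
    diagnosis <- withCallingHandlers(
      diagnose(binding, bw, tolerance = tolerance),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    stop("expression must be an expression_panel or a weighted_energy_table",
         call. = FALSE)
  }
  fits <- list()
  bivariate <- list()
  tpsa <- NULL
  if (!is.null(descriptors)) {
    tcol <- names(descriptors)[tolower(names(descriptors)) == "tpsa"]
    if (length(tcol) == 1L) {
      tpsa <- stats::setNames(descriptors[[tcol]], descriptors$compound)
    }
  }
  for (cl in colnames(bw)) {
    lt <- log_transform(potencies, cl, policy = censor_policy, base = log_base)
    common <- intersect(rownames(bw), names(lt$log_ic50))
    if (length(common) < 3L) next
    xv <- stats::setNames(unclass(bw)[common, cl], common)
    yv <- lt$log_ic50[common]
    fits[[cl]] <- fit_linear(as.numeric(xv), as.numeric(yv), excluded = lt$excluded)
    fits[[cl]]$compounds <- common
    if (!is.null(tpsa)) {
      cc <- intersect(common, names(tpsa)[!is.na(tpsa)])
      if (length(cc) >= 4L) {
        bf <- try(fit_bivariate(as.numeric(xv[cc]), as.numeric(tpsa[cc]),
                                as.numeric(yv[cc]), excluded = lt$excluded),
                  silent = TRUE)
        if (!inherits(bf, "try-error")) {
          bf$compounds <- cc
          bivariate[[cl]] <- bf
        }
      }
    }
  }
  if (length(fits) == 0L) stop("no cell line has >= 3 usable compounds", call. = FALSE)
  r2 <- r2_panel(bw, potencies, descriptors = descriptors,
                 policy = censor_policy, base = log_base)
  out <- list(call = match.call(),
              bw_table = bw,
              fits = fits,
              bivariate = if (length(bivariate)) bivariate else NULL,
              r2 = r2,
              diagnosis = diagnosis,
              settings = list(censor_policy = censor_policy, log_base = log_base,
                              restrict = restrict, tolerance = tolerance))
  class(out) <- "bw_qsar"
  out
}

#' @export
print.bw_qsar <- function(x, ...) {
  cat("Expression-weighted binding-energy QSAR\n")
  cat(sprintf("  %d compounds x %d cell lines; censor policy '%s', log base %g\n",
              nrow(x$bw_table), ncol(x$bw_table),
              x$settings$censor_policy, x$settings$log_base))
  r2 <- vapply(x$fits, `[[`, numeric(1), "r_squared")
  n <- vapply(x$fits, `[[`, numeric(1), "n_used")
  cat("  per-cell-line logIC50 ~ BE_w:\n")
  print(data.frame(cell_line = names(x$fits), n = n, r_squared = round(r2, 4),
                   row.names = NULL))
  if (!is.null(x$diagnosis) && sum(x$diagnosis$summary$n_out_of_hull) > 0) {
    cat(sprintf("  WARNING: %d BE_w entries outside the convex hull of their energy rows\n",
                sum(x$diagnosis$summary$n_out_of_hull)))
  }
  invisible(x)
}

#' @export
summary.bw_qsar <- function(object, ...) {
  structure(list(object = object), class = "summary.bw_qsar")
}

#' @export
print.summary.bw_qsar <- function(x, ...) {
  obj <- x$object
  print(obj)
  cat("\n")
  print(obj$r2)
  if (!is.null(obj$bivariate)) {
    cat("\nbivariate BE_w + TPSA:\n")
    r2b <- vapply(obj$bivariate, `[[`, numeric(1), "r_squared")
    print(round(r2b, 4))
  }
  if (!is.null(obj$diagnosis)) {
    cat("\n")
    print(obj$diagnosis)
  }
  invisible(x)
}

#' @export
coef.bw_qsar <- function(object, ...) {
  t(vapply(object$fits, function(f) f$coefficients, numeric(2)))
}

#' @export
residuals.bw_qsar <- function(object, ...) {
  lapply(object$fits, `[[`, "residuals")
}

#' Predict logIC50 from fitted per-cell-line models
#'
#' @param object a `bw_qsar` fit.
#' @param newdata optional [weighted_energy_table] (or plain matrix with
#'   compound rownames and cell-line colnames) of BE_w values; defaults to
#'   the table the model was fitted on.
#' @param ... unused.
#' @return matrix of predicted logIC50, compounds by cell lines (NA for cell
#'   lines without a fitted model).
#' @export
predict.bw_qsar <- function(object, newdata = NULL, ...) {
  bw <- if (is.null(newdata)) object$bw_table else newdata
  bw <- as.matrix(unclass(bw))
  out <- matrix(NA_real_, nrow(bw), ncol(bw), dimnames = dimnames(bw))
  for (cl in colnames(bw)) {
    f <- object$fits[[cl]]
    if (is.null(f)) next
    out[, cl] <- f$coefficients[1L] + f$coefficients[2L] * bw[, cl]
  }
  out
}

#' Simulate potency tables from a fitted model
#'
#' Draws IC50 tables from the fitted per-cell-line linear models with the
#' residual standard error as Gaussian noise on the logIC50 scale, applying
#' right-censoring at `censor_bound`.
#'
#' @param object a `bw_qsar` fit.
#' @param nsim number of tables to draw.
#' @param seed optional integer seed.
#' @param censor_bound right-censoring bound in uM, default 100.
#' @param ... unused.
#' @return list of [potency_table] objects, length `nsim`.
#' @export
simulate.bw_qsar <- function(object, nsim = 1, seed = NULL, censor_bound = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$settings$log_base
  pred <- predict(object)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    rows <- list()
    for (cl in colnames(pred)) {
      f <- object$fits[[cl]]
      if (is.null(f)) next
      sigma <- sqrt(sum(f$residuals^2) / max(f$n_used - 2L, 1L))
      mu <- pred[f$compounds, cl]
      ly <- mu + stats::rnorm(length(mu), 0, sigma)
      ic <- base^ly
      cens <- ic > censor_bound
      rows[[cl]] <- data.frame(compound = f$compounds, cell_line = cl,
                               value = ifelse(cens, censor_bound, ic),
                               status = ifelse(cens, "censored", "observed"),
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    out[[s]] <- potency_table(df$compound, df$cell_line, df$value, df$status)
  }
  out
}

#' Scatter plots of logIC50 against BE_w with fitted lines
#'
#' @param x a `bw_qsar` fit.
#' @param cell_lines which cell lines to draw, default all fitted.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bw_qsar <- function(x, cell_lines = names(x$fits), ...) {
  base <- x$settings$log_base
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(cell_lines)))
  on.exit(graphics::par(old))
  for (cl in cell_lines) {
    f <- x$fits[[cl]]
    bwv <- unclass(x$bw_table)[f$compounds, cl]
    yv <- f$fitted + f$residuals
    graphics::plot(bwv, yv, xlab = "BE_w (kcal/mol)",
                   ylab = sprintf("log%g(IC50 / uM)", base),
                   main = sprintf("%s  (R^2 = %.2f)", cl, f$r_squared), ...)
    graphics::abline(f$coefficients[1L], f$coefficients[2L], col = "steelblue")
  }
  invisible(x)
}
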