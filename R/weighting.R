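# Expression-weighted binding energies and their inverse problem.
#
# Forward: BE_w(c) = sum_i w_i * E(c, i), a convex combination of the
# per-isotype docking energies with weights equal to a cell line's isotype
# abundance fractions. Inverse: given a BE_w column, find the simplex
# weights that best explain it (nonnegative least squares with a sum-to-one
# constraint). A necessary feasibility condition for any convex combination
# is that each BE_w value lies in [row min, row max] of its energy row;
# hull_check() screens for violations.

.align_profile <- function(matrix, profile, restrict = FALSE) {
  iso_m <- colnames(matrix)
  iso_p <- names(profile)
  extra <- setdiff(iso_p, iso_m)
  if (length(extra) > 0L) {
    if (!restrict) {
      stop("profile references isotypes absent from the matrix: ",
           paste(extra, collapse = ", "),
           " (set restrict = TRUE to renormalize over the intersection)",
           call. = FALSE)
    }
    keep <- intersect(iso_p, iso_m)
    if (length(keep) == 0L || sum(profile[keep]) <= 0) {
      stop("no overlapping isotypes with positive weight", call. = FALSE)
    }
    profile <- expression_profile(profile[keep] / sum(profile[keep]),
                                  cell_line = attr(profile, "cell_line"))
  }
  w <- stats::setNames(numeric(length(iso_m)), iso_m)
  w[names(profile)] <- as.numeric(profile)
  w
}

#' Expression-weighted binding energy per compound
#'
#' Computes BE_w for every compound as the weighted average of its
#' per-isotype binding energies, the weights being the cell line's isotype
#' abundance fractions. Isotypes present in the matrix but absent from the
#' profile get weight zero; isotypes present in the profile but absent from
#' the matrix are an error unless `restrict = TRUE`, which renormalizes the
#' profile over the common isotype set.
#'
#' @param matrix a [binding_matrix].
#' @param profile an [expression_profile].
#' @param restrict renormalize the profile over the matrix's isotypes.
#' @return named numeric vector of BE_w (kcal/mol) per compound. Each value
#'   lies within the row min/max over the isotypes carrying positive weight.
#' @export
weighted_energy <- function(matrix, profile, restrict = FALSE) {
  stopifnot(inherits(matrix, "binding_matrix"), inherits(profile, "expression_profile"))
  w <- .align_profile(matrix, profile, restrict)
  stats::setNames(as.numeric(unclass(matrix) %*% w), rownames(matrix))
}

#' Weighted energies for a whole cell-line panel
#'
#' Column-wise application of [weighted_energy()] over an expression panel.
#'
#' @param matrix a [binding_matrix].
#' @param panel an `expression_panel` (see [expression_panel()]).
#' @param restrict passed to [weighted_energy()].
#' @return a [weighted_energy_table], one column per cell line.
#' @export
weighted_energy_panel <- function(matrix, panel, restrict = FALSE) {
  stopifnot(inherits(panel, "expression_panel"))
  cols <- lapply(colnames(panel), function(cl) {
    p <- expression_profile(stats::setNames(panel[, cl], rownames(panel)), cell_line = cl)
    weighted_energy(matrix, p, restrict = restrict)
  })
  bw <- do.call(cbind, cols)
  colnames(bw) <- colnames(panel)
  weighted_energy_table(bw)
}

# Simplex-constrained least squares ------------------------------------------
#
# min ||E w - b||^2  s.t.  sum(w) = 1, w >= 0.
# Active-set method: start from the uniform vector; on the current free set F
# solve the equality-constrained problem via the KKT system
#   [ 2 E_F'E_F   1 ] [w_F]   [2 E_F'b]
#   [ 1'          0 ] [ mu] = [1      ]
# (pseudo-inverse solve, giving the minimum-norm solution when E_F is
# rank-deficient); clip the most negative coordinate into the active set
# until w >= 0; then check the KKT multipliers of the active bounds and
# release any with negative reduced gradient. Deterministic throughout.

.pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  d <- sv$d
  pos <- d > tol * max(d, .Machine$double.eps)
  x <- sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% b) / d[pos])
  list(x = drop(x), rank = sum(pos), n = length(d))
}

.simplex_ls <- function(E, b, max_iter = 200L) {
  k <- ncol(E)
  G <- crossprod(E)          # E'E
  h <- crossprod(E, b)       # E'b
  free <- rep(TRUE, k)
  w <- rep(1 / k, k)
  nonunique <- FALSE
  solve_free <- function(free) {
    kf <- sum(free)
    K <- rbind(cbind(2 * G[free, free, drop = FALSE], 1), c(rep(1, kf), 0))
    rhs <- c(2 * h[free], 1)
    sol <- .pinv_solve(K, rhs)
    list(w = sol$x[seq_len(kf)], mu = sol$x[kf + 1L], deficient = sol$rank < sol$n)
  }
  for (iter in seq_len(max_iter)) {
    sol <- solve_free(free)
    if (sol$deficient) nonunique <- TRUE
    wf <- sol$w
    if (all(wf >= -1e-12)) {
      w[] <- 0
      w[free] <- pmax(wf, 0)
      w <- w / sum(w)
      # KKT check on active bounds: reduced gradient must be >= 0
      grad <- 2 * (G %*% w - h)
      mu <- sol$mu
      viol <- which(!free & (grad + mu < -1e-9))
      if (length(viol) == 0L) break
      free[viol[which.min((grad + mu)[viol])]] <- TRUE
    } else {
      # move the most negative coordinate to the bound
      idx <- which(free)[which.min(wf)]
      free[idx] <- FALSE
      if (sum(free) == 0L) {  # pathological; restore the least-bad one
        free[idx] <- TRUE
        w[] <- 0
        w[idx] <- 1
        break
      }
    }
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  list(weights = w, nonunique = nonunique)
}

#' Recover isotype weights from a weighted-energy column
#'
#' Solves the inverse of the weighting step: finds the abundance fractions
#' `w` on the probability simplex minimizing `||E w - bw||^2`, where `E` is
#' the binding matrix and `bw` the observed weighted energies. The fit is
#' convex, solved by a deterministic active-set method initialized at the
#' uniform vector; with a rank-deficient energy matrix the minimum-norm
#' minimizer is reported and `nonunique` is flagged. The column is declared
#' feasible when the worst per-compound residual does not exceed
#' `tolerance` — the default 0.02 kcal/mol is four times the 0.005 rounding
#' half-width of two-decimal tables, separating rounding noise from genuine
#' inconsistency.
#'
#' @param matrix a [binding_matrix].
#' @param bw numeric vector of BE_w values, one per compound (matrix row
#'   order, or named by compound id).
#' @param tolerance feasibility tolerance in kcal/mol.
#' @return an object of class `weight_recovery`: list with `weights`
#'   (simplex vector over isotypes), `fitted`, `residuals`, `residual_rms`,
#'   `residual_max`, `feasible`, `nonunique`, `tolerance`.
#' @export
recover_weights <- function(matrix, bw, tolerance = 0.02) {
  stopifnot(inherits(matrix, "binding_matrix"))
  E <- unclass(matrix)
  if (!is.null(names(bw))) {
    if (!setequal(names(bw), rownames(E))) {
      stop("bw names do not match the matrix's compounds", call. = FALSE)
    }
    bw <- bw[rownames(E)]
  }
  if (length(bw) != nrow(E)) {
    stop(sprintf("bw has length %d, matrix has %d compounds", length(bw), nrow(E)),
         call. = FALSE)
  }
  sol <- .simplex_ls(E, as.numeric(bw))
  fitted <- drop(E %*% sol$weights)
  res <- fitted - as.numeric(bw)
  out <- list(weights = stats::setNames(sol$weights, colnames(E)),
              fitted = stats::setNames(fitted, rownames(E)),
              residuals = stats::setNames(res, rownames(E)),
              residual_rms = sqrt(mean(res^2)),
              residual_max = max(abs(res)),
              feasible = max(abs(res)) <= tolerance,
              nonunique = sol$nonunique,
              tolerance = tolerance)
  class(out) <- "weight_recovery"
  out
}

#' @export
print.weight_recovery <- function(x, ...) {
  cat("Simplex least-squares weight recovery\n")
  cat(sprintf("  residual RMS %.4g, max %.4g kcal/mol -> %s (tolerance %.3g)\n",
              x$residual_rms, x$residual_max,
              if (x$feasible) "feasible" else "INFEASIBLE", x$tolerance))
  if (x$nonunique) cat("  note: minimizer not unique (rank-deficient matrix); minimum-norm weights shown\n")
  cat("  weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Convex-hull feasibility screen for a weighted-energy column
#'
#' Any weighted average of a row lies between that row's minimum and
#' maximum; a BE_w value outside this interval cannot arise from any
#' abundance profile over the tabulated isotypes.
#'
#' @param matrix a [binding_matrix].
#' @param bw numeric vector of BE_w values per compound (matrix row order or
#'   named).
#' @return data frame with one row per compound: `row_min`, `row_max`, `bw`,
#'   `within_bounds`, and `excess` (distance to the interval, 0 if inside).
#' @export
hull_check <- function(matrix, bw) {
  stopifnot(inherits(matrix, "binding_matrix"))
  E <- unclass(matrix)
  if (!is.null(names(bw))) bw <- bw[rownames(E)]
  if (length(bw) != nrow(E)) stop("dimension mismatch", call. = FALSE)
  lo <- apply(E, 1L, min)
  hi <- apply(E, 1L, max)
  bw <- as.numeric(bw)
  excess <- pmax(lo - bw, 0) + pmax(bw - hi, 0)
  data.frame(compound = rownames(E), row_min = lo, row_max = hi, bw = bw,
             within_bounds = excess == 0, excess = excess,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consistency diagnostics for an (energy matrix, weighted table) pair
#'
#' Runs [hull_check()] and [recover_weights()] on every cell-line column of
#' a weighted-energy table against the binding matrix. Columns containing
#' out-of-hull entries — values no simplex weighting of the matrix can
#' produce — are surfaced as a data-consistency warning, never an error.
#'
#' @param matrix a [binding_matrix].
#' @param bw_table a [weighted_energy_table] over the same compounds.
#' @param tolerance feasibility tolerance (kcal/mol) for [recover_weights()].
#' @return an object of class `bw_diagnosis`: list with per-cell-line
#'   `hull` reports, `recovery` fits, and a `summary` data frame.
#' @export
diagnose <- function(matrix, bw_table, tolerance = 0.02) {
  stopifnot(inherits(matrix, "binding_matrix"),
            inherits(bw_table, "weighted_energy_table"))
  common <- intersect(rownames(matrix), rownames(bw_table))
  if (length(common) == 0L) stop("no common compounds", call. = FALSE)
  sub <- binding_matrix(unclass(matrix)[common, , drop = FALSE])
  hull <- list()
  recovery <- list()
  rows <- list()
  for (cl in colnames(bw_table)) {
    bwc <- stats::setNames(unclass(bw_table)[common, cl], common)
    hull[[cl]] <- hull_check(sub, bwc)
    recovery[[cl]] <- recover_weights(sub, bwc, tolerance = tolerance)
    rows[[cl]] <- data.frame(cell_line = cl,
                             n_out_of_hull = sum(!hull[[cl]]$within_bounds),
                             max_excess = max(hull[[cl]]$excess),
                             residual_max = recovery[[cl]]$residual_max,
                             feasible = recovery[[cl]]$feasible,
                             stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_bad <- sum(summary_df$n_out_of_hull)
  if (n_bad > 0L) {
    warning(sprintf(paste0("data consistency: %d (compound, cell line) BE_w entries lie outside ",
                           "the convex hull of their energy rows; no simplex weighting of this ",
                           "matrix can reproduce them"), n_bad), call. = FALSE)
  }
  structure(list(hull = hull, recovery = recovery, summary = summary_df,
                 tolerance = tolerance),
            class = "bw_diagnosis")
}

#' @export
print.bw_diagnosis <- function(x, ...) {
  cat("Weighted-energy consistency diagnosis\n")
  print(x$summary, row.names = FALSE)
  if (any(!x$summary$feasible)) {
    cat("Columns marked infeasible cannot be expressed as any isotype-abundance\n")
    cat("weighting of the given energy matrix (tolerance",
        format(x$tolerance), "kcal/mol).\n")
  }
  invisible(x)
}
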