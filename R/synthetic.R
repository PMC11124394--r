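# Seeded generators reproducing the statistical structure the analysis
# assumes: a binding matrix with additive compound and isotype effects,
# Dirichlet abundance profiles, and logIC50 linear in BE_w with Gaussian
# noise and right-censoring at the assay bound.
#
# A single root seed expands deterministically into per-stage child seeds:
# child = (root * 10 + offset) mod 2^31, offsets 1 (matrix), 2 (profiles),
# 3 (potency). Stages are therefore reproducible in isolation.

.child_seed <- function(seed, offset) as.integer((as.numeric(seed) * 10 + offset) %% 2^31)

#' Generate a synthetic binding-energy matrix
#'
#' Entries follow an additive model
#' `E(c, i) = mean_energy + a_c + b_i + eps_ci` with independent Gaussian
#' compound effects `a_c`, isotype effects `b_i` and residuals, mimicking the
#' scale of colchicine-site docking tables (defaults: mean -8.5 kcal/mol,
#' entries roughly -7 to -10).
#'
#' @param n_compounds number of compounds (rows).
#' @param isotype_ids isotype labels (columns); a number is expanded to
#'   `iso1..isoK`.
#' @param compound_effect_sd,isotype_effect_sd,residual_sd standard
#'   deviations (kcal/mol) of the three Gaussian components.
#' @param mean_energy grand mean (kcal/mol).
#' @param seed integer seed.
#' @return a [binding_matrix] with compounds `cpd1..cpdN`.
#' @export
gen_binding_matrix <- function(n_compounds = 9, isotype_ids = 9,
                               compound_effect_sd = 0.3, isotype_effect_sd = 0.3,
                               residual_sd = 0.1, mean_energy = -8.5, seed = 1) {
  if (length(isotype_ids) == 1L && is.numeric(isotype_ids)) {
    if (isotype_ids < 1) stop("empty isotype set", call. = FALSE)
    isotype_ids <- paste0("iso", seq_len(isotype_ids))
  }
  if (length(isotype_ids) < 1L) stop("empty isotype set", call. = FALSE)
  if (n_compounds < 1L) stop("need at least one compound", call. = FALSE)
  stopifnot(compound_effect_sd >= 0, isotype_effect_sd >= 0, residual_sd >= 0)
  set.seed(seed)
  k <- length(isotype_ids)
  a <- stats::rnorm(n_compounds, 0, compound_effect_sd)
  b <- stats::rnorm(k, 0, isotype_effect_sd)
  eps <- matrix(stats::rnorm(n_compounds * k, 0, residual_sd), n_compounds, k)
  E <- mean_energy + outer(a, b, `+`) + eps
  binding_matrix(E, paste0("cpd", seq_len(n_compounds)), isotype_ids)
}

#' Generate Dirichlet abundance profiles for a cell-line panel
#'
#' Each cell line's isotype-abundance vector is drawn from a symmetric
#' Dirichlet (gamma draws normalized to the simplex). Large concentrations
#' approach the uniform profile; concentration 1 is flat over the simplex.
#'
#' @param n_lines number of cell lines.
#' @param isotype_ids isotype labels, or a count.
#' @param concentration symmetric Dirichlet concentration, > 0.
#' @param seed integer seed.
#' @return an `expression_panel` with cell lines `line1..lineN`; the columns
#'   are the true weight vectors.
#' @export
gen_profiles <- function(n_lines = 7, isotype_ids = 9, concentration = 1, seed = 1) {
  if (n_lines < 1L) stop("need at least one cell line", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  if (length(isotype_ids) == 1L && is.numeric(isotype_ids)) {
    isotype_ids <- paste0("iso", seq_len(isotype_ids))
  }
  set.seed(seed)
  k <- length(isotype_ids)
  profiles <- lapply(seq_len(n_lines), function(i) {
    g <- stats::rgamma(k, shape = concentration, rate = 1)
    while (sum(g) == 0) g <- stats::rgamma(k, shape = concentration, rate = 1)
    expression_profile(stats::setNames(g / sum(g), isotype_ids),
                       cell_line = paste0("line", i))
  })
  expression_panel(profiles)
}

#' Bundle ground truth for an end-to-end synthetic experiment
#'
#' Ties together a binding matrix, an abundance panel and the response
#' model `logIC50 = intercept + slope * BE_w + N(0, noise_sd)` with
#' right-censoring of IC50 at `censor_bound` (uM). Defaults mimic the study
#' scale: 9 compounds, 9 isotypes, 7 cell lines, energies near
#' -8.5 kcal/mol, IC50 in the tens-of-micromolar range.
#'
#' @param n_compounds,n_isotypes,n_lines dimensions.
#' @param slope logIC50 units per kcal/mol (positive: weaker binding, higher
#'   IC50).
#' @param intercept logIC50 at BE_w = 0.
#' @param noise_sd Gaussian noise SD on the logIC50 scale.
#' @param censor_bound right-censoring bound in uM.
#' @param concentration Dirichlet concentration for the profiles.
#' @param seed root seed; stages use fixed child seeds derived from it.
#' @param ... further arguments to [gen_binding_matrix()].
#' @return an object of class `synthetic_truth`: list with `matrix`,
#'   `panel`, `bw_table` (noiseless BE_w), model parameters and `seed`.
#' @export
synthetic_truth <- function(n_compounds = 9, n_isotypes = 9, n_lines = 7,
                            slope = 1, intercept = 10.2, noise_sd = 0.1,
                            censor_bound = 100, concentration = 1, seed = 1, ...) {
  stopifnot(noise_sd >= 0, censor_bound > 0)
  mat <- gen_binding_matrix(n_compounds, n_isotypes, seed = .child_seed(seed, 1), ...)
  panel <- gen_profiles(n_lines, colnames(mat), concentration = concentration,
                        seed = .child_seed(seed, 2))
  structure(list(matrix = mat, panel = panel,
                 bw_table = weighted_energy_panel(mat, panel),
                 slope = slope, intercept = intercept, noise_sd = noise_sd,
                 censor_bound = censor_bound, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d compounds x %d isotypes x %d cell lines\n",
              nrow(x$matrix), ncol(x$matrix), ncol(x$panel)))
  cat(sprintf("  logIC50 = %.3g + %.3g * BE_w + N(0, %.3g); censored at %g uM; seed %d\n",
              x$intercept, x$slope, x$noise_sd, x$censor_bound, x$seed))
  invisible(x)
}

#' Simulate a censored potency table from a synthetic truth
#'
#' Applies the truth's linear response model to its noiseless BE_w table,
#' adds Gaussian noise on the log10 scale, exponentiates to uM, and stores
#' entries exceeding the censor bound as right-censored at the bound.
#'
#' @param truth a [synthetic_truth()] object.
#' @param seed optional override of the potency-stage child seed.
#' @return a [potency_table].
#' @export
gen_potency <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(if (is.null(seed)) .child_seed(truth$seed, 3) else seed)
  bw <- unclass(truth$bw_table)
  lmu <- truth$intercept + truth$slope * bw
  noise <- matrix(stats::rnorm(length(lmu), 0, truth$noise_sd),
                  nrow(lmu), ncol(lmu))
  ic <- 10^(lmu + noise)
  cens <- ic > truth$censor_bound
  df <- expand.grid(compound = rownames(bw), cell_line = colnames(bw),
                    stringsAsFactors = FALSE)
  idx <- cbind(match(df$compound, rownames(bw)), match(df$cell_line, colnames(bw)))
  potency_table(df$compound, df$cell_line,
                ifelse(cens[idx], truth$censor_bound, ic[idx]),
                ifelse(cens[idx], "censored", "observed"))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `binding_matrix.tsv`, `expression.tsv`, `ic50.tsv` and
#' `truth.json` in the package's delimited formats, for use as pipeline
#' inputs.
#'
#' @param truth a [synthetic_truth()] object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(truth$matrix, file.path(dir, "binding_matrix.tsv"))
  write_table(truth$panel, file.path(dir, "expression.tsv"))
  write_table(gen_potency(truth), file.path(dir, "ic50.tsv"))
  write_report(list(slope = truth$slope, intercept = truth$intercept,
                    noise_sd = truth$noise_sd, censor_bound = truth$censor_bound,
                    seed = truth$seed,
                    true_weights = apply(unclass(truth$panel), 2L, identity,
                                         simplify = FALSE)),
               file.path(dir, "truth.json"))
  invisible(dir)
}
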