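# End-to-end orchestration: weighting -> diagnostics -> QSAR, driven by a
# flat key-value config, producing a single JSON-serializable run report
# with input checksums and every analysis decision recorded.

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path config file path.
#' @return named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  stats::setNames(vapply(kv, function(m) trimws(m[3L]), character(1)),
                  vapply(kv, function(m) trimws(m[2L]), character(1)))
}

.cfg <- function(config, key, default = NULL) {
  if (key %in% names(config)) config[[key]] else default
}

#' Run the full weighted-energy QSAR pipeline
#'
#' Reads the configured input tables, computes (or ingests) the
#' weighted-energy table, runs consistency diagnostics, fits the QSAR
#' models, and returns a structured report. Recognized config keys:
#' `matrix` (required), exactly one of `expression` / `weighted`,
#' `ic50` (required), `descriptors`, `censor_policy` (`exclude` or
#' `at_bound`), `log_base`, `tolerance`, `restrict` (`true`/`false`),
#' `gene_map` (path, or `bundled`).
#'
#' @param config named vector or list (as from [read_config()]), or a path
#'   to a config file.
#' @return an object of class `bw_report`: nested list with `inputs`
#'   (paths + MD5 checksums), `settings`, `bw_table`, `diagnostics`,
#'   `r2_panel`, per-cell-line fits and exclusions. Serialize with
#'   [write_report()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- read_config(config)
  }
  config <- as.list(config)
  need <- function(key) {
    v <- .cfg(config, key)
    if (is.null(v)) stop("config is missing required key '", key, "'", call. = FALSE)
    v
  }
  policy <- .cfg(config, "censor_policy", "exclude")
  if (!policy %in% c("exclude", "at_bound")) {
    stop("config error: unknown censor policy '", policy, "'", call. = FALSE)
  }
  log_base <- as.numeric(.cfg(config, "log_base", "10"))
  tolerance <- as.numeric(.cfg(config, "tolerance", "0.02"))
  restrict <- tolower(.cfg(config, "restrict", "false")) %in% c("true", "yes", "1")

  paths <- list(matrix = need("matrix"), ic50 = need("ic50"))
  if (!is.null(.cfg(config, "expression"))) paths$expression <- config$expression
  if (!is.null(.cfg(config, "weighted"))) paths$weighted <- config$weighted
  if (is.null(paths$expression) && is.null(paths$weighted)) {
    stop("config must name either 'expression' or 'weighted'", call. = FALSE)
  }
  if (!is.null(.cfg(config, "descriptors"))) paths$descriptors <- config$descriptors
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  checksums <- vapply(unlist(paths), function(p) unname(tools::md5sum(p)), character(1))

  mat <- read_binding_matrix(paths$matrix)
  pot <- read_potency_table(paths$ic50)
  desc <- NULL
  if (!is.null(paths$descriptors)) {
    desc <- utils::read.delim(paths$descriptors, sep = "\t",
                              stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (ncol(desc) == 1L) {
      desc <- utils::read.csv(paths$descriptors, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
    }
    names(desc)[1L] <- "compound"
    desc$compound <- as.character(desc$compound)
  }
  if (!is.null(paths$expression)) {
    gm_key <- .cfg(config, "gene_map")
    gm <- if (is.null(gm_key)) NULL
          else if (identical(gm_key, "bundled")) read_gene_isotype_map()
          else read_gene_isotype_map(gm_key)
    expr <- read_expression_panel(paths$expression, gene_map = gm)
  } else {
    expr <- read_weighted_energy_table(paths$weighted)
  }

  fit <- withCallingHandlers(
    bw_qsar(mat, expr, pot, descriptors = desc, censor_policy = policy,
            log_base = log_base, restrict = restrict, tolerance = tolerance),
    warning = function(w) invokeRestart("muffleWarning"))

  r2m <- unclass(fit$r2)
  attributes(r2m)[setdiff(names(attributes(r2m)), c("dim", "dimnames"))] <- NULL
  diagnostics <- NULL
  if (!is.null(fit$diagnosis)) {
    diagnostics <- list(
      summary = fit$diagnosis$summary,
      out_of_hull = lapply(fit$diagnosis$hull, function(h)
        h[!h$within_bounds, c("compound", "row_min", "row_max", "bw", "excess")]))
  }
  report <- list(
    inputs = list(paths = paths, md5 = as.list(checksums)),
    settings = list(censor_policy = policy, log_base = log_base,
                    tolerance = tolerance, restrict = restrict),
    bw_table = as.data.frame(unclass(fit$bw_table)),
    diagnostics = diagnostics,
    r2_panel = as.data.frame(r2m),
    fits = lapply(fit$fits, function(f) list(
      coefficients = as.list(f$coefficients),
      r_squared = f$r_squared,
      n_used = f$n_used,
      excluded = f$excluded)),
    bivariate = if (is.null(fit$bivariate)) NULL else
      lapply(fit$bivariate, function(f) list(
        coefficients = as.list(f$coefficients),
        r_squared = f$r_squared, n_used = f$n_used)))
  structure(list(report = report, fit = fit), class = "bw_report")
}

#' @export
print.bw_report <- function(x, ...) {
  cat("Pipeline run report\n")
  print(x$fit)
  if (!is.null(x$report$diagnostics)) {
    cat("\n")
    print(x$report$diagnostics$summary, row.names = FALSE)
  }
  invisible(x)
}
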