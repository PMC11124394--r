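# Shared parsing helpers --------------------------------------------------

# Tables arrive as they are typeset: Unicode minus (U+2212) and ASCII hyphen
# must parse identically.
.normalize_minus <- function(x) gsub("−", "-", x, fixed = TRUE)

.parse_numeric_cell <- function(cell, row_label, col_label) {
  txt <- trimws(.normalize_minus(cell))
  if (grepl(",", txt, fixed = TRUE)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' (comma decimals are not accepted)",
                 cell, row_label, col_label), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cell, row_label, col_label), call. = FALSE)
  }
  val
}

# Delimiter auto-detection is deliberately narrow: tab or comma only.
.detect_delim <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

.read_cells <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(sprintf("parse error: '%s' has no data rows", path), call. = FALSE)
  }
  delim <- .detect_delim(lines[[1L]])
  strsplit(lines, delim, fixed = TRUE)
}

# Constructors and validators ----------------------------------------------

#' Construct a compound-by-isotype binding-energy matrix
#'
#' A `binding_matrix` is a numeric matrix of docking binding energies in
#' kcal/mol, rows labelled by compound id and columns by tubulin isotype
#' (more negative = stronger predicted binding). All entries must be finite
#' and row/column labels unique.
#'
#' @param energies numeric matrix, compounds in rows, isotypes in columns.
#' @param compound_ids,isotype_ids optional label vectors overriding dimnames.
#' @return an object of class `binding_matrix`.
#' @export
binding_matrix <- function(energies, compound_ids = rownames(energies),
                           isotype_ids = colnames(energies)) {
  energies <- as.matrix(energies)
  storage.mode(energies) <- "double"
  if (is.null(compound_ids) || is.null(isotype_ids)) {
    stop("binding_matrix requires compound and isotype labels", call. = FALSE)
  }
  if (length(compound_ids) != nrow(energies) || length(isotype_ids) != ncol(energies)) {
    stop("label counts do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) stop("duplicate compound ids", call. = FALSE)
  if (anyDuplicated(isotype_ids)) stop("duplicate isotype ids", call. = FALSE)
  if (!all(is.finite(energies))) stop("binding energies must all be finite", call. = FALSE)
  dimnames(energies) <- list(as.character(compound_ids), as.character(isotype_ids))
  class(energies) <- c("binding_matrix", class(energies))
  energies
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("binding_matrix: %d compounds x %d isotypes (kcal/mol)\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a censored potency table
#'
#' Long-format IC50 table: one row per (compound, cell line) with the value in
#' micromolar and a status flag. `"censored"` rows carry the right-censoring
#' bound (an entry printed as ">100" has `value = 100`,
#' `status = "censored"`). Standard deviations, when the source prints
#' "mean +/- SD" cells, are kept in `sd` but unused downstream.
#'
#' @param compound,cell_line character vectors.
#' @param value numeric, IC50 in uM (or the censor bound).
#' @param status `"observed"` or `"censored"`.
#' @param sd optional numeric vector of reported SDs.
#' @return a data frame of class `potency_table`.
#' @export
potency_table <- function(compound, cell_line, value, status, sd = NA_real_) {
  status <- match.arg(status, c("observed", "censored"), several.ok = TRUE)
  df <- data.frame(compound = as.character(compound),
                   cell_line = as.character(cell_line),
                   value = as.numeric(value),
                   status = status,
                   sd = as.numeric(sd),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("compound", "cell_line")])) {
    stop("duplicate (compound, cell line) keys", call. = FALSE)
  }
  bad <- !is.finite(df$value) | df$value <= 0
  if (any(bad)) {
    stop(sprintf("nonpositive or non-finite IC50 for (%s, %s)",
                 df$compound[bad][1L], df$cell_line[bad][1L]), call. = FALSE)
  }
  class(df) <- c("potency_table", "data.frame")
  df
}

#' @export
print.potency_table <- function(x, ...) {
  cat(sprintf("potency_table: %d entries (%d observed, %d right-censored), %d compounds x %d cell lines\n",
              nrow(x), sum(x$status == "observed"), sum(x$status == "censored"),
              length(unique(x$compound)), length(unique(x$cell_line))))
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Construct a weighted-energy table
#'
#' Matrix of expression-weighted binding energies BE_w (kcal/mol),
#' compounds in rows, cell lines in columns.
#'
#' @param energies numeric matrix with compound rownames and cell-line colnames.
#' @return an object of class `weighted_energy_table`.
#' @export
weighted_energy_table <- function(energies) {
  energies <- as.matrix(energies)
  storage.mode(energies) <- "double"
  if (is.null(rownames(energies)) || is.null(colnames(energies))) {
    stop("weighted_energy_table requires compound and cell-line labels", call. = FALSE)
  }
  if (anyDuplicated(rownames(energies)) || anyDuplicated(colnames(energies))) {
    stop("duplicate labels", call. = FALSE)
  }
  if (!all(is.finite(energies))) stop("BE_w values must be finite", call. = FALSE)
  class(energies) <- c("weighted_energy_table", class(energies))
  energies
}

#' @export
print.weighted_energy_table <- function(x, ...) {
  cat(sprintf("weighted_energy_table: %d compounds x %d cell lines (BE_w, kcal/mol)\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

# Readers -------------------------------------------------------------------

#' Read a compound-by-isotype binding-energy table
#'
#' Expects one header row of isotype labels (first field names the compound
#' column) and one row per compound. Tab or comma delimited; decimal
#' separator is the period; Unicode minus and ASCII hyphen both accepted.
#'
#' @param path path to the delimited text file.
#' @return a [binding_matrix].
#' @export
read_binding_matrix <- function(path) {
  cells <- .read_cells(path)
  header <- cells[[1L]]
  isotypes <- trimws(header[-1L])
  rows <- cells[-1L]
  compounds <- vapply(rows, function(r) trimws(r[[1L]]), character(1))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(isotypes))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(isotypes) + 1L) {
      stop(sprintf("row '%s' has %d cells, expected %d",
                   compounds[i], length(r) - 1L, length(isotypes)), call. = FALSE)
    }
    for (j in seq_along(isotypes)) {
      mat[i, j] <- .parse_numeric_cell(r[[j + 1L]], compounds[i], isotypes[j])
    }
  }
  binding_matrix(mat, compounds, isotypes)
}

.parse_potency_cell <- function(cell, row_label, col_label, censor_token = ">") {
  txt <- trimws(.normalize_minus(cell))
  if (startsWith(txt, censor_token)) {
    bound <- suppressWarnings(as.numeric(trimws(substring(txt, nchar(censor_token) + 1L))))
    if (is.na(bound)) {
      stop(sprintf("malformed censor cell '%s' at row '%s', column '%s'",
                   cell, row_label, col_label), call. = FALSE)
    }
    return(list(value = bound, status = "censored", sd = NA_real_))
  }
  # "mean +/- SD": keep the mean, stash the SD
  parts <- strsplit(txt, "±", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) {
    m <- suppressWarnings(as.numeric(trimws(parts[1L])))
    s <- suppressWarnings(as.numeric(trimws(parts[2L])))
    if (is.na(m) || is.na(s)) {
      stop(sprintf("malformed cell '%s' at row '%s', column '%s'",
                   cell, row_label, col_label), call. = FALSE)
    }
    return(list(value = m, status = "observed", sd = s))
  }
  val <- .parse_numeric_cell(txt, row_label, col_label)
  list(value = val, status = "observed", sd = NA_real_)
}

#' Read a compound-by-cell-line IC50 table with right-censoring
#'
#' Cells may be plain numbers, "mean ± SD" pairs (the mean is kept, the
#' SD stored in the `sd` column), or censor tokens like ">100" which become
#' right-censored entries at the stated bound.
#'
#' @param path path to the delimited text file (compounds in rows, cell lines
#'   in columns).
#' @param censor_token prefix marking a right-censored cell, default `">"`.
#' @return a [potency_table].
#' @export
read_potency_table <- function(path, censor_token = ">") {
  cells <- .read_cells(path)
  header <- trimws(cells[[1L]])
  lines_ids <- header[-1L]
  rows <- cells[-1L]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- trimws(rows[[i]])
    cmp <- r[[1L]]
    if (length(r) != length(lines_ids) + 1L) {
      stop(sprintf("row '%s' has %d cells, expected %d",
                   cmp, length(r) - 1L, length(lines_ids)), call. = FALSE)
    }
    parsed <- lapply(seq_along(lines_ids), function(j)
      .parse_potency_cell(r[[j + 1L]], cmp, lines_ids[j], censor_token))
    out[[i]] <- data.frame(compound = cmp,
                           cell_line = lines_ids,
                           value = vapply(parsed, `[[`, numeric(1), "value"),
                           status = vapply(parsed, `[[`, character(1), "status"),
                           sd = vapply(parsed, `[[`, numeric(1), "sd"),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  potency_table(df$compound, df$cell_line, df$value, df$status, df$sd)
}

#' Read a weighted-energy table (compounds x cell lines)
#'
#' @param path path to the delimited text file.
#' @return a [weighted_energy_table].
#' @export
read_weighted_energy_table <- function(path) {
  m <- read_binding_matrix(path)
  weighted_energy_table(unclass(m))
}

# Writers -------------------------------------------------------------------

# Full-precision numeric formatting so that write-then-read is exact.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, digits = 17, format = "g")
    if (as.numeric(s) != v) s <- sprintf("%.17e", v)
    s
  }, character(1))
}

#' Write a pipeline table to delimited text
#'
#' Generic writer; layouts mirror the in-memory shapes (matrices as
#' compound-rowed grids, potency tables with censor tokens and "+/-" cells)
#' so that `read(write(x))` reproduces `x` exactly.
#'
#' @param x a `binding_matrix`, `weighted_energy_table`, `potency_table` or
#'   `expression_panel`.
#' @param path output file path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = "\t") UseMethod("write_table")

.write_matrix_grid <- function(x, path, sep, corner = "compound") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(corner, colnames(x)), collapse = sep), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], .fmt_num(x[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' @export
write_table.binding_matrix <- function(x, path, sep = "\t") {
  .write_matrix_grid(unclass(x), path, sep)
}

#' @export
write_table.weighted_energy_table <- function(x, path, sep = "\t") {
  .write_matrix_grid(unclass(x), path, sep)
}

#' @export
write_table.potency_table <- function(x, path, sep = "\t") {
  compounds <- unique(x$compound)
  lines_ids <- unique(x$cell_line)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("compound", lines_ids), collapse = sep), con)
  key <- paste(x$compound, x$cell_line, sep = "\r")
  idx <- stats::setNames(seq_len(nrow(x)), key)
  for (cmp in compounds) {
    cells <- vapply(lines_ids, function(cl) {
      i <- idx[paste(cmp, cl, sep = "\r")]
      if (is.na(i)) return("")
      if (x$status[i] == "censored") return(paste0(">", .fmt_num(x$value[i])))
      if (!is.na(x$sd[i])) return(paste0(.fmt_num(x$value[i]), " ± ", .fmt_num(x$sd[i])))
      .fmt_num(x$value[i])
    }, character(1))
    writeLines(paste(c(cmp, cells), collapse = sep), con)
  }
  invisible(path)
}

#' @export
write_table.expression_panel <- function(x, path, sep = "\t") {
  .write_matrix_grid(unclass(x), path, sep, corner = "isotype")
}

#' Write a run report as JSON
#'
#' @param report a named list (as produced by [run_pipeline()]).
#' @param path output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "bw_report")) report <- report$report
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# Bundled fixtures -----------------------------------------------------------

#' Paths to the bundled example tables
#'
#' The package ships transcriptions of the published compound/isotype
#' binding-energy grid (nine combretastatin-family compounds by nine
#' alpha/beta-tubulin isotype complexes), the expression-weighted energy
#' table over seven cell lines, and the SRB-assay IC50 panel with its
#' ">100 uM" right-censored entries.
#'
#' @param which one of `"binding"`, `"weighted"`, `"ic50"`, `"gene_map"`.
#' @return a file path.
#' @export
bindweight_example <- function(which = c("binding", "weighted", "ic50", "gene_map")) {
  which <- match.arg(which)
  fn <- switch(which,
               binding = "table3_binding_energies.tsv",
               weighted = "table4_weighted_energies.tsv",
               ic50 = "table2_ic50.tsv",
               gene_map = "gene_isotype_map.tsv")
  system.file("extdata", fn, package = "bindweight", mustWork = TRUE)
}
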