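# Isotype expression profiles live on the probability simplex: nonnegative
# abundance fractions over tubulin isotypes summing to 1. Cell-line panels
# are isotype-by-cell-line matrices of such columns.

.SIMPLEX_TOL <- 1e-9

#' Construct an isotype expression profile
#'
#' @param fractions named numeric vector, isotype id -> abundance fraction.
#' @param cell_line optional cell-line label, stored as an attribute.
#' @return an object of class `expression_profile` (a named numeric vector on
#'   the probability simplex).
#' @export
expression_profile <- function(fractions, cell_line = NULL) {
  if (length(fractions) < 1L) stop("at least one isotype required", call. = FALSE)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named by isotype id", call. = FALSE)
  }
  if (anyDuplicated(names(fractions))) stop("duplicate isotype ids", call. = FALSE)
  ids <- names(fractions)
  fractions <- stats::setNames(as.numeric(fractions), ids)
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("fractions must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > .SIMPLEX_TOL) {
    stop(sprintf("fractions sum to %.12g, not 1", sum(fractions)), call. = FALSE)
  }
  structure(fractions, class = "expression_profile", cell_line = cell_line)
}

#' @export
print.expression_profile <- function(x, ...) {
  cl <- attr(x, "cell_line")
  cat(sprintf("expression_profile%s over %d isotypes:\n",
              if (is.null(cl)) "" else paste0(" [", cl, "]"), length(x)))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Normalize raw expression values to abundance fractions
#'
#' Divides each raw value by the total so the profile lands on the
#' probability simplex. Scale-invariant: `normalize_expression(c * raw)`
#' equals `normalize_expression(raw)` for any `c > 0`.
#'
#' @param raw named nonnegative numeric vector of raw expression values
#'   (at least one strictly positive).
#' @param cell_line optional cell-line label.
#' @return an [expression_profile].
#' @export
normalize_expression <- function(raw, cell_line = NULL) {
  if (length(raw) < 1L) stop("empty expression vector", call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw expression values must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(raw)
  if (total <= 0) stop("degenerate profile: all expression values are zero", call. = FALSE)
  expression_profile(raw / total, cell_line = cell_line)
}

#' Average a set of expression profiles
#'
#' Unweighted arithmetic mean of abundance fractions (mean of simplex
#' points), renormalized to sum exactly to 1. Used to approximate a cell
#' line by the tissue-average expression of related lines. Isotypes missing
#' from a profile count as zero. With `on_raw = TRUE` the profiles are
#' treated as raw values summed before normalization (equivalent here since
#' each profile already sums to 1; the flag matters for callers averaging
#' unnormalized inputs via [normalize_expression()]).
#'
#' @param profiles list of [expression_profile] objects.
#' @param cell_line label for the averaged profile.
#' @param on_raw average-then-normalize instead of mean-of-fractions;
#'   default `FALSE` keeps each cell line equally weighted.
#' @return an [expression_profile].
#' @export
average_profiles <- function(profiles, cell_line = NULL, on_raw = FALSE) {
  if (length(profiles) < 1L) stop("at least one profile required", call. = FALSE)
  isotypes <- unique(unlist(lapply(profiles, names)))
  acc <- stats::setNames(numeric(length(isotypes)), isotypes)
  for (p in profiles) {
    v <- stats::setNames(numeric(length(isotypes)), isotypes)
    v[names(p)] <- as.numeric(p)
    acc <- acc + v
  }
  if (!on_raw) acc <- acc / length(profiles)
  normalize_expression(acc, cell_line = cell_line)
}

#' Uniform profile over a stated isotype set
#'
#' Assigns fraction 1/k to each of the k listed isotypes — the fallback when
#' no quantitative expression data exist for a cell line and one assumes a
#' uniform distribution over the isotypes it is known to express.
#'
#' @param isotype_ids nonempty character vector of isotype labels.
#' @param cell_line optional cell-line label.
#' @return an [expression_profile].
#' @export
uniform_profile <- function(isotype_ids, cell_line = NULL) {
  if (length(isotype_ids) < 1L) stop("empty isotype set", call. = FALSE)
  expression_profile(stats::setNames(rep(1 / length(isotype_ids), length(isotype_ids)),
                                     isotype_ids),
                     cell_line = cell_line)
}

#' Assemble profiles into an expression panel
#'
#' @param profiles list of [expression_profile] objects; cell-line labels are
#'   taken from their `cell_line` attributes or from `names(profiles)`.
#' @return an `expression_panel`: isotype-by-cell-line matrix whose columns
#'   are simplex vectors.
#' @export
expression_panel <- function(profiles) {
  if (length(profiles) < 1L) stop("at least one profile required", call. = FALSE)
  labels <- vapply(seq_along(profiles), function(i) {
    cl <- attr(profiles[[i]], "cell_line")
    if (!is.null(cl)) return(as.character(cl))
    if (!is.null(names(profiles)) && nzchar(names(profiles)[i])) return(names(profiles)[i])
    stop("profile ", i, " has no cell-line label", call. = FALSE)
  }, character(1))
  if (anyDuplicated(labels)) stop("duplicate cell-line ids", call. = FALSE)
  isotypes <- unique(unlist(lapply(profiles, names)))
  m <- matrix(0, nrow = length(isotypes), ncol = length(profiles),
              dimnames = list(isotypes, labels))
  for (i in seq_along(profiles)) m[names(profiles[[i]]), i] <- as.numeric(profiles[[i]])
  structure(m, class = c("expression_panel", class(m)))
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d isotypes x %d cell lines\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a gene-to-isotype label map
#'
#' Two-column delimited file (gene, isotype). The bundled default covers the
#' six beta-tubulin genes with unambiguous isotype assignments (TUBB, TUBB2A,
#' TUBB2B, TUBB3, TUBB4, TUBB2C).
#'
#' @param path file path; defaults to the bundled map.
#' @return named character vector, gene -> isotype label.
#' @export
read_gene_isotype_map <- function(path = bindweight_example("gene_map")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stats::setNames(df$isotype, df$gene)
}

#' Read an expression table and build a panel of simplex profiles
#'
#' Rows are genes or isotypes, columns are cell lines. Columns summing to
#' 1 (within 0.01) are treated as pre-normalized fractions; otherwise values
#' are taken as raw expression and normalized per column. Row labels found in
#' `gene_map` are relabelled to isotypes (values for genes mapping to the
#' same isotype are summed); labels already matching an isotype are kept;
#' anything else is dropped with a warning.
#'
#' @param path delimited text file (tab or comma).
#' @param gene_map optional named character vector gene -> isotype, as from
#'   [read_gene_isotype_map()]; `NULL` leaves row labels untouched.
#' @return an `expression_panel`.
#' @export
read_expression_panel <- function(path, gene_map = NULL) {
  cells <- .read_cells(path)
  header <- trimws(cells[[1L]])
  lines_ids <- header[-1L]
  rows <- cells[-1L]
  labels <- vapply(rows, function(r) trimws(r[[1L]]), character(1))
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(lines_ids),
              dimnames = list(labels, lines_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    for (j in seq_along(lines_ids)) {
      m[i, j] <- .parse_numeric_cell(r[[j + 1L]], labels[i], lines_ids[j])
    }
  }
  if (!is.null(gene_map)) {
    mapped <- ifelse(labels %in% names(gene_map), gene_map[labels], labels)
    # rows neither a mapped gene nor already an isotype label are dropped
    known <- labels %in% names(gene_map) | labels %in% unname(gene_map)
    if (any(!known)) {
      warning("ignoring unmapped expression rows: ",
              paste(labels[!known], collapse = ", "), call. = FALSE)
      m <- m[known, , drop = FALSE]
      mapped <- mapped[known]
    }
    m <- rowsum(m, group = mapped)
  }
  profiles <- lapply(colnames(m), function(cl) {
    col <- stats::setNames(m[, cl], rownames(m))
    if (abs(sum(col) - 1) <= 0.01) {
      expression_profile(col / sum(col), cell_line = cl)
    } else {
      normalize_expression(col, cell_line = cl)
    }
  })
  expression_panel(profiles)
}
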