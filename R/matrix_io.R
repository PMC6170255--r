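#' Construct an inhibition matrix
#'
#' The central container of the package: a compounds-by-kinases matrix of
#' percent-inhibition values. Rows are compound entries (the same chemical at
#' two doses gives two independent rows), columns are kinases, cells are
#' percent inhibition in \[0, 100\] or `NA` where the pair was never profiled.
#'
#' @param values Numeric matrix with unique row names (compound entry labels)
#'   and unique column names (kinase names). Values must lie in \[0, 100\] or
#'   be `NA`.
#' @param dataset Short name of the source screen (free text).
#' @param convention Value convention of the *source* file the matrix came
#'   from, kept as provenance; stored values are always percent inhibition.
#' @param notes Optional free-text dose/assay notes.
#' @return An object of class `inhib_matrix`: a list with elements `values`
#'   (the numeric matrix) and `meta` (dataset, convention, notes).
#' @examples
#' m <- inhib_matrix(matrix(c(90, 5, 10, 80), 2, 2,
#'                          dimnames = list(c("cmpdA", "cmpdB"),
#'                                          c("AKT1", "AKT2"))))
#' pairwise_coverage(m)
#' @export
inhib_matrix <- function(values, dataset = "unnamed",
                         convention = "percent-inhibition", notes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_validation("`values` must have row names (compounds) and column names (kinases)")
  }
  x <- structure(list(values = values,
                      meta = list(dataset = dataset,
                                  convention = convention,
                                  notes = notes)),
                 class = "inhib_matrix")
  validate_inhib_matrix(x)
}

validate_inhib_matrix <- function(x) {
  v <- x$values
  if (nrow(v) < 1L) abort_validation("matrix needs at least 1 compound row")
  if (ncol(v) < 2L) {
    abort_validation("matrix needs at least 2 kinase columns (a selectivity score needs at least one potential off-target)")
  }
  dup_r <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup_r)) {
    abort_validation("duplicate compound labels: %s", toString(dup_r),
                     data = dup_r)
  }
  dup_c <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup_c)) {
    abort_validation("duplicate kinase labels: %s", toString(dup_c),
                     data = dup_c)
  }
  bad <- which(!is.na(v) & (v < 0 | v > 100 | !is.finite(v)))
  if (length(bad)) {
    abort_validation("%d cell(s) outside [0, 100]; first offender: %s / %s = %g",
                     length(bad),
                     rownames(v)[row(v)[bad[1]]], colnames(v)[col(v)[bad[1]]],
                     v[bad[1]])
  }
  x
}

#' @export
print.inhib_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<inhib_matrix> %d compound entries x %d kinases (dataset: %s)\n",
              nrow(v), ncol(v), x$meta$dataset))
  cat(sprintf("  pairwise coverage: %.1f%%\n", pairwise_coverage(x)))
  invisible(x)
}

#' @export
dim.inhib_matrix <- function(x) dim(x$values)

#' @export
as.matrix.inhib_matrix <- function(x, ...) x$values

#' Compound entry labels of an inhibition matrix
#' @param x An `inhib_matrix`.
#' @return Character vector of row labels.
#' @export
compounds <- function(x) rownames(x$values)

#' Kinase names of an inhibition matrix
#' @param x An `inhib_matrix`.
#' @return Character vector of column labels.
#' @export
kinases <- function(x) colnames(x$values)

# Default tokens treated as "not profiled" when parsing delimited files; the
# public screens use different dialects so the set is configurable.
DEFAULT_MISSING_TOKENS <- c("", "NA", "NaN", "ND")

#' Convert values to the internal percent-inhibition convention
#'
#' Screen exports come in two conventions: percent inhibition (higher = more
#' inhibited) and percent of control, i.e. residual activity (lower = more
#' inhibited). Internally everything is percent inhibition; percent-of-control
#' values v are mapped to 100 - v. Results are clamped to \[0, 100\]:
#' activation (percent of control above 100) clamps to 0 inhibition so that
#' downstream geometric means stay defined.
#'
#' @param value Numeric vector of finite values.
#' @param convention `"percent-inhibition"` or `"percent-of-control"`.
#' @return Numeric vector in \[0, 100\]; `NA` elements pass through.
#' @examples
#' to_percent_inhibition(10, "percent-of-control")   # 90
#' to_percent_inhibition(120, "percent-of-control")  # 0 (activation)
#' @export
to_percent_inhibition <- function(value,
                                  convention = c("percent-inhibition",
                                                 "percent-of-control")) {
  convention <- match.arg(convention)
  if (!is.numeric(value)) abort_validation("`value` must be numeric")
  if (any(!is.na(value) & !is.finite(value))) {
    abort_validation("non-finite inhibition value")
  }
  out <- if (convention == "percent-of-control") 100 - value else value
  pmin(pmax(out, 0), 100)
}

detect_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a compound-by-kinase matrix from delimited text
#'
#' Reads a wide-format CSV/TSV export of a kinase inhibitor screen: one header
#' row of kinase names, first column of compound entry labels (or the
#' transpose, via `orientation`). Values are converted to percent inhibition
#' (see [to_percent_inhibition()]) and clamped to \[0, 100\].
#'
#' @param path Path to a delimited text file.
#' @param orientation `"compounds"` if rows are compounds (the canonical
#'   layout), `"kinases"` if rows are kinases.
#' @param convention Value convention of the file; see
#'   [to_percent_inhibition()].
#' @param missing_tokens Strings parsed as missing cells.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param dataset Dataset name stored in the result's metadata; defaults to
#'   the file name.
#' @return An [inhib_matrix()] in canonical compounds-by-kinases orientation.
#' @export
read_inhib_matrix <- function(path,
                              orientation = c("compounds", "kinases"),
                              convention = c("percent-inhibition",
                                             "percent-of-control"),
                              missing_tokens = DEFAULT_MISSING_TOKENS,
                              delim = NULL,
                              dataset = NULL) {
  orientation <- match.arg(orientation)
  convention <- match.arg(convention)
  if (!file.exists(path)) abort_io("cannot read matrix file: %s", path)
  if (is.null(delim)) delim <- detect_delim(readLines(path, n = 1L))

  raw <- tryCatch(
    utils::read.table(path, sep = delim, header = FALSE, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) abort_io("failed to parse %s: %s", path, conditionMessage(e)))
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    abort_validation("matrix file %s needs a header row plus at least one data row", path)
  }

  col_labels <- trimws(as.character(raw[1, -1]))
  row_labels <- trimws(as.character(raw[-1, 1]))
  cells <- as.matrix(raw[-1, -1, drop = FALSE])

  vals <- matrix(NA_real_, nrow = length(row_labels), ncol = length(col_labels),
                 dimnames = list(row_labels, col_labels))
  for (j in seq_along(col_labels)) {
    tok <- trimws(cells[, j])
    is_missing <- tok %in% missing_tokens
    parsed <- suppressWarnings(as.numeric(tok))
    bad <- !is_missing & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1]
      abort_validation("non-numeric cell at row '%s', column '%s': '%s'",
                       row_labels[i], col_labels[j], tok[i])
    }
    vals[!is_missing, j] <- parsed[!is_missing]
  }

  if (orientation == "kinases") vals <- t(vals)

  dup_r <- unique(rownames(vals)[duplicated(rownames(vals))])
  dup_c <- unique(colnames(vals)[duplicated(colnames(vals))])
  if (length(dup_r) || length(dup_c)) {
    abort_validation("duplicate labels in %s: %s", path,
                     toString(c(dup_r, dup_c)), data = c(dup_r, dup_c))
  }

  keep <- !is.na(vals)
  vals[keep] <- to_percent_inhibition(vals[keep], convention)
  inhib_matrix(vals,
               dataset = dataset %||% basename(path),
               convention = convention)
}

#' Write an inhibition matrix to delimited text
#'
#' Inverse of [read_inhib_matrix()]: a header row of kinase names, one row per
#' compound entry, missing cells written as empty fields. Reading the file
#' back yields an identical matrix.
#'
#' @param x An `inhib_matrix`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_inhib_matrix <- function(x, path, delim = ",") {
  v <- x$values
  header <- paste(c("compound", colnames(v)), collapse = delim)
  body <- vapply(seq_len(nrow(v)), function(i) {
    cells <- ifelse(is.na(v[i, ]), "",
                    formatC(v[i, ], format = "g", digits = 15))
    paste(c(rownames(v)[i], cells), collapse = delim)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# Case- and whitespace-insensitive key under which raw kinase labels match.
alias_key <- function(x) tolower(gsub("[[:space:]]+", "", x))

#' Construct a kinase-name alias table
#'
#' Maps raw kinase labels, as they appear in a screen export, to standardized
#' names so that panels from different providers line up. Matching of raw
#' labels is case- and whitespace-insensitive. Every standard name implicitly
#' maps to itself, so applying the table is idempotent; an alias that would
#' redirect one of its own standard names is rejected.
#'
#' @param raw_label Character vector of labels as found in source files.
#' @param standard_name Character vector (same length) of standardized names.
#' @return An object of class `alias_table`.
#' @examples
#' al <- alias_table(c("Akt1", "PKB alpha"), c("AKT1", "AKT1"))
#' @export
alias_table <- function(raw_label = character(), standard_name = character()) {
  raw_label <- as.character(raw_label)
  standard_name <- as.character(standard_name)
  if (length(raw_label) != length(standard_name)) {
    abort_validation("raw_label and standard_name must have equal length")
  }
  key <- alias_key(raw_label)
  conflicting <- tapply(standard_name, key, function(s) length(unique(s)) > 1L)
  if (any(conflicting)) {
    abort_validation("raw label(s) mapped to more than one standard name: %s",
                     toString(names(conflicting)[conflicting]))
  }
  dup <- duplicated(key)
  tab <- data.frame(raw_label = raw_label[!dup],
                    standard_name = standard_name[!dup],
                    stringsAsFactors = FALSE)
  # idempotence: a standard name looked up as a raw label must map to itself
  skey <- alias_key(tab$standard_name)
  hit <- match(skey, alias_key(tab$raw_label))
  bad <- !is.na(hit) & tab$standard_name[hit] != tab$standard_name
  if (any(bad)) {
    abort_validation("alias table is not idempotent; standard name(s) re-mapped: %s",
                     toString(unique(tab$standard_name[bad])))
  }
  structure(tab, class = c("alias_table", "data.frame"))
}

#' Read an alias table from two-column delimited text
#'
#' @param path File with a header row and two columns: raw label, standard
#'   name. Comma or tab delimited (auto-detected).
#' @return An [alias_table()].
#' @export
read_alias_table <- function(path) {
  if (!file.exists(path)) abort_io("cannot read alias file: %s", path)
  delim <- detect_delim(readLines(path, n = 1L))
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  if (ncol(raw) < 2L) abort_validation("alias file %s needs two columns", path)
  alias_table(trimws(raw[[1]]), trimws(raw[[2]]))
}

lookup_alias <- function(labels, aliases) {
  hit <- match(alias_key(labels), alias_key(aliases$raw_label))
  out <- labels
  out[!is.na(hit)] <- aliases$standard_name[hit[!is.na(hit)]]
  out
}

#' Standardize kinase names in an inhibition matrix
#'
#' Replaces each kinase column label by its standard name from an alias table.
#' Labels absent from the table pass through unchanged with a warning (a
#' standardization table only covers the panels it was built for). When two
#' source columns map to the same standard name the behaviour is governed by
#' `on_collision`: `"error"` rejects the matrix, `"merge-mean"` averages the
#' non-missing cells of the colliding columns per compound.
#'
#' @param x An `inhib_matrix`.
#' @param aliases An [alias_table()].
#' @param on_collision `"error"` or `"merge-mean"`.
#' @return A standardized `inhib_matrix`. The operation is idempotent.
#' @export
standardize_kinase_names <- function(x, aliases,
                                     on_collision = c("error", "merge-mean")) {
  on_collision <- match.arg(on_collision)
  old <- colnames(x$values)
  new <- lookup_alias(old, aliases)
  unknown <- old[alias_key(old) %in% setdiff(alias_key(old), alias_key(aliases$raw_label))]
  if (length(unknown) && nrow(aliases)) {
    warn_kinsel("%d kinase label(s) not in alias table, passed through: %s",
                length(unknown), toString(utils::head(unknown, 10)))
  }
  v <- x$values
  colnames(v) <- new
  collided <- unique(new[duplicated(new)])
  if (length(collided)) {
    if (on_collision == "error") {
      abort_validation("kinase name collision after standardization: %s",
                       toString(collided), data = collided)
    }
    merged <- vapply(unique(new), function(nm) {
      sub <- v[, new == nm, drop = FALSE]
      rowMeans(sub, na.rm = TRUE)
    }, numeric(nrow(v)))
    if (nrow(v) == 1L) merged <- matrix(merged, nrow = 1L,
                                        dimnames = list(rownames(v), unique(new)))
    merged[is.nan(merged)] <- NA_real_
    v <- merged
  }
  inhib_matrix(v, dataset = x$meta$dataset,
               convention = x$meta$convention, notes = x$meta$notes)
}

#' Pairwise coverage of an inhibition matrix
#'
#' Percent of compound-by-kinase cells that carry a measured value; screens
#' differ widely in how completely their panel was profiled.
#'
#' @param x An `inhib_matrix`.
#' @return A percentage in \[0, 100\]; 100 iff no cell is missing.
#' @export
pairwise_coverage <- function(x) {
  100 * mean(!is.na(x$values))
}

#' Summary statistics for a screen matrix
#'
#' @param x An `inhib_matrix`.
#' @param base_compound_of Optional named character vector mapping compound
#'   entry labels to base compound names, used to count distinct chemicals
#'   when the same compound appears at several doses. With no mapping, each
#'   entry counts as its own compound.
#' @return A list of class `dataset_stats`: `n_compounds`, `n_entries`,
#'   `n_kinases`, `pairwise_coverage`.
#' @export
dataset_stats <- function(x, base_compound_of = NULL) {
  entries <- compounds(x)
  if (is.null(base_compound_of)) {
    base <- entries
  } else {
    unknown <- setdiff(names(base_compound_of), entries)
    if (length(unknown)) {
      abort_validation("base-compound mapping references unknown entries: %s",
                       toString(utils::head(unknown, 10)))
    }
    base <- entries
    hit <- match(entries, names(base_compound_of))
    base[!is.na(hit)] <- base_compound_of[hit[!is.na(hit)]]
  }
  structure(list(n_compounds = length(unique(base)),
                 n_entries = length(entries),
                 n_kinases = length(kinases(x)),
                 pairwise_coverage = pairwise_coverage(x)),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("compounds: %d  entries: %d  kinases: %d  coverage: %.1f%%\n",
              x$n_compounds, x$n_entries, x$n_kinases, x$pairwise_coverage))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
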