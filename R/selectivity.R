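#' Define a set of on-target kinases
#'
#' A compound is scored for a user-chosen set of 1 to 10 target kinases. The
#' ten-kinase cap mirrors common query-interface practice rather than a
#' mathematical constraint, so it can be lifted with `max_targets`.
#'
#' @param kinases Character vector of standardized kinase names, no
#'   duplicates.
#' @param max_targets Upper bound on the number of targets (default 10).
#' @return Character vector of class `target_set`.
#' @export
target_set <- function(kinases, max_targets = 10L) {
  kinases <- as.character(kinases)
  if (length(kinases) < 1L) abort_validation("at least one target kinase required")
  if (anyDuplicated(kinases)) {
    abort_validation("duplicate target kinases: %s",
                     toString(unique(kinases[duplicated(kinases)])))
  }
  if (length(kinases) > max_targets) {
    abort_validation("%d targets exceed the limit of %d on-target kinases",
                     length(kinases), max_targets)
  }
  structure(kinases, class = "target_set")
}

as_target_set <- function(targets, max_targets = 10L) {
  if (inherits(targets, "target_set")) targets else target_set(targets, max_targets)
}

check_targets_in_matrix <- function(x, targets) {
  missing <- setdiff(as.character(targets), kinases(x))
  if (length(missing)) {
    abort_validation("target kinase(s) not in matrix: %s", toString(missing),
                     data = missing)
  }
  invisible(targets)
}

split_row <- function(row, targets) {
  targets <- as.character(targets)
  t_vals <- row[names(row) %in% targets]
  o_vals <- row[!(names(row) %in% targets)]
  list(target = t_vals[!is.na(t_vals)], off = o_vals[!is.na(o_vals)])
}

#' On-target inhibition score
#'
#' The target component of the selectivity score: the percent inhibition of
#' the chosen kinase, or the geometric mean across the chosen kinases when
#' several are selected. A zero anywhere among the measured targets forces the
#' score to zero (the geometric mean annihilates), reflecting that a compound
#' failing to touch one intended target is not a usable inhibitor of the set.
#'
#' @param row Named numeric vector: one compound's percent-inhibition values
#'   across the panel (`NA` = not profiled).
#' @param targets A [target_set()] or character vector of target kinases.
#' @return The score G in \[0, 100\], or `NA` when no target kinase was
#'   profiled for this compound (the compound is undefined, not zero).
#' @export
inhibition_score <- function(row, targets) {
  parts <- split_row(row, as_target_set(targets))
  vals <- parts$target
  if (!length(vals)) return(NA_real_)
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Broad-activity off-target penalty
#'
#' Mean percent inhibition over all profiled off-target kinases. This captures
#' the promiscuous archetype: a compound that weakly inhibits nearly the whole
#' panel accumulates a penalty equal to that weak level, regardless of panel
#' size.
#'
#' @inheritParams inhibition_score
#' @return Penalty in \[0, 100\]; 0 (with a warning) when no off-target was
#'   profiled.
#' @export
broad_penalty <- function(row, targets) {
  off <- split_row(row, as_target_set(targets))$off
  if (!length(off)) {
    warn_kinsel("no measured off-target kinases; broad penalty set to 0")
    return(0)
  }
  mean(off)
}

#' Near-magnitude off-target penalty
#'
#' Penalizes off-target effects close in magnitude to the on-target score G.
#' Each off-target with inhibition I contributes I * I / (I + G), averaged
#' over the profiled off-targets. The weight I / (I + G) is continuous and
#' threshold-free: it approaches 1 when I greatly exceeds G (the off-target
#' counts at nearly full magnitude) and 0 when I is negligible next to G. An
#' off-target with I = 0 contributes 0 even when G = 0.
#'
#' @inheritParams inhibition_score
#' @param G The on-target score from [inhibition_score()].
#' @return Penalty in \[0, 100\]; 0 (with a warning) when no off-target was
#'   profiled.
#' @export
near_penalty <- function(row, targets, G) {
  off <- split_row(row, as_target_set(targets))$off
  if (!length(off)) {
    warn_kinsel("no measured off-target kinases; near penalty set to 0")
    return(0)
  }
  terms <- ifelse(off == 0, 0, off * off / (off + G))
  mean(terms)
}

#' Composite selectivity score for one compound
#'
#' S = G - P_b - P_n: on-target inhibition minus the broad-activity penalty
#' minus the near-magnitude penalty, all in percent units. Only kinases for
#' which the compound has been profiled enter any term; missing cells are
#' excluded, never imputed. A compound with no profiled target kinase is
#' flagged undefined rather than scored.
#'
#' @inheritParams inhibition_score
#' @return A one-row data frame (a score record) with columns `compound_id`,
#'   `inhibition_score`, `penalty_broad`, `penalty_near`, `selectivity_score`,
#'   `n_targets_measured`, `n_offtargets_measured`, `defined`.
#' @examples
#' row <- c(AKT1 = 80, MAPK1 = 40, CDK2 = 20)
#' selectivity_score(row, "AKT1")  # S = 80 - 30 - 8.667
#' @export
selectivity_score <- function(row, targets) {
  targets <- as_target_set(targets)
  parts <- split_row(row, targets)
  id <- attr(row, "compound_id") %||% NA_character_
  rec <- data.frame(compound_id = id,
                    inhibition_score = NA_real_,
                    penalty_broad = NA_real_,
                    penalty_near = NA_real_,
                    selectivity_score = NA_real_,
                    n_targets_measured = length(parts$target),
                    n_offtargets_measured = length(parts$off),
                    defined = FALSE,
                    stringsAsFactors = FALSE)
  if (!length(parts$target)) return(rec)
  G <- inhibition_score(row, targets)
  suppressWarnings({
    Pb <- broad_penalty(row, targets)
    Pn <- near_penalty(row, targets, G)
  })
  rec$inhibition_score <- G
  rec$penalty_broad <- Pb
  rec$penalty_near <- Pn
  rec$selectivity_score <- G - Pb - Pn
  rec$defined <- TRUE
  rec
}

#' Significant off-targets of one compound
#'
#' A significant off-target is a kinase inhibited at least half as much as the
#' chosen target (or half of the geometric mean for several targets); the
#' boundary I = G/2 is included. When G = 0 every off-target with any
#' inhibition at all is reported, and the ratio to target is undefined.
#'
#' @inheritParams inhibition_score
#' @return Data frame with columns `kinase`, `inhibition`, `ratio`
#'   (inhibition / G, `NA` when G = 0), sorted by descending inhibition.
#' @export
significant_off_targets <- function(row, targets) {
  targets <- as_target_set(targets)
  G <- inhibition_score(row, targets)
  if (is.na(G)) {
    abort_validation("selectivity score undefined for this compound (no profiled target); off-targets not reported")
  }
  off <- split_row(row, targets)$off
  keep <- if (G == 0) off > 0 else off >= 0.5 * G
  off <- off[keep]
  ord <- order(-off, names(off))
  off <- off[ord]
  data.frame(kinase = names(off),
             inhibition = unname(off),
             ratio = if (G == 0) rep(NA_real_, length(off)) else unname(off) / G,
             stringsAsFactors = FALSE)
}

#' Rank every compound in a matrix for a target set
#'
#' Scores each compound entry with [selectivity_score()] and sorts by
#' descending selectivity score; ties break by descending on-target score,
#' then alphabetically by compound label. Compounds with no profiled target
#' are appended last, flagged undefined rather than dropped, so the table is
#' exhaustive for the dataset.
#'
#' @param x An `inhib_matrix`.
#' @param targets A [target_set()] or character vector; every target must be a
#'   column of `x`.
#' @param max_targets Cap on the number of targets (default 10).
#' @return Data frame of score records (one row per compound entry) with the
#'   columns of [selectivity_score()] plus `n_significant_offtargets`.
#' @export
rank_compounds <- function(x, targets, max_targets = 10L) {
  targets <- as_target_set(targets, max_targets)
  check_targets_in_matrix(x, targets)
  v <- x$values
  recs <- lapply(seq_len(nrow(v)), function(i) {
    row <- v[i, ]
    attr(row, "compound_id") <- rownames(v)[i]
    rec <- selectivity_score(row, targets)
    rec$n_significant_offtargets <-
      if (rec$defined) nrow(significant_off_targets(row, targets)) else NA_integer_
    rec
  })
  tab <- do.call(rbind, recs)
  def <- tab[tab$defined, , drop = FALSE]
  undef <- tab[!tab$defined, , drop = FALSE]
  def <- def[order(-def$selectivity_score, -def$inhibition_score,
                   def$compound_id), , drop = FALSE]
  undef <- undef[order(undef$compound_id), , drop = FALSE]
  out <- rbind(def, undef)
  rownames(out) <- NULL
  out
}

#' Significant off-targets for several compounds of a matrix
#'
#' Convenience wrapper around [significant_off_targets()] producing one long
#' table suitable for export.
#'
#' @param x An `inhib_matrix`.
#' @param targets Target kinases.
#' @param compound_ids Entries to report; default all entries with a defined
#'   score.
#' @return Data frame with columns `compound_id`, `kinase`,
#'   `percent_inhibition`, `ratio_to_target`.
#' @export
off_target_table <- function(x, targets, compound_ids = NULL) {
  targets <- as_target_set(targets)
  check_targets_in_matrix(x, targets)
  ids <- compound_ids %||% compounds(x)
  unknown <- setdiff(ids, compounds(x))
  if (length(unknown)) {
    abort_validation("unknown compound entries: %s", toString(unknown))
  }
  pieces <- lapply(ids, function(id) {
    row <- x$values[id, ]
    if (all(is.na(row[names(row) %in% as.character(targets)]))) return(NULL)
    ot <- significant_off_targets(row, targets)
    if (!nrow(ot)) return(NULL)
    data.frame(compound_id = id, kinase = ot$kinase,
               percent_inhibition = ot$inhibition,
               ratio_to_target = ot$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(compound_id = character(), kinase = character(),
                      percent_inhibition = numeric(),
                      ratio_to_target = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
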