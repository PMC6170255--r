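# Synthetic screen matrices built from three compound archetypes:
#   clean_selective — strong on-target, baseline off-targets
#   pan_weak        — strong on-target, every off-target weakly inhibited
#   few_strong      — strong on-target, a handful of off-targets at a
#                     magnitude comparable to the target
# plus `random` filler rows. These are the motivating extremes of off-target
# behaviour a selectivity metric must separate; the generator makes them
# testable without any real screen export.

#' Describe an archetype compound for the generator
#'
#' @param label Compound entry label (row name in the generated matrix).
#' @param kind One of `"clean_selective"`, `"pan_weak"`, `"few_strong"`,
#'   `"random"`.
#' @param target_inhibition Percent inhibition of every target kinase
#'   (default 90).
#' @param baseline Baseline off-target inhibition in percent (default 2).
#' @param level Off-target level for `pan_weak` (default 10 percent).
#' @param count Number of strong off-targets for `few_strong`, in \[2, 10\]
#'   (default 5).
#' @param magnitude Strong off-target inhibition for `few_strong`
#'   (default 90).
#' @return A list of class `archetype`.
#' @export
archetype <- function(label,
                      kind = c("clean_selective", "pan_weak", "few_strong",
                               "random"),
                      target_inhibition = 90, baseline = 2,
                      level = 10, count = 5L, magnitude = 90) {
  kind <- match.arg(kind)
  if (kind == "few_strong" && (count < 2L || count > 10L)) {
    abort_validation("few_strong count must lie in [2, 10], got %d", count)
  }
  structure(list(label = as.character(label), kind = kind,
                 target_inhibition = target_inhibition, baseline = baseline,
                 level = level, count = as.integer(count),
                 magnitude = magnitude),
            class = "archetype")
}

#' Specify a synthetic screen matrix
#'
#' @param n_kinases Panel size (total kinase columns, targets included).
#' @param archetypes List of [archetype()] objects, one generated row each.
#'   Default: one of each named archetype.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   percent scale, truncated to \[0, 100\] (default 0).
#' @param missing_rate Fraction of cells masked as unprofiled, in \[0, 1)
#'   (default 0).
#' @param seed Integer seed; identical specs generate identical matrices.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_kinases = 51L,
                           archetypes = list(
                             archetype("clean_selective", "clean_selective"),
                             archetype("pan_weak", "pan_weak"),
                             archetype("few_strong", "few_strong")),
                           noise_sd = 0, missing_rate = 0, seed = 1L) {
  if (n_kinases < 2L) abort_validation("panel needs at least 2 kinases")
  if (noise_sd < 0) abort_validation("noise_sd must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_validation("missing_rate must lie in [0, 1)")
  }
  if (!length(archetypes)) abort_validation("at least one archetype required")
  archetypes <- lapply(archetypes, function(a) {
    if (!inherits(a, "archetype")) abort_validation("archetypes must be archetype() objects")
    a
  })
  labels <- vapply(archetypes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort_validation("duplicate archetype labels: %s",
                     toString(unique(labels[duplicated(labels)])))
  }
  structure(list(n_kinases = as.integer(n_kinases), archetypes = archetypes,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Noiseless row construction shared by the generator and the closed-form
# expectations; off-target positions are deterministic (first `count` off
# columns carry the few_strong magnitude).
noiseless_row <- function(a, target_idx, n_kinases) {
  row <- rep(a$baseline, n_kinases)
  off_idx <- setdiff(seq_len(n_kinases), target_idx)
  switch(a$kind,
    clean_selective = NULL,
    pan_weak = { row[off_idx] <- a$level },
    few_strong = {
      if (a$count > length(off_idx)) {
        abort_validation("few_strong count %d exceeds the %d off-target columns",
                         a$count, length(off_idx))
      }
      row[off_idx[seq_len(a$count)]] <- a$magnitude
    },
    random = { row[] <- NA_real_ }  # filled stochastically later
  )
  row[target_idx] <- a$target_inhibition
  row
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic inhibition matrix
#'
#' Builds one row per archetype in the spec: the noiseless archetype profile,
#' plus truncated-Gaussian noise, plus missing-cell masking. The same spec
#' (including seed) always reproduces the same matrix bit for bit.
#'
#' @param spec A [synthetic_spec()].
#' @param targets Target kinases; must fit inside the generated panel. Panel
#'   columns are the target names followed by `KIN_001`, `KIN_002`, ...
#' @return An [inhib_matrix()].
#' @export
generate_matrix <- function(spec, targets) {
  targets <- as_target_set(targets)
  nt <- length(targets)
  if (nt >= spec$n_kinases) {
    abort_validation("panel of %d kinases cannot hold %d targets plus off-targets",
                     spec$n_kinases, nt)
  }
  panel <- c(as.character(targets),
             sprintf("KIN_%03d", seq_len(spec$n_kinases - nt)))
  target_idx <- seq_len(nt)

  with_seed(spec$seed, {
    rows <- lapply(spec$archetypes, function(a) {
      row <- noiseless_row(a, target_idx, spec$n_kinases)
      if (a$kind == "random") row <- stats::runif(spec$n_kinases, 0, 100)
      row
    })
    v <- do.call(rbind, rows)
    dimnames(v) <- list(vapply(spec$archetypes, `[[`, character(1), "label"),
                        panel)
    if (spec$noise_sd > 0) {
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
      v <- pmin(pmax(v, 0), 100)
    }
    if (spec$missing_rate > 0) {
      v[stats::runif(length(v)) < spec$missing_rate] <- NA_real_
    }
    inhib_matrix(v, dataset = "synthetic",
                 notes = sprintf("generated, seed %d", spec$seed))
  })
}

#' Expected archetype ordering under the selectivity score
#'
#' Evaluates the composite score analytically on the noiseless archetype
#' profiles (no generated matrix involved) and returns the labels in
#' descending score order, with ties broken as [rank_compounds()] breaks them.
#' Serves as a closed-form oracle for ranking tests; only meaningful for
#' noiseless specs.
#'
#' @param spec A [synthetic_spec()] with `noise_sd = 0`.
#' @param targets Target kinases (as for [generate_matrix()]).
#' @return Character vector of archetype labels, best score first, with the
#'   scores as the `scores` attribute.
#' @export
archetype_expectations <- function(spec, targets) {
  if (spec$noise_sd > 0) {
    abort_validation("archetype expectations are exact only for noise_sd = 0")
  }
  targets <- as_target_set(targets)
  nt <- length(targets)
  n <- spec$n_kinases
  M <- n - nt
  scores <- vapply(spec$archetypes, function(a) {
    if (a$kind == "random") {
      abort_validation("random archetypes have no closed-form expectation")
    }
    row <- noiseless_row(a, seq_len(nt), n)
    G <- a$target_inhibition
    off <- row[-seq_len(nt)]
    Pb <- sum(off) / M
    Pn <- sum(ifelse(off == 0, 0, off^2 / (off + G))) / M
    G - Pb - Pn
  }, numeric(1))
  labels <- vapply(spec$archetypes, `[[`, character(1), "label")
  G_all <- vapply(spec$archetypes, `[[`, numeric(1), "target_inhibition")
  ord <- order(-scores, -G_all, labels)
  structure(labels[ord], scores = scores[ord])
}
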