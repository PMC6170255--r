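# Naive, loop-based re-statements of the score formulas and the Gini
# coefficient, kept deliberately independent of the package's vectorized
# implementations so they can serve as oracles.

naive_geom_mean <- function(x) {
  if (any(x == 0)) return(0)
  prod(x)^(1 / length(x))
}

naive_score <- function(row, targets) {
  t_vals <- c(); o_vals <- c()
  for (k in names(row)) {
    if (is.na(row[[k]])) next
    if (k %in% targets) t_vals <- c(t_vals, row[[k]]) else o_vals <- c(o_vals, row[[k]])
  }
  if (length(t_vals) == 0) return(list(G = NA, Pb = NA, Pn = NA, S = NA))
  G <- naive_geom_mean(t_vals)
  Pb <- 0; Pn <- 0
  if (length(o_vals) > 0) {
    for (v in o_vals) {
      Pb <- Pb + v / length(o_vals)
      if (v > 0) Pn <- Pn + (v * v / (v + G)) / length(o_vals)
    }
  }
  list(G = G, Pb = Pb, Pn = Pn, S = G - Pb - Pn)
}

naive_gini <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# Random named profile row with optional missingness; first `n_targets`
# kinases are the targets.
random_row <- function(n_kinases, n_targets = 1, missing_rate = 0) {
  row <- round(runif(n_kinases, 0, 100), 2)
  if (missing_rate > 0) row[runif(n_kinases) < missing_rate] <- NA
  names(row) <- paste0("K", seq_len(n_kinases))
  attr(row, "targets") <- paste0("K", seq_len(n_targets))
  row
}

tiny_matrix <- function() {
  inhib_matrix(matrix(c(90, 5, 10,
                        80, 60, NA,
                        50, 50, 50),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("cmpdA", "cmpdB", "cmpdC"),
                                      c("AKT1", "MAPK1", "CDK2"))))
}

write_tiny_csv <- function(path, delim = ",") {
  lines <- c(paste(c("compound", "AKT1", "MAPK1", "CDK2"), collapse = delim),
             paste(c("cmpdA", "90", "5", "10"), collapse = delim),
             paste(c("cmpdB", "80", "60", ""), collapse = delim),
             paste(c("cmpdC", "50", "50", "50"), collapse = delim))
  writeLines(lines, path)
  path
}
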