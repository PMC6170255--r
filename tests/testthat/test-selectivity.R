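test_that("the on-target score is the inhibition, or a geometric mean", {
  expect_equal(inhibition_score(c(A = 80, B = 10), "A"), 80)
  expect_equal(inhibition_score(c(A = 81, B = 100, C = 5), c("A", "B")), 90)
  # a zero among the targets annihilates the geometric mean
  expect_equal(inhibition_score(c(A = 0, B = 100, C = 5), c("A", "B")), 0)
  # no profiled target -> undefined, not zero
  expect_true(is.na(inhibition_score(c(A = NA, B = 50), "A")))
})

test_that("the broad penalty is the mean measured off-target inhibition", {
  row <- c(T1 = 80, a = 40, b = 20)
  expect_equal(broad_penalty(row, "T1"), 30)
  expect_equal(broad_penalty(c(T1 = 80, a = 0, b = 0, c = 0), "T1"), 0)
  pan <- c(T1 = 80, setNames(rep(10, 60), paste0("k", 1:60)))
  expect_equal(broad_penalty(pan, "T1"), 10)
  # missing off-targets excluded from the mean, not imputed
  expect_equal(broad_penalty(c(T1 = 80, a = 40, b = NA), "T1"), 40)
  expect_warning(p <- broad_penalty(c(T1 = 80, a = NA), "T1"),
                 class = "kinsel_warning")
  expect_equal(p, 0)
})

test_that("the near penalty weighs off-targets by closeness to the target", {
  expect_equal(near_penalty(c(T1 = 80, a = 40, b = 20), "T1", G = 80),
               (40 * 40 / 120 + 20 * 20 / 100) / 2)
  # a single off-target stronger than the target is punished near full size
  expect_equal(near_penalty(c(T1 = 10, a = 90), "T1", G = 10), 81)
  # zero off-targets contribute nothing, even at G = 0
  expect_equal(near_penalty(c(T1 = 0, a = 0, b = 0), "T1", G = 0), 0)
  expect_equal(near_penalty(c(T1 = 0, a = 50), "T1", G = 0), 50)
})

test_that("the composite score assembles S = G - Pb - Pn with coverage counts", {
  rec <- selectivity_score(c(T1 = 80, a = 40, b = 20), "T1")
  expect_equal(rec$inhibition_score, 80)
  expect_equal(rec$penalty_broad, 30)
  expect_equal(rec$penalty_near, 8.6667, tolerance = 1e-4)
  expect_equal(rec$selectivity_score, 41.3333, tolerance = 1e-4)
  expect_equal(rec$n_offtargets_measured, 2)
  expect_true(rec$defined)

  # perfectly selective compound
  perfect <- c(T1 = 100, setNames(rep(0, 30), paste0("k", 1:30)))
  expect_equal(selectivity_score(perfect, "T1")$selectivity_score, 100)

  # pan-weak archetype: penalized mostly by the broad term
  pan <- c(T1 = 80, setNames(rep(10, 100), paste0("k", 1:100)))
  expect_equal(selectivity_score(pan, "T1")$selectivity_score,
               68.8889, tolerance = 1e-4)

  undef <- selectivity_score(c(T1 = NA, a = 50), "T1")
  expect_false(undef$defined)
  expect_true(is.na(undef$selectivity_score))
})

test_that("significant off-targets use the inclusive half-of-target rule", {
  row <- c(T1 = 80, a = 40, b = 39, c = 81)
  ot <- significant_off_targets(row, "T1")
  expect_equal(ot$kinase, c("c", "a"))       # descending inhibition
  expect_equal(ot$inhibition, c(81, 40))     # boundary 40 = G/2 included
  expect_equal(ot$ratio, c(81, 40) / 80)

  expect_equal(nrow(significant_off_targets(c(T1 = 80, a = 39, b = 1), "T1")), 0)

  # G = 0: anything touched at all is reported, ratio undefined
  ot0 <- significant_off_targets(c(T1 = 0, a = 5, b = 0), "T1")
  expect_equal(ot0$kinase, "a")
  expect_true(is.na(ot0$ratio))

  expect_error(significant_off_targets(c(T1 = NA, a = 50), "T1"),
               class = "kinsel_validation_error")
})

test_that("ranking sorts by score with documented tie-breaks and keeps undefined rows", {
  v <- rbind(
    dominant  = c(90, 5, 5, NA),
    dominated = c(90, 50, 50, NA),
    twin_a    = c(70, 10, 10, 10),
    twin_b    = c(70, 10, 10, 10),
    unscored  = c(NA, 60, 60, 60))
  colnames(v) <- c("T1", "k1", "k2", "k3")
  m <- inhib_matrix(v)
  ranked <- rank_compounds(m, "T1")
  expect_equal(ranked$compound_id,
               c("dominant", "twin_a", "twin_b", "dominated", "unscored"))
  expect_false(ranked$defined[5])
  expect_true(is.na(ranked$selectivity_score[5]))
  expect_equal(ranked$n_significant_offtargets[4], 2)

  expect_error(rank_compounds(m, c("T1", "NOT_A_KINASE")), "NOT_A_KINASE",
               class = "kinsel_validation_error")
})

test_that("target sets cap at ten kinases unless the cap is lifted", {
  expect_error(target_set(paste0("K", 1:11)), "10",
               class = "kinsel_validation_error")
  expect_length(target_set(paste0("K", 1:11), max_targets = 11), 11)
  expect_error(target_set(character(0)), class = "kinsel_validation_error")
  expect_error(target_set(c("A", "A")), class = "kinsel_validation_error")
})

test_that("score components match a naive oracle on random small rows", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    nt <- sample(1:min(2, n - 1), 1)
    row <- random_row(n, nt, missing_rate = 0.2)
    targets <- attr(row, "targets")
    exp_rec <- naive_score(row, targets)
    if (is.na(exp_rec$G)) {
      expect_false(selectivity_score(row, targets)$defined)
    } else {
      got <- suppressWarnings(selectivity_score(row, targets))
      expect_equal(got$inhibition_score, exp_rec$G, tolerance = 1e-9)
      expect_equal(got$penalty_broad, exp_rec$Pb, tolerance = 1e-9)
      expect_equal(got$penalty_near, exp_rec$Pn, tolerance = 1e-9)
      expect_equal(got$selectivity_score, exp_rec$S, tolerance = 1e-9)
    }
  }
})

test_that("score is monotone: up in target inhibition, down in off-target inhibition", {
  set.seed(7)
  for (i in 1:50) {
    row <- random_row(12, 1)
    targets <- attr(row, "targets")
    base <- selectivity_score(row, targets)$selectivity_score
    up <- row; up[targets[1]] <- min(100, up[targets[1]] + 5 + runif(1, 0.1, 3))
    if (row[targets[1]] > 0 && up[targets[1]] > row[targets[1]]) {
      expect_gt(selectivity_score(up, targets)$selectivity_score, base)
    }
    off <- setdiff(names(row), targets)
    j <- sample(off, 1)
    worse <- row
    worse[j] <- min(100, worse[j] + 5 + runif(1, 0.1, 3))
    if (worse[j] > row[j]) {
      expect_lt(selectivity_score(worse, targets)$selectivity_score, base)
    }
  }
})

test_that("dominance: better-everywhere compounds never rank worse", {
  set.seed(21)
  for (i in 1:50) {
    rowB <- random_row(15, 1)
    targets <- attr(rowB, "targets")
    rowA <- rowB
    rowA[targets] <- pmin(100, rowB[targets] + runif(1, 0, 10))
    off <- setdiff(names(rowB), targets)
    rowA[off] <- pmax(0, rowB[off] - runif(length(off), 0, 10))
    sA <- selectivity_score(rowA, targets)$selectivity_score
    sB <- selectivity_score(rowB, targets)$selectivity_score
    expect_gte(sA, sB)
  }
})

test_that("the off-target table covers all scored compounds and matches per-row calls", {
  m <- tiny_matrix()
  tab <- off_target_table(m, "AKT1")
  per_row <- significant_off_targets(as.matrix(m)["cmpdC", ], "AKT1")
  expect_equal(tab[tab$compound_id == "cmpdC", "kinase"], per_row$kinase)
  expect_named(tab, c("compound_id", "kinase", "percent_inhibition",
                      "ratio_to_target"))
  expect_error(off_target_table(m, "AKT1", compound_ids = "ghost"),
               class = "kinsel_validation_error")
})
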