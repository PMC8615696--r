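test_that("jaccard obeys the set-algebra identities", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("x", "y")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard(character(0), character(0)), "both sets are empty")
  set.seed(61)
  universe <- letters[1:12]
  for (rep in 1:50) {
    a <- sample(universe, sample(0:12, 1))
    b <- sample(universe, sample(1:12, 1))
    expect_identical(jaccard(a, b), jaccard(b, a))
    # adding a shared member never decreases the score
    extra <- setdiff(universe, union(a, b))
    if (length(extra) > 0) {
      g <- extra[1]
      expect_gte(jaccard(c(a, g), c(b, g)), jaccard(a, b))
    }
  }
})

test_that("a drug's score is the max over its condition signatures", {
  uni <- sprintf("g%02d", 1:30)
  ds <- disease_signature("d", up = uni[1:10], gene_universe = uni)
  mk <- function(id, down) perturbation_signature(id, "drugX", character(0), down, uni)
  sigs <- list(mk("s1", uni[c(1, 20)]),       # J = 1/11
               mk("s2", uni[c(1:4, 25)]),     # J = 4/11
               mk("s3", uni[c(1:2, 21:22)]))  # J = 2/12
  expect_equal(best_score_for_drug(ds, sigs), 4 / 11)
  expect_equal(best_score_for_drug(ds, sigs[1]), 1 / 11)
  expect_error(best_score_for_drug(ds, list()), "no signatures")
  # brute force over a random 20-signature drug
  set.seed(62)
  rs <- lapply(1:20, function(i)
    mk(paste0("r", i), sample(uni, sample(1:15, 1))))
  expect_equal(best_score_for_drug(ds, rs),
               max(sapply(rs, function(s)
                 jaccard_oracle(ds$up, s$down, uni))))
  # an empty down set contributes 0, not an error
  expect_equal(best_score_for_drug(ds, list(mk("s0", character(0)))), 0)
})

test_that("library scoring averages per-disease best scores and ranks with lexicographic ties", {
  uni <- sprintf("g%02d", 1:40)
  d1 <- disease_signature("d1", up = uni[1:10], gene_universe = uni)
  d2 <- disease_signature("d2", up = uni[11:20], gene_universe = uni)
  mk <- function(id, drug, down)
    perturbation_signature(id, drug, character(0), down, uni)
  # drug A: best 1/4 vs d1 (k=2 of 10 -> 2/(10+2-2)... construct exact:
  # down = 5 genes, 2 in d1's up -> J = 2/13; vs d2 0
  lib <- list(mk("a1", "dA", uni[c(1, 2, 30, 31, 32)]),
              mk("a2", "dA", uni[36:38]),
              mk("b1", "dB", uni[c(11, 12, 30, 31, 32)]))
  tab <- score_library(list(d1, d2), lib)
  expect_equal(tab$average_score[tab$drug_id == "dA"],
               (2 / 13 + 0) / 2)
  expect_equal(tab$average_score[tab$drug_id == "dB"],
               (0 + 2 / 13) / 2)
  # tie on average: dA before dB
  expect_identical(tab$drug_id, c("dA", "dB"))
  expect_identical(tab$rank, 1:2)
  # one disease signature: average equals best
  tab1 <- score_library(list(d1), lib)
  expect_equal(tab1$average_score, tab1$score_d1)
  # stated two-score average
  expect_equal(mean(c(0.2, 0.4)), 0.3)
  d_empty <- disease_signature("dx", up = uni[1], gene_universe = uni)
  d_empty$up <- character(0)
  expect_error(score_library(list(d_empty), lib), "up set is empty")
})

test_that("library scoring equals a naive triple-loop oracle", {
  set.seed(63)
  uni <- sprintf("g%02d", 1:25)
  d1 <- disease_signature("d1", sample(uni, 6), gene_universe = uni)
  d2 <- disease_signature("d2", sample(uni, 8), gene_universe = uni)
  drugs <- paste0("drug", 1:12)
  lib <- lapply(1:50, function(i)
    perturbation_signature(sprintf("s%02d", i), sample(drugs, 1), character(0),
              sample(uni, sample(1:12, 1)), uni))
  tab <- score_library(list(d1, d2), lib)
  for (dr in unique(vapply(lib, `[[`, "", "drug_id"))) {
    expected <- mean(sapply(list(d1, d2), function(ds) {
      best <- 0
      for (s in lib)
        if (s$drug_id == dr)
          best <- max(best, jaccard_oracle(ds$up, s$down, uni))
      best
    }))
    expect_identical(tab$average_score[tab$drug_id == dr], expected)
  }
})

test_that("adding a signature never decreases a drug's best score", {
  set.seed(64)
  uni <- sprintf("g%02d", 1:30)
  ds <- disease_signature("d", sample(uni, 8), gene_universe = uni)
  sigs <- lapply(1:5, function(i)
    perturbation_signature(paste0("s", i), "dX", character(0),
              sample(uni, sample(1:10, 1)), uni))
  base <- best_score_for_drug(ds, sigs)
  for (rep in 1:10) {
    extra <- perturbation_signature("sx", "dX", character(0),
                       sample(uni, sample(1:10, 1)), uni)
    expect_gte(best_score_for_drug(ds, c(sigs, list(extra))), base)
  }
})

test_that("gene universes are intersected before scoring", {
  uni_d <- sprintf("g%02d", 1:20)
  uni_s <- sprintf("g%02d", 11:30)  # shares g11..g20 only
  ds <- disease_signature("d", up = sprintf("g%02d", c(5, 12, 13)),
                          gene_universe = uni_d)
  s <- perturbation_signature("s1", "dA", character(0),
                 down = sprintf("g%02d", c(12, 25)), uni_s)
  # restricted: disease up {g12,g13}, drug down {g12} -> J = 1/2
  tab <- score_library(list(ds), list(s))
  expect_equal(tab$average_score, 0.5)
})

test_that("the symmetric flag averages in the mirrored term", {
  uni <- sprintf("g%02d", 1:20)
  ds <- disease_signature("d", up = uni[1:4], down = uni[5:8],
                          gene_universe = uni)
  s <- perturbation_signature("s1", "dA", up = uni[5:8], down = uni[1:4], uni)
  expect_equal(score_library(list(ds), list(s))$average_score, 1)
  expect_equal(score_library(list(ds), list(s),
                             symmetric = TRUE)$average_score, 1)
  s2 <- perturbation_signature("s2", "dB", up = uni[11:14], down = uni[1:4], uni)
  expect_equal(score_library(list(ds), list(s2),
                             symmetric = TRUE)$average_score, 0.5)
})

test_that("top_k slices by rank with deterministic ties", {
  uni <- sprintf("g%02d", 1:20)
  ds <- disease_signature("d", up = uni[1:5], gene_universe = uni)
  lib <- lapply(c("dB", "dA", "dC"), function(dr)
    perturbation_signature(paste0(dr, "_s"), dr, character(0), uni[1:5], uni))
  tab <- score_library(list(ds), lib)
  expect_identical(top_k(tab, 3)$drug_id, c("dA", "dB", "dC"))
  expect_identical(top_k(tab, 1)$drug_id, "dA")
  expect_identical(nrow(top_k(tab, nrow(tab))), nrow(tab))
  expect_error(top_k(tab, 4), "exceeds the number of drugs")
})
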