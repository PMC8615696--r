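test_that("characteristic direction reduces to the mean difference at full shrinkage", {
  # noise-free replicates, mu_ctrl = (0,0,0), mu_trt = (0,0,2)
  m <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 2), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ee <- expression_experiment(m, c("control", "control",
                                   "treatment", "treatment"))
  expect_equal(unname(characteristic_direction(ee, gamma = 1)),
               c(0, 0, 1), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:10) {
    ee <- make_experiment(p = sample(3:40, 1))
    b <- characteristic_direction(ee, gamma = 1)
    is_t <- ee$sample_class == "treatment"
    d <- rowMeans(ee$values[, is_t]) - rowMeans(ee$values[, !is_t])
    d <- d / sqrt(sum(d^2))
    expect_lt(sqrt(sum((b - d)^2)), 1e-8)  # angle < 1e-8 rad
  }
})

test_that("characteristic direction matches direct dense inversion at intermediate shrinkage", {
  set.seed(22)
  for (gamma in c(0.1, 0.5, 0.9)) {
    ee <- make_experiment(p = 2, n_ctl = 4, n_trt = 4)
    b <- characteristic_direction(ee, gamma = gamma)
    # hand 2x2 inverse: (a b; c d)^-1 = (d -b; -c a)/det
    is_t <- ee$sample_class == "treatment"
    X <- ee$values
    d <- unname(rowMeans(X[, is_t]) - rowMeans(X[, !is_t]))
    R <- cbind(X[, !is_t] - rowMeans(X[, !is_t]),
               X[, is_t] - rowMeans(X[, is_t]))
    S <- R %*% t(R) / 6
    M <- (1 - gamma) * S + gamma * (sum(diag(S)) / 2) * diag(2)
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    bo <- c(M[2, 2] * d[1] - M[1, 2] * d[2],
            -M[2, 1] * d[1] + M[1, 1] * d[2]) / det
    if (sum(bo * d) < 0) bo <- -bo
    bo <- bo / sqrt(sum(bo^2))
    expect_equal(unname(b), bo, tolerance = 1e-10)
  }
  # larger p, against the generic dense-solve oracle
  ee <- make_experiment(p = 5, n_ctl = 5, n_trt = 5)
  expect_equal(unname(characteristic_direction(ee, gamma = 0.5)),
               unname(chdir_oracle(ee$values, ee$sample_class, 0.5)),
               tolerance = 1e-10)
})

test_that("characteristic direction is permutation-equivariant and scale-invariant", {
  set.seed(23)
  ee <- make_experiment(p = 30)
  b <- characteristic_direction(ee)
  perm <- sample(30)
  ee_p <- expression_experiment(ee$values[perm, ], ee$sample_class)
  expect_equal(characteristic_direction(ee_p), b[perm], tolerance = 1e-12)
  ee_s <- expression_experiment(ee$values * 7.3, ee$sample_class)
  expect_lt(max(abs(characteristic_direction(ee_s) - b)), 1e-9)
})

test_that("characteristic direction enforces unit norm, orientation and degeneracy errors", {
  set.seed(24)
  for (rep in 1:20) {
    ee <- make_experiment(p = sample(3:100, 1),
                          n_ctl = sample(2:4, 1), n_trt = sample(2:4, 1))
    b <- characteristic_direction(ee, gamma = runif(1, 0.05, 1))
    expect_equal(sum(b^2), 1, tolerance = 1e-9)
    is_t <- ee$sample_class == "treatment"
    d <- rowMeans(ee$values[, is_t, drop = FALSE]) -
      rowMeans(ee$values[, !is_t, drop = FALSE])
    expect_gte(sum(b * d), 0)
  }
  # p >> n demands regularization at gamma = 0
  ee <- make_experiment(p = 50)
  expect_error(characteristic_direction(ee, gamma = 0), "gamma > 0")
  # identical class means
  m <- matrix(rep(c(1, 2, 3), 4), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ee0 <- expression_experiment(m, c("control", "control",
                                    "treatment", "treatment"))
  expect_error(characteristic_direction(ee0), "degenerate signal")
})

test_that("z-test DEG calling follows the two-sided normal rule", {
  set.seed(30)
  b <- c(rnorm(100, sd = 1e-3), big = 10)
  names(b)[1:100] <- paste0("g", 1:100)
  degs <- call_degs(b, alpha = 0.01)
  expect_identical(degs$up, "big")
  expect_length(degs$down, 0)
  # alpha -> 0+ empties both sets
  set.seed(31)
  b2 <- rnorm(100); names(b2) <- paste0("g", 1:100)
  degs2 <- call_degs(b2, alpha = 1e-15)
  expect_length(c(degs2$up, degs2$down), 0)
  # i.i.d. standard normal coefficients: binomial sampling window
  set.seed(32)
  b3 <- rnorm(10000); names(b3) <- paste0("g", 1:10000)
  degs3 <- call_degs(b3, alpha = 0.01)
  n_calls <- length(degs3$up) + length(degs3$down)
  expect_lt(abs(n_calls - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # up/down signs agree with coefficients
  expect_true(all(b3[degs3$up] > 0) && all(b3[degs3$down] < 0))
  expect_error(call_degs(c(a = 1, b = 1, c = 1)), "zero standard deviation")
  expect_error(call_degs(b3, alpha = 0), "alpha")
})

test_that("library building keys experiments to metadata deterministically", {
  set.seed(41)
  meta <- expand.grid(drug_id = c("dA", "dB"), cond = 1:3,
                      stringsAsFactors = FALSE)
  meta$signature_id <- paste0(meta$drug_id, "_", meta$cond)
  meta$cell_line <- "CL1"; meta$dose <- "1uM"; meta$time <- "6h"
  exps <- setNames(lapply(meta$signature_id, function(i)
    make_experiment(p = 20)), meta$signature_id)
  lib <- build_signature_library(exps, meta)
  expect_length(lib, 6)
  expect_identical(names(lib), sort(meta$signature_id))
  expect_setequal(unique(vapply(lib, `[[`, "", "drug_id")), c("dA", "dB"))
  for (s in lib) {
    expect_length(intersect(s$up, s$down), 0)
    if (!is.null(s$coefficients))
      expect_equal(sum(s$coefficients^2), 1, tolerance = 1e-9)
  }
  expect_identical(build_signature_library(list(), meta[0, ]), list())
  expect_error(build_signature_library(exps[-1], meta), "key mismatch")
})

test_that("planted reversers' down-sets overlap the disease up-set in built libraries", {
  cfg <- synthetic_config(n_drugs = 20, conditions_per_drug = 2,
                          n_planted_reversers = 3, planted_moa_size = 6,
                          n_moa_terms = 5, n_bbb_high = 6, seed = 51)
  bundle <- generate_screen_inputs(cfg, mode = "expression")
  lib <- build_signature_library(bundle$library$experiments,
                                 bundle$library$metadata)
  drug_of <- vapply(lib, `[[`, "", "drug_id")
  ds1_up <- bundle$disease$disease_1$up
  for (rev in bundle$truth$reversers) {
    best <- max(vapply(lib[drug_of == rev], function(s)
      length(intersect(s$down, ds1_up)), 0L))
    expect_gt(best, 0)
  }
})

test_that("set-only libraries round-trip through GMT pairs plus metadata", {
  cfg <- small_config(seed = 52)
  dir <- withr::local_tempdir()
  bundle <- write_screen_inputs(cfg, dir, mode = "sets")
  lib <- signatures_from_sets(read_gmt(file.path(dir, "library_up.gmt")),
                              read_gmt(file.path(dir, "library_down.gmt")),
                              read_signature_metadata(
                                file.path(dir, "metadata.tsv")),
                              synthetic_genes(cfg))
  orig <- bundle$library$signatures
  expect_identical(names(lib), names(orig))
  for (id in names(lib)) {
    expect_setequal(lib[[id]]$up, orig[[id]]$up)
    expect_setequal(lib[[id]]$down, orig[[id]]$down)
    expect_identical(lib[[id]]$drug_id, orig[[id]]$drug_id)
  }
})
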