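test_that("coefficient tables round-trip through the reader/writer", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "clocks.csv")
  b <- tiny_beta()
  clocks <- list(
    a = tiny_clock(b, seed = 1, intercept = 0, transform = "identity"),
    b = tiny_clock(b, seed = 2, intercept = -3.2, transform = "horvath_age"),
    c = tiny_clock(b, seed = 3, intercept = 1, transform = "rate"))
  clocks <- lapply(names(clocks), function(nm) { ck <- clocks[[nm]]; ck$name <- nm; ck })
  write_clock_definitions(clocks, path)
  back <- read_clock_definitions(path)
  expect_named(back, c("a", "b", "c"))
  for (i in 1:3) {
    expect_equal(back[[i]]$weights, clocks[[i]]$weights)
    expect_equal(back[[i]]$intercept, clocks[[i]]$intercept)
    expect_identical(back[[i]]$transform, clocks[[i]]$transform)
  }

  # minimal single-probe file
  writeLines(c("clock,probe,weight", "one,cg00000001,1.0",
               "one,__intercept__,0", "one,__transform__,identity"),
             file.path(dir, "one.csv"))
  one <- read_clock_definitions(file.path(dir, "one.csv"))
  expect_length(one$one$weights, 1L)
  expect_equal(unname(one$one$weights), 1)

  # validation: unknown transform and duplicate pair both reject
  writeLines(c("clock,probe,weight", "x,cg1,1", "x,__transform__,bogus"),
             file.path(dir, "bad.csv"))
  expect_error(read_clock_definitions(file.path(dir, "bad.csv")), "unknown transform")
  writeLines(c("clock,probe,weight", "x,cg1,1", "x,cg1,2"),
             file.path(dir, "dup.csv"))
  expect_error(read_clock_definitions(file.path(dir, "dup.csv")), "duplicate")
})

test_that("pc blocks round-trip via companion files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "clocks.csv")
  set.seed(7)
  L <- matrix(rnorm(6), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("PC1", "PC2")))
  ck <- clock_definition("pcclock", weights = c(PC1 = 0.5, PC2 = -0.2),
                         intercept = 10, pc_block = list(
                           loadings = L,
                           centers = c(cg1 = 0.4, cg2 = 0.5, cg3 = 0.6),
                           component_weights = c(PC1 = 0.5, PC2 = -0.2)))
  write_clock_definitions(list(ck), path)
  back <- read_clock_definitions(path)$pcclock
  expect_equal(back$pc_block$loadings, L)
  expect_equal(back$pc_block$centers, ck$pc_block$centers)
  expect_equal(back$pc_block$component_weights, ck$pc_block$component_weights)
})

test_that("linear_predictor matches a term-by-term oracle and handles edge cases", {
  b <- tiny_beta(n_probes = 5, n_samples = 4)
  ck <- tiny_clock(b, intercept = 1.5)

  # brute-force oracle: explicit double loop
  oracle <- sapply(seq_len(ncol(b)), function(s) {
    acc <- ck$intercept
    for (p in rownames(b)) acc <- acc + ck$weights[[p]] * b[p, s]
    acc
  })
  expect_equal(unname(linear_predictor(b, ck)), oracle)

  # constant clock
  zk <- clock_definition("zero", stats::setNames(rep(0, 5), rownames(b)),
                         intercept = 5)
  expect_equal(unname(linear_predictor(b, zk)), rep(5, 4))

  # single-term arithmetic: w=2, b=0.5, intercept 1 -> 2
  one <- beta_matrix(matrix(0.5, 1, 1), "cgX", "S1")
  expect_equal(unname(linear_predictor(one, clock_definition("u", c(cgX = 2), 1))), 2)

  # missing probe errors by name unless truncation allowed
  ck2 <- ck; ck2$weights <- c(ck$weights, cgMISSING = 1)
  expect_error(linear_predictor(b, ck2), "cgMISSING")
  expect_equal(linear_predictor(b, ck2, allow_missing = TRUE),
               linear_predictor(b, ck))
})

test_that("linearity: doubling weights doubles the centered score", {
  b <- tiny_beta(n_probes = 7, seed = 5)
  ck <- tiny_clock(b, seed = 6, intercept = 2)
  ck2 <- ck; ck2$weights <- 2 * ck$weights
  expect_equal(linear_predictor(b, ck2) - ck2$intercept,
               2 * (linear_predictor(b, ck) - ck$intercept))
})

test_that("missing beta values are imputed by probe mean with a message", {
  b <- tiny_beta(n_probes = 3, n_samples = 5)
  ck <- tiny_clock(b, seed = 9)
  b_na <- b; b_na[2, 3] <- NA
  expect_message(out <- linear_predictor(b_na, ck), "imputed 1 missing")
  b_imp <- b; b_imp[2, 3] <- mean(b_na[2, -3])
  expect_equal(out, linear_predictor(b_imp, ck))
})

test_that("age anti-transform is correct, continuous and monotone", {
  expect_equal(horvath_age_inverse(0, 20), 20)
  expect_equal(horvath_age_inverse(1, 20), 41)
  expect_equal(horvath_age_inverse(-0.5, 20), 21 * exp(-0.5) - 1)
  # continuity at the branch point and strict monotonicity
  raw <- seq(-3, 3, length.out = 401)
  ages <- horvath_age_inverse(raw, 20)
  expect_true(all(diff(ages) > 0))
  expect_equal(horvath_age_inverse(-1e-12, 20), horvath_age_inverse(1e-12, 20),
               tolerance = 1e-9)
  expect_true(all(ages > -1))
  expect_error(horvath_age_inverse(0, -1), "adult_age")
})

test_that("evaluate_clock applies transforms and PC projection", {
  b <- tiny_beta(n_probes = 4, n_samples = 6)
  ck <- tiny_clock(b, seed = 11)
  expect_equal(evaluate_clock(b, ck), linear_predictor(b, ck),
               ignore_attr = TRUE)
  expect_false(attr(evaluate_clock(b, ck), "is_rate"))

  hk <- ck; hk$transform <- "horvath_age"
  expect_equal(as.numeric(evaluate_clock(b, hk)),
               horvath_age_inverse(unname(linear_predictor(b, ck)), 20))

  rk <- ck; rk$transform <- "rate"
  expect_true(attr(evaluate_clock(b, rk), "is_rate"))

  # 2-probe, 2-component pc clock vs hand matrix multiplication
  bm <- beta_matrix(matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2),
                    c("cg1", "cg2"), c("A", "B"))
  L <- matrix(c(1, 0.5, -0.5, 1), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("PC1", "PC2")))
  ctr <- c(cg1 = 0.3, cg2 = 0.5)
  cw <- c(PC1 = 2, PC2 = -1)
  pck <- clock_definition("pc", weights = cw, intercept = 4,
                          pc_block = list(loadings = L, centers = ctr,
                                          component_weights = cw))
  hand <- sapply(c("A", "B"), function(s) {
    cb <- bm[, s] - ctr
    scores <- c(PC1 = L["cg1", "PC1"] * cb[["cg1"]] + L["cg2", "PC1"] * cb[["cg2"]],
                PC2 = L["cg1", "PC2"] * cb[["cg1"]] + L["cg2", "PC2"] * cb[["cg2"]])
    4 + sum(cw * scores)
  })
  expect_equal(as.numeric(evaluate_clock(bm, pck)), unname(hand))

  # pc clock with identity loadings and a linear clock's weights reproduces
  # that linear clock on centered data
  w <- c(cg1 = 1.2, cg2 = -0.7)
  I2 <- diag(2); dimnames(I2) <- list(c("cg1", "cg2"), c("cg1", "cg2"))
  pid <- clock_definition("pcid", weights = w, intercept = 0,
                          pc_block = list(loadings = I2,
                                          centers = c(cg1 = 0, cg2 = 0),
                                          component_weights = w))
  lin <- clock_definition("lin", weights = w, intercept = 0)
  expect_equal(as.numeric(evaluate_clock(bm, pid)),
               unname(linear_predictor(bm, lin)))
})

test_that("truncation overlap gates inclusion at r >= 0.9", {
  set.seed(42)
  n <- 20
  ref <- beta_matrix(matrix(runif(6 * n), 6, n),
                     sprintf("cg%d", 1:6), sprintf("R%02d", 1:n))
  # one dominant probe carrying most of the predictor variance
  ck <- clock_definition("dom",
                         weights = c(cg1 = 10, cg2 = 0.1, cg3 = 0.1,
                                     cg4 = 0.1, cg5 = 0.1, cg6 = 0),
                         intercept = 2)

  full <- truncation_overlap(ck, rownames(ref), ref)
  expect_equal(full$overlap_r, 1)
  expect_true(full$included)
  expect_equal(full$signal_loss_pct, 0)

  # removing a zero-weight probe leaves r = 1 exactly
  no6 <- truncation_overlap(ck, setdiff(rownames(ref), "cg6"), ref)
  expect_equal(no6$overlap_r, 1)

  # removing the dominant probe breaks the gate
  no1 <- truncation_overlap(ck, setdiff(rownames(ref), "cg1"), ref)
  expect_lt(no1$overlap_r, 0.9)
  expect_false(no1$included)
  expect_equal(no1$n_missing, 1L)

  # identity between loss and r^2 holds on every report
  rep3 <- rbind(full, no6, no1)
  expect_equal(rep3$signal_loss_pct, (1 - rep3$overlap_r^2) * 100)
  expect_equal(rep3$signal_loss_pct_int, trunc(rep3$signal_loss_pct))

  # zero-variance truncated predictor -> excluded with diagnostic
  none <- truncation_overlap(ck, character(0), ref)
  expect_false(none$included)
  expect_match(none$note, "zero variance")
})

test_that("signal_loss_pct reproduces the ~18% reading of r = 0.901", {
  expect_equal(signal_loss_pct(0.901, integer_truncate = TRUE), 18)
  expect_equal(signal_loss_pct(0.901), (1 - 0.901^2) * 100)
})
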