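# two-stage cell-cycle classifier: shallow network + constrained mixture

# small shared fixture (full 500/class lives in the acceptance suite)
small_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    fixture_env$fx <- balanced_training_fixture(n_per_class = 60, seed = 3)
  }
  fixture_env$fx
}

test_that("network training is deterministic and learns the small fixture", {
  fx <- small_fixture()
  m1 <- train_mitosis_classifier(fx$records, fx$labels, seed = 11,
                                 max_epochs = 400)
  m2 <- train_mitosis_classifier(fx$records, fx$labels, seed = 11,
                                 max_epochs = 400)
  expect_identical(m1$split_idx, m2$split_idx)
  expect_identical(m1$par, m2$par)
  expect_gt(m1$test_accuracy, 0.85)
})

test_that("shuffled labels train to chance accuracy", {
  fx <- small_fixture()
  set.seed(4)
  m <- train_mitosis_classifier(fx$records, sample(fx$labels), seed = 4,
                                max_epochs = 150)
  expect_within(m$test_accuracy, 0.2, 0.12)
})

test_that("training validates classes and split", {
  fx <- small_fixture()
  labs <- fx$labels
  labs[labs == 3] <- 2
  labs[seq_len(nrow(fx$records))[labs == 2][1:(sum(labs == 2) - 4)]] <- 1
  expect_error(train_mitosis_classifier(fx$records, labs, seed = 1),
               "fewer than 10")
  expect_error(train_mitosis_classifier(fx$records, fx$labels,
                                        split = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("classification: probabilities, batching, schema check", {
  fx <- small_fixture()
  m <- train_mitosis_classifier(fx$records, fx$labels, seed = 11,
                                max_epochs = 200)
  out <- classify_mitosis(m, fx$records)
  expect_true(all(abs(rowSums(out$prob) - 1) < 1e-6))
  one <- classify_mitosis(m, fx$records[7, ])
  expect_identical(out$class[7], one$class)
  expect_equal(out$prob[7, ], one$prob[1, ], tolerance = 1e-12)
  # an interphase training nucleus classifies as class 1
  i_int <- which(fx$labels == 1L)[1]
  expect_identical(out$class[i_int], 1L)
  expect_error(classify_mitosis(m, fx$records[, 1:4]), "missing feature columns")
})

# sample from a known constrained 8-Gaussian + uniform model
sample_mog <- function(n, g1 = c(170, 1), g2 = c(300, 2),
                       weights = c(0.30, 0.04, 0.04, 0.04, 0.04, 0.04,
                                   0.25, 0.20), bg = 0.05, seed = 1) {
  set.seed(seed)
  t <- c(seq(0, 1, length.out = 7), 0)
  means <- t(vapply(t, function(tt) (1 - tt) * g1 + tt * g2, numeric(2)))
  sd_a <- 14; sd_i <- 0.05
  comp <- sample.int(9L, n, TRUE, prob = c(weights, bg))
  x <- matrix(NA_real_, n, 2)
  for (j in 1:8) {
    sel <- comp == j
    x[sel, 1] <- rnorm(sum(sel), means[j, 1], sd_a * (1 + 0.3 * t[j]))
    x[sel, 2] <- rnorm(sum(sel), means[j, 2], sd_i * (1 + t[j]))
  }
  sel <- comp == 9L
  x[sel, 1] <- runif(sum(sel), 80, 420)
  x[sel, 2] <- runif(sum(sel), 0.5, 2.8)
  list(records = data.frame(area_um2 = x[, 1], i_dapi = x[, 2]),
       comp = comp, means = means, weights = weights, bg = bg,
       g1 = g1, g2 = g2)
}

test_that("constrained EM recovers a known model (unit-scale run)", {
  gen <- sample_mog(8000, seed = 21)
  fit <- fit_interphase_mog(gen$records, seed = 21)
  expect_within(fit$g1[2], gen$g1[2], 0.02 * gen$g1[2])
  expect_within(fit$g2[2], gen$g2[2], 0.02 * gen$g2[2])
  expect_within(fit$g1[1], gen$g1[1], 0.05 * gen$g1[1])
  expect_within(fit$g2[1], gen$g2[1], 0.05 * gen$g2[1])
  # components 1 and 8 share the G1 mean, so only their weight sum is
  # identifiable; compare it and the interior/G2 weights individually
  expect_within(fit$weights[1] + fit$weights[8],
                gen$weights[1] + gen$weights[8], 0.04)
  expect_true(all(abs(fit$weights[2:7] - gen$weights[2:7]) < 0.04))
  expect_within(fit$background_weight, gen$bg, 0.02)
  # log-likelihood non-decreasing at every EM iteration
  expect_true(all(diff(fit$loglik) >= -1e-7 * abs(fit$loglik[-1])))
  # equal-spacing constraint holds exactly in the returned model
  for (j in 1:7) {
    expected <- (1 - (j - 1) / 6) * fit$g1 + (j - 1) / 6 * fit$g2
    expect_lt(max(abs(fit$means[j, ] - expected)), 1e-9)
  }
  expect_lt(max(abs(fit$means[8, ] - fit$g1)), 1e-9)
})

test_that("EM input validation", {
  rec <- data.frame(area_um2 = rep(100, 3000), i_dapi = rep(1, 3000))
  expect_error(fit_interphase_mog(rec), "degenerate|zero variance")
  set.seed(2)
  uni <- data.frame(area_um2 = rnorm(3000, 170, 15),
                    i_dapi = rnorm(3000, 1, 0.05))
  expect_error(fit_interphase_mog(uni), "undetectable")
  expect_error(fit_interphase_mog(sample_mog(500)$records), "at least")
})

test_that("interphase classification maps components to phases correctly", {
  gen <- sample_mog(8000, seed = 22)
  fit <- fit_interphase_mog(gen$records, seed = 22)
  at_g1 <- data.frame(area_um2 = fit$g1[1], i_dapi = fit$g1[2])
  at_g2 <- data.frame(area_um2 = fit$g2[1], i_dapi = fit$g2[2])
  expect_identical(classify_interphase(fit, at_g1)$phase, "G1")
  expect_identical(classify_interphase(fit, at_g2)$phase, "G2")

  # generator-truth phases: G1 = components 1/8, S = 2..6, G2 = 7
  truth <- c("G1", "S", "S", "S", "S", "S", "G2", "G1", NA)[gen$comp]
  pred <- classify_interphase(fit, gen$records)$phase
  ok <- !is.na(truth) & !is.na(pred)
  expect_gt(mean(pred[ok] == truth[ok]), 0.90)
})

test_that("interphase population with continuous S-phase DNA classifies >= 90%", {
  set.seed(31)
  n <- 6000
  phase <- sample(c("G1", "S", "G2"), n, TRUE, c(0.5, 0.15, 0.35))
  dna <- ifelse(phase == "G1", rnorm(n, 1, 0.05),
                ifelse(phase == "G2", rnorm(n, 2, 0.1), runif(n, 1.12, 1.88)))
  area <- 170 + (dna - 1) * 110 + rnorm(n, 0, 15)
  rec <- data.frame(area_um2 = area, i_dapi = dna)
  fit <- fit_interphase_mog(rec, seed = 31)
  pred <- classify_interphase(fit, rec)$phase
  ok <- !is.na(pred)
  expect_gt(mean(pred[ok] == phase[ok], na.rm = TRUE), 0.90)
})

test_that("models survive a JSON round trip", {
  d <- withr::local_tempdir()
  fx <- small_fixture()
  m <- train_mitosis_classifier(fx$records, fx$labels, seed = 11,
                                max_epochs = 100)
  f <- file.path(d, "nn.json")
  save_model(m, f)
  m2 <- load_model(f)
  p1 <- classify_mitosis(m, fx$records[1:20, ])
  p2 <- classify_mitosis(m2, fx$records[1:20, ])
  expect_equal(p1$prob, p2$prob, tolerance = 1e-9)

  gen <- sample_mog(8000, seed = 23)
  g <- fit_interphase_mog(gen$records, seed = 23)
  fg <- file.path(d, "mog.json")
  save_model(g, fg)
  g2 <- load_model(fg)
  expect_equal(classify_interphase(g, gen$records[1:50, ])$posterior,
               classify_interphase(g2, gen$records[1:50, ])$posterior,
               tolerance = 1e-9)
})
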