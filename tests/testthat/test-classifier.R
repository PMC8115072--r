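# Amplitude-topography direction classifier.

# Minimal analytic_band stand-in with prescribed amplitude features.
fake_band <- function(amp, geometry = std_grid()) {
  structure(list(center_freq = 6, bandwidth = 3,
                 amplitude = amp, amplitude_raw = abs(amp), phase = amp * 0,
                 fs_analysis = 30,
                 times = seq(0, by = 1 / 30, length.out = ncol(amp)),
                 valid_mask = rep(TRUE, ncol(amp)),
                 channels = seq_len(nrow(amp)), geometry = geometry),
            class = "analytic_band")
}

fake_split <- function(idx1, idx2, modes = c(30, 210)) {
  list(idx1 = idx1, idx2 = idx2,
       labels = factor(rep(c("mode1", "mode2"), c(length(idx1), length(idx2))),
                       levels = c("mode1", "mode2")),
       modes = modes)
}

test_that("build_dataset balances classes and propagates channel masks", {
  set.seed(91)
  amp <- matrix(rnorm(32 * 1000), 32, 1000)
  ds <- build_dataset(fake_band(amp), fake_split(1:600, 601:1000), seed = 1)
  expect_equal(unname(ds$counts), c(400, 400))
  expect_equal(nrow(ds$features), 800)
  expect_equal(ncol(ds$features), 32)
  expect_error(build_dataset(fake_band(amp), fake_split(1:600, 601:640)),
               "fewer than 50")
  # bad channels reduce the feature dimension
  amp30 <- amp[1:30, ]
  b <- fake_band(amp30); b$channels <- setdiff(1:32, c(3, 7))
  ds30 <- build_dataset(b, fake_split(1:600, 601:1000), seed = 1)
  expect_equal(ncol(ds30$features), 30)
})

test_that("separable topographies reach high accuracy; chance sits near 50%", {
  set.seed(92)
  n <- 300
  amp <- matrix(rnorm(32 * 2 * n, sd = 0.5), 32, 2 * n)
  shift <- rep(c(1, -1), each = 16)           # opposite half-grid loading
  amp[, 1:n] <- amp[, 1:n] + shift
  amp[, (n + 1):(2 * n)] <- amp[, (n + 1):(2 * n)] - shift
  ds <- build_dataset(fake_band(amp), fake_split(1:n, (n + 1):(2 * n)),
                      seed = 2)
  acc <- train_evaluate(ds, seed = 3)
  expect_gte(acc, 95)
  # labels independent of features: accuracy near chance
  amp0 <- matrix(rnorm(32 * 2 * n), 32, 2 * n)
  ds0 <- build_dataset(fake_band(amp0), fake_split(1:n, (n + 1):(2 * n)),
                       seed = 2)
  acc0 <- train_evaluate(ds0, seed = 3)
  expect_lt(abs(acc0 - 50), 10)
  # deterministic under a fixed seed
  expect_identical(train_evaluate(ds, seed = 3), train_evaluate(ds, seed = 3))
})

test_that("accuracy is invariant to consistent channel reordering", {
  set.seed(93)
  n <- 150
  amp <- matrix(rnorm(32 * 2 * n, sd = 1), 32, 2 * n)
  amp[1:8, 1:n] <- amp[1:8, 1:n] + 0.8
  ds <- build_dataset(fake_band(amp), fake_split(1:n, (n + 1):(2 * n)),
                      seed = 4)
  perm <- sample(32)
  ds2 <- ds; ds2$features <- ds$features[, perm]
  expect_equal(train_evaluate(ds, seed = 5), train_evaluate(ds2, seed = 5))
})

test_that("label-shuffle null is centred on 50% and flags coupled topographies", {
  set.seed(94)
  n <- 120
  amp <- matrix(rnorm(32 * 2 * n, sd = 0.7), 32, 2 * n)
  shift <- rep(c(0.6, -0.6), each = 16)
  amp[, 1:n] <- amp[, 1:n] + shift
  amp[, (n + 1):(2 * n)] <- amp[, (n + 1):(2 * n)] - shift
  ds <- build_dataset(fake_band(amp), fake_split(1:n, (n + 1):(2 * n)),
                      seed = 6)
  res <- shuffle_null(ds, n_iter = 120, seed = 7)
  expect_lt(abs(res$null_mean - 50), 2.5)
  expect_lt(abs(res$null_p50 - 50), 3)
  expect_gt(res$accuracy, res$null_p99)
  expect_true(res$significant)
  expect_error(shuffle_null(ds, n_iter = 50), ">= 100")
})

test_that("uncoupled topographies are significant at roughly the nominal rate", {
  set.seed(95)
  n <- 60
  hits <- vapply(1:15, function(i) {
    amp <- matrix(rnorm(16 * 2 * n), 16, 2 * n)
    ds <- build_dataset(fake_band(amp, make_grid(4, 4, 2)),
                        fake_split(1:n, (n + 1):(2 * n)), seed = i,
                        min_per_class = 50)
    shuffle_null(ds, n_iter = 100, seed = 100 + i)$significant
  }, logical(1))
  # nominal 1%: seeing 3+ of 15 significant would be surprising
  expect_lte(sum(hits), 2)
})

test_that("direction ratio and amplitude gradients summarize across frequencies", {
  set.seed(96)
  g <- std_grid()
  mk_entry <- function(freq, grad = 0, n1 = 200, n2 = 200) {
    amp <- matrix(rnorm(32 * (n1 + n2), sd = 0.5), 32, n1 + n2)
    if (grad != 0) {
      load <- (g$coords[, 1] - mean(g$coords[, 1])) / 14 * 2 * grad
      amp[, 1:n1] <- amp[, 1:n1] + load
    }
    list(freq = freq, band = fake_band(amp),
         split = fake_split(1:n1, (n1 + 1):(n1 + n2), modes = c(10, 190)))
  }
  expect_error(direction_ratio_and_gradient(list(mk_entry(2), mk_entry(5))),
               ">= 3")
  # class sizes vary but independently of frequency, gain maps identical:
  # both tests null
  freqs <- c(1.6, 3, 5.2, 8, 13.8)
  n1s <- c(210, 180, 220, 190, 200)
  ents <- Map(function(f, n1) mk_entry(f, n1 = n1), freqs, n1s)
  out <- direction_ratio_and_gradient(ents)
  expect_gt(out$spearman$p, 0.05)
  expect_gt(out$paired_t$p, 0.05)
  expect_equal(out$table$ratio_anterior, n1s / (n1s + 200))
  # anterior-loaded gain for one condition only: paired t detects it
  ents2 <- lapply(c(1.6, 3, 5.2, 8, 13.8), mk_entry, grad = 0.5)
  out2 <- direction_ratio_and_gradient(ents2)
  expect_lt(out2$paired_t$p, 0.01)
  expect_true(all(out2$table$grad_anterior > out2$table$grad_posterior))
})
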