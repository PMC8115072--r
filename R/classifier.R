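# Does amplitude topography over the grid predict which way the wave is
# traveling? Balanced two-class dataset from the angle split, 5-fold
# cross-validated linear SVM, and label-shuffle significance.

#' Build a balanced classifier dataset from an angle split
#'
#' Uses the per-electrode z-scored analytic amplitudes at the split
#' timepoints as features (up to one feature per usable electrode) and the
#' direction condition as the binary label. The majority class is randomly
#' subsampled once to the minority size.
#'
#' @param band an \code{analytic_band} (amplitudes are its z-scored
#'   channel x timepoint matrix).
#' @param split output of \code{\link{angle_split}} on the matching
#'   \code{wave_fit_series}.
#' @param seed seed for the balancing draw.
#' @param min_per_class refuse classes smaller than this (default 50).
#' @return a \code{classifier_dataset}: list with \code{features}
#'   (timepoints x electrodes), \code{labels} (factor mode1/mode2),
#'   \code{counts}, \code{channels}.
#' @export
build_dataset <- function(band, split, seed = 1, min_per_class = 50) {
  stopifnot(inherits(band, "analytic_band"))
  n1 <- length(split$idx1); n2 <- length(split$idx2)
  if (min(n1, n2) < min_per_class)
    stop("build_dataset: a class has fewer than ", min_per_class,
         " timepoints (", n1, "/", n2, ")")
  m <- min(n1, n2)
  with_seed(seed, {
    i1 <- if (n1 > m) sort(sample(split$idx1, m)) else split$idx1
    i2 <- if (n2 > m) sort(sample(split$idx2, m)) else split$idx2
    feats <- t(band$amplitude[, c(i1, i2), drop = FALSE])
    colnames(feats) <- paste0("ch", band$channels)
    structure(list(features = feats,
                   labels = factor(rep(c("mode1", "mode2"), each = m)),
                   counts = c(mode1 = m, mode2 = m),
                   channels = band$channels),
              class = "classifier_dataset")
  })
}

#' Cross-validated SVM accuracy
#'
#' Linear-kernel support vector machine with feature standardization,
#' evaluated by k-fold cross-validation (80% train / 20% test per fold at
#' the default k = 5); the returned accuracy is the mean held-out
#' percentage of correctly predicted direction labels. No hyperparameter
#' optimization is performed.
#'
#' @param ds a \code{classifier_dataset} (balanced).
#' @param k_folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param labels optional label vector overriding \code{ds$labels} (used by
#'   the shuffle null).
#' @return mean held-out accuracy in percent.
#' @export
train_evaluate <- function(ds, k_folds = 5, seed = 1, labels = NULL) {
  stopifnot(inherits(ds, "classifier_dataset"))
  y <- labels %||% ds$labels
  n <- nrow(ds$features)
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k_folds), n))
    acc <- vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      fit <- e1071::svm(ds$features[tr, , drop = FALSE], y[tr],
                        kernel = "linear", scale = TRUE)
      mean(stats::predict(fit, ds$features[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    100 * mean(acc)
  })
}

#' Label-shuffle null for the direction classifier
#'
#' Repeats the full cross-validated training with randomly permuted labels
#' to build a chance distribution of accuracies; the observed accuracy is
#' significant when it exceeds the 99th percentile of the null.
#'
#' @param ds a \code{classifier_dataset}.
#' @param k_folds folds for each evaluation (default 5).
#' @param n_iter null iterations (default 10000; >= 100 required.
#'   Calibration studies may scale this down).
#' @param seed master seed (fold draws and label permutations derive from
#'   it).
#' @return a \code{classifier_result}: list with \code{accuracy} (observed,
#'   %), \code{null_mean}, \code{null_p50}, \code{null_p99},
#'   \code{n_iter_null}, \code{significant}, and \code{null_acc} (all null
#'   accuracies).
#' @export
shuffle_null <- function(ds, k_folds = 5, n_iter = 10000, seed = 1) {
  if (n_iter < 100) stop("shuffle_null: n_iter must be >= 100")
  obs <- train_evaluate(ds, k_folds = k_folds, seed = seed)
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      perm <- sample(ds$labels)
      train_evaluate(ds, k_folds = k_folds,
                     seed = sample.int(.Machine$integer.max, 1),
                     labels = perm)
    }, numeric(1))
  })
  p50 <- unname(stats::quantile(null_acc, 0.50))
  p99 <- unname(stats::quantile(null_acc, 0.99))
  structure(list(accuracy = obs, null_mean = mean(null_acc),
                 null_p50 = p50, null_p99 = p99,
                 n_iter_null = n_iter, significant = obs > p99,
                 null_acc = null_acc),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "<classifier_result> accuracy %.1f%% | null: mean %.1f%%, p50 %.1f%%, p99 %.1f%% (%d iter) -> %s\n",
    x$accuracy, x$null_mean, x$null_p50, x$null_p99, x$n_iter_null,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# Mean z-scored amplitude difference, anterior half minus posterior half of
# the grid (halves by electrode x-coordinate), over the given timepoints.
ap_amplitude_gradient <- function(band, idx) {
  x <- band$geometry$coords[band$channels, 1]
  ord <- order(x)
  half <- floor(length(ord) / 2)
  post <- ord[seq_len(half)]
  ant <- ord[(length(ord) - half + 1):length(ord)]
  amp <- band$amplitude[, idx, drop = FALSE]
  mean(amp[ant, ]) - mean(amp[post, ])
}

#' Direction ratio and amplitude-gradient summary across frequencies
#'
#' For each bidirectional frequency, computes the proportion of split
#' timepoints traveling toward the anterior (temporal) pole, and the
#' anterior-minus-posterior mean amplitude for each direction condition.
#' Reports a Spearman correlation of frequency against the anterior ratio
#' and a paired t-test of the amplitude gradients between the two
#' conditions.
#'
#' @param entries list; each element a list with \code{freq} (Hz),
#'   \code{band} (\code{analytic_band}), and \code{split}
#'   (\code{\link{angle_split}} output). At least 3 entries for the
#'   correlation.
#' @return list with \code{table} (per-frequency summary),
#'   \code{spearman} (rho, p), \code{paired_t} (statistic, p).
#' @export
direction_ratio_and_gradient <- function(entries) {
  if (length(entries) < 3)
    stop("direction_ratio_and_gradient: need >= 3 frequencies")
  tab <- do.call(rbind, lapply(entries, function(e) {
    # anterior-directed condition: mode with positive x-component
    ant_first <- cos(deg2rad(e$split$modes[1])) >= cos(deg2rad(e$split$modes[2]))
    ia <- if (ant_first) e$split$idx1 else e$split$idx2
    ip <- if (ant_first) e$split$idx2 else e$split$idx1
    data.frame(freq = e$freq,
               ratio_anterior = length(ia) / (length(ia) + length(ip)),
               grad_anterior = ap_amplitude_gradient(e$band, ia),
               grad_posterior = ap_amplitude_gradient(e$band, ip))
  }))
  sp <- suppressWarnings(
    stats::cor.test(tab$freq, tab$ratio_anterior, method = "spearman"))
  tt <- stats::t.test(tab$grad_anterior, tab$grad_posterior, paired = TRUE)
  list(table = tab,
       spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       paired_t = list(statistic = unname(tt$statistic), p = tt$p.value))
}
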