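# Cross-validated experimental protocol: filter bank -> OVR-FBCSP ->
# feature extraction -> linear SVM, with 5-fold stratified selection of
# (m, d_op) on the training set and single-shot test-set evaluation.
#
# The filter bank is stateless (each trial is filtered independently), so it
# may be applied once to the whole session; CSP and the embeddings are
# refitted inside every training fold so validation trials never enter any
# fit.

pipeline_methods <- function() c("none", "lda", "2dlda", "dlpp", "2ddlpp", "b2ddlpp")

#' Experiment configuration
#'
#' @param method feature extractor: `"none"` (FBCSP features straight to the
#'   classifier), `"lda"`, `"2dlda"`, `"dlpp"`, `"2ddlpp"` or `"b2ddlpp"`.
#' @param m_grid CSP pair counts to scan, a subset of 1..4.
#' @param d_grid output dimensionalities to scan, or `"auto"`: all of
#'   `1..N_f` for the one-sided matrix methods, a geometric grid over
#'   `1..N_f*N_g` capped at 40 points for vector and bilinear methods.
#' @param n_folds stratified folds (default 5).
#' @param t heat-kernel bandwidth (default 1).
#' @param svm_cost linear-SVM regularization constant (default 1).
#' @param seed RNG seed controlling fold assignment.
#' @param time_window_s optional `c(start, end)` seconds relative to trial
#'   onset to crop before filtering.
#' @param target_fs optional rate (Hz) to decimate to before filtering
#'   (anti-aliased), e.g. 250 for high-rate recordings.
#' @param filter_order,attenuation_db,zero_phase filter-bank settings passed
#'   through to [design_filter_bank()] / [apply_filter_bank()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(method = "b2ddlpp", m_grid = 1:4,
                              d_grid = "auto", n_folds = 5, t = 1,
                              svm_cost = 1, seed = 1L,
                              time_window_s = NULL, target_fs = NULL,
                              filter_order = 6, attenuation_db = 40,
                              zero_phase = TRUE) {
  method <- match.arg(method, pipeline_methods())
  stopifnot(n_folds >= 2, all(m_grid >= 1), t > 0, svm_cost > 0)
  structure(
    list(method = method, m_grid = sort(unique(as.integer(m_grid))),
         d_grid = d_grid, n_folds = as.integer(n_folds), t = t,
         svm_cost = svm_cost, seed = as.integer(seed),
         time_window_s = time_window_s, target_fs = target_fs,
         filter_order = filter_order, attenuation_db = attenuation_db,
         zero_phase = zero_phase),
    class = "experiment_config")
}

#' Crop epochs to a time window
#' @param epochs an `epoched_eeg`.
#' @param window `c(start, end)` in seconds relative to trial onset.
#' @export
crop_epochs <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoched_eeg"), length(window) == 2,
            window[1] >= 0, window[2] > window[1])
  i0 <- max(1L, round(window[1] * epochs$fs) + 1L)
  i1 <- min(dim(epochs$data)[3], round(window[2] * epochs$fs))
  if (i1 <= i0) stop("time window is empty for this trial length", call. = FALSE)
  validate_epochs(epochs$data[, , i0:i1, drop = FALSE],
                  epochs$label_map[epochs$labels], epochs$fs,
                  epochs$channel_names)
}

#' Decimate epochs to a lower sampling rate
#'
#' Integer-factor decimation with anti-alias filtering
#' (via [signal::decimate()]), e.g. 1000 Hz recordings down to 250 Hz.
#' @param epochs an `epoched_eeg`.
#' @param target_fs target rate; `fs / target_fs` must be a whole number.
#' @export
downsample_epochs <- function(epochs, target_fs) {
  stopifnot(inherits(epochs, "epoched_eeg"), target_fs > 0)
  q <- epochs$fs / target_fs
  if (abs(q - round(q)) > 1e-8)
    stop("fs must be an integer multiple of target_fs", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  d <- dim(epochs$data)
  n_out <- length(signal::decimate(epochs$data[1, 1, ], q))
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2]))
    out[tr, ch, ] <- signal::decimate(epochs$data[tr, ch, ], q)
  validate_epochs(out, epochs$label_map[epochs$labels], target_fs,
                  epochs$channel_names)
}

preprocess_epochs <- function(epochs, config) {
  if (!is.null(config$time_window_s))
    epochs <- crop_epochs(epochs, config$time_window_s)
  if (!is.null(config$target_fs))
    epochs <- downsample_epochs(epochs, config$target_fs)
  epochs
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, keeping class proportions within one trial of each other.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    if (length(idx) < k)
      stop(sprintf("class %d has %d trials < %d folds; use fewer folds",
                   s, length(idx), k), call. = FALSE)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

subset_banded <- function(banded, idx) {
  labels <- banded$labels[idx]
  structure(
    list(data = banded$data[, idx, , , drop = FALSE], fs = banded$fs,
         labels = labels, bands = banded$bands,
         Z = banded$Z, n_s = tabulate(labels, nbins = banded$Z)),
    class = "band_filtered")
}

resolve_d_grid <- function(config, nf, ng) {
  if (config$method == "none") return(NA_integer_)
  if (!identical(config$d_grid, "auto")) {
    dmax <- if (config$method %in% c("2dlda", "2ddlpp")) nf else nf * ng
    g <- sort(unique(as.integer(config$d_grid)))
    g <- g[g >= 1 & g <= dmax]
    if (length(g) == 0) stop("d_grid has no valid entries for this shape", call. = FALSE)
    return(g)
  }
  if (config$method %in% c("2dlda", "2ddlpp")) return(seq_len(nf))
  p <- nf * ng
  sort(unique(round(exp(seq(log(1), log(p), length.out = min(40, p))))))
}

# Fit the configured extractor once at the largest d of the grid; the
# feature sets at smaller d are nested truncations.
fit_extractor <- function(method, set, d_max, t) {
  switch(method,
         none = NULL,
         lda = fit_lda(set, d_max),
         `2dlda` = fit_2dlda(set, d_max),
         dlpp = fit_dlpp(set, d_max, t),
         `2ddlpp` = fit_2ddlpp(set, d_max, t),
         b2ddlpp = fit_b2ddlpp(set, t))
}

extract_features <- function(method, extractor, set, d) {
  switch(method,
         none = do.call(rbind, lapply(set$matrices, vec)),
         b2ddlpp = transform_b2ddlpp(extractor, set, d),
         embed_features(extractor, set, d))
}

svm_accuracy <- function(Xtr, ytr, Xval, yval, cost) {
  lev <- sort(unique(c(ytr, yval)))
  fit <- e1071::svm(Xtr, factor(ytr, levels = lev), kernel = "linear",
                    cost = cost, scale = FALSE)
  pred <- stats::predict(fit, Xval)
  100 * mean(pred == factor(yval, levels = lev))
}

#' Cross-validated (m, d) selection
#'
#' For every `m` in `m_grid`, OVR-FBCSP is fitted inside each training fold
#' and the configured extractor scanned over the `d` grid; fold-validation
#' accuracy is averaged per `(m, d)` cell. The best cell maximizes mean
#' accuracy, with ties broken toward smaller `d`, then smaller `m`. The
#' report records the fold assignment and a leakage check (the number of
#' trials appearing in both a fold's training and validation split, always
#' expected to be 0).
#'
#' @param train an `epoched_eeg` training session.
#' @param config an [experiment_config()].
#' @return A `cv_report` with `grid` (`m`, `d`, `mean_accuracy`),
#'   `per_fold` accuracies, `best` (`m`, `d_op`, `cv_accuracy`), `folds`,
#'   `contamination`, `method`.
#' @export
run_cv <- function(train, config) {
  stopifnot(inherits(train, "epoched_eeg"), inherits(config, "experiment_config"))
  set.seed(config$seed)
  ep <- preprocess_epochs(train, config)
  fb <- design_filter_bank(ep$fs, order = config$filter_order,
                           attenuation_db = config$attenuation_db)
  banded <- apply_filter_bank(ep, fb, zero_phase = config$zero_phase)
  fold <- stratified_folds(ep$labels, config$n_folds)
  rows <- list()
  per_fold <- list()
  contamination <- 0L
  for (m in config$m_grid) {
    ng <- 2L * m * ep$Z
    d_grid <- resolve_d_grid(config, length(fb$bands), ng)
    acc <- matrix(NA_real_, config$n_folds, length(d_grid))
    for (f in seq_len(config$n_folds)) {
      tr_idx <- which(fold != f)
      val_idx <- which(fold == f)
      contamination <- contamination + length(intersect(tr_idx, val_idx))
      btr <- subset_banded(banded, tr_idx)
      bval <- subset_banded(banded, val_idx)
      csp <- fit_ovr_fbcsp(btr, m)
      set_tr <- transform_ovr_fbcsp(csp, btr)
      set_val <- transform_ovr_fbcsp(csp, bval)
      ext <- if (config$method == "none") NULL else
        fit_extractor(config$method, set_tr, max(d_grid), config$t)
      for (di in seq_along(d_grid)) {
        Xtr <- extract_features(config$method, ext, set_tr, d_grid[di])
        Xval <- extract_features(config$method, ext, set_val, d_grid[di])
        acc[f, di] <- svm_accuracy(Xtr, set_tr$labels, Xval, set_val$labels,
                                   config$svm_cost)
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(m = m, d = d_grid, mean_accuracy = colMeans(acc))
    per_fold[[as.character(m)]] <- acc
  }
  grid <- do.call(rbind, rows)
  best_i <- order(-grid$mean_accuracy, grid$d, grid$m)[1]
  structure(
    list(grid = grid,
         per_fold = per_fold,
         best = list(m = grid$m[best_i], d_op = grid$d[best_i],
                     cv_accuracy = grid$mean_accuracy[best_i]),
         folds = fold, contamination = contamination,
         method = config$method, config = config),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report [%s]: best mean accuracy %.2f%% at m = %d, d_op = %s\n",
              x$method, x$best$cv_accuracy, x$best$m,
              ifelse(is.na(x$best$d_op), "-", x$best$d_op)))
  invisible(x)
}

#' Evaluate on a held-out test session at fixed (m, d_op)
#'
#' Refits the complete pipeline (CSP and extractor) on the full training
#' session at the supplied `m` and `d_op` — typically the pair selected by
#' [run_cv()] — and reports classification accuracy on the test session.
#'
#' @param train,test `epoched_eeg` sessions with matching montages.
#' @param config an [experiment_config()].
#' @param m CSP pair count to use.
#' @param d_op feature dimensionality to use (ignored for `method = "none"`;
#'   required otherwise).
#' @return accuracy in percent.
#' @export
evaluate_test <- function(train, test, config, m, d_op = NULL) {
  stopifnot(inherits(train, "epoched_eeg"), inherits(test, "epoched_eeg"))
  if (dim(train$data)[2] != dim(test$data)[2])
    stop("train and test montages differ", call. = FALSE)
  if (config$method != "none" && (is.null(d_op) || is.na(d_op)))
    stop("d_op is required for this method; take it from run_cv()$best",
         call. = FALSE)
  set.seed(config$seed)
  eptr <- preprocess_epochs(train, config)
  epte <- preprocess_epochs(test, config)
  fb <- design_filter_bank(eptr$fs, order = config$filter_order,
                           attenuation_db = config$attenuation_db)
  btr <- apply_filter_bank(eptr, fb, zero_phase = config$zero_phase)
  bte <- apply_filter_bank(epte, fb, zero_phase = config$zero_phase)
  csp <- fit_ovr_fbcsp(btr, m)
  set_tr <- transform_ovr_fbcsp(csp, btr)
  set_te <- transform_ovr_fbcsp(csp, bte)
  d_use <- if (config$method == "none") NA_integer_ else as.integer(d_op)
  ext <- fit_extractor(config$method, set_tr, d_use, config$t)
  Xtr <- extract_features(config$method, ext, set_tr, d_use)
  Xte <- extract_features(config$method, ext, set_te, d_use)
  svm_accuracy(Xtr, set_tr$labels, Xte, set_te$labels, config$svm_cost)
}

#' Compare all extraction methods on one train/test split
#'
#' Runs [run_cv()] per method, then [evaluate_test()] at each method's
#' selected `(m, d_op)`.
#'
#' @param train,test `epoched_eeg` sessions.
#' @param config base [experiment_config()]; its `method` field is replaced
#'   per row.
#' @param methods methods to compare (default all six).
#' @return data.frame with one row per method: `method`, `cv_accuracy`, `m`,
#'   `d_op`, `test_accuracy`.
#' @export
compare_methods <- function(train, test, config = experiment_config(),
                            methods = pipeline_methods()) {
  rows <- lapply(methods, function(mth) {
    cfg <- config
    cfg$method <- mth
    rep <- run_cv(train, cfg)
    test_acc <- evaluate_test(train, test, cfg, rep$best$m, rep$best$d_op)
    data.frame(method = mth, cv_accuracy = rep$best$cv_accuracy,
               m = rep$best$m, d_op = rep$best$d_op,
               test_accuracy = test_acc)
  })
  do.call(rbind, rows)
}
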