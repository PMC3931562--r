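#' Build balanced, length-binned training and test sets
#'
#' From a labelled corpus, samples per length bin and class: `sizes[i]`
#' sequences into the training set and an equal, disjoint number into the
#' test set, so every class contributes the same number of sequences to
#' each bin. Whatever is left over per class is routed to the custom
#' database pool, whose best-hit feature the classifier consumes.
#'
#' @param truth Data.frame with columns `id`, `class`
#'   (one of [TAXON_GROUPS]) and `length` (bp).
#' @param bins Length-bin table (default [length_bins()]).
#' @param sizes Per-bin training-set size per class; default
#'   `c(1076, 2000, 2000)` for the 150-300, 300-500 and >500 bp bins.
#' @param seed Integer seed; the same seed always reproduces the same
#'   split.
#' @return List of data.frames `train`, `test`, `customdb`, each with
#'   columns `id`, `class`, `length`, `bin`.
#' @export
build_training_sets <- function(truth, bins = length_bins(),
                                sizes = c(1076, 2000, 2000), seed = 1) {
  stopifnot(all(c("id", "class", "length") %in% names(truth)),
            length(sizes) == nrow(bins))
  bad <- setdiff(unique(truth$class), TAXON_GROUPS)
  if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
  truth$bin <- bin_of(truth$length, bins)
  pool <- truth[!is.na(truth$bin), , drop = FALSE]

  set.seed(seed)
  train <- test <- list()
  for (i in seq_len(nrow(bins))) {
    for (cl in TAXON_GROUPS) {
      avail <- pool[pool$bin == bins$label[i] & pool$class == cl, , drop = FALSE]
      need <- 2L * sizes[i]
      if (nrow(avail) < need)
        stop(sprintf(
          "insufficient sequences for class '%s' in bin %s: have %d, need %d",
          cl, bins$label[i], nrow(avail), need))
      pick <- avail[sample.int(nrow(avail), need), , drop = FALSE]
      train[[paste(i, cl)]] <- pick[seq_len(sizes[i]), , drop = FALSE]
      test[[paste(i, cl)]] <- pick[sizes[i] + seq_len(sizes[i]), , drop = FALSE]
    }
  }
  train <- do.call(rbind, train)
  test <- do.call(rbind, test)
  used <- c(train$id, test$id)
  customdb <- truth[!truth$id %in% used, , drop = FALSE]
  rownames(train) <- rownames(test) <- rownames(customdb) <- NULL
  list(train = train, test = test, customdb = customdb)
}

#' Train the four-class origin classifier
#'
#' Fits a multi-class support vector machine (one-vs-one voting) on scaled
#' features. Per-feature centring and scaling statistics are computed on
#' the training data only, frozen into the model, and re-applied verbatim
#' at prediction time — never re-estimated on new data, which would leak
#' test information into the decision function.
#'
#' @param x Numeric feature matrix (rows = contigs, columns in
#'   [feature_names()] order or any fixed order).
#' @param y Class labels, one of [TAXON_GROUPS] per row.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost Regularisation parameter C (default 1).
#' @param gamma RBF kernel width; default `1/ncol(x)`, the standard
#'   heuristic.
#' @param seed Integer seed (the underlying optimiser is deterministic,
#'   but the seed is stored for provenance and any shuffling).
#' @return A `symbiosort_model` object.
#' @export
train_classifier <- function(x, y, kernel = c("radial", "linear"),
                             cost = 1, gamma = NULL, seed = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = TAXON_GROUPS)
  if (anyNA(y)) stop("labels must be one of: ", paste(TAXON_GROUPS, collapse = ", "))
  if (length(unique(y)) < 2) stop("training data must contain >= 2 classes")
  if (!all(is.finite(x))) stop("features must be finite")
  scaler <- fit_scaler(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  set.seed(seed)
  fit <- e1071::svm(apply_scaler(scaler, x), droplevels(y), kernel = kernel,
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, scaler = scaler, kernel = kernel, cost = cost,
                 gamma = gamma, classes = levels(droplevels(y)),
                 features = colnames(x), seed = seed,
                 version = as.character(utils::packageVersion("symbiosort"))),
            class = "symbiosort_model")
}

# per-feature mean/sd scaler; sd 0 (constant feature) -> scale 1 so the
# column maps to exactly 0 rather than NaN
fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' @export
print.symbiosort_model <- function(x, ...) {
  cat(sprintf(
    "symbiosort %s-kernel SVM (C = %g, gamma = %g)\n%d features, classes: %s\n",
    x$kernel, x$cost, x$gamma, length(x$features),
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify contigs with a trained model
#'
#' @param model A `symbiosort_model` from [train_classifier()].
#' @param x Feature matrix with the same columns the model was trained on.
#' @return Data.frame with `contig_id`, `predicted`, and one aggregated
#'   decision-margin column per class (sum of the signed one-vs-one
#'   decision values in that class's favour).
#' @export
classify_contigs <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$features))
    stop(sprintf("feature dimensionality mismatch: model expects %d, got %d",
                 length(model$features), ncol(x)))
  if (!is.null(colnames(x)) && !identical(colnames(x), model$features))
    stop("feature columns do not match the model's feature order")
  pred <- predict(model$fit, apply_scaler(model$scaler, x),
                  decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  margins <- matrix(0, nrow(x), length(model$classes),
                    dimnames = list(NULL, model$classes))
  for (cmp in colnames(dv)) {
    pair <- strsplit(cmp, "/", fixed = TRUE)[[1]]
    margins[, pair[1]] <- margins[, pair[1]] + dv[, cmp]
    margins[, pair[2]] <- margins[, pair[2]] - dv[, cmp]
  }
  colnames(margins) <- paste0("margin_", model$classes)
  data.frame(contig_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
             else rownames(x),
             predicted = as.character(pred), margins,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-bin classification accuracy
#'
#' Accuracy within each length bin plus the pooled accuracy and error rate
#' (1 - pooled accuracy). Contigs shorter than the smallest bin are
#' reported in an explicit `unbinned` row rather than silently dropped.
#'
#' @param predicted Character vector of predicted classes.
#' @param truth Character vector of true classes (same order).
#' @param lengths Contig lengths in bp (same order).
#' @param bins Length-bin table (default [length_bins()]).
#' @return Data.frame with rows per bin (plus `unbinned` if needed and
#'   `overall`), columns `bin`, `n`, `correct`, `accuracy`.
#' @export
evaluate_by_bin <- function(predicted, truth, lengths, bins = length_bins()) {
  stopifnot(length(predicted) == length(truth),
            length(truth) == length(lengths))
  lab <- bin_of(lengths, bins)
  lab[is.na(lab)] <- "unbinned"
  ok <- predicted == truth
  rows <- c(bins$label, if (any(lab == "unbinned")) "unbinned")
  out <- do.call(rbind, lapply(rows, function(b) {
    idx <- lab == b
    data.frame(bin = b, n = sum(idx), correct = sum(ok[idx]),
               accuracy = if (sum(idx)) sum(ok[idx]) / sum(idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(out, data.frame(bin = "overall", n = length(ok),
                               correct = sum(ok),
                               accuracy = mean(ok), stringsAsFactors = FALSE))
  out$error_rate <- 1 - out$accuracy
  out
}

#' Save / load a trained model
#'
#' The model is serialised as a single versioned RDS archive.
#'
#' @param model A `symbiosort_model`.
#' @param path File path.
#' @return `path` (writer) or the model (reader).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "symbiosort_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "symbiosort_model"))
    stop("not a symbiosort model archive")
  model
}
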