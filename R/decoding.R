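#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded package functions never perturb the global
#' random stream.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Assemble a balanced binary decoding problem
#'
#' Builds the 36-sample problem for one participant, chromophore and
#' contrast: 6 clips per class, 3 samples (10-s windows) per clip, so 18
#' samples per class. Cross-validation folds are clip-grouped: each of
#' the 6 folds holds one clip from each class (6 test samples), so the
#' three windows of a clip never split across folds and no within-clip
#' information leaks from training to test. The clip pairing is seeded
#' and recorded. A `"sample"` fold mode (random 6-way split of samples,
#' ignoring clip identity) is available for comparison.
#'
#' @param features a `feature_samples` data.frame (see [build_features()]).
#' @param clips_a,clips_b clip ids of the two classes (6 each).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param labels class labels, length 2 (A then B).
#' @param fold_mode `"clip"` (default) or `"sample"`.
#' @param seed seed for the fold construction.
#' @return object of class `decode_problem`: list with `x` (36 x channels),
#'   `y` (factor), `clip`, `fold`, `labels`, `chromophore`, `participant`,
#'   `fold_mode`, `seed`.
#' @export
assemble_problem <- function(features, clips_a, clips_b,
                             chromophore = "HbO",
                             labels = c("A", "B"),
                             fold_mode = c("clip", "sample"),
                             seed = 1) {
  fold_mode <- match.arg(fold_mode)
  if (length(clips_a) != length(clips_b))
    stop(sprintf("unbalanced clip counts: %d vs %d",
                 length(clips_a), length(clips_b)))
  if (length(intersect(clips_a, clips_b)))
    stop("classes share clips")
  n_folds <- length(clips_a)
  f <- features[features$chromophore == chromophore &
                  features$clip_id %in% c(clips_a, clips_b), , drop = FALSE]
  cnt <- table(f$clip_id)
  if (length(cnt) != 2 * n_folds || any(cnt != 3))
    stop("each clip must contribute exactly 3 samples; got counts: ",
         paste(cnt, collapse = ", "))
  y <- factor(ifelse(f$clip_id %in% clips_a, labels[1], labels[2]),
              levels = labels)
  fold <- integer(nrow(f))
  if (fold_mode == "clip") {
    perm <- with_seed(seed, list(a = sample(clips_a), b = sample(clips_b)))
    for (k in seq_len(n_folds))
      fold[f$clip_id %in% c(perm$a[k], perm$b[k])] <- k
  } else {
    fold <- with_seed(seed, sample(rep(seq_len(n_folds),
                                       length.out = nrow(f))))
  }
  structure(list(x = feature_matrix(f), y = y, clip = f$clip_id,
                 fold = fold, labels = labels, chromophore = chromophore,
                 participant = f$participant[1], fold_mode = fold_mode,
                 seed = seed),
            class = "decode_problem")
}

#' @export
print.decode_problem <- function(x, ...) {
  cat(sprintf("decoding problem: %d samples (%s), %d features, %d folds (%s mode)\n",
              length(x$y), paste(table(x$y), collapse = "+"),
              ncol(x$x), length(unique(x$fold)), x$fold_mode))
  invisible(x)
}

svm_cv <- function(x, y, fold, cost) {
  pred <- factor(rep(NA, length(y)), levels = levels(y))
  fold_acc <- numeric(length(unique(fold)))
  for (k in sort(unique(fold))) {
    tr <- fold != k; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], center = mu, scale = sg)
    xte <- scale(x[te, , drop = FALSE], center = mu, scale = sg)
    fit <- e1071::svm(x = xtr, y = y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    pk <- predict(fit, xte)
    pred[te] <- pk
    fold_acc[k] <- mean(pk == y[te])
  }
  list(accuracy = 100 * mean(pred == y), fold_accuracy = 100 * fold_acc,
       predictions = pred)
}

#' Cross-validated linear SVM accuracy
#'
#' Trains a linear-kernel support vector machine per fold (30 training
#' samples for the standard sixfold problem), z-scoring features with
#' statistics fitted on the training folds only, and reports the pooled
#' fraction of correct held-out predictions as a percentage. With
#' equal-sized folds this equals the mean of the fold accuracies.
#'
#' @param problem a [assemble_problem()] result.
#' @param cost SVM regularisation parameter C.
#' @return object of class `decode_result`: list with `accuracy` (%),
#'   `fold_accuracy`, `n`, plus the problem metadata.
#' @export
crossval_accuracy <- function(problem, cost = 1) {
  stopifnot(inherits(problem, "decode_problem"))
  sds <- apply(problem$x, 2, sd)
  if (any(sds == 0))
    stop("degenerate constant feature(s): ",
         paste(colnames(problem$x)[sds == 0], collapse = ", "))
  cv <- svm_cv(problem$x, problem$y, problem$fold, cost)
  structure(list(accuracy = cv$accuracy, fold_accuracy = cv$fold_accuracy,
                 n = length(problem$y), participant = problem$participant,
                 chromophore = problem$chromophore, labels = problem$labels,
                 cost = cost, seed = problem$seed),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decoding accuracy: %.2f%% over %d held-out samples", x$accuracy, x$n))
  if (!is.null(x$chance_mean))
    cat(sprintf(" (chance %.2f +/- %.2f%% over %d shuffles)",
                x$chance_mean, x$chance_sd, length(x$chance_accuracies)))
  cat("\n")
  invisible(x)
}

#' Permutation-based chance level
#'
#' Estimates the null accuracy distribution by shuffling the 36 class
#' labels uniformly at random `n_shuffles` times (default 100) and
#' re-running the full fold-wise training and testing for each shuffle.
#' The mean of the shuffle accuracies is the chance level; the SD
#' describes the null spread across shuffles.
#'
#' @param problem a [assemble_problem()] result.
#' @param n_shuffles number of label permutations.
#' @param seed RNG seed for the shuffles (bit-exact reproducibility).
#' @param cost SVM regularisation parameter C.
#' @return object of class `decode_result` with `accuracy` (observed),
#'   `chance_mean`, `chance_sd` (%, over shuffles) and
#'   `chance_accuracies` (all shuffle accuracies).
#' @export
permutation_chance <- function(problem, n_shuffles = 100, seed = 1,
                               cost = 1) {
  stopifnot(inherits(problem, "decode_problem"))
  res <- crossval_accuracy(problem, cost = cost)
  acc <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    y_perm <- sample(problem$y)
    svm_cv(problem$x, y_perm, problem$fold, cost)$accuracy
  }, numeric(1)))
  res$chance_mean <- mean(acc)
  res$chance_sd <- sd(acc)
  res$chance_accuracies <- acc
  res$chance_seed <- seed
  res
}

#' Group summary of per-participant decoding results
#'
#' Collates per-participant accuracies into the study's table layout:
#' one row per participant, one column per contrast, with a mean +/- SD
#' footer across participants; chance levels (when present) are
#' summarised as the across-participant mean of the per-participant
#' chance means, with the SD pooled over all shuffle accuracies.
#'
#' @param results either a list of `decode_result` objects each carrying
#'   `participant`, `contrast` and `chromophore` fields, or a data.frame
#'   with columns `participant`, `contrast`, `accuracy` (and optionally
#'   `chromophore`, `chance_mean`).
#' @return list of class `decode_summary`: `per_participant` (wide
#'   data.frame participants x contrasts) and `summary` (per contrast:
#'   `mean`, `sd`, and chance statistics when available).
#' @export
summarize_group <- function(results) {
  if (is.data.frame(results)) {
    df <- results
    chance_pool <- NULL
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, logical(1), "decode_result"))) {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(participant = r$participant,
                 chromophore = r$chromophore %||% NA,
                 contrast = r$contrast %||% paste(r$labels, collapse = " vs "),
                 accuracy = r$accuracy,
                 chance_mean = r$chance_mean %||% NA_real_)
    }))
    chance_pool <- lapply(results, function(r) r$chance_accuracies)
    names(chance_pool) <- paste(df$chromophore, df$contrast, sep = "|")
  } else stop("results must be a non-empty data.frame or list of decode_result")
  if (!nrow(df)) stop("no results to summarise")
  if (!"chromophore" %in% names(df)) df$chromophore <- ""
  df$chromophore[is.na(df$chromophore)] <- ""
  if (!"contrast" %in% names(df)) stop("results need a 'contrast' field")
  key <- interaction(df$chromophore, df$contrast, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(key), function(kk) {
    sub <- df[key == kk, ]
    out <- data.frame(chromophore = sub$chromophore[1],
                      contrast = sub$contrast[1],
                      n = nrow(sub),
                      mean = mean(sub$accuracy), sd = sd(sub$accuracy))
    if ("chance_mean" %in% names(sub) && !all(is.na(sub$chance_mean))) {
      out$chance_mean <- mean(sub$chance_mean, na.rm = TRUE)
      if (!is.null(chance_pool)) {
        pool <- unlist(chance_pool[paste(sub$chromophore, sub$contrast,
                                         sep = "|")])
        out$chance_sd <- if (length(pool) > 1) sd(pool) else NA_real_
      }
    }
    out
  }))
  wide <- stats::reshape(
    df[, c("participant", "chromophore", "contrast", "accuracy")],
    idvar = c("participant", "chromophore"), timevar = "contrast",
    direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  rownames(wide) <- NULL
  structure(list(per_participant = wide, summary = summ),
            class = "decode_summary")
}

#' @export
print.decode_summary <- function(x, ...) {
  cat("decoding summary (mean +/- SD across participants):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %-32s %5.2f +/- %5.2f%%%s\n",
                ifelse(is.na(s$chromophore[i]), "", s$chromophore[i]),
                s$contrast[i], s$mean[i], s$sd[i],
                if (!is.null(s$chance_mean) && !is.na(s$chance_mean[i]))
                  sprintf("  (chance %.2f%%)", s$chance_mean[i]) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
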