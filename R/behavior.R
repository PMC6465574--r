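#' Emotion rating items
#'
#' The 14 self-report items: 10 discrete positive emotions plus arousal,
#' valence, familiarity and liking, each rated on a 7-point Likert scale
#' (1 = not at all, 7 = extremely).
#'
#' @param which `"all"`, `"positive"` or `"dimensions"`.
#' @return character vector of item names.
#' @export
emotion_items <- function(which = c("all", "positive", "dimensions")) {
  which <- match.arg(which)
  pos <- c("amusement", "awe", "gratitude", "hope", "inspiration",
           "interest", "joy", "love", "pride", "serenity")
  dims <- c("arousal", "valence", "familiarity", "liking")
  switch(which, all = c(pos, dims), positive = pos, dimensions = dims)
}

#' Default emotion-cluster definition
#'
#' Partition of the 10 positive-emotion items into three clusters:
#' encouragement (awe, gratitude, hope, inspiration, pride), playfulness
#' (amusement, interest, joy) and harmony (love, serenity). The
#' assignment is configuration, reflecting the geometric grouping of the
#' items in MDS space; override by passing your own named list.
#'
#' @return named list of character vectors partitioning the positive items.
#' @export
default_clusters <- function() {
  list(encouragement = c("awe", "gratitude", "hope", "inspiration", "pride"),
       playfulness = c("amusement", "interest", "joy"),
       harmony = c("love", "serenity"))
}

validate_clusters <- function(clusters, items = emotion_items("positive")) {
  all_members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("cluster definition assigns an item to more than one cluster")
  if (!setequal(all_members, items))
    stop("cluster definition must partition the positive-emotion items")
  invisible(clusters)
}

#' Construct a participants x clips x items rating matrix
#'
#' @param ratings numeric array `[participant, clip, item]`, values in 1..7.
#' @param items item names for the third dimension.
#' @param clip_info `data.frame` with `clip_id`, `condition` and
#'   (for positive clips) `target_emotion`, one row per clip.
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(ratings, items = emotion_items(), clip_info) {
  stopifnot(is.array(ratings), length(dim(ratings)) == 3)
  if (dim(ratings)[3] != length(items))
    stop("third dimension must match the item list")
  if (dim(ratings)[2] != nrow(clip_info))
    stop("second dimension must match clip_info rows")
  ok <- is.na(ratings) | (ratings >= 1 & ratings <= 7)
  if (!all(ok)) stop("ratings must lie in [1, 7]")
  dimnames(ratings) <- list(
    sprintf("p%02d", seq_len(dim(ratings)[1])),
    clip_info$clip_id, items)
  structure(list(ratings = ratings, items = items, clip_info = clip_info),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("rating matrix: %d participants x %d clips x %d items\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Cross-participant mean ratings per clip
#' @param ratings a [rating_matrix()].
#' @return matrix clips x items of across-participant mean ratings.
#' @export
mean_ratings <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  apply(ratings$ratings, c(2, 3), mean)
}

#' Intraclass correlation of one rating item across participants
#'
#' Inter-rater reliability of the clips x participants rating table for a
#' single item. The default form is ICC(2,k): two-way random effects,
#' absolute agreement, average measures over the k raters
#' (participants) — appropriate when every participant rates every clip
#' and the participants are a random sample of raters. Computed from the
#' two-way ANOVA mean squares: with n clips and k raters,
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#'
#' @param ratings a [rating_matrix()].
#' @param item item name.
#' @param type `"ICC2k"` (default), `"ICC2_1"` (single measures) or
#'   `"ICC3k"` (two-way mixed, consistency).
#' @param conditions clip conditions to include (default `"positive"`).
#' @return numeric ICC (\eqn{\le} 1). When the between-clip variance is
#'   zero the ICC is undefined; `NA` is returned with a warning.
#' @export
icc_per_item <- function(ratings, item, type = c("ICC2k", "ICC2_1", "ICC3k"),
                         conditions = "positive") {
  stopifnot(inherits(ratings, "rating_matrix"))
  type <- match.arg(type)
  if (!item %in% ratings$items) stop("unknown item: ", item)
  keep <- ratings$clip_info$condition %in% conditions
  tab <- t(ratings$ratings[, keep, item])   # clips x raters
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2 || k < 2) stop("need at least 2 clips and 2 participants")
  row_m <- rowMeans(tab); col_m <- colMeans(tab); g <- mean(tab)
  ss_r <- k * sum((row_m - g)^2)
  ss_c <- n * sum((col_m - g)^2)
  ss_e <- sum((tab - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + g)^2)
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  denom <- switch(type,
    ICC2k = msr + (msc - mse) / n,
    ICC2_1 = msr + (k - 1) * mse + k * (msc - mse) / n,
    ICC3k = msr)
  num <- switch(type,
    ICC2k = msr - mse,
    ICC2_1 = msr - mse,
    ICC3k = msr - mse)
  if (denom <= .Machine$double.eps * max(1, abs(msr))) {
    if (num == 0 && msr > 0) return(1)
    warning(sprintf("item '%s': zero between-clip variance; ICC undefined", item))
    return(NA_real_)
  }
  num / denom
}

#' ICC table over all items
#' @inheritParams icc_per_item
#' @return data.frame with `item` and `icc`.
#' @export
icc_table <- function(ratings, type = "ICC2k", conditions = "positive") {
  data.frame(item = ratings$items,
             icc = vapply(ratings$items, function(it)
               icc_per_item(ratings, it, type = type,
                            conditions = conditions), numeric(1)),
             row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction; a thin wrapper over
#' [stats::p.adjust()] with `method = "BH"` so the pipeline's correction
#' method is named in one place.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  p.adjust(pvalues, method = "BH")
}

rmanova_oneway <- function(mat) {
  # mat: participants x conditions; one-way repeated-measures ANOVA
  n_p <- nrow(mat); n_c <- ncol(mat)
  long <- data.frame(
    value = as.vector(mat),
    participant = factor(rep(seq_len(n_p), times = n_c)),
    condition = factor(rep(colnames(mat), each = n_p),
                       levels = colnames(mat)))
  fit <- aov(value ~ condition + Error(participant/condition), data = long)
  s <- summary(fit)
  tab <- s[["Error: participant:condition"]][[1]]
  list(F = tab["condition", "F value"],
       df1 = tab["condition", "Df"],
       df2 = tab["Residuals", "Df"],
       p = tab["condition", "Pr(>F)"])
}

#' Manipulation check for one target emotion's film clips
#'
#' For the group of clips designated to elicit `target_emotion`, tests
#' whether that emotion was rated more prominently than the other
#' positive emotions: a one-way repeated-measures ANOVA over the 10
#' positive items on each participant's mean rating of the clip group,
#' followed by paired t-tests of the target item against each other item
#' with Benjamini-Hochberg correction over the 9 post hoc p-values. Items
#' are categorised as `"target"`, `"lower"` (significantly below the
#' target after FDR) or `"not-different"`.
#'
#' @param ratings a [rating_matrix()].
#' @param target_emotion one of the positive items.
#' @param alpha significance level for the adjusted post hoc p-values.
#' @return list with `F`, `df`, `p` (rmANOVA), and `items`: a data.frame
#'   with `item`, `mean`, `t`, `p_raw`, `p_adj`, `category`.
#' @export
manipulation_check <- function(ratings, target_emotion, alpha = 0.05) {
  stopifnot(inherits(ratings, "rating_matrix"))
  pos_items <- intersect(emotion_items("positive"), ratings$items)
  if (!target_emotion %in% pos_items)
    stop("target_emotion must be a positive-emotion item")
  if (length(pos_items) < 2) stop("need at least 2 items")
  keep <- which(ratings$clip_info$target_emotion %in% target_emotion)
  if (!length(keep)) stop("no clips target emotion: ", target_emotion)
  # participant means over the clip group, per item
  pm <- apply(ratings$ratings[, keep, pos_items, drop = FALSE], c(1, 3), mean)
  if (nrow(pm) < 3) stop("need at least 3 participants")
  an <- rmanova_oneway(pm)
  others <- setdiff(pos_items, target_emotion)
  tgt <- pm[, target_emotion]
  post <- lapply(others, function(it) {
    d <- tgt - pm[, it]
    if (sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
      warning(sprintf("degenerate (zero-variance) pair %s vs %s",
                      target_emotion, it))
      return(c(t = NA_real_, p = if (all(d == 0)) 1 else 0))
    }
    tt <- t.test(tgt, pm[, it], paired = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  p_raw <- vapply(post, `[[`, numeric(1), "p")
  t_stat <- vapply(post, `[[`, numeric(1), "t")
  p_adj <- bh_fdr(p_raw)
  lower <- p_adj < alpha & colMeans(pm)[others] < mean(tgt)
  items <- data.frame(
    item = c(target_emotion, others),
    mean = c(mean(tgt), colMeans(pm)[others]),
    t = c(NA, t_stat), p_raw = c(NA, p_raw), p_adj = c(NA, p_adj),
    category = c("target", ifelse(lower, "lower", "not-different")),
    row.names = NULL)
  list(F = an$F, df = c(an$df1, an$df2), p = an$p, items = items)
}

#' Pairwise Pearson correlations between rating items
#'
#' Correlations are computed across clips on the cross-participant
#' averaged ratings (by default over the positive clips only), for every
#' pair of items. Two-sided significance is flagged at p < 0.05 (`*`) and
#' p < 0.01 (`**`).
#'
#' @param ratings a [rating_matrix()].
#' @param items items to include (default: all 14).
#' @param conditions clip conditions to include.
#' @return list of class `rating_correlations` with symmetric matrices
#'   `r` (unit diagonal) and `p`, a character matrix `stars`, and `n`
#'   (number of clips).
#' @export
rating_correlations <- function(ratings, items = ratings$items,
                                conditions = "positive") {
  stopifnot(inherits(ratings, "rating_matrix"))
  keep <- ratings$clip_info$condition %in% conditions
  m <- apply(ratings$ratings[, keep, items, drop = FALSE], c(2, 3), mean)
  if (nrow(m) < 3) stop("need at least 3 clips")
  k <- length(items)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(items, items)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- cor.test(m[, i], m[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = nrow(m)),
            class = "rating_correlations")
}

#' Nonmetric multidimensional scaling with Kruskal Stress-1
#'
#' Embeds a dissimilarity matrix in `dims` dimensions by nonmetric
#' (Kruskal) MDS, initialised from classical scaling so the solution is
#' deterministic. The reported badness of fit is Kruskal's Stress-1,
#' `sqrt(sum((dhat_ij - d_ij)^2) / sum(d_ij^2))` over the embedded
#' distances `d_ij` and the monotone-regressed disparities `dhat_ij`.
#' Coordinates are centred at the origin.
#'
#' @param dissim square symmetric nonnegative matrix with zero diagonal.
#' @param dims embedding dimensionality.
#' @return object of class `mds_solution`: list with `points`
#'   (items x dims, centred) and `stress` (Stress-1, in [0, 1]).
#' @export
mds_embed <- function(dissim, dims = 2) {
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim)) stop("dissimilarity matrix must be square")
  if (max(abs(dissim - t(dissim))) > 1e-12)
    stop("dissimilarity matrix must be symmetric")
  if (any(dissim < 0)) stop("dissimilarities must be nonnegative")
  if (any(abs(diag(dissim)) > 1e-12))
    stop("dissimilarity diagonal must be zero")
  n <- nrow(dissim)
  if (dims >= n) stop("dims must be smaller than the number of items")
  d <- as.dist(dissim)
  # isoMDS requires strictly positive off-diagonal dissimilarities
  if (any(d <= 0)) {
    eps <- max(d) * 1e-9
    d[d <= 0] <- if (eps > 0) eps else 1e-12
  }
  init <- cmdscale(d, k = dims)
  if (ncol(init) < dims)   # degenerate classical solution: pad with zeros
    init <- cbind(init, matrix(0, n, dims - ncol(init)))
  fit <- MASS::isoMDS(d, y = init, k = dims, trace = FALSE)
  pts <- sweep(fit$points, 2, colMeans(fit$points))
  rownames(pts) <- rownames(dissim)
  structure(list(points = pts, stress = fit$stress / 100, dims = dims),
            class = "mds_solution")
}

#' @export
print.mds_solution <- function(x, ...) {
  cat(sprintf("nonmetric MDS solution: %d items in %d dimensions, Stress-1 = %.3f\n",
              nrow(x$points), x$dims, x$stress))
  invisible(x)
}

#' Suggest item clusters from an MDS embedding
#'
#' Optional helper: hierarchical clustering (average linkage) of the
#' embedded item coordinates, with the number of clusters chosen by mean
#' silhouette width over `k_range` unless fixed. This is a suggestion
#' tool only — the operative cluster assignment is always explicit
#' configuration (see [default_clusters()]) and is never overridden
#' silently.
#'
#' @param solution an [mds_embed()] result.
#' @param k number of clusters; `NULL` to choose by silhouette.
#' @param k_range candidate cluster counts when `k` is `NULL`.
#' @return named list of item character vectors (one per cluster).
#' @export
suggest_clusters <- function(solution, k = NULL, k_range = 2:5) {
  stopifnot(inherits(solution, "mds_solution"))
  d <- dist(solution$points)
  hc <- stats::hclust(d, method = "average")
  if (is.null(k)) {
    sil <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
    }, numeric(1))
    k <- k_range[which.max(sil)]
  }
  ct <- stats::cutree(hc, k)
  out <- split(names(ct), ct)
  names(out) <- paste0("cluster", seq_along(out))
  out
}

#' Per-clip emotion-cluster scores
#'
#' A clip's score on a cluster is the arithmetic mean of its ratings on
#' the cluster's member emotions; e.g. with playfulness = (interest, joy,
#' amusement) rated 1, 2, 2 the playfulness score is 1.67. Scores are
#' computed on the cross-participant mean ratings when a full
#' [rating_matrix()] is supplied, or directly on a clips x items matrix.
#'
#' @param ratings a [rating_matrix()] or a numeric matrix (clips x items,
#'   with item column names).
#' @param clusters named list partitioning the positive items; see
#'   [default_clusters()].
#' @return data.frame with `clip_id`, `condition`, `target_emotion`
#'   (when known) and one column per cluster; values in [1, 7].
#' @export
cluster_scores <- function(ratings, clusters = default_clusters()) {
  validate_clusters(clusters, unlist(clusters, use.names = FALSE))
  if (inherits(ratings, "rating_matrix")) {
    m <- mean_ratings(ratings)
    info <- ratings$clip_info
  } else {
    m <- as.matrix(ratings)
    if (is.null(colnames(m))) stop("rating matrix must have item column names")
    info <- data.frame(clip_id = if (is.null(rownames(m)))
      seq_len(nrow(m)) else rownames(m))
  }
  missing_items <- setdiff(unlist(clusters), colnames(m))
  if (length(missing_items))
    stop("items missing from ratings: ", paste(missing_items, collapse = ", "))
  out <- info
  for (cl in names(clusters))
    out[[cl]] <- rowMeans(m[, clusters[[cl]], drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Select the clips scoring highest on one cluster
#'
#' Returns the `k` positive clips with the highest scores on the given
#' cluster; ties at the cut are broken deterministically by ascending
#' clip id (and reported via `message()`).
#'
#' @param scores data.frame from [cluster_scores()].
#' @param cluster cluster column name.
#' @param k number of clips to select.
#' @return vector of `k` clip ids, ordered by descending score.
#' @export
select_top_clips <- function(scores, cluster, k = 6) {
  if (!cluster %in% names(scores)) stop("unknown cluster: ", cluster)
  df <- scores
  if ("condition" %in% names(df)) df <- df[df$condition == "positive", ]
  if (k > nrow(df))
    stop(sprintf("k = %d exceeds the %d available clips", k, nrow(df)))
  ord <- order(-df[[cluster]], df$clip_id)
  sel <- df[ord, ]
  if (nrow(df) > k && sel[[cluster]][k] == sel[[cluster]][k + 1])
    message(sprintf(
      "tie at rank %d on '%s' (score %.4g): lower clip id selected",
      k, cluster, sel[[cluster]][k]))
  sel$clip_id[seq_len(k)]
}
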