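#' Per-clip channel responses
#'
#' Collapses the three 10-s sample windows of each clip to a single
#' per-clip response per channel and chromophore: the mean concentration
#' change over the extracted 30-s period. These per-clip responses are
#' the observations entering the channel-wise correlations with emotion
#' scores.
#'
#' @param features a `feature_samples` data.frame (see [build_features()]).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param conditions clip conditions to include (default `"positive"`).
#' @return list with `responses` (clips x channels matrix), `clip_id`,
#'   `condition`.
#' @export
clip_responses <- function(features, chromophore = "HbO",
                           conditions = "positive") {
  f <- features[features$chromophore == chromophore &
                  features$condition %in% conditions, , drop = FALSE]
  if (!nrow(f)) stop("no matching feature samples")
  x <- feature_matrix(f)
  clip <- f$clip_id
  ids <- unique(clip)
  resp <- t(vapply(ids, function(cid)
    colMeans(x[clip == cid, , drop = FALSE]), numeric(ncol(x))))
  rownames(resp) <- ids
  cond <- f$condition[match(ids, f$clip_id)]
  list(responses = resp, clip_id = ids, condition = cond,
       chromophore = chromophore)
}

#' Channel-wise correlation between responses and an emotion score
#'
#' For a single participant, the Pearson correlation across the positive
#' film clips between each channel's per-clip hemodynamic response and a
#' per-clip emotion score (a cluster score or the valence rating),
#' producing one topographic map of r values per score and chromophore.
#'
#' @param responses clips x channels matrix of per-clip responses (see
#'   [clip_responses()]), or the list returned by [clip_responses()].
#' @param scores numeric vector of per-clip scores, aligned with the
#'   response rows.
#' @param score_name label stored with the map.
#' @param chromophore label stored with the map.
#' @param participant identifier stored with the map.
#' @return data.frame of class `topo_map` with `channel` and `r`
#'   (`NA` with a warning for zero-variance channels); attributes
#'   `score_name`, `chromophore`, `participant`, `n_clips`.
#' @export
channel_score_correlation <- function(responses, scores, score_name = "score",
                                      chromophore = NA, participant = NA) {
  if (is.list(responses) && !is.data.frame(responses)) {
    if (is.na(chromophore)) chromophore <- responses$chromophore
    responses <- responses$responses
  }
  responses <- as.matrix(responses)
  if (nrow(responses) != length(scores))
    stop("scores must align with response rows (one per clip)")
  if (nrow(responses) < 3) stop("need at least 3 clips")
  if (sd(scores) == 0) stop("score vector has zero variance")
  r <- vapply(seq_len(ncol(responses)), function(ch) {
    v <- responses[, ch]
    if (sd(v) == 0) {
      warning(sprintf("channel %d has zero variance; r undefined", ch))
      return(NA_real_)
    }
    cor(v, scores)
  }, numeric(1))
  out <- data.frame(channel = seq_len(ncol(responses)), r = r)
  class(out) <- c("topo_map", "data.frame")
  attr(out, "score_name") <- score_name
  attr(out, "chromophore") <- chromophore
  attr(out, "participant") <- participant
  attr(out, "n_clips") <- nrow(responses)
  out
}

#' Group-level correlation topography with FDR flags
#'
#' Averages per-participant correlation maps channel-wise, tests each
#' channel's correlations against zero with a one-sample t-test (on
#' Fisher z-transformed r by default, since r is bounded and skewed
#' under the alternative), and corrects the 24 channel p-values by
#' Benjamini-Hochberg FDR.
#'
#' @param maps list of `topo_map` data.frames (one per participant), or a
#'   participants x channels matrix of r values.
#' @param fisher_z apply the Fisher z-transform before the t-test.
#' @param alpha FDR level for the significance flags.
#' @return data.frame of class `topo_map` with `channel`, `mean_r`, `t`,
#'   `p`, `p_adj`, `significant`.
#' @export
group_topography <- function(maps, fisher_z = TRUE, alpha = 0.05) {
  if (is.list(maps) && !is.data.frame(maps) && !is.matrix(maps)) {
    rmat <- do.call(rbind, lapply(maps, function(m) m$r))
  } else rmat <- as.matrix(maps)
  if (is.null(rmat) || !nrow(rmat)) stop("no maps provided")
  mean_r <- colMeans(rmat, na.rm = TRUE)
  tv <- if (fisher_z) atanh(pmin(pmax(rmat, -1 + 1e-12), 1 - 1e-12)) else rmat
  tests <- apply(tv, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2 || sd(col) == 0)
      return(c(t = NA_real_, p = NA_real_))
    tt <- t.test(col)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  p_adj <- bh_fdr(tests["p", ])
  out <- data.frame(channel = seq_along(mean_r), mean_r = mean_r,
                    t = tests["t", ], p = tests["p", ], p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha)
  rownames(out) <- NULL
  class(out) <- c("topo_map", "data.frame")
  attr(out, "n_participants") <- nrow(rmat)
  out
}

#' Write a topographic map to CSV
#' @param map a `topo_map` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_topo <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Plot a topographic map on the montage grid
#'
#' Simple channel-grid rendering (no cortical surface): channels drawn at
#' their montage x/y positions, coloured by value.
#'
#' @param map a `topo_map` data.frame with `r` or `mean_r` column.
#' @param montage montage supplying channel positions.
#' @param main plot title.
#' @return invisibly, the plotted values.
#' @export
plot_topo <- function(map, montage = default_montage(), main = NULL) {
  val <- if ("mean_r" %in% names(map)) map$mean_r else map$r
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(101)
  idx <- pmin(101, pmax(1, round(50 * (val / max(abs(val), na.rm = TRUE)) + 51)))
  graphics::plot(montage$x, montage$y, pch = 21, cex = 4,
                 bg = pal[idx], xlab = "", ylab = "", axes = FALSE,
                 main = main %||% attr(map, "score_name"))
  graphics::text(montage$x, montage$y, montage$channel, cex = 0.6)
  invisible(val)
}
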