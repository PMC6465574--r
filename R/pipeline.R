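#' Preprocess a raw recording to spatial feature samples
#'
#' The standard chain: band-pass filter the raw intensity (0.01-0.2 Hz,
#' zero-phase), convert to optical density, invert the modified
#' Beer-Lambert law to HbO/HbR concentration changes, baseline-correct
#' each clip against the 10 s preceding its onset, extract the last 30 s
#' of each clip as three 10-s windows, and reduce each window to its
#' per-channel mean.
#'
#' @param raw a [raw_recording()] with an event table.
#' @param ext extinction/DPF table (must match the forward model for
#'   exact concentration recovery).
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param baseline_s pre-stimulus baseline window (s).
#' @param window_s,n_windows sample-window geometry.
#' @param reference_policy intensity reference for [compute_delta_od()].
#' @return a `feature_samples` data.frame (see [build_features()]).
#' @export
preprocess_recording <- function(raw, ext = default_extinction(),
                                 low_hz = 0.01, high_hz = 0.2,
                                 baseline_s = 10, window_s = 10,
                                 n_windows = 3,
                                 reference_policy = "mean") {
  stopifnot(inherits(raw, "raw_recording"))
  if (is.null(raw$events)) stop("recording has no event table")
  filt <- bandpass(raw, low_hz, high_hz)
  od <- compute_delta_od(filt, reference_policy)
  hemo <- invert_mbll(od, ext, raw$montage)
  epochs <- baseline_correct(hemo, raw$events, window_s = baseline_s)
  windows <- extract_samples(epochs, window_s = window_s,
                             n_windows = n_windows)
  build_features(windows, participant_id = raw$participant_id)
}

#' Pipeline run configuration
#'
#' @param design a [sim_design()] (ignored when `ratings_path` /
#'   `recordings` supply real data).
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @param out_dir optional output directory for CSV tables and manifest.
#' @param n_shuffles permutation count for chance levels (0 disables).
#' @param cost SVM regularisation C.
#' @param chromophores chromophores to decode.
#' @param k_clips clips per class entering decoding.
#' @param low_hz,high_hz,baseline_s,window_s,n_windows preprocessing
#'   parameters.
#' @param clusters cluster definition (see [default_clusters()]).
#' @param ratings_path optional path to a ratings CSV (replaces
#'   simulated ratings).
#' @param recordings optional list of [raw_recording()] objects
#'   (replaces simulated recordings).
#' @return list of class `run_config`.
#' @export
run_config <- function(design = sim_design(), seed = 1, out_dir = NULL,
                       n_shuffles = 100, cost = 1,
                       chromophores = c("HbO", "HbR"), k_clips = 6,
                       low_hz = 0.01, high_hz = 0.2, baseline_s = 10,
                       window_s = 10, n_windows = 3,
                       clusters = default_clusters(),
                       ratings_path = NULL, recordings = NULL) {
  stopifnot(low_hz > 0, high_hz > low_hz, baseline_s > 0, window_s > 0,
            n_windows >= 1, cost > 0, n_shuffles >= 0, k_clips >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Resolve disjoint top-k clip sets for a cluster-vs-cluster contrast
#'
#' Top-k selections for two clusters can overlap (a clip may score high
#' on both). Shared clips are assigned to the cluster on which they
#' score higher, and the other side refills from its next-best clips,
#' iterating until the two k-sets are disjoint.
#'
#' @param scores data.frame from [cluster_scores()].
#' @param cluster_a,cluster_b cluster column names.
#' @param k clips per side.
#' @return list with `a` and `b`, each k clip ids.
#' @export
contrast_clips <- function(scores, cluster_a, cluster_b, k = 6) {
  df <- scores
  if ("condition" %in% names(df)) df <- df[df$condition == "positive", ]
  excl_a <- excl_b <- c()
  for (it in seq_len(nrow(df))) {
    a <- top_k(df, cluster_a, k, excl_a)
    b <- top_k(df, cluster_b, k, excl_b)
    shared <- intersect(a, b)
    if (!length(shared)) return(list(a = a, b = b))
    for (cid in shared) {
      row <- df[df$clip_id == cid, ]
      if (row[[cluster_a]] >= row[[cluster_b]])
        excl_b <- c(excl_b, cid)
      else excl_a <- c(excl_a, cid)
    }
  }
  stop("could not build disjoint clip sets")
}

top_k <- function(df, cluster, k, exclude = c()) {
  df <- df[!df$clip_id %in% exclude, ]
  if (k > nrow(df)) stop("not enough clips for contrast")
  df$clip_id[order(-df[[cluster]], df$clip_id)][seq_len(k)]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) simulate or load ratings; (2) behavioural
#' analytics (ICC per item, manipulation checks, item correlations,
#' nonmetric MDS of the positive items, cluster scores, top-clip
#' selection); (3) simulate or load recordings and preprocess each to
#' feature samples; (4) per-participant binary SVM decoding for the six
#' contrasts (three cluster-vs-negative, three cluster-vs-cluster) per
#' chromophore, with permutation chance levels when `n_shuffles > 0`;
#' (5) channel-wise correlation topographies per score and chromophore
#' with group-level FDR flags. Writes CSV tables and a run manifest to
#' `out_dir` when given.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return list of class `pipeline_result` with elements `behavior`,
#'   `features`, `decoding`, `topographies`, `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  say <- function(...) if (!quiet) message(sprintf(...))

  # ---- ratings -------------------------------------------------------
  if (!is.null(config$ratings_path)) {
    if (!file.exists(config$ratings_path))
      stop("behavior stage: ratings file not found: ", config$ratings_path)
    ratings <- read_ratings(config$ratings_path)
  } else {
    ratings <- gen_ratings(design, seed = config$seed)$ratings
  }
  say("[ratings] %d participants x %d clips x %d items",
      dim(ratings$ratings)[1], dim(ratings$ratings)[2],
      dim(ratings$ratings)[3])

  # ---- behavior ------------------------------------------------------
  icc <- icc_table(ratings)
  corr <- rating_correlations(ratings)
  pos <- intersect(emotion_items("positive"), ratings$items)
  mds <- mds_embed(1 - corr$r[pos, pos])
  scores <- cluster_scores(ratings, config$clusters)
  vm <- mean_ratings(ratings)
  if ("valence" %in% colnames(vm))
    scores$valence <- vm[match(scores$clip_id, rownames(vm)), "valence"]
  checks <- lapply(setNames(nm = unique(stats::na.omit(
    ratings$clip_info$target_emotion))), function(em)
      manipulation_check(ratings, em))
  top <- lapply(setNames(nm = names(config$clusters)), function(cl)
    select_top_clips(scores, cl, k = config$k_clips))
  say("[behavior] mean ICC %.2f; MDS Stress-1 %.3f", mean(icc$icc),
      mds$stress)

  # ---- preprocessing -------------------------------------------------
  n_p <- if (!is.null(config$recordings)) length(config$recordings)
         else design$n_participants
  features <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    raw <- if (!is.null(config$recordings)) config$recordings[[p]]
           else gen_recording(design, participant = p,
                              seed = config$seed)$recording
    if (is.na(raw$participant_id)) raw$participant_id <- p
    features[[p]] <- preprocess_recording(
      raw, ext = design$ext, low_hz = config$low_hz,
      high_hz = config$high_hz, baseline_s = config$baseline_s,
      window_s = config$window_s, n_windows = config$n_windows)
    say("[preprocess] participant %d: %d feature samples", p,
        nrow(features[[p]]))
  }

  # ---- decoding ------------------------------------------------------
  neg_clips <- ratings$clip_info$clip_id[
    ratings$clip_info$condition == "negative"]
  cl_names <- names(config$clusters)
  contrasts <- list()
  for (cl in cl_names)
    contrasts[[paste0(cl, " vs negative")]] <-
      list(a = top[[cl]], b = neg_clips)
  for (i in seq_len(length(cl_names) - 1))
    for (j in (i + 1):length(cl_names)) {
      cc <- contrast_clips(scores, cl_names[i], cl_names[j],
                           k = config$k_clips)
      contrasts[[paste(cl_names[i], "vs", cl_names[j])]] <- cc
    }
  results <- list()
  for (p in seq_len(n_p)) for (chrom in config$chromophores)
    for (cn in names(contrasts)) {
      prob <- assemble_problem(features[[p]], contrasts[[cn]]$a,
                               contrasts[[cn]]$b, chromophore = chrom,
                               seed = config$seed * 101 + p)
      res <- if (config$n_shuffles > 0)
        permutation_chance(prob, n_shuffles = config$n_shuffles,
                           seed = config$seed * 307 + p,
                           cost = config$cost)
      else crossval_accuracy(prob, cost = config$cost)
      res$contrast <- cn
      results[[length(results) + 1]] <- res
    }
  decoding <- summarize_group(results)
  say("[decode] %d classifiers (%d participants x %d chromophores x %d contrasts)",
      length(results), n_p, length(config$chromophores), length(contrasts))

  # ---- topographies --------------------------------------------------
  topographies <- list()
  score_names <- c(cl_names, if ("valence" %in% names(scores)) "valence")
  for (chrom in config$chromophores) for (sn in score_names) {
    maps <- lapply(seq_len(n_p), function(p) {
      resp <- clip_responses(features[[p]], chromophore = chrom)
      sc <- scores[[sn]][match(resp$clip_id, scores$clip_id)]
      channel_score_correlation(resp, sc, score_name = sn,
                                chromophore = chrom, participant = p)
    })
    topographies[[paste(chrom, sn, sep = ".")]] <-
      list(individual = maps, group = group_topography(maps))
  }
  say("[topo] %d group topographies", length(topographies))

  out <- structure(list(
    behavior = list(ratings = ratings, icc = icc, correlations = corr,
                    mds = mds, cluster_scores = scores,
                    manipulation_checks = checks, top_clips = top),
    features = features, decoding = decoding,
    topographies = topographies, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bh <- result$behavior
  write.csv(bh$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  write.csv(as.data.frame(bh$correlations$r),
            file.path(out_dir, "item_correlations.csv"))
  write.csv(data.frame(item = rownames(bh$mds$points), bh$mds$points,
                       stress1 = bh$mds$stress),
            file.path(out_dir, "mds.csv"), row.names = FALSE)
  write.csv(bh$cluster_scores, file.path(out_dir, "cluster_scores.csv"),
            row.names = FALSE)
  s <- result$decoding
  write.csv(s$per_participant,
            file.path(out_dir, "accuracy_per_participant.csv"),
            row.names = FALSE)
  write.csv(s$summary, file.path(out_dir, "accuracy_summary.csv"),
            row.names = FALSE)
  for (nm in names(result$topographies))
    write_topo(result$topographies[[nm]]$group,
               file.path(out_dir, paste0("topo_", gsub("[^A-Za-z0-9._-]",
                                                       "_", nm), ".csv")))
  cfg <- result$config
  cfg_txt <- deparse(cfg[setdiff(names(cfg), c("recordings", "design"))])
  tmp <- file.path(out_dir, "manifest.txt")
  writeLines(c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("nirsemotion"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %s", cfg$seed),
    sprintf("n_shuffles: %s", cfg$n_shuffles),
    sprintf("config_hash: %s", config_hash(cfg)),
    "config:", cfg_txt), tmp)
  invisible(out_dir)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[setdiff(names(cfg), "recordings")], tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  cat(sprintf("  participants: %d\n", length(x$features)))
  cat(sprintf("  MDS Stress-1: %.3f\n", x$behavior$mds$stress))
  print(x$decoding)
  invisible(x)
}
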