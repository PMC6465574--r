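make_ratings <- function(vals, n_p, clip_info, items = emotion_items()) {
  rating_matrix(array(vals, dim = c(n_p, nrow(clip_info), length(items))),
                items = items, clip_info = clip_info)
}

pos_clip_info <- function(n_clips, target = NA_character_) {
  data.frame(clip_id = seq_len(n_clips), condition = "positive",
             target_emotion = rep_len(target, n_clips))
}

test_that("ICC(2,k) is 1 for perfect agreement and ~0 for pure noise", {
  # all raters identical, clips differ
  n_p <- 5; n_c <- 8
  clipvals <- rep(rep(1:7, length.out = n_c), each = n_p)
  r <- make_ratings(rep(clipvals, 14), n_p, pos_clip_info(n_c))
  expect_equal(icc_per_item(r, "joy"), 1)

  # independent uniform noise, 13 raters x 30 clips; the single-measures
  # form is the stable null statistic (average-measures ICC(2,k) swings
  # wildly under the null by Spearman-Brown amplification)
  iccs1 <- vapply(1:100, function(s) {
    set.seed(s)
    rn <- make_ratings(sample(1:7, 13 * 30, replace = TRUE), 13,
                       pos_clip_info(30), items = "awe")
    icc_per_item(rn, "awe", type = "ICC2_1")
  }, numeric(1))
  expect_lt(max(abs(iccs1)), 0.2)
  expect_lt(abs(mean(iccs1)), 0.05)

  # degenerate: no variance anywhere
  rz <- make_ratings(rep(4, 2 * 3 * 14), 2, pos_clip_info(3))
  expect_warning(v <- icc_per_item(rz, "joy"), "undefined")
  expect_true(is.na(v))
})

test_that("ICC(2,k) recovers known variance components at n = 500", {
  # y_ic = clip_i + e_ic; no rater effect:
  # ICC(2,k) = var_c / (var_c + var_e / k)
  var_c <- 0.5; var_e <- 1; k <- 13; n <- 500
  set.seed(99)
  lat <- outer(rnorm(n, 0, sqrt(var_c)), rep(1, k)) +
    matrix(rnorm(n * k, 0, sqrt(var_e)), n, k)
  # map to a 1..7 scale loosely (ICC on the continuous values via array);
  # keep the matrix first in pmin/pmax so dims survive
  sc <- pmin(pmax(4 + lat, 1), 7)
  arr <- array(0, dim = c(k, n, 1))
  arr[, , 1] <- t(sc)
  r <- rating_matrix(arr, items = "joy", clip_info = pos_clip_info(n))
  expected <- var_c / (var_c + var_e / k)
  expect_equal(icc_per_item(r, "joy"), expected, tolerance = 0.05)
})

test_that("manipulation check flags a dominant target and controls nulls", {
  items <- emotion_items("positive")
  ci <- pos_clip_info(3, target = "awe")
  n_p <- 13
  set.seed(5)
  base <- array(pmin(7, pmax(1, round(rnorm(n_p * 3 * 10, 3, 0.5)))),
                c(n_p, 3, 10))
  base[, , match("awe", items)] <-
    pmin(7, base[, , match("awe", items)] + 3)
  r <- rating_matrix(base, items = items, clip_info = ci)
  mc <- manipulation_check(r, "awe")
  expect_lt(mc$p, 0.001)
  expect_equal(sum(mc$items$category == "lower"), 9)
  expect_equal(mc$items$category[mc$items$item == "awe"], "target")

  # null: all items identically distributed -> FDR keeps "lower" rare
  frac_lower <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    rn <- rating_matrix(
      array(sample(1:7, n_p * 3 * 10, replace = TRUE), c(n_p, 3, 10)),
      items = items, clip_info = ci)
    mean(manipulation_check(rn, "awe")$items$category[-1] == "lower")
  }, numeric(1))
  expect_lte(mean(frac_lower), 0.05)
})

test_that("two-condition rmANOVA F equals the squared paired t", {
  items <- c("amusement", "joy")
  ci <- pos_clip_info(3, target = "amusement")
  set.seed(11)
  arr <- array(runif(10 * 3 * 2, 1, 7), c(10, 3, 2))
  r <- rating_matrix(arr, items = items, clip_info = ci)
  mc <- manipulation_check(r, "amusement")
  pm <- apply(arr, c(1, 3), mean)
  tt <- t.test(pm[, 1], pm[, 2], paired = TRUE)
  expect_equal(mc$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(mc$p, tt$p.value, tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up everywhere", {
  expect_equal(bh_fdr(0.03), 0.03)                      # single p unchanged
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))        # equal ps unchanged

  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  # exhaustive up to length 3
  for (len in 1:3) {
    combos <- do.call(expand.grid, rep(list(grid), len))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      expect_equal(bh_fdr(p), bh_stepup_oracle(p))
    }
  }
  # random vectors up to length 6
  set.seed(3)
  for (i in 1:200) {
    p <- sample(grid, sample(4:6, 1), replace = TRUE)
    expect_equal(bh_fdr(p), bh_stepup_oracle(p))
    expect_true(all(bh_fdr(p) >= p))                    # adjusted >= raw
  }
})

test_that("rating correlations are symmetric with exact hand values", {
  items <- c("amusement", "joy", "love")
  ci <- pos_clip_info(3)
  arr <- array(0, c(2, 3, 3))
  base <- matrix(c(1, 4, 7, 2, 3, 6, 5, 2, 4), 3, 3)  # clips x items
  arr[1, , ] <- base; arr[2, , ] <- base              # duplicated raters
  r <- rating_matrix(arr, items = items, clip_info = ci)
  rc <- rating_correlations(r)
  expect_equal(rc$r, t(rc$r))
  expect_equal(unname(diag(rc$r)), rep(1, 3))
  # product-moment oracle on the 3-clip hand example
  pm <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rc$r["amusement", "joy"], pm(base[, 1], base[, 2]),
               tolerance = 1e-12)
  expect_equal(rc$r["joy", "love"], pm(base[, 2], base[, 3]),
               tolerance = 1e-12)

  # duplicated item -> off-diagonal r = 1
  arr2 <- arr; arr2[, , 3] <- arr2[, , 1]
  r2 <- rating_matrix(arr2, items = items, clip_info = ci)
  expect_equal(rating_correlations(r2)$r["amusement", "love"], 1)
})

test_that("nonmetric MDS embeds perfect distances with near-zero stress", {
  set.seed(4)
  truth <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(truth))
  sol <- mds_embed(d)
  expect_lt(sol$stress, 0.01)
  got <- as.vector(dist(sol$points))
  expect_gt(cor(got, as.vector(dist(truth))), 0.999)
  expect_equal(unname(colMeans(sol$points)), c(0, 0), tolerance = 1e-8)

  # determinism: identical runs bit for bit
  dd <- matrix(runif(16), 4, 4); dd <- (dd + t(dd)) / 2; diag(dd) <- 0
  s1 <- mds_embed(dd); s2 <- mds_embed(dd)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$stress, s2$stress)

  # stress non-increasing with dimensionality
  set.seed(6)
  hi <- as.matrix(dist(matrix(rnorm(9 * 5), 9, 5)))
  stresses <- vapply(1:3, function(k) mds_embed(hi, dims = k)$stress,
                     numeric(1))
  expect_true(all(diff(stresses) <= 1e-8))

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(mds_embed(neg), "nonnegative")
})

test_that("the printed item-correlation structure recovers three clusters", {
  # 10-item dissimilarity 1 - r from the shipped correlation table: the
  # playfulness trio stays together (each member's nearest neighbour is
  # in the trio) and the embedding's 3-cluster structure reproduces the
  # encouragement / playfulness / harmony partition
  r <- rating_target_correlations()
  pos <- emotion_items("positive")
  sol <- mds_embed(1 - r[pos, pos])
  d <- as.matrix(dist(sol$points))
  diag(d) <- Inf
  trio <- c("amusement", "interest", "joy")
  for (it in trio)
    expect_in(names(which.min(d[it, ])), setdiff(trio, it))

  found <- suggest_clusters(sol, k = 3)
  expected <- default_clusters()
  for (cl in expected)
    expect_true(any(vapply(found, setequal, logical(1), cl)))
  # and silhouette alone picks k = 3 on this structure
  expect_length(suggest_clusters(sol), 3)
})

test_that("cluster scores average member items and commute with pooling", {
  m <- matrix(c(1, 2, 2), 1,
              dimnames = list("c1", c("interest", "joy", "amusement")))
  sc <- cluster_scores(m, clusters = list(playfulness = colnames(m)))
  expect_equal(round(sc$playfulness, 2), 1.67)

  m2 <- matrix(7, 2, 10, dimnames = list(NULL, emotion_items("positive")))
  sc2 <- cluster_scores(m2)
  expect_true(all(sc2$encouragement == 7 & sc2$playfulness == 7 &
                    sc2$harmony == 7))

  m3 <- matrix(c(3, 5), 1, dimnames = list(NULL, c("love", "serenity")))
  expect_equal(cluster_scores(m3, list(harmony = c("love", "serenity")))$harmony, 4)

  # mean over participants of per-participant scores == scores of means
  set.seed(8)
  d <- small_design()
  r <- gen_ratings(d, seed = 3)$ratings
  pooled <- cluster_scores(r)
  per_p <- lapply(seq_len(dim(r$ratings)[1]), function(p) {
    m_p <- r$ratings[p, , ]
    rownames(m_p) <- r$clip_info$clip_id
    cluster_scores(m_p)
  })
  avg <- Reduce(`+`, lapply(per_p, function(x)
    as.matrix(x[, c("encouragement", "playfulness", "harmony")]))) /
    length(per_p)
  expect_equal(as.matrix(pooled[, colnames(avg)]), avg, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("top-clip selection is deterministic with documented tie rule", {
  sc <- data.frame(clip_id = 1:8, condition = "positive",
                   encouragement = c(5, 7, 3, 6, 7, 2, 4, 1))
  expect_equal(select_top_clips(sc, "encouragement", 3), c(2, 5, 4))
  # tie at the cut: equal scores at ranks 3 and 4 -> lower id wins
  sc$encouragement <- c(7, 7, 5, 5, 5, 2, 1, 1)
  expect_message(sel <- select_top_clips(sc, "encouragement", 3), "tie")
  expect_equal(sel, c(1, 2, 3))
  expect_error(select_top_clips(sc, "encouragement", 9), "exceeds")
})
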