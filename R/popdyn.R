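# Population-level analyses: trial-averaged activity matrices, activity
# clustering, SVM activity modes orthogonalised by QR, block-identity
# decoding and PC trajectories.

#' Gaussian smoothing of a signal
#'
#' Discrete convolution with a normalised Gaussian kernel (zero-padded
#' edges), sigma expressed in samples.
#'
#' @param x numeric vector.
#' @param sigma_bins kernel s.d. in samples; 0 returns `x` unchanged.
#' @param radius kernel half-width in s.d. units.
#' @return smoothed vector of the same length.
#' @export
gauss_smooth <- function(x, sigma_bins, radius = 4) {
  if (sigma_bins <= 0) return(x)
  h <- max(1L, ceiling(radius * sigma_bins))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  xp <- c(numeric(h), x, numeric(h))
  out <- numeric(length(x))
  # direct FIR filter; equivalent to explicit convolution with k
  for (i in seq_along(x)) out[i] <- sum(xp[i:(i + 2 * h)] * k)
  out
}

#' Trial-averaged activity matrix
#'
#' Bins each unit's spikes relative to the sound onset, averages across
#' trials within each block, then optionally smooths (Gaussian kernel) and
#' z-scores. The z-score reference is either the unit's concatenated
#' activity across all blocks (`"across_blocks"`), the per-block pre-sound
#' baseline (`"per_block_baseline"`), or none. The transform order follows
#' the calling analysis's convention via `order`.
#'
#' @param dataset a `spike_dataset` (QC-filtered upstream).
#' @param window time window around the sound onset (s), default
#'   `c(-0.1, 3)`.
#' @param bin_s bin width (s).
#' @param sigma_bins Gaussian smoothing s.d. in bins (0 = none).
#' @param zscore z-scoring reference (see above).
#' @param order `"zscore_first"` or `"smooth_first"`.
#' @return object of class `activity_matrix`: `rates` (units x
#'   (blocks*bins) matrix), `raw_rates` (pre-transform Hz), `bins` per
#'   block, `blocks`, `time_s` bin centres, `units` metadata.
#' @export
build_activity_matrix <- function(dataset, window = c(-0.1, 3),
                                  bin_s = 0.01, sigma_bins = 2,
                                  zscore = c("across_blocks",
                                             "per_block_baseline", "none"),
                                  order = c("zscore_first", "smooth_first")) {
  zscore <- match.arg(zscore)
  order <- match.arg(order)
  n_bins <- round((window[2] - window[1]) / bin_s)
  edges <- window[1] + bin_s * (0:n_bins)
  blocks <- sort(unique(dataset$trials$block))
  if (!length(blocks)) stop("empty block: dataset has no trials")
  ids <- dataset$units$unit_id
  sp <- split(dataset$spikes$time_s, dataset$spikes$unit_id)
  raw <- matrix(0, length(ids), n_bins * length(blocks))
  for (b in seq_along(blocks)) {
    tr <- dataset$trials[dataset$trials$block == blocks[b], ]
    if (!nrow(tr)) stop("empty block ", blocks[b])
    cols <- (b - 1) * n_bins + seq_len(n_bins)
    for (i in seq_along(ids)) {
      st <- sp[[as.character(ids[i])]]
      if (is.null(st)) next
      acc <- numeric(n_bins)
      for (on in tr$onset_s) {
        rel <- st[st >= on + window[1] & st < on + window[2]] - on
        if (length(rel))
          acc <- acc + tabulate(findInterval(rel, edges), n_bins)
      }
      raw[i, cols] <- acc / nrow(tr) / bin_s  # Hz
    }
  }
  x <- raw
  zfun <- function(m) {
    t(apply(m, 1, function(r) {
      if (zscore == "none") return(r)
      if (zscore == "across_blocks") {
        s <- sd(r); if (s == 0) return(r * 0)
        return((r - mean(r)) / s)
      }
      # per-block baseline: bins before the sound onset of each block
      out <- r
      base_idx <- which(rep(seq_len(n_bins) * bin_s + window[1] <= 0,
                            length(blocks)))
      for (b in seq_along(blocks)) {
        cols <- (b - 1) * n_bins + seq_len(n_bins)
        bb <- intersect(cols, base_idx)
        mu <- mean(r[bb]); s <- sd(r[bb])
        out[cols] <- if (is.na(s) || s == 0) r[cols] - mu else (r[cols] - mu) / s
      }
      out
    }))
  }
  sfun <- function(m) {
    if (sigma_bins <= 0) return(m)
    for (b in seq_along(blocks)) {          # smooth within block
      cols <- (b - 1) * n_bins + seq_len(n_bins)
      m[, cols] <- t(apply(m[, cols, drop = FALSE], 1, gauss_smooth,
                           sigma_bins = sigma_bins))
    }
    m
  }
  x <- if (order == "zscore_first") sfun(zfun(x)) else zfun(sfun(x))
  structure(list(rates = x, raw_rates = raw, n_bins = n_bins,
                 blocks = blocks, bin_s = bin_s, window = window,
                 time_s = window[1] + bin_s * (seq_len(n_bins) - 0.5),
                 units = dataset$units, sigma_bins = sigma_bins,
                 zscore = zscore),
            class = "activity_matrix")
}

#' Activity-based hierarchical clustering of units
#'
#' Excludes units with fewer than `min_active` active bins (raw rate at or
#' above `active_rate_hz`) across all blocks, extracts the top
#' `n_loadings` principal-component scores of the activity matrix per
#' unit, clusters them with Ward linkage, cuts the tree into `n_clusters`
#' flat clusters, and names each cluster by the dominant primary tuning of
#' its units (`"state"` when the cluster shows a significant baseline
#' shift between the first and last block, Wilcoxon signed-rank with
#' Bonferroni correction).
#'
#' @param am an `activity_matrix`.
#' @param tuning optional `tuning_table` for cluster naming.
#' @param n_clusters flat clusters cut from the Ward tree.
#' @param n_loadings PCs retained as features.
#' @param active_rate_hz,min_active activity filter.
#' @return list: `labels` (per retained unit), `names` (per cluster),
#'   `excluded` (unit ids), `tree` (the hclust object).
#' @export
activity_cluster <- function(am, tuning = NULL, n_clusters = 15,
                             n_loadings = 20, active_rate_hz = 0.5,
                             min_active = 200) {
  active <- rowSums(am$raw_rates >= active_rate_hz)
  keep <- active >= min_active
  if (sum(keep) < 20) stop("fewer than 20 units retained by the activity filter")
  x <- am$rates[keep, , drop = FALSE]
  n_loadings <- min(n_loadings, sum(keep) - 1, ncol(x))
  scores <- pc_scores(x, n_loadings)
  hc <- hclust(dist(scores), method = "ward.D2")
  labels <- cutree(hc, k = min(n_clusters, sum(keep)))
  ids <- am$units$unit_id[keep]
  cl_names <- rep(NA_character_, max(labels))
  if (!is.null(tuning)) {
    n_bl <- length(am$blocks)
    base_cols_first <- which(am$time_s <= 0)
    base_cols_last <- (n_bl - 1) * am$n_bins + base_cols_first
    for (cl in seq_len(max(labels))) {
      u_idx <- which(keep)[labels == cl]
      b1 <- rowMeans(am$raw_rates[u_idx, base_cols_first, drop = FALSE])
      b4 <- rowMeans(am$raw_rates[u_idx, base_cols_last, drop = FALSE])
      p_state <- if (length(u_idx) >= 5 && !all(b1 == b4))
        suppressWarnings(wilcox.test(b1, b4, paired = TRUE,
                                     exact = FALSE)$p.value) else 1
      if (p_state < 0.05 / max(labels)) { cl_names[cl] <- "state"; next }
      tt <- tuning[tuning$unit_id %in% ids[labels == cl], ]
      if (nrow(tt)) {
        prim <- sort(table(tt$primary), decreasing = TRUE)
        cl_names[cl] <- switch(names(prim)[1],
                               opto = "opto", airpuff = "air puff",
                               sound1 = "sound", sound2 = "sound",
                               names(prim)[1])
      }
    }
  }
  list(labels = labels, names = cl_names, excluded = am$units$unit_id[!keep],
       tree = hc, unit_id = ids)
}

# linear-SVM weight vector separating two sets of population vectors
# (columns of x); class-balanced, cost 1
svm_weights <- function(x0, x1) {
  if (!ncol(x0) || !ncol(x1)) stop("single-class epoch labels")
  dat <- t(cbind(x0, x1))
  y <- factor(rep(c(0, 1), c(ncol(x0), ncol(x1))))
  wts <- 1 / table(y); wts <- wts / sum(wts) * 2
  fit <- e1071::svm(dat, y, kernel = "linear", cost = 1, scale = FALSE,
                    class.weights = wts)
  w <- drop(t(fit$coefs) %*% fit$SV)
  as.numeric(w)
}

#' Population activity modes
#'
#' Computes linear-SVM weight vectors for three task contrasts on the
#' trial-averaged (50 ms bin) mean-subtracted activity: `sound`
#' (200 ms before vs after the sound onset), an aversive mode (either
#' `opto-OR-airpuff`: aversive epochs of blocks 2/4 vs the matching epochs
#' of blocks 1/3, or `opto-AND-airpuff`: optogenetic vs air-puff epochs)
#' and `state` (1 s pre-sound baseline, first vs last block). The three
#' vectors are orthogonalised by QR decomposition into W (units x 3,
#' `W'W = I`), and the activity of every block is projected as `W'X`.
#'
#' @param am an `activity_matrix` built at 50 ms bins over a window
#'   including 1 s of pre-sound baseline (e.g. `c(-1.1, 3)`), z-scoring
#'   `"none"`; the mode computation subtracts the per-unit mean itself.
#' @param aversive `"or"` or `"and"` aversive contrast.
#' @param opto_onset_s,airpuff_onset_s event onsets relative to the sound
#'   onset (s).
#' @param groups optional factor over units (genotype or region); per-level
#'   projections use the corresponding rows of W only.
#' @return object of class `mode_set`: `W`, `mode_names`, `projections`
#'   (list per block of 3 x bins), `group_projections` (optional).
#' @export
compute_activity_modes <- function(am, aversive = c("or", "and"),
                                   opto_onset_s = 0.7,
                                   airpuff_onset_s = 0.7,
                                   groups = NULL) {
  aversive <- match.arg(aversive)
  x <- am$rates
  x <- sweep(x, 1, rowMeans(x))           # per-unit mean across blocks
  n_bins <- am$n_bins
  tt <- am$time_s
  n_bl <- length(am$blocks)
  bcols <- function(b) (b - 1) * n_bins + seq_len(n_bins)
  in_win <- function(t0, t1) which(tt >= t0 & tt < t1)
  # sound contrast: all blocks, 200 ms before vs after onset
  pre <- unlist(lapply(seq_len(n_bl), function(b) bcols(b)[in_win(-0.2, 0)]))
  post <- unlist(lapply(seq_len(n_bl), function(b) bcols(b)[in_win(0, 0.2)]))
  v_sound <- svm_weights(x[, pre, drop = FALSE], x[, post, drop = FALSE])
  opto_cols <- bcols(2)[in_win(opto_onset_s, opto_onset_s + 0.5)]
  air_cols <- bcols(4)[in_win(airpuff_onset_s, airpuff_onset_s + 0.5)]
  if (aversive == "or") {
    ctrl <- c(bcols(1)[in_win(opto_onset_s, opto_onset_s + 0.5)],
              bcols(3)[in_win(airpuff_onset_s, airpuff_onset_s + 0.5)])
    v_avers <- svm_weights(x[, ctrl, drop = FALSE],
                           x[, c(opto_cols, air_cols), drop = FALSE])
    avers_name <- "opto-OR-airpuff"
  } else {
    v_avers <- svm_weights(x[, opto_cols, drop = FALSE],
                           x[, air_cols, drop = FALSE])
    avers_name <- "opto-AND-airpuff"
  }
  base1 <- bcols(1)[in_win(-1.1, -0.1)]
  base4 <- bcols(n_bl)[in_win(-1.1, -0.1)]
  v_state <- svm_weights(x[, base1, drop = FALSE],
                         x[, base4, drop = FALSE])
  V <- cbind(v_sound, v_avers, v_state)
  qd <- qr(V)
  W <- qr.Q(qd)
  sgn <- sign(colSums(W * V)); sgn[sgn == 0] <- 1
  W <- sweep(W, 2, sgn, `*`)
  mode_names <- c("sound", avers_name, "state")
  colnames(W) <- mode_names
  proj <- lapply(seq_len(n_bl), function(b)
    t(W) %*% x[, bcols(b), drop = FALSE])
  names(proj) <- paste0("block", am$blocks)
  gp <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    gp <- lapply(levels(groups), function(g) {
      rows <- which(groups == g)
      lapply(seq_len(n_bl), function(b)
        t(W[rows, , drop = FALSE]) %*% x[rows, bcols(b), drop = FALSE])
    })
    names(gp) <- levels(groups)
  }
  structure(list(W = W, mode_names = mode_names, projections = proj,
                 group_projections = gp, svm_vectors = V,
                 time_s = am$time_s),
            class = "mode_set")
}

#' Decode block identity from pre-trial baseline activity
#'
#' Bins the (-2.1, -0.1) s pre-sound baseline of each trial at 100 ms,
#' concatenates the two blocks' time bins, z-scores within unit, removes
#' units without baseline spikes, then repeatedly (i) samples a unit
#' subset, (ii) splits time bins 50/50 stratified by block, (iii) trains an
#' L2-regularised logistic regression and records test accuracy (repeated
#' twofold cross-validation; both folds are evaluated).
#'
#' @param dataset a `spike_dataset`.
#' @param blocks the two decoded blocks.
#' @param subset_sizes unit-subset sizes; truncated at the available units.
#' @param repeats repeats per subset size.
#' @param seed integer seed.
#' @param bin_s baseline bin width (s).
#' @param window baseline window relative to the sound onset (s).
#' @param lambda ridge penalty of the logistic regression.
#' @return data.frame `n_units`, `mean_accuracy`, `sd_accuracy`; class
#'   `decoding_curve`.
#' @export
decode_block_identity <- function(dataset, blocks = c(1, 2),
                                  subset_sizes = seq(5, 150, by = 5),
                                  repeats = 50, seed = 1, bin_s = 0.1,
                                  window = c(-2.1, -0.1), lambda = 0.01) {
  n_bins <- round((window[2] - window[1]) / bin_s)
  edges <- window[1] + bin_s * (0:n_bins)
  ids <- dataset$units$unit_id
  sp <- split(dataset$spikes$time_s, dataset$spikes$unit_id)
  cols <- list()
  lab <- integer(0)
  for (b in blocks) {
    tr <- dataset$trials[dataset$trials$block == b, ]
    m <- matrix(0, length(ids), nrow(tr) * n_bins)
    for (i in seq_along(ids)) {
      st <- sp[[as.character(ids[i])]]
      if (is.null(st)) next
      for (k in seq_len(nrow(tr))) {
        on <- tr$onset_s[k]
        rel <- st[st >= on + window[1] & st < on + window[2]] - on
        if (length(rel))
          m[i, (k - 1) * n_bins + seq_len(n_bins)] <-
            tabulate(findInterval(rel, edges), n_bins)
      }
    }
    cols[[length(cols) + 1]] <- m
    lab <- c(lab, rep(b, ncol(m)))
  }
  X <- do.call(cbind, cols)
  keep <- rowSums(X) > 0                   # units with baseline spikes
  X <- X[keep, , drop = FALSE]
  X <- t(apply(X, 1, function(r) {
    s <- sd(r); if (s == 0) r * 0 else (r - mean(r)) / s
  }))
  n_avail <- nrow(X)
  subset_sizes <- subset_sizes[subset_sizes <= n_avail]
  if (!length(subset_sizes)) stop("need at least 5 units with baseline spikes")
  y <- as.integer(lab == blocks[2])
  i1 <- which(y == 0); i2 <- which(y == 1)
  res <- with_seed(seed, {
    out <- lapply(subset_sizes, function(ns) {
      acc <- numeric(repeats)
      for (r in seq_len(repeats)) {
        u <- sample.int(n_avail, ns)
        tr1 <- sample(i1, floor(length(i1) / 2))
        tr2 <- sample(i2, floor(length(i2) / 2))
        train <- c(tr1, tr2)
        test <- setdiff(seq_along(y), train)
        a <- numeric(2)
        for (f in 1:2) {
          tri <- if (f == 1) train else test
          tei <- if (f == 1) test else train
          fit <- glmnet::glmnet(t(X[u, tri, drop = FALSE]), y[tri],
                                family = "binomial", alpha = 0,
                                lambda = lambda, standardize = FALSE)
          p <- predict(fit, t(X[u, tei, drop = FALSE]), type = "response")
          a[f] <- mean((p > 0.5) == (y[tei] == 1))
        }
        acc[r] <- mean(a)
      }
      data.frame(n_units = ns, mean_accuracy = mean(acc) * 100,
                 sd_accuracy = sd(acc) * 100)
    })
    do.call(rbind, out)
  })
  class(res) <- c("decoding_curve", class(res))
  res
}

#' Principal-component trajectories per block
#'
#' For each block, performs PCA on the pooled trial-averaged activity
#' (time bins x units) of a random subset of units per group, and projects
#' each group's activity onto the common loadings.
#'
#' @param am an `activity_matrix`.
#' @param groups factor over units (e.g. genotype).
#' @param n_units units drawn per group (all, with a warning, if fewer).
#' @param n_pcs components retained.
#' @param seed integer seed for the subset draw.
#' @return list per block: `trajectory` (bins x n_pcs, pooled),
#'   `group_trajectories`, `explained` (variance fractions).
#' @export
pca_trajectories <- function(am, groups = NULL, n_units = 550, n_pcs = 3,
                             seed = 1) {
  n_total <- nrow(am$rates)
  if (is.null(groups)) groups <- factor(rep("all", n_total))
  groups <- as.factor(groups)
  sel <- with_seed(seed, {
    unlist(lapply(levels(groups), function(g) {
      gi <- which(groups == g)
      if (length(gi) < n_units) {
        warning("group ", g, ": only ", length(gi), " units available")
        gi
      } else sample(gi, n_units)
    }))
  })
  n_bins <- am$n_bins
  out <- lapply(seq_along(am$blocks), function(b) {
    cols <- (b - 1) * n_bins + seq_len(n_bins)
    Xt <- t(am$rates[sel, cols, drop = FALSE])   # bins x units
    p <- prcomp(Xt, center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(p$rotation))
    gt <- lapply(levels(groups), function(g) {
      rows <- which(groups[sel] == g)
      sweep(Xt[, rows, drop = FALSE], 2,
            p$center[rows]) %*% p$rotation[rows, seq_len(k), drop = FALSE]
    })
    names(gt) <- levels(groups)
    list(trajectory = p$x[, seq_len(k), drop = FALSE],
         group_trajectories = gt,
         explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
  })
  names(out) <- paste0("block", am$blocks)
  out
}
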