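# Consensus cell-type classification: normalisation, PCA, Ward + SNN/Louvain
# clustering, label alignment, accuracy vs a reference labelling, and soma
# morphometry scores.

#' Normalise an intrinsic-feature matrix
#'
#' Column-wise: shift positive (subtract the column minimum), divide by the
#' column sum and scale by 10,000, apply `log(1 + x)`, then z-score.
#' Constant columns (zero variance after the transforms) are set to all
#' zeros with a warning rather than dropped.
#'
#' @param m numeric matrix or data.frame (neurons x features), no missing
#'   values.
#' @return matrix of the same shape; columns have mean 0 and s.d. 1 except
#'   constant columns (all zero).
#' @export
normalize_features <- function(m) {
  m <- as.matrix(m)
  if (!length(m)) stop("empty feature matrix")
  if (anyNA(m)) stop("missing values: impute or drop features upstream")
  storage.mode(m) <- "double"
  out <- apply(m, 2, function(x) {
    x <- x - min(x)
    s <- sum(x)
    if (s > 0) x <- x / s * 10000
    log1p(x)
  })
  out <- matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  sds <- apply(out, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sum(const), " constant feature column(s) set to zero")
    out[, const] <- 0
  }
  if (any(!const))
    out[, !const] <- scale(out[, !const, drop = FALSE])
  out
}

# replace NA in structurally-absent features (no ADP/AHP etc.) by an
# explicit zero; drops columns that are entirely missing
#' Impute missing features for clustering
#'
#' Afterpotential amplitudes and similar features are structurally absent
#' for some firing types; for clustering their absence is informative and is
#' encoded as an explicit 0. Columns that are missing for every neuron are
#' dropped.
#'
#' @param df feature data.frame from [extract_feature_table()].
#' @return numeric matrix without missing values.
#' @export
impute_features <- function(df) {
  num <- df[vapply(df, is.numeric, logical(1))]
  m <- as.matrix(num)
  all_na <- colSums(!is.na(m)) == 0
  m <- m[, !all_na, drop = FALSE]
  m[is.na(m)] <- 0
  m
}

# principal-component scores with a deterministic sign convention: the
# largest-magnitude loading of each component is positive
pc_scores <- function(x, n_pcs = 4) {
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(p$rotation))
  rot <- p$rotation[, seq_len(n_pcs), drop = FALSE]
  flip <- apply(rot, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  sweep(p$x[, seq_len(n_pcs), drop = FALSE], 2, flip, `*`)
}

# all permutations of 1..n (n <= 8)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Align two labelings by maximum-overlap matching
#'
#' Finds the one-to-one mapping of `from` clusters onto `to` clusters
#' maximising the total contingency overlap (exhaustive assignment for up
#' to 8 clusters, greedy beyond).
#'
#' @param from,to label vectors of equal length (factors or characters).
#' @return named character vector mapping each `from` level to a `to`
#'   level.
#' @export
match_labels <- function(from, to) {
  tab <- table(from, to)
  fl <- rownames(tab); tl <- colnames(tab)
  nf <- length(fl); nt <- length(tl)
  k <- max(nf, nt)
  m <- matrix(0, k, k)
  m[seq_len(nf), seq_len(nt)] <- tab
  if (k <= 8) {
    pp <- perms(k)
    best <- NULL; best_s <- -Inf
    for (r in seq_len(nrow(pp))) {
      s <- sum(m[cbind(seq_len(k), pp[r, ])])
      if (s > best_s) { best_s <- s; best <- pp[r, ] }
    }
    assign_to <- best
  } else {
    # greedy: repeatedly take the largest remaining cell
    assign_to <- rep(NA_integer_, k)
    mm <- m
    for (i in seq_len(k)) {
      ij <- arrayInd(which.max(mm), dim(mm))
      assign_to[ij[1]] <- ij[2]
      mm[ij[1], ] <- -1; mm[, ij[2]] <- -1
    }
  }
  map <- setNames(rep(NA_character_, nf), fl)
  for (i in seq_len(nf)) {
    j <- assign_to[i]
    map[i] <- if (j <= nt) tl[j] else paste0("unmatched_", i)
  }
  map
}

# shared-nearest-neighbour graph (Jaccard weights, Seurat-style pruning)
snn_graph <- function(x, k = 20, prune = 1 / 15) {
  n <- nrow(x)
  if (n <= k) stop("need more cells than the neighbourhood size k")
  d <- as.matrix(dist(x))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # ties broken by index order
    nn[i, ] <- setdiff(ord, i)[seq_len(k)]
  }
  nb <- lapply(seq_len(n), function(i) c(i, nn[i, ]))  # include self
  edges <- list(); wts <- list(); e <- 0L
  for (i in seq_len(n)) {
    cand <- unique(c(nn[i, ], which(vapply(seq_len(n), function(j)
      i %in% nn[j, ], logical(1)))))
    cand <- cand[cand > i]
    for (j in cand) {
      ov <- length(intersect(nb[[i]], nb[[j]]))
      w <- ov / (2 * (k + 1) - ov)
      if (w > prune) { e <- e + 1L; edges[[e]] <- c(i, j); wts[[e]] <- w }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (e > 0)
    g <- igraph::add_edges(g, unlist(edges),
                           attr = list(weight = unlist(wts)))
  g
}

#' Consensus clustering of neurons by intrinsic features
#'
#' Normalises the feature matrix, reduces to the first four principal
#' components, then clusters twice: hierarchically (Ward linkage, cut at
#' `k_hier` clusters) and on a shared-nearest-neighbour graph (k = `knn`)
#' with Louvain community detection at the given resolution. The graph
#' labels are aligned to the hierarchical labels by maximum-overlap
#' matching; cells on which the two methods disagree are discarded
#' (consensus label `NA`). A 2-D t-SNE embedding of the PCs is attached for
#' reporting.
#'
#' @param features numeric matrix (neurons x features, no NA) or data.frame
#'   from [extract_feature_table()] (imputed via [impute_features()]).
#' @param k_hier number of hierarchical clusters.
#' @param knn neighbourhood size of the SNN graph.
#' @param resolution Louvain resolution.
#' @param seed integer seed (Louvain initialisation and t-SNE).
#' @param expert optional reference labels for the accuracy summary.
#' @param n_pcs number of principal components retained.
#' @param perplexity t-SNE perplexity.
#' @param n_shuffles shuffles for the chance-accuracy estimate.
#' @return object of class `typing_result`: data.frame `cells` (columns
#'   `hier`, `graph`, `consensus`, embedding coordinates, PCs), and a
#'   `summary` list (`n_discarded`, and when `expert` is given `accuracy_pct`
#'   and `chance_pct`).
#' @export
consensus_cluster <- function(features, k_hier = 6, knn = 20,
                              resolution = 1.5, seed = 1, expert = NULL,
                              n_pcs = 4, perplexity = 30,
                              n_shuffles = 10000) {
  if (is.data.frame(features)) features <- impute_features(features)
  norm <- normalize_features(features)
  pcs <- pc_scores(norm, n_pcs)
  hc <- hclust(dist(pcs), method = "ward.D2")
  hier <- cutree(hc, k = k_hier)
  g <- snn_graph(pcs, k = knn)
  graph <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  graph <- as.integer(graph)
  map <- match_labels(graph, hier)
  graph_aligned <- suppressWarnings(as.integer(map[as.character(graph)]))
  consensus <- ifelse(!is.na(graph_aligned) & graph_aligned == hier,
                      hier, NA_integer_)
  emb <- embed_2d(pcs, perplexity = perplexity, seed = seed)
  cells <- data.frame(hier = hier, graph = graph,
                      graph_aligned = graph_aligned,
                      consensus = consensus,
                      tsne1 = emb[, 1], tsne2 = emb[, 2])
  cells <- cbind(cells, as.data.frame(pcs))
  summary <- list(n_discarded = sum(is.na(consensus)),
                  n_consensus_clusters = length(unique(na.omit(consensus))))
  if (!is.null(expert)) {
    keep <- !is.na(consensus)
    acc <- clustering_accuracy(consensus[keep], expert[keep],
                               n_shuffles = n_shuffles, seed = seed)
    summary$accuracy_pct <- acc$accuracy_pct
    summary$chance_pct <- acc$chance_pct
  }
  structure(list(cells = cells, summary = summary), class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat("<typing_result>", nrow(x$cells), "cells,",
      x$summary$n_consensus_clusters, "consensus clusters,",
      x$summary$n_discarded, "discarded\n")
  if (!is.null(x$summary$accuracy_pct))
    cat("  accuracy", round(x$summary$accuracy_pct, 1), "% (chance",
        round(x$summary$chance_pct, 1), "%)\n")
  invisible(x)
}

#' Clustering accuracy against a reference labelling
#'
#' Accuracy is the percentage of cells assigned to the matched cluster
#' after maximum-overlap alignment of the two labelings; chance is the mean
#' accuracy over random shuffles of the (aligned) assignment.
#'
#' @param labels,reference equal-length label vectors (discarded cells
#'   excluded beforehand).
#' @param n_shuffles number of random shuffles for the chance level.
#' @param seed integer seed for the shuffles.
#' @return list with `accuracy_pct` and `chance_pct`.
#' @export
clustering_accuracy <- function(labels, reference, n_shuffles = 10000,
                                seed = 1) {
  stopifnot(length(labels) == length(reference))
  if (!length(labels)) stop("empty overlap between labelings")
  labels <- as.character(labels); reference <- as.character(reference)
  map <- match_labels(labels, reference)
  aligned <- map[labels]
  acc <- mean(aligned == reference) * 100
  chance <- with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i)
      mean(sample(aligned) == reference), numeric(1))) * 100
  })
  list(accuracy_pct = acc, chance_pct = chance)
}

#' Soma morphometry scores
#'
#' Elliptical score E = X/Y and triangular score T = Ymajor/Yminor with the
#' standard thresholds: E < 1.8 and T < 1.2 round; E >= 1.8 and T < 1.2
#' elongated; T >= 1.2 triangular.
#'
#' @param X,Y lengths of the two perpendicular major axes.
#' @param Ymajor,Yminor chords perpendicular to X at 25\% and 75\% of its
#'   length (major/minor).
#' @return data.frame with `E`, `T` and `class`.
#' @export
soma_scores <- function(X, Y, Ymajor, Yminor) {
  if (any(c(X, Y, Ymajor, Yminor) <= 0))
    stop("soma axes must be positive")
  E <- X / Y
  T_ <- Ymajor / Yminor
  cls <- ifelse(T_ >= 1.2, "triangular",
                ifelse(E >= 1.8, "elongated", "round"))
  data.frame(E = E, T = T_, class = cls)
}
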