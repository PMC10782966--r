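#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances with the
#' Ward.D2 update (the squared-distance Lance-Williams recurrence applied
#' to unsquared Euclidean input, implementing Ward's minimum-variance
#' criterion). Lipids with any missing value are dropped from the distance
#' computation.
#'
#' @param m An `intensity_matrix` (typically `"log2_median"` state) with
#'   >= 2 samples.
#' @return An object of class `ward_cluster`: list with `merge`, `height`,
#'   `order`, `labels`, `distance` (`"euclidean"`), `linkage`
#'   (`"ward.D2"`), and the underlying `hclust` object.
#' @export
ward_cluster <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (ncol(m$values) < 2L) stop("need >= 2 samples", call. = FALSE)
  complete <- stats::complete.cases(m$values)
  x <- t(m$values[complete, , drop = FALSE])
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  structure(
    list(
      merge = hc$merge,
      height = hc$height,
      order = hc$order,
      labels = hc$labels,
      distance = "euclidean",
      linkage = "ward.D2",
      hclust = hc
    ),
    class = "ward_cluster"
  )
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat(sprintf(
    "<ward_cluster> %d samples, euclidean / ward.D2, max height %.3f\n",
    length(x$labels), max(x$height)
  ))
  invisible(x)
}

#' Cut a sample dendrogram into k clusters
#'
#' @param clustering A `ward_cluster` object.
#' @param k Number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(clustering, k) {
  stopifnot(inherits(clustering, "ward_cluster"))
  stats::cutree(clustering$hclust, k = k)
}

#' Export a dendrogram as Newick text
#'
#' @param clustering A `ward_cluster` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
cluster_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "ward_cluster"))
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# ---- PLS-DA (NIPALS) -------------------------------------------------------

# NIPALS PLS1 on a centered/scaled X and centered y; returns regression
# coefficients (on the processed scale) and scores.
.pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- X
  yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  if (ncomp == 0L) stop("X has no covariance with the labels", call. = FALSE)
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # B = W (P'W)^-1 q
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = B, scores = Tm, ncomp = ncomp)
}

.pls_preprocess <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv,
       X = sweep(sweep(X, 2, mu, "-"), 2, sdv, "/"))
}

#' Partial least squares discriminant analysis with leave-one-out Q2
#'
#' Two-class PLS-DA: a NIPALS PLS1 regression of a 0/1 class indicator on
#' the autoscaled lipid matrix with (by default) two latent variables.
#' Reports in-fit scores and R2 (fraction of indicator variance explained),
#' leave-one-out classification accuracy (predicted indicator cut at 0.5),
#' and the leave-one-out predictive Q2 = 1 - PRESS/TSS.
#'
#' @param m An `intensity_matrix` (samples are classified) or a numeric
#'   samples-by-features matrix.
#' @param labels Two-level factor (or coercible) of length n samples, each
#'   class >= 3 samples; may also be the name of a `sample_meta` column.
#' @param n_components Number of latent variables (default 2).
#' @return An object of class `plsda_report`: `n_components`, `scores`
#'   (n x ncomp), `accuracy`, `R2`, `Q2`, `labels`, `loocv_predictions`.
#' @export
plsda <- function(m, labels, n_components = 2) {
  if (inherits(m, "intensity_matrix")) {
    if (is.character(labels) && length(labels) == 1L &&
        !is.null(m$sample_meta) && labels %in% names(m$sample_meta)) {
      labels <- m$sample_meta[[labels]]
    }
    X <- t(m$values)
  } else {
    X <- as.matrix(m)
  }
  if (anyNA(X)) stop("PLS-DA requires a complete matrix", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) < 3L)) stop("each class needs >= 3 samples", call. = FALSE)
  stopifnot(length(labels) == nrow(X))
  y <- as.numeric(labels) - 1 # 0/1 indicator
  n <- nrow(X)

  prep <- .pls_preprocess(X)
  yc <- y - mean(y)
  fit <- .pls1_fit(prep$X, yc, n_components)
  yhat_in <- as.numeric(prep$X %*% fit$coef) + mean(y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - yhat_in)^2) / tss

  # leave-one-out
  yhat_loo <- numeric(n)
  for (i in seq_len(n)) {
    prep_i <- .pls_preprocess(X[-i, , drop = FALSE])
    yi <- y[-i]
    fit_i <- .pls1_fit(prep_i$X, yi - mean(yi), n_components)
    xnew <- (X[i, ] - prep_i$mu) / prep_i$sd
    yhat_loo[i] <- sum(xnew * fit_i$coef) + mean(yi)
  }
  press <- sum((y - yhat_loo)^2)
  q2 <- 1 - press / tss
  pred_class <- levels(labels)[(yhat_loo >= 0.5) + 1L]
  accuracy <- mean(pred_class == as.character(labels))

  scores <- fit$scores
  rownames(scores) <- rownames(X)
  structure(
    list(
      n_components = fit$ncomp,
      scores = scores,
      accuracy = accuracy,
      R2 = r2,
      Q2 = q2,
      labels = labels,
      loocv_predictions = yhat_loo
    ),
    class = "plsda_report"
  )
}

#' @export
print.plsda_report <- function(x, ...) {
  cat(sprintf(
    "<plsda_report> %d components: accuracy %.3f, R2 %.3f, Q2 %.3f\n",
    x$n_components, x$accuracy, x$R2, x$Q2
  ))
  invisible(x)
}

#' ROC area under the curve (Mann-Whitney formulation)
#'
#' AUC = P(score of a positive > score of a negative), ties counting 1/2 —
#' computed from midranks.
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Two-level factor/logical; the positive class is `TRUE` or
#'   the second factor level (override with `positive`).
#' @param positive Optional explicit positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)) # 1
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have two classes", call. = FALSE)
    if (is.null(positive)) positive <- levels(labels)[2]
    pos <- labels == positive
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- MCCV random-forest biomarker procedure --------------------------------

# stratified 2/3-1/3 split of indices grouped by class
.split_two_thirds <- function(idx_by_class) {
  train <- valid <- integer(0)
  for (idx in idx_by_class) {
    n_tr <- max(1L, round(2 / 3 * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    shuffled <- sample(idx)
    train <- c(train, shuffled[seq_len(n_tr)])
    valid <- c(valid, shuffled[-seq_len(n_tr)])
  }
  list(train = train, valid = valid)
}

#' Monte-Carlo cross-validated random-forest biomarker ranking
#'
#' The multivariate exploratory ROC procedure: in each of `n_rounds`
#' rounds, the majority class is downsampled to the minority size (balanced
#' subsampling), the balanced set is split stratified two-thirds train /
#' one-third validation, a random forest is fitted on the training
#' two-thirds to rank all features, and for each candidate panel size a
#' forest refitted on that round's top-ranked features is scored on the
#' held-out third (ROC AUC of its class votes). Features are finally ranked
#' by mean importance across rounds; the selected panel is the top
#' `panel_size` features of that ranking, and predictive accuracy is the
#' mean held-out vote accuracy at that panel size.
#'
#' @param m An `intensity_matrix` or samples-by-features numeric matrix.
#' @param labels Two-level class labels (each class >= 3 samples), or a
#'   `sample_meta` column name.
#' @param panel_sizes Candidate panel sizes to evaluate.
#' @param n_rounds Number of MCCV rounds (default 100; < 10 warns).
#' @param panel_size Panel size of the reported selected panel (default 15).
#' @param seed Integer seed making the whole procedure reproducible.
#' @param ntree,importance_measure Random-forest hyperparameters: 500 trees
#'   and `sqrt(p)` features per split (the `randomForest` default) are
#'   conventional; importance is mean decrease in Gini by default, or
#'   `"permutation"` for mean decrease in accuracy.
#' @return An object of class `biomarker_report`: `ranking` (tibble
#'   `lipid_id`, `mean_importance`, `rank`), `panel_auc` (tibble
#'   `panel_size`, `mean_auc`, `sd_auc`, `ci_lower`, `ci_upper`),
#'   `accuracy` (held-out accuracy at `panel_size`), `selected_panel`,
#'   `panel_size`, `n_rounds`, `seed`, `hyperparameters`.
#' @export
rf_biomarker_mccv <- function(m, labels,
                              panel_sizes = c(3, 5, 10, 15, 25, 50),
                              n_rounds = 100, panel_size = 15,
                              seed = NULL, ntree = 500,
                              importance_measure = c("gini", "permutation")) {
  importance_measure <- match.arg(importance_measure)
  if (inherits(m, "intensity_matrix")) {
    if (is.character(labels) && length(labels) == 1L &&
        !is.null(m$sample_meta) && labels %in% names(m$sample_meta)) {
      labels <- m$sample_meta[[labels]]
    }
    X <- t(m$values)
  } else {
    X <- as.matrix(m)
  }
  if (anyNA(X)) stop("the biomarker procedure requires a complete matrix", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) < 3L)) stop("each class needs >= 3 samples", call. = FALSE)
  stopifnot(length(labels) == nrow(X))
  panel_sizes <- sort(unique(as.integer(panel_sizes)))
  if (any(panel_sizes < 1L) || any(panel_sizes > ncol(X))) {
    stop("panel sizes must lie in [1, number of lipids]", call. = FALSE)
  }
  if (!panel_size %in% panel_sizes) panel_sizes <- sort(c(panel_sizes, panel_size))
  if (n_rounds < 10) warning("fewer than 10 MCCV rounds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  feat_names <- colnames(X)
  if (is.null(feat_names)) {
    feat_names <- sprintf("feature_%d", seq_len(ncol(X)))
    colnames(X) <- feat_names
  }
  pos_level <- levels(labels)[2]
  minority_n <- min(table(labels))
  imp_sum <- stats::setNames(numeric(ncol(X)), feat_names)
  auc_mat <- matrix(NA_real_, n_rounds, length(panel_sizes),
                    dimnames = list(NULL, panel_sizes))
  acc <- numeric(n_rounds)
  imp_type <- if (importance_measure == "gini") 2L else 3L

  for (r in seq_len(n_rounds)) {
    # balanced subsample: downsample the majority class to the minority size
    idx_by_class <- lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      if (length(idx) > minority_n) sample(idx, minority_n) else idx
    })
    split <- .split_two_thirds(idx_by_class)
    x_tr <- X[split$train, , drop = FALSE]
    y_tr <- droplevels(labels[split$train])
    x_va <- X[split$valid, , drop = FALSE]
    y_va <- labels[split$valid]

    rf_full <- randomForest::randomForest(
      x_tr, y_tr, ntree = ntree,
      importance = (importance_measure == "permutation")
    )
    imp <- randomForest::importance(
      rf_full,
      type = if (importance_measure == "gini") 2 else 1
    )[, 1]
    imp_sum <- imp_sum + imp[feat_names]
    round_rank <- feat_names[order(-imp[feat_names], feat_names)]

    for (j in seq_along(panel_sizes)) {
      s <- panel_sizes[j]
      top <- round_rank[seq_len(s)]
      rf_s <- randomForest::randomForest(
        x_tr[, top, drop = FALSE], y_tr, ntree = ntree
      )
      votes <- stats::predict(rf_s, x_va[, top, drop = FALSE], type = "vote")
      score <- votes[, pos_level]
      auc_mat[r, j] <- roc_auc(score, y_va, positive = pos_level)
      if (s == panel_size) {
        pred <- stats::predict(rf_s, x_va[, top, drop = FALSE])
        acc[r] <- mean(pred == y_va)
      }
    }
  }

  mean_imp <- imp_sum / n_rounds
  ord <- order(-mean_imp, feat_names)
  ranking <- tibble(
    lipid_id = feat_names[ord],
    mean_importance = unname(mean_imp[ord]),
    rank = seq_along(ord)
  )
  panel_auc <- tibble(
    panel_size = panel_sizes,
    mean_auc = colMeans(auc_mat),
    sd_auc = apply(auc_mat, 2, stats::sd),
    ci_lower = colMeans(auc_mat) - 1.96 * apply(auc_mat, 2, stats::sd) / sqrt(n_rounds),
    ci_upper = colMeans(auc_mat) + 1.96 * apply(auc_mat, 2, stats::sd) / sqrt(n_rounds)
  )
  structure(
    list(
      ranking = ranking,
      panel_auc = panel_auc,
      accuracy = mean(acc),
      selected_panel = ranking$lipid_id[seq_len(panel_size)],
      panel_size = panel_size,
      n_rounds = n_rounds,
      seed = seed,
      hyperparameters = list(
        ntree = ntree, mtry = "sqrt(p)",
        importance = importance_measure,
        split = "2/3 train / 1/3 validation, stratified",
        balancing = "majority class downsampled to minority size"
      )
    ),
    class = "biomarker_report"
  )
}

#' @export
print.biomarker_report <- function(x, ...) {
  auc_at <- x$panel_auc$mean_auc[x$panel_auc$panel_size == x$panel_size]
  cat(sprintf(
    "<biomarker_report> %d MCCV rounds; panel of %d lipids: AUC %.3f, accuracy %.3f\n",
    x$n_rounds, x$panel_size, auc_at, x$accuracy
  ))
  cat("  top lipids:", paste(utils::head(x$selected_panel, 5), collapse = ", "),
      "...\n")
  invisible(x)
}
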