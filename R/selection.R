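#' Feature table construction
#'
#' A feature table holds one row per image: its anatomy id (the pairing key
#' across noise levels), its noise level in percent, and the feature
#' columns. Every (anatomy id, noise level) pair must be unique so that
#' observations can be paired across levels.
#'
#' @param features numeric matrix or data.frame of feature columns.
#' @param anatomy_id integer vector, one per row.
#' @param noise_level numeric vector of levels in percent (1/3/5/7/9).
#' @return a data.frame with columns `anatomy_id`, `noise_level` and the
#'   features; attribute `features` lists the feature column names.
#' @export
feature_table <- function(features, anatomy_id, noise_level) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(anatomy_id),
            nrow(features) == length(noise_level))
  if (anyDuplicated(paste(anatomy_id, noise_level)))
    stop("each (anatomy_id, noise_level) pair may appear at most once",
         call. = FALSE)
  out <- cbind(data.frame(anatomy_id = anatomy_id,
                          noise_level = noise_level), features)
  attr(out, "features") <- names(features)
  out
}

table_features <- function(table) {
  f <- attr(table, "features")
  if (is.null(f))
    f <- setdiff(names(table),
                 c("anatomy_id", "noise_level", "noise_class", "split",
                   "bias", "thickness"))
  f
}

# paired t-test p-value on matched differences; constant differences give
# p = 1 (no discriminating evidence)
paired_p <- function(d) {
  n <- length(d)
  if (n < 3) return(NA_real_)
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero-variance paired differences: p set to 1")
    return(1)
  }
  t <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(t), df = n - 1)
}

#' Rank features by paired t-tests across noise levels
#'
#' For each feature, a paired-samples t-test is run between every unordered
#' pair of noise levels (pairing rows on `anatomy_id`), and the resulting
#' p-values are averaged. Features are ranked by ascending mean p-value
#' (ties broken lexicographically by name); those with mean p < 0.05 become
#' the candidate set for the floating selection.
#'
#' @param table a [feature_table()] (extra label columns are ignored).
#' @param alpha candidate threshold on the mean p-value.
#' @return a list with `ranked` (data.frame `feature`, `mean_p`) and
#'   `candidates` (character vector).
#' @export
ttest_rank <- function(table, alpha = 0.05) {
  feats <- table_features(table)
  levels <- sort(unique(table$noise_level))
  if (length(levels) < 2)
    stop("need at least 2 noise levels", call. = FALSE)
  pairs <- utils::combn(levels, 2)
  mean_p <- vapply(feats, function(f) {
    ps <- apply(pairs, 2, function(lv) {
      a <- table[table$noise_level == lv[1], c("anatomy_id", f)]
      b <- table[table$noise_level == lv[2], c("anatomy_id", f)]
      ids <- intersect(a$anatomy_id, b$anatomy_id)
      if (length(ids) < 3)
        stop("need >= 3 paired observations per level pair", call. = FALSE)
      paired_p(a[[f]][match(ids, a$anatomy_id)] -
               b[[f]][match(ids, b$anatomy_id)])
    })
    mean(ps)
  }, numeric(1))
  ord <- order(mean_p, feats)
  ranked <- data.frame(feature = feats[ord], mean_p = mean_p[ord],
                       row.names = NULL)
  list(ranked = ranked,
       candidates = ranked$feature[ranked$mean_p < alpha])
}

#' Sequential forward floating selection
#'
#' Classic SFFS: repeatedly add the single feature that most improves the
#' criterion, then, while it helps, conditionally remove features whose
#' exclusion beats the best subset previously seen at that size. The best
#' subset of size at most `k_max` found anywhere in the search is returned.
#' All ties are broken lexicographically by feature name, so the search is
#' deterministic given a deterministic criterion.
#'
#' @param candidates character vector of candidate feature names.
#' @param criterion function taking a character vector of feature names and
#'   returning a scalar score (higher is better).
#' @param k_max maximal subset size (the automation uses 5).
#' @param floating set `FALSE` to disable the backward exclusions, reducing
#'   the search to plain sequential forward selection.
#' @return a list with `selected` (character vector), `score`, and
#'   `criterion_trace` (data.frame of the evaluation history:
#'   `action`, `size`, `score`).
#' @export
sffs_select <- function(candidates, criterion, k_max = 5, floating = TRUE) {
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(candidates))
  cache <- new.env(parent = emptyenv())
  score_of <- function(sub) {
    key <- paste(sort(sub), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- criterion(sort(sub))
    cache[[key]] <- v
    v
  }
  trace <- list()
  note <- function(action, sub, sc)
    trace[[length(trace) + 1L]] <<- data.frame(action = action,
                                               size = length(sub),
                                               score = sc)
  # best subset seen at each size
  best_sub <- vector("list", k_max)
  best_score <- rep(-Inf, k_max)
  remember <- function(sub, sc) {
    k <- length(sub)
    if (k >= 1 && k <= k_max && sc > best_score[k]) {
      best_score[k] <<- sc
      best_sub[[k]] <<- sort(sub)
    }
  }
  cur <- character(0)
  repeat {
    pool <- setdiff(candidates, cur)
    if (length(pool) == 0 || length(cur) >= k_max) break
    sc_add <- vapply(pool, function(f) score_of(c(cur, f)), numeric(1))
    f_best <- pool[order(-sc_add, pool)][1]
    cur <- sort(c(cur, f_best))
    sc <- max(sc_add)
    remember(cur, sc)
    note("add", cur, sc)
    # conditional backward exclusions
    while (floating && length(cur) > 2) {
      sc_rm <- vapply(cur, function(f) score_of(setdiff(cur, f)),
                      numeric(1))
      r_best <- cur[order(-sc_rm, cur)][1]
      sc_r <- max(sc_rm)
      if (sc_r > best_score[length(cur) - 1]) {
        cur <- setdiff(cur, r_best)
        remember(cur, sc_r)
        note("remove", cur, sc_r)
      } else break
    }
  }
  k_star <- order(-best_score, seq_len(k_max))[1]
  list(selected = best_sub[[k_star]], score = best_score[k_star],
       criterion_trace = do.call(rbind, trace))
}

#' @rdname sffs_select
#' @param table a [feature_table()] whose rows carry `noise_level`.
#' @param folds cross-validation folds.
#' @param hidden,max_iter size and training length of the fold classifiers;
#'   kept small since the criterion is evaluated many times.
#' @param seed fold assignment and weight initialization seed.
#' @return `criterion_stage1_cv()`: a criterion closure returning the
#'   `folds`-fold cross-validated accuracy of the stage-1 noise-class
#'   classifier restricted to a feature subset.
#' @export
criterion_stage1_cv <- function(table, folds = 5, hidden = 5, max_iter = 30,
                                seed = 1L) {
  cls <- noise_class(table$noise_level)
  classes <- c("low", "median", "high")
  y <- t(vapply(cls, function(cc) as.numeric(classes == cc),
                numeric(3)))
  n <- nrow(table)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  function(subset) {
    X <- as.matrix(table[, subset, drop = FALSE])
    acc <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- pmax(apply(X[tr, , drop = FALSE], 2, stats::sd), 1e-12)
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      net <- train_network(Xs[tr, , drop = FALSE], y[tr, , drop = FALSE],
                           hidden = hidden, max_iter = max_iter,
                           seed = seed + k, val_frac = 0)
      pred <- predict_network(net, Xs[!tr, , drop = FALSE])
      acc <- acc + sum(max.col(pred, ties.method = "first") ==
                         max.col(y[!tr, , drop = FALSE],
                                 ties.method = "first"))
    }
    acc / n
  }
}
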