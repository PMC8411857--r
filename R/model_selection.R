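## Model-order selection: train/CV residual curves over a range of k and an
## explicit elbow rule.

#' Residual-sum-of-squares curve over candidate model orders
#'
#' For each candidate `k`, fits the archetype model to the full data
#' (`train_rss`) and runs 10-fold cross-validation: the rows are shuffled once
#' (seeded), split into `folds` subsets, and each subset in turn is held out,
#' decomposed against a model fit on the remaining rows, and its held-out RSS
#' recorded; `cv_rss` is the mean over folds.
#'
#' @param X numeric matrix of fields (rows) or a `vf_cohort`.
#' @param k_values candidate numbers of archetypes (default 2:20).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed (fold assignment and fit initialization).
#' @param n_restarts,max_iter,tol passed to [fit_archetypes()].
#' @return object of class `rss_curve`: data.frame with columns `k`,
#'   `train_rss`, `cv_rss`, plus attributes `folds` and `seed`.
#' @export
rss_curve <- function(X, k_values = 2:20, folds = 10L, seed = NULL,
                      n_restarts = 5L, max_iter = 200L, tol = 1e-6) {
  if (inherits(X, "vf_cohort")) X <- cohort_matrix(X)$td
  X <- as.matrix(X)
  n <- nrow(X)
  k_values <- sort(unique(as.integer(k_values)))
  if (n < max(k_values) + ceiling(n / folds)) {
    stop("not enough rows for the requested k range and fold count")
  }
  if (floor(n / folds) < 1L) stop("fold smaller than 1 row")
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  train_rss <- cv_rss <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    m <- fit_archetypes(X, k, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol)
    train_rss[i] <- m$rss
    held <- numeric(folds)
    for (f in seq_len(folds)) {
      mf <- fit_archetypes(X[fold_id != f, , drop = FALSE], k,
                           n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol)
      held[f] <- model_rss(X[fold_id == f, , drop = FALSE], mf)
    }
    cv_rss[i] <- mean(held)
  }
  structure(data.frame(k = k_values, train_rss = train_rss, cv_rss = cv_rss),
            folds = as.integer(folds),
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
            class = c("rss_curve", "data.frame"))
}

#' Select the number of archetypes at the elbow of the RSS curve
#'
#' Implements the "flattening point" rule explicitly.  The default `chord`
#' criterion min-max normalizes both axes of the (k, RSS) curve and returns
#' the k maximizing the perpendicular distance to the straight line joining
#' its first and last points.  The `relative_drop` criterion returns the
#' smallest k whose relative RSS improvement over the previous k falls below
#' `rel_tol`.
#'
#' @param curve an `rss_curve`, or a data.frame with columns `k` and the
#'   chosen RSS column.
#' @param criterion `"chord"` (default) or `"relative_drop"`.
#' @param rel_tol relative-improvement cutoff for `relative_drop`
#'   (default 0.05).
#' @param use which curve to inspect: `"cv"` (default) or `"train"`.
#' @return the selected k (integer).
#' @export
select_k_elbow <- function(curve, criterion = c("chord", "relative_drop"),
                           rel_tol = 0.05, use = c("cv", "train")) {
  criterion <- match.arg(criterion)
  use <- match.arg(use)
  col <- if (use == "cv" && "cv_rss" %in% names(curve)) "cv_rss" else "train_rss"
  k <- curve$k
  rss <- curve[[col]]
  if (length(k) < 3L) stop("need at least 3 points to locate an elbow")

  if (criterion == "relative_drop") {
    drop_rel <- (rss[-length(rss)] - rss[-1L]) / rss[-length(rss)]
    hit <- which(drop_rel < rel_tol)
    return(if (length(hit)) k[hit[1L] + 1L] else k[length(k)])
  }

  kr <- diff(range(k)); rr <- diff(range(rss))
  if (rr <= 0) {
    warning("flat RSS curve; returning smallest k")
    return(k[1L])
  }
  kn <- (k - min(k)) / kr
  rn <- (rss - min(rss)) / rr
  # distance from each point to the chord joining the endpoints
  p1 <- c(kn[1L], rn[1L]); p2 <- c(kn[length(kn)], rn[length(rn)])
  v <- p2 - p1
  dist <- abs(v[2L] * (kn - p1[1L]) - v[1L] * (rn - p1[2L])) / sqrt(sum(v^2))
  if (max(dist) < 1e-12) {
    warning("RSS curve is a straight line; returning smallest k")
    return(k[1L])
  }
  k[which.max(dist)]
}

#' @export
plot.rss_curve <- function(x, ...) {
  graphics::plot(x$k, x$train_rss, type = "b", pch = 19,
                 xlab = "number of archetypes k", ylab = "RSS",
                 ylim = range(c(x$train_rss, x$cv_rss)), ...)
  graphics::lines(x$k, x$cv_rss, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", c("training", "10-fold CV"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
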