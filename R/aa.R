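## Archetypal analysis: fitting, decomposition, RSS, serialization.
## Each observation x_i is approximated as a convex combination of k
## archetypes Z (x_i ~ alpha_i Z, alpha_i on the probability simplex), and the
## archetypes themselves are convex combinations of the observations
## (Z = beta X, beta rows on the simplex).  Both constrained least-squares
## subproblems are solved by non-negative least squares on a design augmented
## with a penalty row of weight M forcing the coefficients to sum to one.

furthest_sum_init <- function(X, k) {
  n <- nrow(X)
  if (k == 1L) return(sample.int(n, 1L))
  idx <- sample.int(n, 1L)
  sumdist <- rep(0, n)
  for (j in 2:k) {
    d <- sqrt(rowSums((X - matrix(X[idx[length(idx)], ], n, ncol(X), byrow = TRUE))^2))
    sumdist <- sumdist + d
    cand <- setdiff(order(sumdist, decreasing = TRUE), idx)
    idx <- c(idx, cand[1L])
  }
  # replace the arbitrary first pick by the point furthest from the rest
  d1 <- sqrt(rowSums((X - matrix(X[idx[2L], ], n, ncol(X), byrow = TRUE))^2))
  sd1 <- d1
  for (j in idx[-(1:2)]) {
    sd1 <- sd1 + sqrt(rowSums((X - matrix(X[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  cand <- setdiff(order(sd1, decreasing = TRUE), idx[-1L])
  idx[1L] <- cand[1L]
  idx
}

#' Fit an archetype model to a matrix of visual fields
#'
#' Fits `k` archetypes to the rows of `x` by alternating simplex-constrained
#' least squares: the per-field weights `alpha` and the archetype compositions
#' `beta` are each solved by penalized non-negative least squares, and the
#' archetypes are `beta %*% x`, i.e. convex combinations of observed fields
#' lying on the boundary of the data's convex hull.  The best of `n_restarts`
#' furthest-sum-seeded runs (by final residual sum of squares) is returned.
#' Archetypes are ordered by relative weight (the mean of their decomposition
#' weights over the fitted fields), descending, matching the convention used
#' when archetypal visual-field models are displayed.
#'
#' @param x numeric matrix (n fields x p locations, TD in dB) or a
#'   `vf_cohort` (all fields' TD vectors are used).
#' @param k number of archetypes, `1 <= k <= n`.
#' @param seed integer seed controlling initialization; fits with the same
#'   seed are bit-identical.
#' @param n_restarts independent restarts (default 5).
#' @param max_iter maximum alternating iterations per restart (default 200).
#' @param tol relative RSS change declaring convergence (default 1e-6).
#' @param M penalty multiplier for the simplex constraint row; default
#'   200 times the data scale (`max(abs(x), 1)`).
#' @return an object of class `archetype_model` with elements `k`,
#'   `archetypes` (k x p, dB), `relative_weight`, `average_td`, `rss`,
#'   `n_fit`, `alpha` (n x k training weight fractions), `seed`, `n_restarts`,
#'   `n_iterations`, `converged`, `rss_history`, `grid`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' m <- fit_archetypes(X, k = 2, seed = 1)
#' m
#' @export
fit_archetypes <- function(x, k, seed = NULL, n_restarts = 5L, max_iter = 200L,
                           tol = 1e-6, M = NULL) {
  X <- if (inherits(x, "vf_cohort")) cohort_matrix(x)$td else as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k (%d) exceeds the number of fields (%d)", k, n))
  if (k == n) warning("k equals the number of fields; archetypes are the data rows")
  if (any(!is.finite(X))) stop("x must be finite")
  if (is.null(M)) M <- 200 * max(abs(X), 1)
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- furthest_sum_init(X, k)
    fit <- aa_fit_cpp(X, k, init - 1L, as.integer(max_iter), tol, M)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (!best$converged) {
    warning("fit did not converge within max_iter; returning best iterate")
  }

  Z <- best$Z
  alpha <- best$alpha
  rw <- colMeans(alpha)
  avg_td <- rowMeans(Z)
  # order by relative weight desc; ties by average TD desc, then index
  ord <- order(-rw, -avg_td, seq_len(k))
  Z <- Z[ord, , drop = FALSE]
  alpha <- alpha[, ord, drop = FALSE]
  rw <- rw[ord]
  avg_td <- avg_td[ord]
  at_names <- paste0("AT", seq_len(k))
  rownames(Z) <- at_names
  colnames(alpha) <- at_names

  structure(list(
    k = k,
    archetypes = Z,
    relative_weight = setNames(rw, at_names),
    average_td = setNames(avg_td, at_names),
    rss = best$rss,
    n_fit = n,
    alpha = alpha,
    training = X,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_restarts = as.integer(n_restarts),
    n_iterations = best$iterations,
    converged = best$converged,
    rss_history = best$history,
    grid = if (ncol(X) == 54L) "24-2/54" else sprintf("generic/%d", ncol(X)),
    M = M,
    call = match.call()
  ), class = "archetype_model")
}

#' Decompose fields into archetype weights
#'
#' Solves, for each field, the simplex-constrained least-squares problem
#' min ||td - t(Z) w||^2 with w >= 0 and sum(w) = 1, against the fixed fitted
#' archetypes Z, and reports the weights as percentages summing to 100.  The
#' solution is deterministic.
#'
#' @param model an `archetype_model`.
#' @param fields a numeric vector (one field), a matrix (fields in rows), a
#'   `vf_field`, an `eye_series` or a `vf_cohort`.
#' @return an object of class `vf_decomposition`: list with `weights`
#'   (m x k matrix, percent), `residual_norm` (dB, per field) and `meta`
#'   (data.frame of field identities where available).
#' @export
decompose <- function(model, fields) {
  stopifnot(inherits(model, "archetype_model"))
  meta <- NULL
  if (inherits(fields, "vf_field")) fields <- eye_series(list(fields))
  if (inherits(fields, "eye_series")) fields <- new_cohort(list(fields))
  if (inherits(fields, "vf_cohort")) {
    cm <- cohort_matrix(fields)
    X <- cm$td
    meta <- cm$meta
  } else if (is.matrix(fields)) {
    X <- fields
  } else {
    X <- matrix(as.numeric(fields), nrow = 1L)
  }
  storage.mode(X) <- "double"
  if (ncol(X) != ncol(model$archetypes)) {
    stop(sprintf("grid mismatch: fields have %d locations, model expects %d",
                 ncol(X), ncol(model$archetypes)))
  }
  alpha <- simplex_coef_cpp(model$archetypes, X, model$M)
  colnames(alpha) <- rownames(model$archetypes)
  resid <- X - alpha %*% model$archetypes
  structure(list(
    weights = alpha * 100,
    residual_norm = sqrt(rowSums(resid^2)),
    meta = meta,
    k = model$k
  ), class = "vf_decomposition")
}

#' @export
print.vf_decomposition <- function(x, ...) {
  cat(sprintf("<vf_decomposition> %d field(s) x %d archetypes (percent weights)\n",
              nrow(x$weights), x$k))
  print(round(head(x$weights, 6), 1))
  if (nrow(x$weights) > 6) cat("...\n")
  invisible(x)
}

#' Residual sum of squares of a model on a data matrix
#'
#' Each field is decomposed independently against the fixed archetypes and
#' the squared reconstruction residuals are summed; this is also the held-out
#' criterion used during cross-validation.
#'
#' @param X numeric matrix of fields (rows) or a `vf_cohort`.
#' @param model an `archetype_model`.
#' @return the RSS (squared dB).
#' @export
model_rss <- function(X, model) {
  if (inherits(X, "vf_cohort")) X <- cohort_matrix(X)$td
  d <- decompose(model, X)
  sum(d$residual_norm^2)
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("Archetype model: k = %d (grid %s), fit to %d fields\n",
              x$k, x$grid, x$n_fit))
  cat(sprintf("  RSS %.4g | %d restart(s), %d iteration(s)%s\n",
              x$rss, x$n_restarts, x$n_iterations,
              if (x$converged) "" else " [not converged]"))
  cat("  relative weights (%): ",
      paste(sprintf("%s=%.1f", names(x$relative_weight),
                    100 * x$relative_weight), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.archetype_model <- function(object, ...) {
  s <- data.frame(
    archetype = names(object$relative_weight),
    relative_weight_pct = 100 * object$relative_weight,
    average_td_db = object$average_td,
    row.names = NULL
  )
  structure(list(table = s, k = object$k, rss = object$rss,
                 n_fit = object$n_fit, converged = object$converged),
            class = "summary.archetype_model")
}

#' @export
print.summary.archetype_model <- function(x, ...) {
  cat(sprintf("Archetype model with k = %d (RSS %.4g over %d fields)\n\n",
              x$k, x$rss, x$n_fit))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.archetype_model <- function(object, ...) object$archetypes

#' @export
fitted.archetype_model <- function(object, ...) object$alpha %*% object$archetypes

#' @export
residuals.archetype_model <- function(object, ...) {
  object$training - fitted(object)
}

#' @export
predict.archetype_model <- function(object, newdata, ...) {
  if (missing(newdata)) {
    return(structure(list(weights = object$alpha * 100,
                          residual_norm = sqrt(rowSums(residuals(object)^2)),
                          meta = NULL, k = object$k),
                     class = "vf_decomposition"))
  }
  decompose(object, newdata)
}

#' Plot the fitted archetypes as 24-2 grayscale maps
#'
#' One panel per archetype on the 24-2 lattice, annotated with its relative
#' weight and average TD; darker points mark deeper total-deviation loss.
#'
#' @param x an `archetype_model` on the 54-location grid.
#' @param ... ignored.
#' @export
plot.archetype_model <- function(x, ...) {
  if (x$grid != "24-2/54") stop("plotting requires the 24-2/54 grid")
  loc <- vf_locations()
  k <- x$k
  nc <- ceiling(sqrt(k))
  nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_len(k)) {
    td <- x$archetypes[j, ]
    shade <- pmin(pmax((5 - td) / 40, 0), 1)
    graphics::plot(loc$x_deg, loc$y_deg, pch = 15, cex = 1.6,
                   col = grDevices::gray(1 - shade), axes = FALSE,
                   xlab = "", ylab = "", asp = 1,
                   main = sprintf("%s  RW %.1f%%  avgTD %.1f dB",
                                  rownames(x$archetypes)[j],
                                  100 * x$relative_weight[j], x$average_td[j]))
    graphics::box()
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Values are written with full precision so that a save/load round trip
#' preserves archetypes, ordering and weights exactly.
#'
#' @param model an `archetype_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "archetype_model"))
  payload <- list(
    version = "1.0",
    k = model$k,
    grid = model$grid,
    archetypes = unname(apply(model$archetypes, 1, as.numeric, simplify = FALSE)),
    relative_weight = unname(as.numeric(model$relative_weight)),
    average_td = unname(as.numeric(model$average_td)),
    rss = model$rss,
    n_fit = model$n_fit,
    seed = model$seed,
    n_restarts = model$n_restarts,
    M = model$M
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a serialized model
#'
#' @param path JSON file written by [serialize_model()].
#' @return an `archetype_model` (without training data; decomposition, RSS
#'   and scoring all work, training-set methods like `residuals()` do not).
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$version) || !identical(as.character(p$version), "1.0")) {
    stop("unsupported model schema version: ",
         if (is.null(p$version)) "<missing>" else p$version)
  }
  Z <- if (is.matrix(p$archetypes)) p$archetypes else
    do.call(rbind, lapply(p$archetypes, as.numeric))
  if (!identical(as.integer(p$k), nrow(Z))) {
    stop(sprintf("model file inconsistent: k = %d but %d archetypes stored",
                 as.integer(p$k), nrow(Z)))
  }
  at_names <- paste0("AT", seq_len(nrow(Z)))
  rownames(Z) <- at_names
  structure(list(
    k = as.integer(p$k),
    archetypes = Z,
    relative_weight = setNames(as.numeric(p$relative_weight), at_names),
    average_td = setNames(as.numeric(p$average_td), at_names),
    rss = as.numeric(p$rss),
    n_fit = as.integer(p$n_fit),
    alpha = NULL,
    training = NULL,
    seed = p$seed,
    n_restarts = as.integer(p$n_restarts),
    n_iterations = NA_integer_,
    converged = NA,
    rss_history = NULL,
    grid = as.character(p$grid),
    M = as.numeric(p$M),
    call = NULL
  ), class = "archetype_model")
}
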