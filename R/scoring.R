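## Meaningful-weight calls, dominant archetypes, the signed archetype-sum
## composite, expert-label matching and cohort-level report tables.

weights_matrix <- function(d) {
  if (inherits(d, "vf_decomposition")) d$weights
  else if (is.matrix(d)) d
  else matrix(as.numeric(d), nrow = 1L,
              dimnames = list(NULL, names(d)))
}

#' Archetypes carrying meaningful weight
#'
#' Returns, per field, the archetypes whose percent weight reaches the
#' calibrated threshold (boundary inclusive: a weight exactly at the
#' threshold counts).
#'
#' @param d a `vf_decomposition`, a weight matrix (percent), or one weight
#'   vector.
#' @param threshold percent cutoff (> 0), typically the calibrated value 9.
#' @return list (one element per field) of integer archetype indices.
#' @export
meaningful_archetypes <- function(d, threshold = 9) {
  if (threshold <= 0) stop("threshold must be positive")
  W <- weights_matrix(d)
  lapply(seq_len(nrow(W)), function(i) which(W[i, ] >= threshold))
}

#' Dominant archetype of a field
#'
#' The unique archetype carrying at least half of a field's weight, or `NA`
#' if no archetype reaches 50% (an exact 50/50 tie also yields `NA`).
#'
#' @param d as in [meaningful_archetypes()].
#' @return integer vector (one per field), `NA` where no dominant archetype
#'   exists.
#' @export
dominant_archetype <- function(d) {
  W <- weights_matrix(d)
  vapply(seq_len(nrow(W)), function(i) {
    hit <- which(W[i, ] >= 50)
    if (length(hit) == 1L) hit else {
      if (length(hit) > 1L) warning("tie at 50/50: no dominant archetype")
      NA_integer_
    }
  }, integer(1))
}

#' Assign composite-score signs to archetypes
#'
#' The archetype-sum composite gives a positive sign to normal or less
#' abnormal archetypes and a negative sign to more abnormal ones.  The
#' default `median_split` rule ranks archetypes by average TD: the better
#' half (higher average TD) is positive, the worse half negative; for odd k
#' the median archetype is positive.  An explicit set of positive archetypes
#' may be supplied instead.
#'
#' @param model an `archetype_model`.
#' @param rule `"median_split"` (default) or `"explicit"`.
#' @param positive for `rule = "explicit"`, character vector of archetype
#'   names to sign positive; the rest are negative.
#' @return object of class `sign_assignment`: named numeric vector of +1/-1.
#' @export
assign_signs <- function(model, rule = c("median_split", "explicit"),
                         positive = NULL) {
  rule <- match.arg(rule)
  at_names <- rownames(model$archetypes)
  k <- model$k
  if (rule == "explicit") {
    if (is.null(positive) || !all(positive %in% at_names)) {
      stop("explicit rule needs `positive` naming a subset of the archetypes")
    }
    s <- ifelse(at_names %in% positive, 1, -1)
  } else {
    n_pos <- ceiling(k / 2)
    ord <- order(-model$average_td, seq_len(k))  # best TD first
    s <- rep(-1, k)
    s[ord[seq_len(n_pos)]] <- 1
  }
  structure(setNames(s, at_names), rule = rule, class = "sign_assignment")
}

#' Signed archetype-sum composite score
#'
#' The sum of the percent weights with each archetype's sign applied; bounded
#' in \[-100, 100\], with lower values indicating worse field function.
#' Unlike MD it reflects all regional deficits, not mainly the central
#' points.
#'
#' @param d as in [meaningful_archetypes()].
#' @param signs a `sign_assignment` covering all k archetypes.
#' @return numeric vector of scores (one per field).
#' @export
at_sum <- function(d, signs) {
  W <- weights_matrix(d)
  if (length(signs) != ncol(W)) {
    stop(sprintf("sign assignment covers %d archetypes but decomposition has %d",
                 length(signs), ncol(W)))
  }
  as.numeric(W %*% as.numeric(signs))
}

#' Compare a dominant archetype's features with an expert classification
#'
#' Both classifications are given as sets of feature tags from a small
#' controlled vocabulary (e.g. `normal`, `general_depression_mild`,
#' `blind_spot_enlargement`, `arcuate_superior`, ...).  The match is `exact`
#' when the tag sets are equal, `partial` when they share at least one tag,
#' and `different` otherwise; the comparison is symmetric and order-free.
#'
#' @param dominant_tags character vector of tags for the dominant archetype.
#' @param expert_tags character vector of tags for the expert classification.
#' @return `"exact"`, `"partial"` or `"different"`.
#' @export
match_classification <- function(dominant_tags, expert_tags) {
  if (!length(dominant_tags)) stop("dominant archetype has no feature tags")
  if (!length(expert_tags)) stop("expert classification has no feature tags")
  a <- unique(as.character(dominant_tags))
  b <- unique(as.character(expert_tags))
  if (setequal(a, b)) "exact"
  else if (length(intersect(a, b))) "partial"
  else "different"
}

spearman_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 3L || length(unique(y)) < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = n, note = "skipped: <3 distinct values"))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, note = ""))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), n = n, note = "")
}

#' Cohort-level report tables
#'
#' Summarises a set of decompositions sharing one model: (a) per-archetype
#' frequency of fields at or above the meaningful-weight threshold; (b) the
#' distribution of meaningful-archetype counts per field; (c) Spearman rank
#' correlations (t-approximation p-values, average ranks for ties) of each
#' archetype weight — and of the archetype-sum score when `signs` is given —
#' against each supplied numeric covariate; (d) per-archetype Wilcoxon
#' rank-sum comparisons between two groups; (e) a chi-square test on the
#' 2 x k above-threshold frequency table between groups.
#'
#' @param d a `vf_decomposition` (or percent-weight matrix).
#' @param threshold meaningful-weight cutoff in percent (default 9).
#' @param signs optional `sign_assignment` enabling archetype-sum rows.
#' @param covariates optional data.frame of numeric covariates (one row per
#'   field), e.g. MD, PSD, acuity, papilledema grade.
#' @param group optional factor/character vector (two levels, one per field)
#'   for the group comparisons.
#' @param holm apply Holm adjustment to each table's p-values
#'   (default `FALSE`; raw p-values are reported as in routine practice).
#' @return list of data.frames: `frequencies`, `meaningful_counts`,
#'   `correlations` (if covariates), `group_tests` and `chisq` (if group).
#' @export
cohort_report <- function(d, threshold = 9, signs = NULL, covariates = NULL,
                          group = NULL, holm = FALSE) {
  W <- weights_matrix(d)
  k <- ncol(W)
  at_names <- colnames(W)
  if (is.null(at_names)) at_names <- paste0("AT", seq_len(k))

  above <- W >= threshold
  freq <- data.frame(archetype = at_names,
                     n_meaningful = colSums(above),
                     prop = colSums(above) / nrow(W), row.names = NULL)
  counts <- table(factor(rowSums(above), levels = 0:floor(100 / threshold)))
  counts_df <- data.frame(n_archetypes = as.integer(names(counts)),
                          n_fields = as.integer(counts))

  out <- list(frequencies = freq, meaningful_counts = counts_df)

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(W))
    rows <- list()
    score <- if (!is.null(signs)) at_sum(W, signs) else NULL
    for (cv in names(covariates)) {
      for (j in seq_len(k)) {
        s <- spearman_t(W[, j], covariates[[cv]])
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, variable = at_names[j],
          r = s$r, p = s$p, n = s$n, note = s$note)
      }
      if (!is.null(score)) {
        s <- spearman_t(score, covariates[[cv]])
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, variable = "AT_sum",
          r = s$r, p = s$p, n = s$n, note = s$note)
      }
    }
    corr <- do.call(rbind, rows)
    if (holm) corr$p_adj <- stats::p.adjust(corr$p, "holm")
    out$correlations <- corr
  }

  if (!is.null(group)) {
    g <- factor(group)
    if (nlevels(g) != 2L) stop("group must have exactly two levels")
    rows <- lapply(seq_len(k), function(j) {
      wt <- suppressWarnings(wilcox.test(W[g == levels(g)[1L], j],
                                         W[g == levels(g)[2L], j]))
      data.frame(archetype = at_names[j], statistic = unname(wt$statistic),
                 p = wt$p.value)
    })
    gt <- do.call(rbind, rows)
    if (holm) gt$p_adj <- stats::p.adjust(gt$p, "holm")
    out$group_tests <- gt
    tab <- rbind(colSums(above[g == levels(g)[1L], , drop = FALSE]),
                 colSums(above[g == levels(g)[2L], , drop = FALSE]))
    keep <- colSums(tab) > 0
    out$chisq <- if (any(keep) && all(rowSums(tab) > 0)) {
      ct <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE]))
      data.frame(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
    } else {
      data.frame(statistic = NA_real_, df = NA_real_, p = NA_real_)
    }
  }
  out
}
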