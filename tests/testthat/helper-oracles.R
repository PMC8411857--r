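# Independent oracles and small fixtures used across the suite.  Everything
# here is deliberately brute-force / closed-form and shares no code with the
# package's fitting path.

# Minimum of ||w Z - td||^2 over the 2-simplex (k = 3) by exhaustive grid
# search with the given step in weight space; TD fields in rows.  The grid of
# candidate reconstructions is precomputed once for all fields.
simplex_grid_min <- function(Z, TD, step = 1e-3) {
  stopifnot(nrow(Z) == 3L)
  if (is.null(dim(TD))) TD <- matrix(TD, nrow = 1L)
  m <- round(1 / step)
  i <- rep(0:m, (m + 1):1)
  j <- sequence((m + 1):1) - 1L
  W <- cbind(i, j, m - i - j) / m
  G <- W %*% Z
  qn <- rowSums(G^2)
  vapply(seq_len(nrow(TD)), function(r) {
    td <- TD[r, ]
    min(qn - 2 * as.numeric(G %*% td) + sum(td^2))
  }, numeric(1))
}

simplex_grid_obj <- function(Z, td, step = 1e-3) simplex_grid_min(Z, td, step)

# Squared distances from the rows of Q to the segment [a, b] (closed form).
seg_dist2 <- function(Q, a, b) {
  v <- b - a
  vv <- sum(v^2)
  t <- if (vv > 0) pmin(pmax(((Q[, 1] - a[1]) * v[1] + (Q[, 2] - a[2]) * v[2]) / vv, 0), 1) else 0
  px <- a[1] + t * v[1]; py <- a[2] + t * v[2]
  (Q[, 1] - px)^2 + (Q[, 2] - py)^2
}

# Squared distances from the rows of Q to the triangle (a, b, c): zero inside,
# else the nearest edge.
tri_dist2 <- function(Q, a, b, c) {
  d <- pmin(seg_dist2(Q, a, b), seg_dist2(Q, b, c), seg_dist2(Q, a, c))
  det <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  s1 <- (b[1] - a[1]) * (Q[, 2] - a[2]) - (b[2] - a[2]) * (Q[, 1] - a[1])
  s2 <- (c[1] - b[1]) * (Q[, 2] - b[2]) - (c[2] - b[2]) * (Q[, 1] - b[1])
  s3 <- (a[1] - c[1]) * (Q[, 2] - c[2]) - (a[2] - c[2]) * (Q[, 1] - c[1])
  inside <- (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  d[inside] <- 0
  d
}

# Candidate archetype positions: the convex-hull boundary of a 2-D point set,
# discretized with n_per_edge interior points per hull edge.
hull_boundary_candidates <- function(X, n_per_edge = 12L) {
  h <- grDevices::chull(X)
  V <- X[h, , drop = FALSE]
  out <- list()
  nv <- nrow(V)
  for (i in seq_len(nv)) {
    a <- V[i, ]; b <- V[if (i == nv) 1L else i + 1L, ]
    t <- seq(0, 1, length.out = n_per_edge + 2L)[-(n_per_edge + 2L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  unique(do.call(rbind, out))
}

# Exhaustive archetypal-analysis oracle for 2-D data and k in {2, 3}: the
# minimum RSS over all k-subsets of hull-boundary candidates, with each data
# point projected onto the candidate segment/triangle in closed form.
oracle_aa_rss_2d <- function(X, k, n_per_edge = 12L) {
  C <- hull_boundary_candidates(X, n_per_edge)
  nc <- nrow(C)
  best <- Inf
  if (k == 2L) {
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      r <- sum(seg_dist2(X, C[i, ], C[j, ]))
      if (r < best) best <- r
    }
  } else if (k == 3L) {
    for (i in 1:(nc - 2)) for (j in (i + 1):(nc - 1)) {
      dij <- seg_dist2(X, C[i, ], C[j, ])
      for (l in (j + 1):nc) {
        r <- sum(tri_dist2(X, C[i, ], C[j, ], C[l, ]))
        if (r < best) best <- r
      }
    }
  } else stop("oracle supports k = 2 or 3")
  best
}

# Best assignment of fitted archetypes to reference prototypes by mean cosine
# similarity over all permutations (small k only).
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }))
}

match_prototypes <- function(ref, fitted) {
  k <- nrow(ref)
  cosm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cosm[i, j] <- sum(ref[i, ] * fitted[j, ]) /
      sqrt(sum(ref[i, ]^2) * sum(fitted[j, ]^2))
  }
  best <- -Inf; bp <- NULL
  for (p in perms(seq_len(k))) {
    s <- mean(cosm[cbind(seq_len(k), p)])
    if (s > best) { best <- s; bp <- p }
  }
  list(perm = bp, mean_cosine = best)
}

# Four distinctly shaped regional-defect prototypes used in planted-recovery
# experiments (all have nonzero norm, unlike the flat normal prototype).
planted4 <- function() {
  vf_prototypes()[c("blind_spot_enlargement", "arcuate_superior",
                    "arcuate_inferior", "nasal_defect"), ]
}

# A tiny cohort built in code: one eye, reliable/unreliable mix.
make_series <- function(eye_id = "e1", visits, mds, fl = NULL, td_fun = NULL) {
  n <- length(visits)
  if (is.null(fl)) fl <- rep(0.05, n)
  fields <- lapply(seq_len(n), function(i) {
    td <- if (is.null(td_fun)) rep(mds[i], 54) else td_fun(i)
    visual_field(eye_id, "OD", visits[i], td, fixation_loss_rate = fl[i],
                 md = mds[i])
  })
  eye_series(fields)
}
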