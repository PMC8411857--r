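## Synthetic cohorts with known ground truth.  Hand-authored prototype TD
## maps mimic the qualitative visual-field patterns reported in papilledema
## (blind-spot enlargement, arcuate loss respecting the horizontal midline,
## nasal defects, hemianopia, general depression, normal); cohorts are
## Dirichlet mixtures of prototypes plus truncated Gaussian noise.

#' The synthetic prototype library
#'
#' Eight hand-authored TD-map prototypes on the canonical 54-location grid.
#' They are qualitative stand-ins for characteristic field patterns, not
#' estimates of any fitted archetypes: `normal` (0 dB), mild and severe
#' general depression (uniform -3 / -20 dB), blind-spot enlargement (deep
#' loss at and around the two blind-spot locations), superior and inferior
#' partial arcuate loss (nerve-fiber-bundle arcs confined to one horizontal
#' hemifield), a nasal defect, and a temporal hemianopia (loss confined to
#' one vertical hemifield).
#'
#' @return numeric matrix, prototypes in rows (named), 54 columns, dB in
#'   \[-35, 5\].
#' @export
vf_prototypes <- function() {
  loc <- vf_locations()
  x <- loc$x_deg; y <- loc$y_deg
  p <- list()
  p$normal <- rep(0, 54)
  p$general_depression_mild <- rep(-3, 54)
  p$general_depression_severe <- rep(-20, 54)

  bs <- rep(0, 54)
  d1 <- sqrt((x - 15)^2 + (y - 3)^2)
  d2 <- sqrt((x - 15)^2 + (y + 3)^2)
  bs[pmin(d1, d2) < 0.5] <- -30
  bs[pmin(d1, d2) >= 0.5 & pmin(d1, d2) <= 6.5] <- -12
  p$blind_spot_enlargement <- bs

  arc <- function(hemi) {
    r <- sqrt(x^2 + y^2)
    depth <- -18 * exp(-((r - 15) / 7)^2)
    out <- ifelse(hemi * y > 0, depth, 0)
    out[abs(out) < 1] <- 0
    out
  }
  p$arcuate_superior <- arc(+1)
  p$arcuate_inferior <- arc(-1)

  p$nasal_defect <- ifelse(x <= -15, -15, 0)
  p$temporal_hemianopia <- ifelse(x > 0, -22, 0)

  P <- do.call(rbind, p)
  colnames(P) <- sprintf("td_%02d", 1:54)
  P
}

rdirichlet1 <- function(n, alpha, k) {
  g <- matrix(rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Simulate fields as Dirichlet mixtures of prototypes
#'
#' Low-level generator used in parameter-recovery experiments: each field is
#' a convex combination of the supplied prototypes (symmetric Dirichlet
#' mixing weights) plus iid Gaussian noise, truncated to the valid TD range.
#'
#' @param n number of fields.
#' @param prototypes prototype matrix (rows = prototypes); default the
#'   non-normal-inclusive full library [vf_prototypes()].
#' @param dirichlet_alpha symmetric Dirichlet concentration (default 0.3;
#'   small values place most fields near single prototypes).
#' @param noise_sd_db per-location Gaussian noise SD in dB (default 1.5).
#' @param seed optional integer seed.
#' @return list with `td` (n x p matrix), `weights` (n x #prototypes ground
#'   truth), `prototypes`.
#' @export
simulate_mixture <- function(n, prototypes = vf_prototypes(),
                             dirichlet_alpha = 0.3, noise_sd_db = 1.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- rdirichlet1(n, dirichlet_alpha, nrow(prototypes))
  colnames(W) <- rownames(prototypes)
  td <- W %*% prototypes
  if (noise_sd_db > 0) {
    td <- td + matrix(rnorm(length(td), sd = noise_sd_db), nrow(td), ncol(td))
  }
  td <- pmin(pmax(td, -40), 10)
  list(td = td, weights = W, prototypes = prototypes)
}

## shift/scale a mixture map so its surrogate MD equals `target` exactly,
## keeping the deepest point above the clamp
adjust_to_md <- function(m0, target) {
  md0 <- surrogate_md(m0)
  if (md0 < -0.25) {
    s <- min(target / md0, -34 / min(min(m0), -1))
    m0 <- s * m0
  }
  m0 + (target - surrogate_md(m0))
}

#' Generate a papilledema-trial-like cohort with ground truth
#'
#' Emulates the structure of a treatment-trial visual-field dataset: per eye,
#' a baseline defect composed as a Dirichlet mixture of the prototype
#' library, scaled and shifted so the measured baseline MD (surrogate) falls
#' in the trial's inclusion window; two baseline replicate tests; monthly
#' follow-up through month six during which the defect shrinks at a per-eye
#' recovery rate; a configurable fraction of eyes instead worsen steadily so
#' that the two-stratum MD-drop rule trips (with confirmation at the next
#' visit); and a configurable fraction of unreliable fields.  Eyes whose
#' noisy baseline MDs land outside `md_range` are redrawn (bounded retries).
#'
#' @param n_eyes number of eyes (default 165, the trial's study-eye count).
#' @param dirichlet_alpha mixing concentration (default 0.3).
#' @param noise_sd_db measurement noise SD per location (default 1.5 dB).
#' @param md_range inclusion window for baseline MD in dB (default c(-7, -2)).
#' @param failure_fraction fraction of eyes on a worsening trajectory
#'   (default 7/165, the trial's treatment-failure rate).
#' @param unreliable_fraction fraction of fields flagged unreliable
#'   (default 0.025, matching the trial's discard rate).
#' @param seed integer seed.
#' @return list with `cohort` (a `vf_cohort`) and `truth` (data.frame of
#'   per-eye mixing weights, recovery rate, failure month, target MD).
#' @export
generate_cohort <- function(n_eyes = 165L, dirichlet_alpha = 0.3,
                            noise_sd_db = 1.5, md_range = c(-7, -2),
                            failure_fraction = 7 / 165,
                            unreliable_fraction = 0.025, seed = NULL) {
  stopifnot(n_eyes >= 1L, noise_sd_db >= 0)
  if (!is.null(seed)) set.seed(seed)
  P <- vf_prototypes()
  target_lo <- md_range[1L] + 0.75
  target_hi <- md_range[2L] - 0.75
  n_fail <- round(failure_fraction * n_eyes)
  fail_eyes <- if (n_fail > 0) sample.int(n_eyes, n_fail) else integer(0)

  noisy <- function(m) pmin(pmax(m + rnorm(54, sd = noise_sd_db), -40), 10)
  rel_meta <- function(unreliable) {
    if (unreliable) c(fl = runif(1, 0.35, 0.6), fp = runif(1, 0, 0.10))
    else c(fl = runif(1, 0, 0.25), fp = runif(1, 0, 0.10))
  }

  series_list <- vector("list", n_eyes)
  truth_rows <- vector("list", n_eyes)
  for (e in seq_len(n_eyes)) {
    eye_id <- sprintf("iih%03d", e)
    lat <- if (e %% 2L == 0L) "OS" else "OD"
    arm <- if (runif(1) < 0.5) "acetazolamide" else "placebo"
    is_fail <- e %in% fail_eyes

    for (try in 1:100) {
      w <- as.numeric(rdirichlet1(1L, dirichlet_alpha, nrow(P)))
      target <- runif(1, target_lo, target_hi)
      base_map <- adjust_to_md(as.numeric(w %*% P), target)
      td1 <- noisy(base_map); td2 <- noisy(base_map)
      ok <- all(c(surrogate_md(td1), surrogate_md(td2)) >= md_range[1L] &
                  c(surrogate_md(td1), surrogate_md(td2)) <= md_range[2L])
      if (ok) break
      if (try == 100L) stop("generation error: md_range unreachable for the prototype library")
    }

    rate <- runif(1, 0.02, 0.12)
    fail_month <- if (is_fail) sample(2:5, 1L) else NA_integer_
    base_md <- surrogate_md(base_map)
    gamma <- if (is_fail) {
      need <- (if (base_md <= -3.5) 2 else 3) + 0.75
      need / (abs(base_md) * fail_month)
    } else NA_real_

    fields <- list()
    for (rep_i in 1:2) {
      rm <- rel_meta(runif(1) < unreliable_fraction)
      fields[[length(fields) + 1L]] <- visual_field(
        eye_id, lat, "baseline", noisy(base_map),
        fixation_loss_rate = rm[["fl"]], false_positive_rate = rm[["fp"]],
        arm = arm)
    }
    for (t in 1:6) {
      map_t <- if (is_fail) (1 + gamma * t) * base_map else (1 - rate * t) * base_map
      map_t <- pmin(pmax(map_t, -39), 9)
      rm <- rel_meta(runif(1) < unreliable_fraction)
      fields[[length(fields) + 1L]] <- visual_field(
        eye_id, lat, paste0("m", t), noisy(map_t),
        fixation_loss_rate = rm[["fl"]], false_positive_rate = rm[["fp"]],
        arm = arm)
    }
    series_list[[e]] <- eye_series(fields)
    truth_rows[[e]] <- data.frame(
      eye_id = eye_id, t(setNames(w, rownames(P))), recovery_rate = rate,
      failure = is_fail, failure_month = fail_month, target_md = target)
  }
  list(cohort = new_cohort(series_list),
       truth = do.call(rbind, truth_rows))
}

#' Generate a normal-control cohort
#'
#' Repeated normal fields (zero-mean prototype plus truncated Gaussian noise)
#' spanning one nominal year; all fields pass the reliability cutoffs.
#'
#' @param n_eyes number of control eyes (default 61, as in the reference
#'   control set).
#' @param visits_per_eye fields per eye (default 9, ~568/61; two baseline
#'   replicates, monthly visits, a repeat at month six).
#' @param noise_sd_db per-location noise SD (default 1.5 dB).
#' @param seed integer seed.
#' @return a `vf_cohort`.
#' @export
generate_controls <- function(n_eyes = 61L, visits_per_eye = 9L,
                              noise_sd_db = 1.5, seed = NULL) {
  stopifnot(n_eyes >= 1L, visits_per_eye >= 1L)
  if (!is.null(seed)) set.seed(seed)
  labels <- c("baseline", "baseline", paste0("m", 1:6), "m6")
  labels <- rep_len(labels, visits_per_eye)
  series_list <- vector("list", n_eyes)
  for (e in seq_len(n_eyes)) {
    eye_id <- sprintf("ctl%03d", e)
    lat <- if (e %% 2L == 0L) "OS" else "OD"
    fields <- lapply(labels, function(v) {
      td <- pmin(pmax(rnorm(54, sd = noise_sd_db), -40), 10)
      visual_field(eye_id, lat, v, td,
                   fixation_loss_rate = runif(1, 0, 0.15),
                   false_positive_rate = runif(1, 0, 0.08))
    })
    series_list[[e]] <- eye_series(fields)
  }
  new_cohort(series_list)
}
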