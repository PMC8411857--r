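## Canonical per-eye/per-visit data model and the cohort curation rules:
## reliability filtering, replicate averaging, treatment-failure detection and
## the six-month outcome window.

#' Ordered visit labels
#'
#' Visits are ordinal: baseline, then monthly visits m1..m6, then the optional
#' failure-confirmation label `fail`.
#' @return character vector of visit labels in order.
#' @export
vf_visit_levels <- function() c("baseline", paste0("m", 1:6), "fail")

visit_rank <- function(visit) {
  r <- match(visit, vf_visit_levels())
  if (anyNA(r)) stop("unknown visit label(s): ",
                     paste(unique(visit[is.na(r)]), collapse = ", "))
  r
}

#' Construct a single visual field
#'
#' One eye/visit observation: a 54-location total-deviation vector in dB plus
#' its metadata.  Left-eye (OS) fields are expected to be supplied already in
#' right-eye orientation when `mirrored = TRUE` (the default used by
#' [read_cohort()], which performs the mirroring itself).  Reliability follows
#' the trial's cutoffs: a field is unreliable when fixation losses reach 33%
#' or false positives reach 15%.
#'
#' @param eye_id opaque subject+laterality identifier.
#' @param laterality `"OD"` or `"OS"`.
#' @param visit one of [vf_visit_levels()].
#' @param td numeric vector of 54 TD values in dB, each in \[-40, 10\].
#' @param fixation_loss_rate,false_positive_rate fractions in \[0, 1\].
#' @param md,psd global indices in dB; computed from `td` via the surrogate
#'   formulas when omitted.
#' @param expert_label optional expert visual-field category string.
#' @param arm optional treatment-arm label.
#' @return an object of class `vf_field`.
#' @export
visual_field <- function(eye_id, laterality = c("OD", "OS"), visit, td,
                         fixation_loss_rate = 0, false_positive_rate = 0,
                         md = NULL, psd = NULL, expert_label = NA_character_,
                         arm = NA_character_) {
  laterality <- match.arg(laterality)
  td <- as.numeric(td)
  if (length(td) != 54L) {
    stop("td must have exactly 54 entries (got ", length(td), ")")
  }
  if (any(!is.finite(td)) || any(td < -40 | td > 10)) {
    stop("td values must be finite and within [-40, 10] dB")
  }
  visit_rank(visit)  # validates
  f <- list(
    eye_id = as.character(eye_id),
    laterality = laterality,
    visit = visit,
    td = td,
    md = if (is.null(md)) surrogate_md(td) else as.numeric(md),
    psd = if (is.null(psd)) surrogate_psd(td) else as.numeric(psd),
    fixation_loss_rate = as.numeric(fixation_loss_rate),
    false_positive_rate = as.numeric(false_positive_rate),
    expert_label = as.character(expert_label),
    arm = as.character(arm)
  )
  f$reliable <- f$fixation_loss_rate < 0.33 && f$false_positive_rate < 0.15
  structure(f, class = "vf_field")
}

#' @export
print.vf_field <- function(x, ...) {
  cat(sprintf("<vf_field> %s %s visit=%s MD=%.2f PSD=%.2f %s\n",
              x$eye_id, x$laterality, x$visit, x$md, x$psd,
              if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Bundle the visits of one eye into a series
#'
#' @param fields list of [visual_field()] objects sharing one `eye_id`.
#' @return an object of class `eye_series` with fields ordered by visit (ties
#'   keep input order) and a `baseline_md` taken as the mean MD over baseline
#'   replicates.
#' @export
eye_series <- function(fields) {
  stopifnot(length(fields) >= 1L)
  ids <- vapply(fields, `[[`, "", "eye_id")
  if (length(unique(ids)) != 1L) stop("all fields must share one eye_id")
  ord <- order(visit_rank(vapply(fields, `[[`, "", "visit")))
  fields <- fields[ord]
  base <- Filter(function(f) f$visit == "baseline", fields)
  structure(list(
    eye_id = ids[[1L]],
    fields = fields,
    baseline_md = if (length(base)) mean(vapply(base, `[[`, 0, "md")) else NA_real_,
    failure_status = "none",
    failure_visit = NA_character_
  ), class = "eye_series")
}

#' @export
print.eye_series <- function(x, ...) {
  cat(sprintf("<eye_series> %s: %d fields (%s), baseline MD %.2f dB, status %s\n",
              x$eye_id, length(x$fields),
              paste(vapply(x$fields, `[[`, "", "visit"), collapse = ", "),
              x$baseline_md, x$failure_status))
  invisible(x)
}

new_cohort <- function(series_list) {
  names(series_list) <- vapply(series_list, `[[`, "", "eye_id")
  structure(series_list, class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  nf <- sum(vapply(x, function(s) length(s$fields), 0L))
  cat(sprintf("<vf_cohort> %d eyes, %d fields\n", length(x), nf))
  invisible(x)
}

cohort_csv_columns <- function() {
  c("eye_id", "laterality", "visit", "fixation_loss_rate",
    "false_positive_rate", "md", "psd", "expert_label", "arm",
    sprintf("td_%02d", 1:54))
}

#' Read a cohort CSV
#'
#' One row per field with columns `eye_id`, `laterality`, `visit`,
#' `fixation_loss_rate`, `false_positive_rate`, `md`, `psd`, `expert_label`,
#' `arm`, `td_01`..`td_54` (dB, canonical right-eye order for OD rows,
#' native left-eye order for OS rows).  OS rows are mirrored into right-eye
#' orientation at load when `mirror_os = TRUE` so that archetypes are
#' laterality-invariant.  Malformed rows raise errors naming the offending
#' line.
#'
#' @param path CSV file path.
#' @param mirror_os mirror left-eye fields into right-eye orientation
#'   (default `TRUE`).
#' @return a `vf_cohort`: a list of [eye_series()] grouped by `eye_id`.
#' @export
read_cohort <- function(path, mirror_os = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(eye_id = "character"))
  missing_cols <- setdiff(cohort_csv_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort CSV schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tdcols <- sprintf("td_%02d", 1:54)
  fields <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    td <- suppressWarnings(as.numeric(df[i, tdcols]))
    if (anyNA(td)) {
      stop(sprintf("row error at line %d (eye %s, visit %s): non-numeric TD entry",
                   i + 1L, df$eye_id[i], df$visit[i]))
    }
    if (mirror_os && identical(df$laterality[i], "OS")) td <- mirror_td(td)
    fields[[i]] <- tryCatch(
      visual_field(df$eye_id[i], df$laterality[i], df$visit[i], td,
                   fixation_loss_rate = df$fixation_loss_rate[i],
                   false_positive_rate = df$false_positive_rate[i],
                   md = df$md[i], psd = df$psd[i],
                   expert_label = df$expert_label[i], arm = df$arm[i]),
      error = function(e) stop(sprintf(
        "row error at line %d (eye %s, visit %s): %s",
        i + 1L, df$eye_id[i], df$visit[i], conditionMessage(e)), call. = FALSE)
    )
  }
  new_cohort(lapply(split(fields, vapply(fields, `[[`, "", "eye_id")), eye_series))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: emits RFC-4180 CSV with '.' decimal separator
#' and full-precision TD values so that a read/write round trip reproduces
#' every TD bit-identically.  Fields stored mirrored (OS) are written back in
#' native left-eye order when `mirror_os = TRUE`.
#'
#' @param cohort a `vf_cohort`.
#' @param path output file.
#' @param mirror_os undo the canonical mirroring for OS rows (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, mirror_os = TRUE) {
  rows <- list()
  for (s in cohort) {
    for (f in s$fields) {
      td <- f$td
      if (mirror_os && identical(f$laterality, "OS")) td <- mirror_td(td)
      row <- c(eye_id = f$eye_id, laterality = f$laterality, visit = f$visit,
               fixation_loss_rate = sprintf("%.17g", f$fixation_loss_rate),
               false_positive_rate = sprintf("%.17g", f$false_positive_rate),
               md = sprintf("%.17g", f$md), psd = sprintf("%.17g", f$psd),
               expert_label = f$expert_label, arm = f$arm,
               setNames(sprintf("%.17g", td), sprintf("td_%02d", 1:54)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Drop unreliable fields
#'
#' Removes every field failing the reliability cutoffs (fixation losses
#' \eqn{\ge} 33% or false positives \eqn{\ge} 15%) from a series or cohort.
#' Empty results are permitted (with a warning).
#'
#' @param x an `eye_series` or `vf_cohort`.
#' @return the filtered object; for cohorts, eyes left with no reliable field
#'   are dropped.
#' @export
filter_reliable <- function(x) UseMethod("filter_reliable")

#' @export
filter_reliable.eye_series <- function(x) {
  keep <- vapply(x$fields, `[[`, TRUE, "reliable")
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(sprintf("filter_reliable: removed %d unreliable field(s) from eye %s",
                    n_removed, x$eye_id))
  }
  if (!any(keep)) {
    warning(sprintf("eye %s has no reliable fields", x$eye_id))
    x$fields <- list()
    return(x)
  }
  out <- eye_series(x$fields[keep])
  out$failure_status <- x$failure_status
  out$failure_visit <- x$failure_visit
  out
}

#' @export
filter_reliable.vf_cohort <- function(x) {
  filtered <- lapply(x, filter_reliable)
  new_cohort(Filter(function(s) length(s$fields) > 0L, filtered))
}

#' Average replicate fields taken at one visit
#'
#' When several reliable fields exist for one eye at one time point, the
#' pointwise arithmetic mean of the TD values replaces them; MD and PSD are
#' recomputed from the averaged map via the surrogate formulas.
#'
#' @param fields list of `vf_field` objects sharing eye and visit.
#' @return one `vf_field`.
#' @export
average_replicates <- function(fields) {
  stopifnot(length(fields) >= 1L)
  if (length(fields) == 1L) return(fields[[1L]])
  ids <- unique(vapply(fields, `[[`, "", "eye_id"))
  visits <- unique(vapply(fields, `[[`, "", "visit"))
  if (length(ids) != 1L || length(visits) != 1L) {
    stop("average_replicates: fields must share one eye_id and one visit")
  }
  td <- rowMeans(vapply(fields, `[[`, numeric(54), "td"))
  proto <- fields[[1L]]
  visual_field(proto$eye_id, proto$laterality, proto$visit, td,
               fixation_loss_rate = mean(vapply(fields, `[[`, 0, "fixation_loss_rate")),
               false_positive_rate = mean(vapply(fields, `[[`, 0, "false_positive_rate")),
               expert_label = proto$expert_label, arm = proto$arm)
}

#' Detect treatment failure from the MD trajectory
#'
#' Applies the trial's two-stratum rule, read literally from its printed
#' wording: the eye fails treatment at the first visit whose MD has dropped
#' from the baseline MD by at least 2 dB when baseline MD \eqn{\le} -3.5 dB,
#' or by at least 3 dB otherwise (baseline between -3.5 and -7 dB), provided
#' the next available field confirms a drop of the same magnitude.
#'
#' @param series an `eye_series` with a baseline field.
#' @return list with `status` (`"none"` or `"treatment_failure"`), `visit`
#'   (label or `NA`) and `threshold_db` used.
#' @export
detect_treatment_failure <- function(series) {
  if (is.na(series$baseline_md)) stop("baseline MD is required")
  thr <- if (series$baseline_md <= -3.5) 2 else 3
  post <- Filter(function(f) f$visit != "baseline", series$fields)
  if (length(post) >= 2L) {
    for (i in seq_len(length(post) - 1L)) {
      drop_i <- series$baseline_md - post[[i]]$md
      drop_next <- series$baseline_md - post[[i + 1L]]$md
      if (drop_i >= thr && drop_next >= thr) {
        return(list(status = "treatment_failure", visit = post[[i]]$visit,
                    threshold_db = thr))
      }
    }
  }
  list(status = "none", visit = NA_character_, threshold_db = thr)
}

#' Restrict a series to the six-month outcome window
#'
#' Drops visits after month six; for treatment failures, the field taken at
#' the failure visit replaces all later visits through month six (visits after
#' confirmation are excluded); for performance failures only reliable
#' confirmatory fields are kept; replicate fields at one visit are averaged.
#'
#' @param series an `eye_series`; its `failure_status` is resolved first via
#'   [detect_treatment_failure()] unless already set.
#' @return the curated `eye_series` (one averaged field per retained visit).
#' @export
curate_outcome_window <- function(series) {
  series <- filter_reliable(series)
  if (!length(series$fields)) return(series)
  if (identical(series$failure_status, "none") && !is.na(series$baseline_md)) {
    det <- detect_treatment_failure(series)
    series$failure_status <- det$status
    series$failure_visit <- det$visit
  }
  keep_visits <- c("baseline", paste0("m", 1:6))
  fields <- Filter(function(f) f$visit %in% keep_visits, series$fields)

  if (identical(series$failure_status, "treatment_failure") &&
      !is.na(series$failure_visit)) {
    fv_rank <- visit_rank(series$failure_visit)
    fail_fields <- Filter(function(f) f$visit == series$failure_visit, fields)
    fail_field <- average_replicates(fail_fields)
    fields <- Filter(function(f) visit_rank(f$visit) < fv_rank, fields)
    for (v in keep_visits[visit_rank(keep_visits) >= fv_rank]) {
      sub <- fail_field
      sub$visit <- v
      fields[[length(fields) + 1L]] <- sub
    }
  }

  by_visit <- split(fields, vapply(fields, `[[`, "", "visit"))
  fields <- lapply(by_visit, average_replicates)
  out <- eye_series(unname(fields))
  out$failure_status <- series$failure_status
  out$failure_visit <- series$failure_visit
  out
}

#' Curate every eye of a cohort
#'
#' Applies [curate_outcome_window()] to each eye after reliability filtering.
#'
#' @param cohort a `vf_cohort`.
#' @return the curated `vf_cohort`.
#' @export
curate_cohort <- function(cohort) {
  new_cohort(lapply(filter_reliable(cohort), curate_outcome_window))
}

#' Extract the TD matrix and metadata from a cohort
#'
#' @param cohort a `vf_cohort`.
#' @param visits optional subset of visit labels to keep.
#' @return list with `td` (n fields x 54 matrix, dB) and `meta` (data.frame
#'   of eye_id, laterality, visit, md, psd, reliable, expert_label, arm).
#' @export
cohort_matrix <- function(cohort, visits = NULL) {
  fields <- unlist(lapply(cohort, `[[`, "fields"), recursive = FALSE)
  if (!is.null(visits)) {
    fields <- Filter(function(f) f$visit %in% visits, fields)
  }
  if (!length(fields)) stop("no fields selected")
  td <- t(vapply(fields, `[[`, numeric(54), "td"))
  meta <- data.frame(
    eye_id = vapply(fields, `[[`, "", "eye_id"),
    laterality = vapply(fields, `[[`, "", "laterality"),
    visit = vapply(fields, `[[`, "", "visit"),
    md = vapply(fields, `[[`, 0, "md"),
    psd = vapply(fields, `[[`, 0, "psd"),
    reliable = vapply(fields, `[[`, TRUE, "reliable"),
    expert_label = vapply(fields, `[[`, "", "expert_label"),
    arm = vapply(fields, `[[`, "", "arm"),
    stringsAsFactors = FALSE
  )
  list(td = td, meta = meta)
}
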