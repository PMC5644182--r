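# deduplicate pooled candidate features: keep the largest-area feature of
# every mutually-matching (mz, rt) group
dedupe_candidates <- function(cand, mz_tol_ppm, rt_tol_min) {
  if (!nrow(cand)) return(cand)
  cand <- arrange(cand, dplyr::desc(.data$area))
  kept <- cand[0, ]
  for (j in seq_len(nrow(cand))) {
    f <- cand[j, ]
    if (!nrow(kept) ||
        !nrow(match_feature(kept, f$mz, f$rt_min, mz_tol_ppm, rt_tol_min))) {
      kept <- bind_rows(kept, f)
    }
  }
  kept
}

#' Metabolite production across fermentation stages
#'
#' Applies the candidate/presence workflow to multi-stage feature data: the
#' candidate compound list is built from the final (latest) stage by
#' area/intensity thresholding, then each candidate is searched for in every
#' stage and replicate without any threshold. The report gives per-stage
#' candidate presence counts and summed matched areas, each candidate's
#' first-appearance stage, and — per condition — whether the summed matched
#' area of the final stage exceeds the preceding stage's (production
#' continuing after the growth phase).
#'
#' @param features Long feature tibble with columns `condition`, `stage`
#'   (sortable; e.g. 1, 2, 3), optional `replicate`, and `mz`, `rt_min`,
#'   `area`, `intensity`.
#' @param min_area,min_intensity Candidate thresholds (strict), applied to
#'   the final stage only.
#' @param mz_tol_ppm,rt_tol_min Matching tolerances.
#' @param min_replicates Replicates a candidate must appear in to count as
#'   present at a stage (capped at the number of replicates available).
#' @param library Optional [compound_library()] for identification of the
#'   candidates (mass match only).
#' @return A `stage_profile` list: `stage_summary` (condition x stage counts
#'   and summed areas), `candidates` (with `first_stage` and, when a library
#'   is given, `compound`), `condition_summary` (with logical `rising`), and
#'   `n_rising`.
#' @export
profile_stages <- function(features, min_area = 5e5, min_intensity = 1e4,
                           mz_tol_ppm = 10, rt_tol_min = 0.1,
                           min_replicates = 2, library = NULL) {
  stopifnot(all(c("condition", "stage", "mz", "area", "intensity") %in%
                  names(features)))
  if (!("replicate" %in% names(features))) features$replicate <- 1L
  if (!("rt_min" %in% names(features))) features$rt_min <- NA_real_
  if (!("feature_id" %in% names(features))) {
    features$feature_id <- paste0("F", seq_len(nrow(features)))
  }

  out_stage <- list()
  out_cand <- list()
  out_cond <- list()
  for (cond in unique(features$condition)) {
    fc <- filter(features, .data$condition == cond)
    stages <- sort(unique(fc$stage))
    if (length(stages) < 2) {
      abort(sprintf("condition '%s' has fewer than 2 stages.", cond),
            class = "fermkin_profile_error")
    }
    final <- filter(fc, .data$stage == stages[length(stages)])
    cand <- threshold_features(final, min_area, min_intensity)
    cand <- dedupe_candidates(cand, mz_tol_ppm, rt_tol_min)

    if (!nrow(cand)) {
      out_stage[[cond]] <- tibble(condition = cond, stage = stages,
                                  n_present = 0L, total_area = 0)
      out_cond[[cond]] <- tibble(condition = cond, n_candidates = 0L,
                                 rising = NA)
      next
    }

    rep_levels <- sort(unique(fc$replicate))   # the condition's design, not
    per_stage <- purrr::map_dfr(stages, function(s) {   # just rows observed
      fs <- filter(fc, .data$stage == s)
      reps <- lapply(rep_levels, function(rr) filter(fs, .data$replicate == rr))
      need <- min(min_replicates, length(rep_levels))
      per_cand <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
        m <- purrr::map_dfr(reps, function(tb)
          match_feature(tb, cand$mz[i], cand$rt_min[i], mz_tol_ppm, rt_tol_min))
        tibble(cand_row = i, n_rep = nrow(m),
               area = if (nrow(m)) mean(m$area) else 0)
      })
      tibble(condition = cond, stage = s,
             n_present = sum(per_cand$n_rep >= need),
             total_area = sum(per_cand$area),
             first_hit = list(per_cand$n_rep > 0))
    })

    hits <- do.call(rbind, per_stage$first_hit)   # stage x candidate
    first_stage <- apply(hits, 2, function(h)
      if (any(h)) stages[which(h)[1]] else NA)
    cand$first_stage <- first_stage
    if (!is.null(library)) {
      der <- dereplicate(cand, library, mz_tol_ppm = mz_tol_ppm,
                         rt_tol_min = rt_tol_min)
      cand <- left_join(cand,
                        dplyr::distinct(der, .data$feature_id, .keep_all = TRUE) |>
                          select("feature_id", "compound", "ppm_error"),
                        by = "feature_id")
    }
    cand$condition <- cond
    out_cand[[cond]] <- cand

    tot <- per_stage$total_area
    n_stage <- length(stages)
    out_stage[[cond]] <- select(per_stage, -"first_hit")
    out_cond[[cond]] <- tibble(
      condition = cond, n_candidates = nrow(cand),
      rising = tot[n_stage] > tot[n_stage - 1])
  }

  res <- list(stage_summary = bind_rows(out_stage),
              candidates = bind_rows(out_cand),
              condition_summary = bind_rows(out_cond))
  res$n_rising <- sum(res$condition_summary$rising, na.rm = TRUE)
  class(res) <- "stage_profile"
  res
}

#' @export
print.stage_profile <- function(x, ...) {
  n_cond <- nrow(x$condition_summary)
  cat(sprintf("<stage_profile> %d condition(s); final-stage levels higher than the preceding stage in %d of %d\n",
              n_cond, x$n_rising, sum(!is.na(x$condition_summary$rising))))
  invisible(x)
}
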