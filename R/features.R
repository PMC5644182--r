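#' Build a compound library
#'
#' A reference library for accurate-mass dereplication: compound name plus an
#' elemental formula and/or monoisotopic mass, optionally a retention time
#' and a flag marking confirmation against a physical standard. Masses are
#' computed from formulas where absent; unparseable formulas are rejected at
#' load time with the entry name.
#'
#' @param entries Tibble with columns `name` and at least one of `formula`,
#'   `monoisotopic_mass`; optional `rt_min`, `standard_confirmed`.
#' @return A validated `compound_library` tibble.
#' @export
compound_library <- function(entries) {
  entries <- as_tibble(entries)
  if (!("name" %in% names(entries)) || anyDuplicated(entries$name)) {
    abort("library entries need unique `name`s.", class = "fermkin_library_error")
  }
  if (!("monoisotopic_mass" %in% names(entries))) {
    entries$monoisotopic_mass <- NA_real_
  }
  if ("formula" %in% names(entries)) {
    needs <- is.na(entries$monoisotopic_mass) & !is.na(entries$formula)
    for (i in which(needs)) {
      entries$monoisotopic_mass[i] <- tryCatch(
        monoisotopic_mass(entries$formula[i]),
        fermkin_formula_error = function(e) {
          abort(sprintf("library entry '%s': %s", entries$name[i],
                        conditionMessage(e)),
                class = "fermkin_library_error")
        })
    }
  }
  if (anyNA(entries$monoisotopic_mass) || any(entries$monoisotopic_mass <= 0)) {
    abort("every library entry needs a positive monoisotopic mass or a formula.",
          class = "fermkin_library_error")
  }
  if (!("rt_min" %in% names(entries))) entries$rt_min <- NA_real_
  if (!("standard_confirmed" %in% names(entries))) {
    entries$standard_confirmed <- FALSE
  }
  class(entries) <- c("compound_library", class(entries))
  entries
}

#' @rdname compound_library
#' @param path CSV file with the columns of `entries`.
#' @export
read_compound_library <- function(path) {
  compound_library(readr::read_csv(path, show_col_types = FALSE))
}

#' Simulate replicate LC-MS feature tables with planted compounds
#'
#' Generates `n_replicates` feature tables for one sample: each planted
#' compound appears at the `[M+H]+` m/z of its library mass (with a small
#' mass jitter well below typical matching tolerance) in every replicate
#' except random dropouts; noise features get random m/z values kept at
#' least `noise_min_separation_ppm` away from every library adduct mass so
#' synthetic identifications are unambiguous.
#'
#' @param planted Tibble `name`, `area`, `intensity` (compounds must exist in
#'   `library`).
#' @param library A [compound_library()].
#' @param n_noise Number of unknown (noise) features per replicate.
#' @param dropout Per-replicate probability that a planted feature is absent.
#' @param mz_jitter_ppm Maximum absolute mass error applied to planted
#'   features (ppm, uniform), so a tolerance of twice the jitter always
#'   recovers them.
#' @param rt_jitter_min Maximum absolute retention-time jitter (min, uniform).
#' @param area_cv Lognormal CV of planted areas/intensities across replicates.
#' @param noise_min_separation_ppm Minimum distance between a noise m/z and
#'   any library adduct m/z.
#' @param mz_range,rt_range Acquisition ranges for noise features.
#' @param n_replicates Number of replicate tables (default 3).
#' @param seed Integer seed.
#' @return List with `tables` (list of tibbles `feature_id, mz, rt_min, area,
#'   intensity`), and `truth` (tibble `name, mz, rt_min` plus logical
#'   `rep1..repN` presence and `n_present`).
#' @export
simulate_feature_tables <- function(planted, library, n_noise = 20,
                                    dropout = 0, mz_jitter_ppm = 2,
                                    rt_jitter_min = 0.02, area_cv = 0.1,
                                    noise_min_separation_ppm = 30,
                                    mz_range = c(100, 1000),
                                    rt_range = c(0.5, 15),
                                    n_replicates = 3, seed = 1L) {
  stopifnot(inherits(library, "compound_library"))
  planted <- as_tibble(planted)
  missing_cpd <- setdiff(planted$name, library$name)
  if (length(missing_cpd)) {
    abort(paste0("planted compound(s) not in library: ",
                 paste(missing_cpd, collapse = ", ")),
          class = "fermkin_library_error")
  }
  if (any(planted$area <= 0) || any(planted$intensity <= 0)) {
    abort("planted areas/intensities must be > 0.", class = "fermkin_library_error")
  }
  set.seed(as.integer(seed))

  lib_idx <- match(planted$name, library$name)
  base_mz <- adduct_mz(library$monoisotopic_mass[lib_idx], "[M+H]+")
  base_rt <- ifelse(is.na(library$rt_min[lib_idx]),
                    runif(nrow(planted), rt_range[1], rt_range[2]),
                    library$rt_min[lib_idx])

  # all library adduct masses a noise feature must keep away from
  lib_adducts <- unlist(lapply(names(.adduct_offsets), function(a)
    adduct_mz(library$monoisotopic_mass, a)))
  draw_noise_mz <- function(n) {
    out <- numeric(0)
    tries <- 0
    while (length(out) < n) {
      tries <- tries + 1
      if (tries > 200) {
        abort("cannot place noise features away from library masses; lower `n_noise` or the separation.",
              class = "fermkin_library_error")
      }
      cand <- runif(n, mz_range[1], mz_range[2])
      ok <- vapply(cand, function(m)
        all(abs(m - lib_adducts) / m * 1e6 >= noise_min_separation_ppm),
        logical(1))
      out <- c(out, cand[ok])[seq_len(min(n, length(out) + sum(ok)))]
    }
    out
  }

  present <- matrix(runif(nrow(planted) * n_replicates) >= dropout,
                    nrow = nrow(planted))
  sarea <- sqrt(log(1 + area_cv^2))
  tables <- lapply(seq_len(n_replicates), function(r) {
    rows <- list()
    keep <- which(present[, r])
    if (length(keep)) {
      jit <- runif(length(keep), -mz_jitter_ppm, mz_jitter_ppm) * 1e-6
      ln <- function(n) rlnorm(n, -sarea^2 / 2, sarea)
      rows$planted <- tibble(
        feature_id = paste0("P", keep),
        mz = base_mz[keep] * (1 + jit),
        rt_min = pmax(base_rt[keep] +
                        runif(length(keep), -rt_jitter_min, rt_jitter_min), 0.01),
        area = planted$area[keep] * ln(length(keep)),
        intensity = planted$intensity[keep] * ln(length(keep))
      )
    }
    if (n_noise > 0) {
      rows$noise <- tibble(
        feature_id = paste0("N", seq_len(n_noise), "_", r),
        mz = draw_noise_mz(n_noise),
        rt_min = runif(n_noise, rt_range[1], rt_range[2]),
        area = exp(runif(n_noise, log(1e4), log(5e6))),
        intensity = exp(runif(n_noise, log(1e3), log(1e5)))
      )
    }
    out <- bind_rows(rows)
    if (!nrow(out)) {
      out <- tibble(feature_id = character(), mz = numeric(),
                    rt_min = numeric(), area = numeric(), intensity = numeric())
    }
    arrange(out, .data$mz)
  })

  truth <- dplyr::bind_cols(
    tibble(name = planted$name, mz = base_mz, rt_min = base_rt),
    setNames(as.data.frame(present),
             paste0("rep", seq_len(n_replicates)))
  )
  truth$n_present <- rowSums(present)
  list(tables = tables, truth = as_tibble(truth))
}

#' Threshold molecular features by area and intensity
#'
#' Keeps features whose area and intensity are strictly above the thresholds
#' (defaults 500,000 and 10,000 counts) — the candidate-compound rule applied
#' to the latest-time sample of a cultivation.
#'
#' @param features Feature tibble (`mz`, `rt_min`, `area`, `intensity`).
#' @param min_area,min_intensity Strict lower thresholds (counts).
#' @return The filtered feature tibble (possibly empty).
#' @export
threshold_features <- function(features, min_area = 5e5, min_intensity = 1e4) {
  if (min_area < 0 || min_intensity < 0) {
    abort("thresholds must be >= 0.", class = "fermkin_config_error")
  }
  filter(features, .data$area > min_area, .data$intensity > min_intensity)
}

#' Match a query feature in a feature table
#'
#' Nearest feature within an m/z tolerance (ppm) and, when the query has a
#' retention time, an rt tolerance. Ties resolve to the smallest ppm error,
#' then the earliest retention time.
#'
#' @param table Feature tibble to search.
#' @param mz Query m/z.
#' @param rt_min Query retention time (min) or `NULL` to match on mass alone.
#' @param mz_tol_ppm,rt_tol_min Matching tolerances.
#' @return The matched feature row with a `ppm_error` column, or a zero-row
#'   tibble when nothing lies within tolerance.
#' @export
match_feature <- function(table, mz, rt_min = NULL, mz_tol_ppm = 10,
                          rt_tol_min = 0.1) {
  if (mz_tol_ppm <= 0 || rt_tol_min <= 0) {
    abort("tolerances must be > 0.", class = "fermkin_config_error")
  }
  cand <- mutate(table, ppm_error = (.data$mz - !!mz) / !!mz * 1e6)
  cand <- filter(cand, abs(.data$ppm_error) <= mz_tol_ppm)
  if (!is.null(rt_min) && "rt_min" %in% names(cand)) {
    cand <- filter(cand, abs(.data$rt_min - !!rt_min) <= rt_tol_min)
  }
  if (!nrow(cand)) return(cand)
  cand <- arrange(cand, abs(.data$ppm_error), .data$rt_min)
  cand[1, ]
}

#' Count candidates reproducibly present across replicates
#'
#' A candidate counts when it matches a feature (any area/intensity — no
#' threshold on the search side) in at least two of the replicate tables.
#'
#' @param tables List of 2-3 replicate feature tibbles for one sample.
#' @param candidates Candidate feature tibble (typically the thresholded
#'   latest-time features, see [threshold_features()]).
#' @param mz_tol_ppm,rt_tol_min Matching tolerances.
#' @param min_replicates Minimum replicates a candidate must appear in
#'   (default 2).
#' @return Integer count.
#' @export
count_reproducible <- function(tables, candidates, mz_tol_ppm = 10,
                               rt_tol_min = 0.1, min_replicates = 2) {
  if (length(tables) < 2) {
    abort("need at least 2 replicate tables.", class = "fermkin_config_error")
  }
  if (!nrow(candidates)) return(0L)
  hits <- vapply(seq_len(nrow(candidates)), function(i) {
    sum(vapply(tables, function(tb)
      nrow(match_feature(tb, candidates$mz[i], candidates$rt_min[i],
                         mz_tol_ppm, rt_tol_min)) > 0, logical(1)))
  }, integer(1))
  sum(hits >= min_replicates)
}

#' Dereplicate features against a compound library
#'
#' For every feature, reports each library entry with an adduct m/z within
#' the ppm tolerance. All qualifying matches are returned — isobaric
#' ambiguity is preserved, not resolved — with their signed ppm error. When
#' a library entry carries a retention time it acts as a secondary filter.
#' Matches are mass matches only; confirmation against physical standards is
#' outside computational scope, so treat identifications accordingly.
#'
#' @param features Feature tibble.
#' @param library A [compound_library()].
#' @param adducts Adducts to consider (positive electrospray defaults).
#' @param mz_tol_ppm m/z tolerance (ppm).
#' @param rt_tol_min Retention-time tolerance (min) for entries with rt.
#' @return Tibble: `feature_id` (if present), `mz`, `rt_min`, `compound`,
#'   `adduct`, `library_mz`, `ppm_error`, `standard_confirmed`.
#' @export
dereplicate <- function(features, library,
                        adducts = c("[M+H]+", "[M+Na]+", "[M+NH4]+"),
                        mz_tol_ppm = 10, rt_tol_min = 0.1) {
  stopifnot(inherits(library, "compound_library"))
  if (!length(adducts)) abort("`adducts` must be non-empty.",
                              class = "fermkin_config_error")
  adducts <- match.arg(adducts, names(.adduct_offsets), several.ok = TRUE)
  empty <- tibble(feature_id = character(), mz = numeric(), rt_min = numeric(),
                  compound = character(), adduct = character(),
                  library_mz = numeric(), ppm_error = numeric(),
                  standard_confirmed = logical())
  if (!nrow(features)) return(empty)

  ref <- tidyr::expand_grid(i = seq_len(nrow(library)), adduct = adducts)
  ref$compound <- library$name[ref$i]
  ref$library_mz <- vapply(seq_len(nrow(ref)), function(k)
    adduct_mz(library$monoisotopic_mass[ref$i[k]], ref$adduct[k]), numeric(1))
  ref$library_rt <- library$rt_min[ref$i]
  ref$standard_confirmed <- library$standard_confirmed[ref$i]

  out <- purrr::map_dfr(seq_len(nrow(features)), function(j) {
    f <- features[j, ]
    ppm <- (f$mz - ref$library_mz) / ref$library_mz * 1e6
    ok <- abs(ppm) <= mz_tol_ppm
    if ("rt_min" %in% names(f)) {
      ok <- ok & (is.na(ref$library_rt) |
                    abs(ref$library_rt - f$rt_min) <= rt_tol_min)
    }
    if (!any(ok)) return(NULL)
    tibble(feature_id = if ("feature_id" %in% names(f)) f$feature_id else NA_character_,
           mz = f$mz,
           rt_min = if ("rt_min" %in% names(f)) f$rt_min else NA_real_,
           compound = ref$compound[ok], adduct = ref$adduct[ok],
           library_mz = ref$library_mz[ok], ppm_error = ppm[ok],
           standard_confirmed = ref$standard_confirmed[ok])
  })
  if (!nrow(out)) empty else out
}
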