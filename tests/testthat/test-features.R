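feat <- function(mz, rt = 5, area = 1e6, intensity = 2e4, id = NULL) {
  tibble::tibble(feature_id = id %||% paste0("f", seq_along(mz)),
                 mz = mz, rt_min = rt, area = area, intensity = intensity)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

demo_library <- function() {
  compound_library(tibble::tibble(
    name = c("cpdA", "cpdB", "cpdC"),
    monoisotopic_mass = c(300.1000, 452.2000, 610.3000)))
}

test_that("area/intensity thresholds are strict and correctly oriented", {
  tbl <- feat(c(200, 300, 400), area = c(6e5, 6e5, 4e5),
              intensity = c(2e4, 5e3, 2e4))
  expect_equal(threshold_features(tbl)$mz, 200)
  border <- feat(500, area = 500000, intensity = 10001)
  expect_equal(nrow(threshold_features(border)), 0)
  expect_equal(nrow(threshold_features(feat(numeric(0)))), 0)
})

test_that("thresholding equals a brute-force row filter on random tables", {
  set.seed(41)
  for (i in 1:25) {
    tbl <- feat(runif(30, 100, 1000), area = 10^runif(30, 4, 7),
                intensity = 10^runif(30, 3, 5))
    a <- 10^runif(1, 4.5, 6.5); b <- 10^runif(1, 3, 4.5)
    got <- threshold_features(tbl, a, b)
    expect_identical(got$feature_id,
                     tbl$feature_id[tbl$area > a & tbl$intensity > b])
    # monotonicity: tightening thresholds never grows the candidate list
    expect_lte(nrow(threshold_features(tbl, a * 2, b)), nrow(got))
    expect_lte(nrow(threshold_features(tbl, a, b * 2)), nrow(got))
  }
})

test_that("feature matching respects tolerances and tie-breaks", {
  tbl <- feat(c(400.0000, 400.0012, 399.9984), rt = c(5, 5.02, 4.98))
  hit <- match_feature(tbl, 400.0000, 5, mz_tol_ppm = 10, rt_tol_min = 0.1)
  expect_equal(hit$mz, 400.0000)
  expect_equal(hit$ppm_error, 0)
  # +3 ppm beats -4 ppm
  tbl2 <- feat(c(400 * (1 + 3e-6), 400 * (1 - 4e-6)))
  expect_equal(match_feature(tbl2, 400, 5)$ppm_error, 3, tolerance = 1e-6)
  # out of tolerance (2x) -> empty
  far <- feat(400 * (1 + 20e-6))
  expect_equal(nrow(match_feature(far, 400, 5, mz_tol_ppm = 10)), 0)
  # rt gate applies only when the query has an rt
  off_rt <- feat(400.0000, rt = 6)
  expect_equal(nrow(match_feature(off_rt, 400, 5, rt_tol_min = 0.1)), 0)
  expect_equal(nrow(match_feature(off_rt, 400, NULL)), 1)
})

test_that("matching is symmetric in query and target at equal tolerance", {
  set.seed(17)
  for (i in 1:30) {
    m1 <- runif(1, 100, 1000)
    m2 <- m1 * (1 + runif(1, -15e-6, 15e-6))
    f1 <- nrow(match_feature(feat(m1), m2, NULL, mz_tol_ppm = 10)) > 0
    f2 <- nrow(match_feature(feat(m2), m1, NULL, mz_tol_ppm = 10)) > 0
    expect_equal(f1, f2)
  }
})

test_that("reproducible counting applies the two-of-three rule", {
  cand <- feat(c(300, 500))
  all3 <- list(feat(c(300, 500)), feat(c(300, 500)), feat(c(300, 500)))
  expect_equal(count_reproducible(all3, cand), 2L)
  only1 <- list(feat(300), feat(700), feat(900))
  expect_equal(count_reproducible(only1, cand), 0L)
  two <- list(feat(300), feat(300), feat(900))
  expect_equal(count_reproducible(two, cand), 1L)
  expect_error(count_reproducible(list(feat(300)), cand),
               class = "fermkin_config_error")
  expect_equal(count_reproducible(all3, cand[0, ]), 0L)
})

test_that("reproducible counts equal the generator's planted truth", {
  lib <- demo_library()
  planted <- tibble::tibble(name = lib$name, area = 1e6, intensity = 2e4)
  set.seed(9)
  for (i in 1:20) {
    ft <- simulate_feature_tables(planted, lib, n_noise = 10,
                                  dropout = runif(1, 0, 0.8),
                                  seed = 100 + i)
    truth <- sum(ft$truth$n_present >= 2)
    cand <- dplyr::mutate(ft$truth[, c("mz", "rt_min")],
                          area = 1, intensity = 1)
    expect_equal(count_reproducible(ft$tables, cand), truth)
  }
})

test_that("dereplication reports exact, absent and ambiguous matches correctly", {
  lib <- demo_library()
  exact <- feat(adduct_mz(300.1000, "[M+H]+"), rt = 3)
  hit <- dereplicate(exact, lib)
  expect_equal(hit$compound, "cpdA")
  expect_equal(hit$ppm_error, 0, tolerance = 1e-9)
  off <- feat(adduct_mz(300.1000, "[M+H]+") * (1 + 25e-6))
  expect_equal(nrow(dereplicate(off, lib, mz_tol_ppm = 5)), 0)
  # isobaric pair within tolerance: both reported, ambiguity preserved
  iso <- compound_library(tibble::tibble(
    name = c("isoA", "isoB"),
    monoisotopic_mass = c(400.2000, 400.2010)))
  both <- dereplicate(feat(adduct_mz(400.2005, "[M+H]+")), iso,
                      mz_tol_ppm = 10)
  expect_setequal(both$compound, c("isoA", "isoB"))
  # sodium adduct found when enabled
  na_feat <- feat(452.2000 + 22.9892207)
  expect_equal(dereplicate(na_feat, lib)$adduct, "[M+Na]+")
})

test_that("library construction computes masses and rejects bad entries", {
  lib <- compound_library(tibble::tibble(name = "griseofulvin",
                                         formula = "C17H17ClO6"))
  expect_equal(lib$monoisotopic_mass, 352.071366, tolerance = 1e-6)
  expect_error(compound_library(tibble::tibble(name = c("a", "a"),
                                               monoisotopic_mass = c(1, 2))),
               class = "fermkin_library_error")
  expect_error(compound_library(tibble::tibble(name = "bad", formula = "Qz9")),
               class = "fermkin_library_error")
})

test_that("dereplication is sound on synthetic tables (perfect precision/recall)", {
  lib <- demo_library()
  planted <- tibble::tibble(name = lib$name, area = 1e6, intensity = 2e4)
  ft <- simulate_feature_tables(planted, lib, n_noise = 25, dropout = 0,
                                mz_jitter_ppm = 5,
                                noise_min_separation_ppm = 30, seed = 77)
  for (tb in ft$tables) {
    der <- dereplicate(tb, lib, adducts = "[M+H]+", mz_tol_ppm = 10,
                       rt_tol_min = 10)
    expect_setequal(der$compound, lib$name)          # recall = 1
    expect_true(all(grepl("^P", der$feature_id)))    # precision = 1
  }
})
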