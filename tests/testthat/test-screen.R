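test_that("the autofluorescence filter uses a strict background-fold rule", {
  expect_true(filter_autofluorescence(600, 10, 100, 100))   # 6x background
  expect_false(filter_autofluorescence(500, 500, 100, 100)) # exactly 5x
  expect_false(filter_autofluorescence(0, 0, 100, 100))     # dark compound
  expect_true(filter_autofluorescence(10, 501, 100, 100))   # either channel
  expect_error(filter_autofluorescence(10, 10, 0, 100),
               class = "fretscreen_error_config")
})

test_that("the deviation filter trips above/below 30% in either channel", {
  expect_true(filter_fret_deviation(140, 100, 100, 100))   # +40%
  expect_true(filter_fret_deviation(100, 60, 100, 100))    # -40%
  expect_false(filter_fret_deviation(110, 92, 100, 100))   # within band
  expect_false(filter_fret_deviation(130, 70, 100, 100))   # exactly 30%
  expect_error(filter_fret_deviation(1, 1, 100, 0),
               class = "fretscreen_error_config")
})

test_that("the dual-excitation filter compares apparent inhibitions", {
  expect_true(filter_dual_excitation(35, 12))
  expect_false(filter_dual_excitation(25, 25))
  expect_true(filter_dual_excitation(25, 15 - 1e-6))  # strict > 10
  expect_false(filter_dual_excitation(25, 15))
})

test_that("the pan-assay filter needs simultaneous reduction and data", {
  expect_true(filter_pan_assay(40, 45))
  expect_false(filter_pan_assay(40, 5))
  expect_true(filter_pan_assay(20, 20))         # inclusive threshold
  expect_false(filter_pan_assay(40, NA))        # not evaluable, never excluded
})

test_that("hit calling is inclusive at the threshold and excludes flagged", {
  res <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    excluded_by = c("none", "none", "dual_excitation"),
    inhibition_410 = c(20.0, 19.9, 80))
  out <- call_hits(res)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE))
})

test_that("screen accounting reproduces printed totals and percentages", {
  arc4 <- screen_summary(1120, 89, 12, 29, 6)
  expect_equal(arc4$n_excluded_total, 130)
  expect_equal(arc4$pct_excluded_total, "11.6%")
  expect_equal(arc4$pct_excluded_fluor, "7.9%")
  expect_equal(arc4$pct_excluded_dual, "1.1%")
  expect_equal(arc4$pct_excluded_pan, "2.6%")
  expect_equal(arc4$pct_hits, "0.54%")

  sam <- screen_summary(1120, 121, 14, 18, 5)
  expect_equal(sam$n_excluded_total, 153)
  expect_equal(sam$pct_excluded_total, "13.7%")
  expect_equal(sam$pct_hits, "0.45%")
})

test_that("summary percentages equal rounded count ratios for random counts", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(200:2000, 1)
    k <- sort(sample(0:(n %/% 4), 3))
    h <- sample(0:10, 1)
    s <- screen_summary(n, k[1], k[2], k[3], h)
    expect_equal(s$pct_excluded_total,
                 paste0(formatC(round(100 * sum(k) / n, 1), format = "f",
                                digits = 1), "%"))
    expect_equal(s$pct_hits,
                 paste0(formatC(round(100 * h / n, 2), format = "f",
                                digits = 2), "%"))
  }
})

test_that("exclusion attribution partitions compounds and is disjoint from hits", {
  zn <- zero_noise()
  sim <- simulate_screen(
    library = compound_library(n_inactive = 60, n_inhibitor_a = 4,
                               n_inhibitor_b = 2, n_blue = 4, n_green = 3,
                               n_shifted = 3, n_quencher = 2),
    config_a = sim_config(noise = zn), config_b = sam_config(noise = zn),
    seed = 9)
  scr <- run_screen(sim$assay_a, sim$assay_b)
  for (lab in c("A", "B")) {
    res <- dplyr::filter(scr$results, assay == lab)
    summ <- dplyr::filter(scr$summary, assay == lab)
    expect_equal(summ$n_excluded_total,
                 summ$n_excluded_fluor + summ$n_excluded_dual +
                   summ$n_excluded_pan)
    expect_equal(sum(res$excluded_by != "none"), summ$n_excluded_total)
    expect_false(any(res$is_hit & res$excluded_by != "none"))
    expect_true(all(table(res$compound_id) == 1))
  }
})

test_that("raising a stage threshold weakly shrinks that stage's count", {
  sim <- simulate_screen(
    library = compound_library(n_inactive = 60, n_inhibitor_a = 4,
                               n_inhibitor_b = 2, n_blue = 4, n_green = 3,
                               n_shifted = 3, n_quencher = 2),
    seed = 10)
  base <- dplyr::filter(run_screen(sim$assay_a, sim$assay_b)$summary,
                        assay == "A")
  looser_rel <- dplyr::filter(
    run_screen(sim$assay_a, sim$assay_b, rel_threshold = 0.6)$summary,
    assay == "A")
  looser_diff <- dplyr::filter(
    run_screen(sim$assay_a, sim$assay_b, diff_threshold = 400)$summary,
    assay == "A")
  expect_lte(looser_rel$n_excluded_fluor, base$n_excluded_fluor)
  expect_lte(looser_diff$n_excluded_dual, base$n_excluded_dual)
})

test_that("a compound excluded in only one assay can still be pan-flagged there", {
  # quencher-like compound A: reduces signal in both assays, but carries
  # strong autofluorescence only in assay B -> pan-excluded in A only
  mk_res <- function(auto) {
    tibble::tibble(compound_id = "X", fluor_477 = if (auto) 1e4 else 10,
                   fluor_527 = 10, sample_477 = 100, sample_527 = 100,
                   inhibition_410 = 42, inhibition_430 = 44,
                   strong_autofluorescence = auto,
                   fret_fluor_deviation = FALSE,
                   dual_excitation_discrepancy = FALSE)
  }
  # reproduce run_screen's attribution logic on a minimal pair
  this <- mk_res(FALSE); other <- mk_res(TRUE)
  survivor <- !(this$strong_autofluorescence | this$fret_fluor_deviation |
                  this$dual_excitation_discrepancy)
  pan_this <- survivor & filter_pan_assay(this$inhibition_410,
                                          other$inhibition_410)
  survivor_other <- !(other$strong_autofluorescence |
                        other$fret_fluor_deviation |
                        other$dual_excitation_discrepancy)
  expect_true(pan_this)
  expect_false(survivor_other)  # in B the first stage wins the attribution
})

test_that("library mismatch and empty libraries are errors", {
  zn <- zero_noise()
  lib_small <- compound_library(n_inactive = 20, n_inhibitor_a = 1,
                                n_inhibitor_b = 1, n_blue = 1, n_green = 1,
                                n_shifted = 1, n_quencher = 1)
  sim <- simulate_screen(library = lib_small, config_a = sim_config(noise = zn),
                         config_b = sam_config(noise = zn), seed = 2)
  sim_other <- simulate_screen(
    library = dplyr::mutate(lib_small,
                            compound_id = paste0(compound_id, "x")),
    config_a = sim_config(noise = zn), config_b = sam_config(noise = zn),
    seed = 2)
  expect_error(run_screen(sim$assay_a, sim_other$assay_b),
               class = "fretscreen_error_reconciliation")
  expect_error(simulate_screen(library = compound_library(
    n_inactive = 0, n_inhibitor_a = 0, n_inhibitor_b = 0, n_blue = 0,
    n_green = 0, n_shifted = 0, n_quencher = 0)),
    class = "fretscreen_error_config")
})

test_that("screen reports round-trip with correct summary counts", {
  res <- tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    inhibition_410 = c(55, 10, 28),
    inhibition_430 = c(54, 11, 27),
    strong_autofluorescence = c(TRUE, FALSE, FALSE),
    fret_fluor_deviation = FALSE,
    dual_excitation_discrepancy = FALSE,
    pan_assay = FALSE,
    excluded_by = c("fluorescence", "none", "none"),
    is_hit = c(FALSE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_screen_report(res, path)
  back <- readr::read_csv(out$csv, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  summ <- jsonlite::read_json(out$json)
  expect_equal(summ$n_excluded_total, 1)
  expect_equal(summ$n_hits, 1)
  expect_equal(summ$pct_excluded_total, "33.3%")

  expect_error(write_screen_report(res[0, ], path),
               class = "fretscreen_error_validation")
  expect_error(write_screen_report(res, "/nonexistent-dir/x/report.csv"),
               class = "fretscreen_error_io")

  expect_s3_class(plot_screen(res), "ggplot")
})
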