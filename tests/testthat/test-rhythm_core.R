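test_that("inter-onset intervals are differences of consecutive onsets", {
  obs <- assemble_observation_set(make_events(c(0, 0.5, 1.0, 1.5)))
  iv <- sequence_intervals(obs)
  expect_equal(iv$t_s, c(0.5, 0.5, 0.5))
  expect_equal(iv$k, 1:3)

  obs2 <- assemble_observation_set(make_events(c(0, 0.4, 1.2)))
  expect_equal(sequence_intervals(obs2)$t_s, c(0.4, 0.8))

  # single event: empty series, not an error
  obs1 <- assemble_observation_set(make_events(2.0))
  expect_equal(nrow(sequence_intervals(obs1)), 0L)
})

test_that("intervals never cross displays or modes", {
  ev <- dplyr::bind_rows(
    make_events(c(0, 0.5), display_id = "D01"),
    make_events(c(100, 100.5), display_id = "D02"),
    make_events(c(0.2, 0.7), display_id = "D01", mode = "motoric",
                behaviour = "sway")
  )
  iv <- sequence_intervals(assemble_observation_set(ev))
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$t_s, rep(0.5, 3))
})

test_that("duplicate onsets are merged with a warning", {
  suppressWarnings(  # assembly also flags the duplicated event row
    obs <- assemble_observation_set(make_events(c(0, 0.5, 0.5, 1.0)))
  )
  expect_warning(iv <- sequence_intervals(obs), "duplicate")
  expect_equal(iv$t_s, c(0.5, 0.5))
})

test_that("interval ratios follow r = t/(t + t_next)", {
  expect_equal(interval_ratio(1, 1), 0.5)
  expect_equal(interval_ratio(1, 3), 0.25)
  expect_equal(round(interval_ratio(1, 2), 3), 0.333)
  expect_equal(round(interval_ratio(2, 1), 3), 0.667)
  expect_equal(interval_ratio(3, 1), 0.75)
  expect_error(interval_ratio(0, 1), "positive")

  obs <- obs_from_intervals(list(c(2, 1, 1)))
  rt <- interval_ratios_table(sequence_intervals(obs))
  expect_equal(round(rt$r, 4), c(0.6667, 0.5))
})

test_that("ratio identities hold: bounds, reversal, scale invariance", {
  set.seed(42)
  for (rep in 1:20) {
    t <- stats::rlnorm(10, log(0.5), 0.6)
    obs <- obs_from_intervals(list(t))
    rt <- interval_ratios_table(sequence_intervals(obs))
    expect_true(all(rt$r > 0 & rt$r < 1))
    # reversal: r(a, b) = 1 - r(b, a)
    expect_equal(interval_ratio(t[-length(t)], t[-1]),
                 1 - interval_ratio(t[-1], t[-length(t)]))
    # scaling all onsets leaves ratios and CV unchanged
    c_scale <- stats::runif(1, 0.1, 10)
    obs_sc <- obs_from_intervals(list(t * c_scale))
    rt_sc <- interval_ratios_table(sequence_intervals(obs_sc))
    expect_equal(rt_sc$r, rt$r)
    expect_equal(unbiased_cv(t * c_scale), unbiased_cv(t))
  }
})

test_that("unbiased CV applies the (1 + 1/(4n)) correction", {
  expect_equal(unbiased_cv(c(1, 1, 1, 1)), 0)
  expect_equal(unbiased_cv(c(1, 2, 1, 2)), 0.40896, tolerance = 1e-5)
  expect_true(is.na(unbiased_cv(3)))
  st <- sequence_stats(sequence_intervals(obs_from_intervals(
    list(c(1, 2, 1, 2), c(0.5, 0.5, 0.5), 1.0)
  )))
  expect_equal(st$n_intervals, c(4L, 3L, 1L))
  expect_equal(st$cv_unbiased[1:2], c(0.40896, 0), tolerance = 1e-5)
  expect_true(is.na(st$cv_unbiased[[3]]))
  expect_equal(st$mean_ioi_s, c(1.5, 0.5, 1.0))
})

test_that("the default scheme has the midpoint-constructed bins", {
  sch <- rhythm_scheme()
  expect_equal(sch$center[sch$kind == "on_integer"],
               c(1/4, 1/3, 1/2, 2/3, 3/4))
  iso <- sch[sch$name == "1:1", ]
  expect_equal(iso$lower, 11/24)
  expect_equal(iso$upper, 13/24)
  expect_equal(iso$width, 1/12)
  off <- sch[sch$name == "off(1:2-1:1)", ]
  expect_equal(off$lower, 0.375)
  expect_equal(off$upper, 11/24)
  expect_equal(off$center, 5/12)
  # contiguous tiling over [0.22917, 0.77083], strictly increasing edges
  expect_equal(sch$lower[-1], sch$upper[-nrow(sch)])
  expect_true(all(diff(sch$lower) > 0))
  expect_equal(sch$lower[[1]], 11/48)
  expect_equal(sch$upper[[nrow(sch)]], 37/48)
  expect_true(all(sch$kind == rep(c("on_integer", "off_integer"),
                                  length.out = 9)))
})

test_that("classification is half-open, matches a linear scan, and flags outside", {
  sch <- rhythm_scheme()
  expect_equal(classify_ratios(0.5, sch), "1:1")
  expect_equal(classify_ratios(0.44, sch), "off(1:2-1:1)")
  expect_equal(classify_ratios(0.10, sch), "outside")
  # shared edges go to the upper bin (half-open [lower, upper))
  expect_equal(classify_ratios(11/24, sch), "1:1")
  expect_equal(classify_ratios(13/24, sch), "off(1:1-2:1)")
  # final bin is closed above
  expect_equal(classify_ratios(37/48, sch), "3:1")
  expect_error(classify_ratios(1.2, sch), "0, 1")

  set.seed(7)
  r <- stats::runif(10000, 1e-6, 1 - 1e-6)
  expect_equal(classify_ratios(r, sch), classify_linear_scan(r, sch))
})

test_that("density profiles normalise by bin width and conserve counts", {
  sch <- rhythm_scheme()
  ratios <- tibble::tibble(individual_id = "I01",
                           r = rep(0.5, 6),
                           bin = "1:1", mode = "vocal")
  prof <- density_profile(ratios, sch)
  expect_equal(prof$density[prof$name == "1:1"], 72)
  expect_equal(sum(prof$density[prof$name != "1:1"]), 0)
  expect_equal(unique(prof$isochrony_rate), 1)
  # conservation: sum(density * width) = in-scheme count, plus outside count
  set.seed(11)
  r <- stats::runif(500, 0.05, 0.95)
  ratios2 <- tibble::tibble(individual_id = rep(c("A", "B"), each = 250),
                            r = r, bin = classify_ratios(r, sch))
  prof2 <- density_profile(ratios2, sch)
  per_ind <- dplyr::summarise(dplyr::group_by(prof2, individual_id),
                              recovered = sum(density * width),
                              n_in = dplyr::first(n_in_scheme),
                              n_out = dplyr::first(n_outside))
  expect_equal(per_ind$recovered, as.numeric(per_ind$n_in))
  expect_equal(per_ind$n_in + per_ind$n_out, c(250, 250))
  # empty group is flagged
  prof3 <- density_profile(
    tibble::tibble(individual_id = "C", r = 0.1,
                   bin = classify_ratios(0.1, sch)), sch)
  expect_true(all(prof3$empty))
  expect_true(is.na(unique(prof3$isochrony_rate)))
})

test_that("inclusion filters apply the 50/25/4 thresholds jointly", {
  # A: 49 ratios total -> excluded overall
  # B: 50 total (25 vocal + 25 motoric) -> kept everywhere count-based
  # C: 55 total but 20 vocal -> kept overall, excluded from the vocal view
  mk <- function(id, n_vocal, n_motoric, n_disp_v = 1) {
    per_disp <- ceiling(n_vocal / n_disp_v)
    vocal <- lapply(seq_len(n_disp_v), function(d) {
      k <- min(per_disp, n_vocal - (d - 1) * per_disp)
      tibble::tibble(individual_id = id, mode = "vocal",
                     display_id = sprintf("%s_V%d", id, d),
                     r = rep(0.5, k))
    })
    dplyr::bind_rows(c(vocal, list(
      tibble::tibble(individual_id = id, mode = "motoric",
                     display_id = paste0(id, "_M1"),
                     r = rep(0.5, n_motoric))
    )))
  }
  ratios <- dplyr::bind_rows(mk("A", 24, 25), mk("B", 25, 25),
                             mk("C", 20, 35, n_disp_v = 4))
  fl <- apply_inclusion_filters(ratios)
  expect_equal(sort(fl$overall), c("B", "C"))
  expect_equal(fl$vocal, "B")
  expect_equal(sort(fl$motoric), c("A", "B", "C"))
  expect_equal(fl$report$n_ratios_total, c(49L, 50L, 55L))
  # tempo view: >= 4 displays within the mode, of the mode-included set
  expect_equal(fl$tempo_vocal, character(0))  # B has 1 vocal display
  fl2 <- apply_inclusion_filters(dplyr::bind_rows(
    mk("D", 28, 25, n_disp_v = 4), mk("E", 25, 25)
  ))
  expect_equal(fl2$tempo_vocal, "D")
})

test_that("tempo summaries recover simulated base tempi and the mode gap", {
  cfg <- simulation_config(displays_per_individual_mean = 8)
  sim <- simulate_colony(cfg, seed = 5)
  iv <- sequence_intervals(sim$observations)
  tmp <- tempo_summary(iv)
  expect_equal(tmp$mean_ioi_s[tmp$individual_id == "I01"][1],
               mean(iv$t_s[iv$individual_id == "I01" &
                             iv$display_id == tmp$display_id[1]]))
  # per-display means scatter around the individual's base tempo
  per_ind <- dplyr::summarise(
    dplyr::group_by(tmp[tmp$mode == "vocal", ], individual_id),
    m = mean(mean_ioi_s), n = dplyr::n())
  per_ind <- dplyr::inner_join(per_ind, sim$individuals, by = "individual_id")
  per_ind <- per_ind[per_ind$n >= 3, ]
  expect_true(stats::cor(per_ind$m, per_ind$base_vocal_s) > 0.8)
  # motoric sequences are slower on average than vocal ones
  expect_gt(mean(tmp$mean_ioi_s[tmp$mode == "motoric"]),
            mean(tmp$mean_ioi_s[tmp$mode == "vocal"]))
})
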