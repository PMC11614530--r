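# Shared fixtures: tiny event tables and an enumeration oracle for the exact
# signed-rank test.

# events for one display: onsets per mode, metadata filled in
make_events <- function(onsets, mode = "vocal", individual_id = "I01",
                        display_id = "D01", zoo = "A", group = "A1",
                        context = "undirected", behaviour = "pant") {
  tibble::tibble(
    individual_id = individual_id, display_id = display_id,
    zoo = zoo, group = group, mode = mode, context = context,
    behaviour = behaviour, onset_s = onsets, offset_s = NA_real_,
    sex = NA_character_, age_years = NA_real_
  )
}

# an observation set whose sequences have prescribed interval vectors
obs_from_intervals <- function(interval_list, mode = "vocal", ...) {
  ev <- dplyr::bind_rows(lapply(seq_along(interval_list), function(i) {
    make_events(cumsum(c(0, interval_list[[i]])), mode = mode,
                display_id = sprintf("D%02d", i), ...)
  }))
  assemble_observation_set(ev)
}

# brute-force two-sided signed-rank p by enumerating all 2^n sign vectors;
# independent of psignrank
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(rk[as.logical(s)]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(v = v_obs, p_two_sided = min(1, 2 * min(p_le, p_ge)))
}

# linear-scan classifier used as the oracle for classify_ratios
classify_linear_scan <- function(r, scheme) {
  vapply(r, function(ri) {
    for (i in seq_len(nrow(scheme))) {
      hit <- if (i == nrow(scheme)) {
        ri >= scheme$lower[[i]] && ri <= scheme$upper[[i]]
      } else {
        ri >= scheme$lower[[i]] && ri < scheme$upper[[i]]
      }
      if (hit) return(scheme$name[[i]])
    }
    "outside"
  }, character(1))
}
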