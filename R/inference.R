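# Paired exact Wilcoxon battery over on-/off-integer densities, mixed models
# for regularity (CV) and isochrony rate, AIC covariate screening, and
# Benjamini-Hochberg correction.

#' Shapiro-Wilk normality check
#'
#' Used to justify the nonparametric on/off battery: the bin-width-normalised
#' category densities are typically strongly non-normal.
#'
#' @param x Numeric vector, `3 <= length(x) <= 5000`, non-constant.
#' @return A one-row tibble: `test`, `statistic` (W), `p_value`, `n`.
#' @export
shapiro_check <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("input is constant; W undefined", call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(test = "shapiro_wilk", statistic = unname(sw$statistic),
                 p_value = sw$p.value, n = length(x))
}

#' Paired exact Wilcoxon signed-rank test
#'
#' Signed-rank test of paired samples. Zero differences are dropped before
#' ranking (with their count reported); V is the sum of the ranks of the
#' positive differences. The p-value is exact (from the signed-rank null
#' distribution) whenever the absolute differences are free of ties; with
#' ties a normal approximation with tie correction is used and flagged.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A one-row tibble: `test`, `statistic` (V), `p_value`, `n_pairs`,
#'   `n_used` (after dropping zeros), `n_zero_dropped`, `exact` (logical),
#'   `alternative`.
#' @examples
#' wilcoxon_signed_exact(2:13, 1:12)   # all positive differences: V = 78
#' @export
wilcoxon_signed_exact <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(test = "wilcoxon_signed_rank", statistic = NA_real_,
                          p_value = NA_real_, n_pairs = n_pairs, n_used = 0L,
                          n_zero_dropped = n_pairs, exact = NA,
                          alternative = alternative))
  }
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  ties <- any(duplicated(rk))
  if (!ties) {
    p_le <- stats::psignrank(v, n)
    p_ge <- 1 - stats::psignrank(v - 1, n)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    exact <- FALSE
  }
  tibble::tibble(test = "wilcoxon_signed_rank", statistic = v, p_value = p,
                 n_pairs = n_pairs, n_used = n,
                 n_zero_dropped = n_pairs - n, exact = exact,
                 alternative = alternative)
}

#' Paired on/off-integer Wilcoxon battery
#'
#' For each on-integer rhythm category, tests across individuals whether the
#' bin-width-normalised density inside the category exceeds the density of
#' its neighbouring off-integer counterpart(s): adjacent off-bin counts are
#' pooled (counts summed, widths summed; the outermost categories have a
#' single interior neighbour) or averaged, per `neighbours`. Two further
#' comparisons centre on isochrony: the 1:1 density against the pooled
#' density of all other in-scheme ratios, and 1:1 against each adjacent
#' on-integer category (1:2 vs 1:1, 1:1 vs 2:1). All p-values of the battery
#' form one Benjamini-Hochberg family.
#'
#' @param profile Output of [density_profile()] grouped by individual.
#' @param scheme The [rhythm_scheme()] used to build the profile.
#' @param neighbours `"pool"` (default) or `"mean"` for combining the two
#'   adjacent off-bins.
#' @param alternative Passed to [wilcoxon_signed_exact()] (default
#'   two-sided).
#' @return A tibble of test results with `comparison`, V, raw and
#'   BH-adjusted p-values, and pair counts.
#' @export
on_off_battery <- function(profile, scheme = rhythm_scheme(),
                           neighbours = c("pool", "mean"),
                           alternative = "two.sided") {
  neighbours <- match.arg(neighbours)
  inds <- unique(profile$individual_id)
  if (length(inds) < 2) {
    stop("need at least 2 individuals for the paired battery", call. = FALSE)
  }
  wide_count <- tidyr::pivot_wider(
    profile[c("individual_id", "name", "count")],
    names_from = "name", values_from = "count", values_fill = 0
  )
  wide_count <- wide_count[match(inds, wide_count$individual_id), ]
  width_of <- stats::setNames(scheme$width, scheme$name)
  dens <- function(bins) {
    counts <- rowSums(as.matrix(wide_count[, bins, drop = FALSE]))
    if (neighbours == "pool" || length(bins) == 1L) {
      counts / sum(width_of[bins])
    } else {
      rowMeans(sapply(bins, function(b) {
        wide_count[[b]] / width_of[[b]]
      }))
    }
  }
  on_idx <- which(scheme$kind == "on_integer")
  results <- list()
  for (i in on_idx) {
    nb <- intersect(c(i - 1L, i + 1L), seq_len(nrow(scheme)))
    nb <- nb[scheme$kind[nb] == "off_integer"]
    res <- wilcoxon_signed_exact(dens(scheme$name[[i]]),
                                 dens(scheme$name[nb]),
                                 alternative = alternative)
    res$comparison <- paste0(scheme$name[[i]], " on vs off")
    results[[length(results) + 1L]] <- res
  }
  iso <- which(scheme$kind == "on_integer" & scheme$center == 0.5)
  others <- setdiff(seq_len(nrow(scheme)), iso)
  res <- wilcoxon_signed_exact(dens(scheme$name[iso]),
                               # rest of the scheme is always pooled: one
                               # combined density of all non-isochronous
                               # in-scheme ratios
                               rowSums(as.matrix(
                                 wide_count[, scheme$name[others], drop = FALSE]
                               )) / sum(scheme$width[others]),
                               alternative = alternative)
  res$comparison <- "isochrony vs off-isochrony"
  results[[length(results) + 1L]] <- res
  on_centers <- scheme$center[on_idx]
  iso_pos <- which(abs(on_centers - 0.5) < 1e-12)
  for (adj in c(iso_pos - 1L, iso_pos + 1L)) {
    if (adj < 1 || adj > length(on_idx)) next
    a <- on_idx[[min(adj, iso_pos)]]
    b <- on_idx[[max(adj, iso_pos)]]
    res <- wilcoxon_signed_exact(dens(scheme$name[[a]]), dens(scheme$name[[b]]),
                                 alternative = alternative)
    res$comparison <- paste0(scheme$name[[a]], " vs ", scheme$name[[b]])
    results[[length(results) + 1L]] <- res
  }
  out <- dplyr::bind_rows(results)
  out$p_adjusted <- bh_adjust(out$p_value)
  dplyr::relocate(out, "comparison")
}

# --- Mixed models -----------------------------------------------------------

tidy_mixed_fit <- function(fit, family) {
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  if (family == "gaussian") {
    # lmerTest gives Satterthwaite df and p; record the mechanism
    stat_col <- "t value"
    p_col <- grep("^Pr", names(coefs), value = TRUE)
    statistic_name <- "t"
    p_method <- if (length(p_col) == 1) "satterthwaite" else "normal_approx"
    if (length(p_col) == 0) {
      coefs[["p"]] <- 2 * stats::pnorm(-abs(coefs[[stat_col]]))
      p_col <- "p"
    }
  } else {
    stat_col <- "z value"
    p_col <- grep("^Pr", names(coefs), value = TRUE)
    statistic_name <- "Z"
    p_method <- "wald_z"
  }
  terms <- tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[["Estimate"]],
    std_error = coefs[["Std. Error"]],
    statistic = coefs[[stat_col]],
    statistic_name = statistic_name,
    p_value = coefs[[p_col[[1]]]],
    p_method = p_method
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      terms = terms,
      varcorr = tibble::tibble(group = vc$grp, variance = vc$vcov,
                               sd = vc$sdcor),
      log_likelihood = as.numeric(stats::logLik(fit)),
      aic = stats::AIC(fit),
      n_obs = stats::nobs(fit),
      singular = lme4::isSingular(fit),
      converged = length(fit@optinfo$conv$lme4$messages) == 0,
      family = family,
      formula = deparse1(stats::formula(fit)),
      fit = fit
    ),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> ", x$family, ", ", x$formula, "\n", sep = "")
  cat("  n = ", x$n_obs, ", AIC = ", round(x$aic, 1),
      if (x$singular) ", SINGULAR FIT" else "",
      if (!x$converged) ", NOT CONVERGED" else "", "\n", sep = "")
  print(as.data.frame(x$terms[c("term", "estimate", "std_error",
                                "statistic", "p_value")]), digits = 3)
  invisible(x)
}

#' Linear mixed model for sequence regularity
#'
#' Fits (by REML) a linear mixed model of the unbiased coefficient of
#' variation of each display sequence on the chosen fixed effects, with a
#' random intercept for the displaying individual. Degrees of freedom and
#' p-values use the Satterthwaite approximation; singular fits are flagged,
#' not hidden.
#'
#' @param stats_tbl Output of [sequence_stats()] (rows with `NA` CV are
#'   dropped with a message).
#' @param fixed Character vector of fixed effects among
#'   `c("zoo", "mode", "context")` (default all three).
#' @param random Random-intercept grouping columns (default individual).
#' @return A `mixed_model_result`.
#' @export
fit_cv_lmm <- function(stats_tbl, fixed = c("zoo", "mode", "context"),
                       random = "individual_id") {
  dat <- stats_tbl[!is.na(stats_tbl$cv_unbiased), ]
  dropped <- nrow(stats_tbl) - nrow(dat)
  if (dropped > 0) {
    message(dropped, " sequence(s) without a defined CV excluded from the LMM")
  }
  for (f in fixed) {
    if (length(unique(dat[[f]])) < 2) {
      stop("fixed effect '", f, "' has fewer than 2 levels in the data",
           call. = FALSE)
    }
  }
  if (length(unique(dat$individual_id)) < 2) {
    stop("need at least 2 individuals", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "cv_unbiased ~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  fit <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  tidy_mixed_fit(fit, "gaussian")
}

#' Binomial mixed model for isochrony rate
#'
#' Fits a binomial-logit mixed model of the per-ratio isochrony indicator
#' (1 = ratio in the 1:1 bin, 0 = any other ratio) on the chosen fixed
#' effects, with random intercepts for the displaying individual and the
#' specific display sequence. Modelling each ratio as a Bernoulli row is
#' likelihood-equivalent to aggregated binomial counts with the same
#' covariates, and is what lets the display-level intercept attach to the
#' right rows. Fitted by Laplace-approximate ML (lme4::glmer).
#'
#' @param ratios Output of [interval_ratios_table()] with the `isochronous`
#'   column (i.e. classified against a scheme).
#' @param fixed Fixed effects among `c("zoo", "mode", "context")`.
#' @param random Random-intercept grouping columns (default individual and
#'   display).
#' @return A `mixed_model_result`; non-convergence and singular fits are
#'   flagged in the result.
#' @export
fit_isochrony_glmm <- function(ratios, fixed = c("zoo", "mode", "context"),
                               random = c("individual_id", "display_id")) {
  stopifnot("isochronous" %in% names(ratios))
  dat <- ratios
  dat$iso <- as.integer(dat$isochronous)
  for (f in fixed) {
    if (length(unique(dat[[f]])) < 2) {
      stop("fixed effect '", f, "' has fewer than 2 levels in the data",
           call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    "iso ~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  fit <- suppressMessages(lme4::glmer(fml, data = dat, family = stats::binomial()))
  tidy_mixed_fit(fit, "binomial")
}

#' AIC comparison of candidate mixed models
#'
#' Screens covariates the way the models were selected: candidate models are
#' refit on identical data and ranked by AIC; an addition that fails to lower
#' AIC is reported as non-improving.
#'
#' @param fits Named list of `mixed_model_result` objects fit to the same
#'   rows.
#' @return A tibble ranked by AIC with `delta_aic` relative to the best model
#'   and `improves_on_first` relative to the first (base) entry.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "mixed_model_result")))
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) {
    stop("models were fit on differing numbers of rows; AIC not comparable",
         call. = FALSE)
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model_", seq_along(fits))
  out <- tibble::tibble(
    model = nm,
    formula = vapply(fits, function(f) f$formula, character(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  out$delta_aic <- out$aic - min(out$aic)
  out$improves_on_first <- out$aic < out$aic[[1]]
  dplyr::arrange(out, .data$aic)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; adjusted values are monotone in
#' the raw p-values and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
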