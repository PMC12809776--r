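#' Prediction accuracy by position-statistic bin
#'
#' Bins residue positions into quantile bins of a fitted position statistic
#' (`sigma2` or `rho`) and reports, per bin, the regression R-squared of the
#' posterior-mean scores of the bin's non-synonymous variants against a
#' predictor: by default the model's own prior mean (the upper bound for a
#' linear predictor using position and substitution information), or an
#' external per-variant score column (e.g. a pathogenicity predictor).
#'
#' @param fit A `dms_fit` of model 3.
#' @param bin_by `"sigma2"` (default) or `"rho"`.
#' @param n_bins Number of quantile bins (default 10, i.e. deciles; 20 gives
#'   ventiles).
#' @param predictor Optional numeric vector aligned with `fit$scores` rows,
#'   used instead of the prior mean.
#' @return A tibble with one row per bin: bin index, the bin's statistic
#'   range, number of variants and `r2`.
#' @export
prediction_r2_by_bin <- function(fit, bin_by = c("sigma2", "rho"),
                                 n_bins = 10, predictor = NULL) {
  bin_by <- match.arg(bin_by)
  if (bin_by == "rho" && fit$model != 3) abort("rho bins need a model-3 fit")
  ps <- fit$positions |> filter(.data$type == "residue")
  stat <- if (bin_by == "sigma2") ps$sigma2_mean else ps$rho_mean
  if (n_bins > nrow(ps)) abort("n_bins exceeds the number of residue positions")
  qs <- stats::quantile(stat, probs = seq(0, 1, length.out = n_bins + 1L), type = 7)
  qs[1L] <- -Inf; qs[n_bins + 1L] <- Inf
  bin_of_pos <- stats::setNames(as.integer(cut(stat, qs, labels = FALSE)),
                                ps$pos_group)

  sc <- fit$scores
  pred <- predictor %||% predict_prior_mean(fit)
  keep <- sc$mclass != "synonymous" &
    sc$pos_group %in% ps$pos_group & !is.na(pred)
  df <- tibble(
    bin = bin_of_pos[as.character(sc$pos_group[keep])],
    beta = sc$beta_mean[keep],
    pred = pred[keep]
  )
  df |>
    group_by(.data$bin) |>
    summarise(
      n_variants = n(),
      r2 = if (n() >= 3 && stats::sd(.data$pred) > 0 && stats::sd(.data$beta) > 0)
        stats::cor(.data$beta, .data$pred)^2 else NA_real_,
      .groups = "drop"
    ) |>
    mutate(bin_by = bin_by)
}

# Prior-mean prediction for every variant of a fit, from its own posterior
# means. Works for variants inside or outside the fitted subset as long as
# the position/substitution maps are supplied.
predict_prior_mean <- function(fit, pmap = fit$scores$pos_group,
                               amap = if (fit$model >= 2) fit$scheme$amap) {
  phi <- fit$positions$phi_mean
  nu <- if (fit$model >= 2) nu_summary(fit)$nu_mean[-fit$scheme$A]
  rho <- if (fit$model == 3) fit$positions$rho_mean
  prior_mean_beta(phi, nu, rho, pmap, amap, model = fit$model)
}

# Subset a substitution scheme to a variant index; the grouping, weights and
# constraint factor stay those of the full pool so fits on subsets remain
# comparable.
scheme_subset <- function(scheme, idx) {
  out <- scheme
  out$amap <- scheme$amap[idx]
  out
}

#' Variance-guided subsampling experiment
#'
#' Emulates a two-round variant-budgeting design on a fully measured screen.
#' Round 1 samples `round1_frac` of the variants at every position uniformly
#' and fits the model. Round 2 either samples another `round2_frac` uniformly
#' at random ("random" arm) or allocates the same expected budget by the
#' round-1 posterior residual variance: positions are split into `n_bins`
#' quantile bins of `sigma2_hat` and sampled at `guided_rates` (lowest bin
#' first) from the not-yet-sampled variants, positions exhausted early
#' contributing what remains ("guided" arm). Both arms are refitted on their
#' unions and the unsampled variants' scores are predicted by the refitted
#' prior mean; out-of-sample R-squared (`1 - SSE/SST` against `truth_beta`)
#' is reported per repeat together with the guided-minus-random difference.
#' Each arm is evaluated on its own unsampled variants, so the contrast
#' includes both estimation quality and the composition of what remains
#' unmeasured (guided sampling deliberately measures more of the
#' high-variance variants, leaving an easier prediction set).
#'
#' @param assay A preprocessed `dms_assay` (the full pool).
#' @param scheme The pool's `substitution_scheme`.
#' @param truth_beta Numeric vector of ground-truth (or full-data) scores
#'   aligned with the assay's variants.
#' @param round1_frac,round2_frac Sampling fractions per position. Defaults 0.2.
#' @param n_bins Number of `sigma2` bins for the guided arm. Default 4.
#' @param guided_rates Increasing per-bin sampling rates, length `n_bins`;
#'   default `c(0.10, 0.20, 0.30, 0.40)`. When their mean equals
#'   `round2_frac` the two arms draw the same expected total budget.
#' @param model Model variant to fit. Default 3.
#' @param mcmc List of `chains`, `warmup`, `iter` for the refits.
#' @param seed Integer seed; repeat `k` uses `seed + k`.
#' @param n_repeats Number of Monte-Carlo repeats. Default 20.
#' @return A tibble of class `dms_sampling_report` with one row per repeat:
#'   `r2_random`, `r2_guided`, `delta_r2`, and sampled-count bookkeeping.
#' @export
guided_sampling_experiment <- function(assay, scheme, truth_beta,
                                       round1_frac = 0.2, round2_frac = 0.2,
                                       n_bins = 4,
                                       guided_rates = c(0.10, 0.20, 0.30, 0.40),
                                       model = 3,
                                       mcmc = list(chains = 2, warmup = 300, iter = 300),
                                       seed, n_repeats = 20) {
  stopifnot(length(guided_rates) == n_bins, !is.unsorted(guided_rates))
  if (missing(seed)) abort("seed is required")
  n <- n_variants(assay)
  if (length(truth_beta) != n) abort("truth_beta must align with the assay variants")
  pos_idx <- split(seq_len(n), assay$pmap)
  if (min(lengths(pos_idx)) * round1_frac < 1) {
    abort("pool too small for round1_frac: a position would get no round-1 sample")
  }

  one_fit <- function(idx, sd) {
    fit_dms(assay_subset(assay, idx), scheme_subset(scheme, idx),
            model = model, chains = mcmc$chains, warmup = mcmc$warmup,
            iter = mcmc$iter, seed = sd)
  }
  oos_r2 <- function(fit, idx) {
    eval_idx <- setdiff(seq_len(n), idx)
    eval_idx <- eval_idx[assay$variants$mclass[eval_idx] != "synonymous"]
    pred <- predict_prior_mean(fit, pmap = assay$pmap[eval_idx],
                               amap = if (model >= 2) scheme$amap[eval_idx])
    tr <- truth_beta[eval_idx]
    1 - sum((tr - pred)^2) / sum((tr - mean(tr))^2)
  }

  res <- purrr::map_dfr(seq_len(n_repeats), function(k) {
    set.seed(seed + k)
    s1 <- unlist(lapply(pos_idx, function(ii) {
      sample(ii, max(1L, round(round1_frac * length(ii))))
    }), use.names = FALSE)
    fit1 <- one_fit(s1, seed + k)

    # sigma2 bins over residue positions from the round-1 fit
    ps <- fit1$positions |> filter(.data$type == "residue")
    qs <- stats::quantile(ps$sigma2_mean,
                          probs = seq(0, 1, length.out = n_bins + 1L), type = 7)
    qs[1L] <- -Inf; qs[n_bins + 1L] <- Inf
    bin_of <- stats::setNames(as.integer(cut(ps$sigma2_mean, qs, labels = FALSE)),
                              ps$pos_group)

    # both arms consume one shared random order per position (coupled
    # draws): each arm's marginal sampling distribution is unchanged, but
    # the guided-minus-random contrast is paired, removing the noise of
    # independent round-2 draws
    perms <- lapply(pos_idx, function(ii) sample(setdiff(ii, s1)))
    draw_round2 <- function(rate_of_group) {
      unlist(lapply(seq_along(pos_idx), function(j) {
        ii <- pos_idx[[j]]
        want <- round(rate_of_group(names(pos_idx)[j]) * length(ii))
        if (want <= 0L) return(integer(0))
        utils::head(perms[[j]], want)
      }), use.names = FALSE)
    }
    s2_rand <- draw_round2(function(gid) round2_frac)
    s2_guid <- draw_round2(function(gid) {
      b <- bin_of[gid]
      if (is.na(b)) round2_frac else guided_rates[b] # control/indel: flat rate
    })

    fit_r <- one_fit(sort(c(s1, s2_rand)), seed + k)
    fit_g <- one_fit(sort(c(s1, s2_guid)), seed + k)
    tibble(
      repeat_id = k,
      n_round1 = length(s1),
      n_random = length(s1) + length(s2_rand),
      n_guided = length(s1) + length(s2_guid),
      r2_random = oos_r2(fit_r, c(s1, s2_rand)),
      r2_guided = oos_r2(fit_g, c(s1, s2_guid))
    )
  })
  res <- res |> mutate(delta_r2 = .data$r2_guided - .data$r2_random)
  class(res) <- c("dms_sampling_report", class(res))
  res
}
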