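#' Protein-level variance decomposition
#'
#' Partitions the variance of the posterior-mean functional scores across
#' non-synonymous variants into the share explained by position effects, by
#' (position-scaled) substitution effects, their cross-covariance, and the
#' residual share unexplained by the prior mean. With posterior means and
#' population variances over variants `v`:
#' `V = Var(beta_hat)`, `share_position = Var(phi_hat[p(v)]) / V`,
#' `share_aa = Var(rho_hat[p(v)] * nu_hat[a(v)]) / V` (`rho == 1` under
#' model 2), `share_cross = 2 Cov(.,.) / V`, and
#' `share_unexplained = Var(beta_hat - prior mean) / V`. The cross term is
#' reported separately so the position and substitution shares remain
#' directly interpretable.
#'
#' @param fit A `dms_fit`.
#' @return A one-row tibble of class `dms_decomposition` with the four shares,
#'   the total variance and the model id.
#' @export
variance_decomposition <- function(fit) {
  sc <- fit$scores
  nsyn <- sc$mclass != "synonymous"
  beta <- sc$beta_mean[nsyn]
  V <- pvar(beta)
  if (V < 1e-12) abort("degenerate assay: zero score variance")
  pos <- fit$positions$phi_mean[sc$pos_group[nsyn]]
  if (fit$model >= 2) {
    nu_full <- c(nu_summary(fit)$nu_mean)
    aa0 <- nu_full[fit$scheme$amap[nsyn]]
    if (fit$model == 3) aa0 <- aa0 * fit$positions$rho_mean[sc$pos_group[nsyn]]
  } else {
    aa0 <- rep(0, length(beta))
  }
  resid <- beta - pos - aa0
  out <- tibble(
    model = fit$model,
    share_position = pvar(pos) / V,
    share_aa = pvar(aa0) / V,
    share_cross = 2 * pcov(pos, aa0) / V,
    share_unexplained = pvar(resid) / V,
    total_variance = V,
    n_variants = sum(nsyn)
  )
  class(out) <- c("dms_decomposition", class(out))
  out
}

# population (denominator n) variance / covariance
pvar <- function(x) mean((x - mean(x))^2)
pcov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Classify the position-level shape of a fitted protein
#'
#' Reduces the fitted position table to one of four qualitative categories
#' based on the dispersion of position effects and the share of variance
#' explained by substitution effects: both low = `no_effect`; dispersed
#' `phi` only = `position_only`; substitution share only = `aa_only`;
#' both = `both`.
#'
#' @param fit A `dms_fit` of model 3.
#' @param tau_phi Threshold on the sd of `phi_hat` across residue positions.
#'   Default 0.5.
#' @param tau_aa Threshold on `share_aa` from [variance_decomposition()].
#'   Default 0.05.
#' @return A one-row tibble with `spread_phi`, `share_aa` and
#'   `shape_category`.
#' @export
classify_shape <- function(fit, tau_phi = 0.5, tau_aa = 0.05) {
  ps <- fit$positions |> filter(.data$type == "residue")
  spread_phi <- stats::sd(ps$phi_mean)
  share_aa <- variance_decomposition(fit)$share_aa
  cat <- if (spread_phi >= tau_phi && share_aa >= tau_aa) "both"
    else if (spread_phi >= tau_phi) "position_only"
    else if (share_aa >= tau_aa) "aa_only"
    else "no_effect"
  tibble(spread_phi = spread_phi, share_aa = share_aa,
         shape_category = factor(cat, levels = c("no_effect", "position_only",
                                                 "aa_only", "both")))
}

#' Compare fits across experimental conditions
#'
#' For multiple fits of the same variant library under different conditions
#' (e.g. a panel of inhibitors), computes the across-condition variance of
#' the position effect `phi_hat` and activation score `rho_hat` per position
#' and flags positions as `phi_variable` (variance of `phi >= var_phi_min`),
#' `rho_variable` (variance of `rho >= var_rho_min`), `both`, or
#' `consistent`.
#'
#' @param fits Named list of `dms_fit` objects sharing one position map.
#' @param var_phi_min Threshold on the across-condition variance of `phi`.
#'   Default 1.
#' @param var_rho_min Threshold on the across-condition variance of `rho`.
#'   Default 0.01.
#' @return A tibble with one row per position group: the two variances and
#'   the category, sorted as supplied.
#' @export
compare_conditions <- function(fits, var_phi_min = 1, var_rho_min = 0.01) {
  if (length(fits) < 2L) abort("need at least two fitted conditions")
  ref <- fits[[1L]]$positions$pos_group
  for (f in fits) {
    if (!identical(f$positions$pos_group, ref) ||
        !identical(nrow(f$positions), nrow(fits[[1L]]$positions))) {
      abort("position maps differ across conditions")
    }
  }
  phim <- sapply(fits, function(f) f$positions$phi_mean)
  rhom <- sapply(fits, function(f) f$positions$rho_mean)
  var_phi <- apply(phim, 1L, pvar)
  var_rho <- apply(rhom, 1L, function(r) if (anyNA(r)) NA_real_ else pvar(r))
  fits[[1L]]$positions |>
    select("pos_group", "label", "type") |>
    mutate(
      var_phi = var_phi,
      var_rho = var_rho,
      category = dplyr::case_when(
        var_phi >= var_phi_min & !is.na(var_rho) & var_rho >= var_rho_min ~ "both",
        var_phi >= var_phi_min ~ "phi_variable",
        !is.na(var_rho) & var_rho >= var_rho_min ~ "rho_variable",
        TRUE ~ "consistent"
      )
    )
}
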