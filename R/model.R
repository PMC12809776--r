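#' Per-variant prior mean of the functional score
#'
#' The hierarchical prior centres each variant's score at its position effect
#' plus (models 2 and 3) the substitution-group effect, scaled (model 3) by
#' the position's activation factor:
#' model 1 `phi[p(v)]`; model 2 `phi[p(v)] + nu[a(v)]`;
#' model 3 `phi[p(v)] + nu[a(v)] * rho[p(v)]`. The synonymous group effect is
#' structurally zero, so synonymous variants are centred at the control
#' position effect under every model.
#'
#' @param phi Numeric vector of position effects (length = position groups).
#' @param nu Numeric vector of substitution-group effects, length `A - 1`
#'   (the synonymous group `A` is fixed at zero); ignored for model 1.
#' @param rho Numeric vector of activation scores in `[0, 1]` per position
#'   group; ignored for models 1 and 2.
#' @param pmap,amap Integer group indices per variant.
#' @param model 1, 2 or 3.
#' @return Numeric vector of per-variant prior means.
#' @export
prior_mean_beta <- function(phi, nu = NULL, rho = NULL, pmap, amap = NULL,
                            model = 3) {
  if (any(pmap < 1L) || any(pmap > length(phi))) abort("pmap index out of range")
  mu <- phi[pmap]
  if (model == 1) return(mu)
  if (is.null(nu) || is.null(amap)) abort("models 2 and 3 need nu and amap")
  A <- length(nu) + 1L
  if (any(amap < 1L) || any(amap > A)) abort("amap index out of range")
  nu_full <- c(nu, 0)[amap]
  if (model == 2) return(mu + nu_full)
  if (is.null(rho)) abort("model 3 needs rho")
  mu + nu_full * rho[pmap]
}

#' Gaussian log likelihood of the aligned counts
#'
#' Aligned counts grow linearly in scaled round:
#' `m[v,t,r] ~ Normal(beta[v] * t/T + b[v], eps[g(v)]^2)`. Returns the total
#' Gaussian log density over all (variant, round, replicate) cells.
#'
#' @param m Aligned count matrix (variants x round/replicate columns).
#' @param beta,b Per-variant slope (functional score) and intercept.
#' @param eps Per-variant error scale (already expanded over `gmap`).
#' @param tt Per-column scaled round `t/T`.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(m, beta, b, eps, tt) {
  if (any(eps <= 0)) abort("error scale eps must be positive")
  mu <- outer(beta, tt) + b
  sum(stats::dnorm(m, mu, eps, log = TRUE))
}

#' Fit the hierarchical DMS model by MCMC
#'
#' Samples the joint posterior of the three nested model variants with a
#' blocked Gibbs sampler: exact conjugate updates for the per-variant
#' (slope, intercept) pair, position effects `phi`, position variances
#' `sigma2` and the whitened substitution effects, and scalar slice updates
#' for the activation scores `rho` (model 3) and the mean-group error scales
#' `eps` (whose prior is inverse-gamma on the scale). Substitution effects are
#' sampled in the `(A-2)`-dimensional whitened space of the degenerate prior,
#' so the weighted sum-to-zero constraint holds exactly on every draw.
#'
#' @param assay A preprocessed `dms_assay`.
#' @param scheme A `substitution_scheme` from [build_groups()]; required for
#'   models 2 and 3.
#' @param model 1 (position effects only), 2 (plus global substitution
#'   effects) or 3 (plus position-scaled substitution effects; default).
#' @param chains Number of chains (default 4).
#' @param warmup,iter Warmup and retained iterations per chain
#'   (defaults 1000 / 1000).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param sb2 Prior variance of the intercept `b ~ Normal(0, sb2)`. Default 1.
#' @param sigma2_floor Numerical lower bound on position variances. Default 1e-6.
#' @param rhat_max Convergence threshold used in the fitted summary. Default 1.05.
#' @return A `dms_fit`: posterior draws, per-variant score table (`scores`),
#'   per-position table, substitution-effect table, diagnostics, and the
#'   inputs needed by the downstream analyses.
#' @export
fit_dms <- function(assay, scheme = NULL, model = 3, chains = 4,
                    warmup = 1000, iter = 1000, seed,
                    sb2 = 1, sigma2_floor = 1e-6, rhat_max = 1.05) {
  stopifnot(model %in% 1:3)
  if (is.null(assay$m) || is.null(assay$pmap) || is.null(assay$gmap)) {
    abort("assay is not preprocessed; run preprocess_assay() first")
  }
  if (model >= 2) {
    if (is.null(scheme)) abort("models 2 and 3 need a substitution_scheme")
    if (scheme$A < 4L) abort("models 2 and 3 need A >= 4 substitution groups")
  }
  if (missing(seed)) abort("seed is required")
  set.seed(as.integer(seed))

  y <- assay$m
  n <- nrow(y)
  x <- assay$rounds$t / assay$T
  K <- length(x)
  p <- assay$pmap; P <- nrow(assay$position_groups)
  g <- assay$gmap; G <- max(g)
  Sxx <- sum(x^2); Sx <- sum(x)
  Sxy <- drop(y %*% x); Sy <- rowSums(y)

  if (model >= 2) {
    amap <- scheme$amap
    A <- scheme$A
    ns <- amap != A           # non-synonymous variants carry nu
    Cmat <- scheme$B / scheme$w # diag(1/w) %*% B, rows = non-syn groups
    D <- A - 2L
  }

  n_p <- as.integer(table(factor(p, levels = seq_len(P))))
  n_obs_g <- as.integer(table(factor(g, levels = seq_len(G)))) * K

  # naive OLS initial values
  xc <- x - mean(x)
  beta0 <- drop(y %*% xc) / sum(xc^2)
  b0 <- Sy / K - beta0 * Sx / K

  keep <- list(
    beta = array(NA_real_, c(iter, n, chains)),
    b = array(NA_real_, c(iter, n, chains)),
    phi = array(NA_real_, c(iter, P, chains)),
    sigma2 = array(NA_real_, c(iter, P, chains)),
    eps = array(NA_real_, c(iter, G, chains)),
    nu = if (model >= 2) array(NA_real_, c(iter, A - 1L, chains)),
    rho = if (model == 3) array(NA_real_, c(iter, P, chains))
  )

  for (ch in seq_len(chains)) {
    beta <- beta0 + stats::rnorm(n, 0, 0.05)
    b <- b0 + stats::rnorm(n, 0, 0.05)
    phi <- tapply(beta, factor(p, levels = seq_len(P)), mean)
    phi[is.na(phi)] <- 0
    phi <- as.numeric(phi)
    sigma2 <- rep(0.2, P)
    rho <- rep(0.5, P)
    z <- if (model >= 2) stats::rnorm(D, 0, 0.1) else NULL
    nu <- if (model >= 2) nu_from_z(z, scheme) else NULL
    eps <- rep(stats::sd(y - outer(beta, x) - b) + 0.01, G)

    for (it in seq_len(warmup + iter)) {
      # per-variant prior mean under the current hyperparameters
      nu_v <- if (model >= 2) c(nu, 0)[amap] else 0
      rho_v <- if (model == 3) rho[p] else rep(1, n)
      mu <- phi[p] + if (model >= 2) nu_v * rho_v else 0

      # (beta, b) joint conjugate update, vectorised 2x2 solve
      s2v <- sigma2[p]
      iv <- 1 / eps[g]^2
      P11 <- Sxx * iv + 1 / s2v
      P12 <- Sx * iv
      P22 <- K * iv + 1 / sb2
      h1 <- Sxy * iv + mu / s2v
      h2 <- Sy * iv
      dt <- P11 * P22 - P12^2
      mB <- (P22 * h1 - P12 * h2) / dt
      mb <- (P11 * h2 - P12 * h1) / dt
      V11 <- P22 / dt; V12 <- -P12 / dt; V22 <- P11 / dt
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      beta <- mB + sqrt(V11) * z1
      b <- mb + (V12 / sqrt(V11)) * z1 + sqrt(pmax(V22 - V12^2 / V11, 1e-12)) * z2

      # phi: conjugate Normal(0, 1) prior
      r_phi <- beta - (if (model >= 2) nu_v * rho_v else 0)
      S_p <- as.numeric(rowsum(r_phi, p, reorder = TRUE))
      prec <- n_p / sigma2 + 1
      phi <- S_p / sigma2 / prec + stats::rnorm(P) / sqrt(prec)

      # whitened substitution effects (models 2 and 3)
      if (model >= 2) {
        res <- beta[ns] - phi[p[ns]]
        Xw <- Cmat[amap[ns], , drop = FALSE] * rho_v[ns]
        wts <- 1 / sigma2[p[ns]]
        Lam <- diag(D) + crossprod(Xw, Xw * wts)
        hh <- crossprod(Xw, res * wts)
        U <- chol(Lam)
        zm <- backsolve(U, forwardsolve(t(U), hh))
        z <- drop(zm + backsolve(U, stats::rnorm(D)))
        nu <- nu_from_z(z, scheme)
        nu_v <- c(nu, 0)[amap]
      }

      # rho: slice update per position (model 3)
      if (model == 3) {
        nr <- nu_v[ns] * (beta[ns] - phi[p[ns]])
        nn <- nu_v[ns]^2
        rs <- rowsum(cbind(nn, nr), p[ns], reorder = FALSE)
        pos_ids <- as.integer(rownames(rs))
        Afull <- numeric(P); Bfull <- numeric(P)
        Afull[pos_ids] <- rs[, 1L] / sigma2[pos_ids]
        Bfull[pos_ids] <- rs[, 2L] / sigma2[pos_ids]
        for (pp in seq_len(P)) {
          aa <- Afull[pp]; bb <- Bfull[pp]
          logf <- function(r) {
            bb * r - 0.5 * aa * r^2 + 0.5 * log(r) + 0.5 * log1p(-r)
          }
          rho[pp] <- slice_bounded(rho[pp], logf, 1e-9, 1 - 1e-9)
        }
        rho_v <- rho[p]
      }

      # sigma2: conjugate inverse-gamma update
      mu <- phi[p] + if (model >= 2) nu_v * (if (model == 3) rho_v else 1) else 0
      SS_p <- as.numeric(rowsum((beta - mu)^2, p, reorder = TRUE))
      sigma2 <- pmax(1 / stats::rgamma(P, shape = 1 + n_p / 2, rate = 1 + SS_p / 2),
                     sigma2_floor)

      # eps: slice update per mean group (InvGamma(1,1) prior on the scale)
      E2 <- rowSums((y - outer(beta, x) - b)^2)
      SS_g <- as.numeric(rowsum(E2, g, reorder = TRUE))
      for (gg in seq_len(G)) {
        ss <- SS_g[gg]; no <- n_obs_g[gg]
        logf <- function(th) { # th = log(eps), includes Jacobian
          -(no + 1) * th - 0.5 * ss * exp(-2 * th) - exp(-th)
        }
        eps[gg] <- exp(slice_stepout(log(eps[gg]), logf, w = 0.5))
      }

      if (it > warmup) {
        k <- it - warmup
        keep$beta[k, , ch] <- beta
        keep$b[k, , ch] <- b
        keep$phi[k, , ch] <- phi
        keep$sigma2[k, , ch] <- sigma2
        keep$eps[k, , ch] <- eps
        if (model >= 2) keep$nu[k, , ch] <- nu
        if (model == 3) keep$rho[k, , ch] <- rho
      }
    }
  }

  fit <- structure(
    list(
      model = model, draws = keep, assay = assay, scheme = scheme,
      chains = chains, warmup = warmup, iter = iter, seed = seed,
      rhat_max = rhat_max
    ),
    class = "dms_fit"
  )
  fit$scores <- summarise_scores(fit)
  fit$positions <- position_summary(fit)
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

# Flatten a draws array [iter, dim, chain] to draws x dim.
flat_draws <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}

#' Local false sign rate from posterior draws
#'
#' `min(Pr(beta > 0), Pr(beta < 0))` per variant, the posterior probability
#' that the reported sign is wrong. Values near 0 indicate confident
#' loss- or gain-of-function calls.
#'
#' @param beta_draws Matrix of draws (rows) by variants (columns).
#' @return Numeric vector in `[0, 0.5]`.
#' @export
lfsr <- function(beta_draws) {
  pp <- colMeans(beta_draws > 0)
  pmin(pp, 1 - pp)
}

summarise_scores <- function(fit) {
  bd <- flat_draws(fit$draws$beta)
  qs <- apply(bd, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95))
  fit$assay$variants |>
    mutate(
      pos_group = fit$assay$pmap,
      mean_group = fit$assay$gmap,
      beta_mean = colMeans(bd),
      beta_sd = apply(bd, 2L, stats::sd),
      beta_q05 = qs[1L, ],
      beta_q50 = qs[2L, ],
      beta_q95 = qs[3L, ],
      lfsr = lfsr(bd)
    )
}

#' Per-position posterior summary
#'
#' Posterior mean and sd of the position effect `phi`, activation score `rho`
#' (model 3) and residual variance `sigma2` for every position group, with
#' the control and indel pseudo-positions flagged.
#'
#' @param fit A `dms_fit`.
#' @return A tibble with one row per position group.
#' @export
position_summary <- function(fit) {
  ph <- flat_draws(fit$draws$phi)
  s2 <- flat_draws(fit$draws$sigma2)
  out <- fit$assay$position_groups |>
    mutate(
      phi_mean = colMeans(ph),
      phi_sd = apply(ph, 2L, stats::sd),
      sigma2_mean = colMeans(s2),
      sigma2_sd = apply(s2, 2L, stats::sd)
    )
  if (fit$model == 3) {
    rh <- flat_draws(fit$draws$rho)
    out$rho_mean <- colMeans(rh)
    out$rho_sd <- apply(rh, 2L, stats::sd)
  } else {
    out$rho_mean <- NA_real_
    out$rho_sd <- NA_real_
  }
  out
}

#' Substitution-group effect summary
#'
#' @param fit A `dms_fit` of model 2 or 3.
#' @return Tibble of posterior means/sds of `nu` per substitution group
#'   (synonymous group shown with its structural zero).
#' @export
nu_summary <- function(fit) {
  if (fit$model < 2) abort("model 1 has no substitution effects")
  nd <- flat_draws(fit$draws$nu)
  fit$scheme$groups |>
    mutate(
      nu_mean = c(colMeans(nd), 0),
      nu_sd = c(apply(nd, 2L, stats::sd), 0)
    )
}

fit_diagnostics <- function(fit) {
  fams <- c("phi", "sigma2", "eps", if (fit$model >= 2) "nu",
            if (fit$model == 3) "rho")
  purrr::map_dfr(fams, function(f) {
    arr <- fit$draws[[f]]
    tibble(
      family = f,
      index = seq_len(dim(arr)[2L]),
      rhat = diag_over(arr, split_rhat),
      ess = diag_over(arr, ess_basic)
    )
  })
}

#' Convergence report
#'
#' Lists parameters whose split-R-hat exceeds the threshold or whose
#' effective sample size is below `min_ess`.
#'
#' @param fit A `dms_fit`.
#' @param rhat_max Threshold on split-R-hat; default taken from the fit (1.05).
#' @param min_ess Minimum effective sample size; default 100.
#' @return A tibble of flagged parameters (zero rows when converged), with
#'   attribute `"n_checked"`. Warns when only one chain was run.
#' @export
check_convergence <- function(fit, rhat_max = fit$rhat_max, min_ess = 100) {
  if (fit$chains < 2L) warn("fewer than 2 chains: R-hat diagnostics are unreliable")
  d <- fit$diagnostics
  bad <- d |> filter(is.finite(.data$rhat) & .data$rhat > rhat_max |
                       (is.finite(.data$ess) & .data$ess < min_ess))
  attr(bad, "n_checked") <- nrow(d)
  bad
}

#' Joint log density of the model, by component
#'
#' Evaluates the hierarchical model's log joint density at a given parameter
#' setting, returning the individual terms: the count likelihood, the score
#' prior, and the priors of `b`, `phi`, `sigma2`, `eps`, `nu` (models 2-3,
#' evaluated in the whitened coordinates of the degenerate prior) and `rho`
#' (model 3). The sub-models are exact pin-downs of model 3 (`rho == 1` gives
#' model 2, additionally `nu == 0` gives model 1): their joint densities agree
#' with model 3's after dropping the prior terms of the pinned parameters,
#' which is the nesting identity the tests assert.
#'
#' @param assay Preprocessed `dms_assay`.
#' @param params Named list with `beta`, `b`, `phi`, `sigma2`, `eps`
#'   (per mean group), and for models 2-3 `nu` (length `A - 1`), for model 3
#'   `rho`.
#' @param scheme `substitution_scheme` (models 2-3).
#' @param model 1, 2 or 3.
#' @return Named list of component log densities plus `total`.
#' @export
log_joint <- function(assay, params, scheme = NULL, model = 3) {
  y <- assay$m
  x <- assay$rounds$t / assay$T
  p <- assay$pmap; g <- assay$gmap
  beta <- params$beta; b <- params$b
  phi <- params$phi; sigma2 <- params$sigma2; eps <- params$eps
  out <- list()
  out$likelihood <- log_likelihood(y, beta, b, eps[g], x)
  mu <- prior_mean_beta(phi, params$nu, params$rho, p,
                        if (model >= 2) scheme$amap, model = model)
  out$lp_beta <- sum(stats::dnorm(beta, mu, sqrt(sigma2[p]), log = TRUE))
  out$lp_b <- sum(stats::dnorm(b, 0, 1, log = TRUE))
  out$lp_phi <- sum(stats::dnorm(phi, 0, 1, log = TRUE))
  out$lp_sigma2 <- sum(-2 * log(sigma2) - 1 / sigma2)
  out$lp_eps <- sum(-2 * log(eps) - 1 / eps)
  if (model >= 2) {
    nu <- params$nu
    if (abs(sum(scheme$w * nu)) > 1e-6) {
      abort("nu violates the weighted sum-to-zero constraint")
    }
    lam <- colSums(scheme$B^2) # eigenvalues (A-1)/(A-2)
    zz <- drop(crossprod(scheme$B, scheme$w * nu)) / lam
    out$lp_nu <- sum(stats::dnorm(zz, 0, 1, log = TRUE))
  }
  if (model == 3) {
    out$lp_rho <- sum(stats::dbeta(params$rho, 1.5, 1.5, log = TRUE))
  }
  out$total <- sum(unlist(out))
  out
}

#' @export
print.dms_fit <- function(x, ...) {
  cat(sprintf(
    "<dms_fit> model %d: %d variants, %d position groups, %d chains x %d draws\n",
    x$model, nrow(x$scores), nrow(x$positions), x$chains, x$iter
  ))
  bad <- check_convergence(x)
  cat(sprintf("  convergence: %d/%d hyperparameters flagged (R-hat > %.2f or low ESS)\n",
              nrow(bad), attr(bad, "n_checked"), x$rhat_max))
  invisible(x)
}
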