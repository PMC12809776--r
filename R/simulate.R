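#' Simulation configuration
#'
#' Describes a synthetic growth screen drawn from the model's own generative
#' structure: a protein of `n_positions` residues, each carrying a set of
#' missense variants plus (optionally) synonymous, nonsense and single-residue
#' deletion variants; position effects, activation scores, substitution-group
#' effects satisfying the weighted sum-to-zero constraint, per-position
#' residual variances, mean-group error scales, and a count layer obtained by
#' exponentiating the aligned log counts at a given sequencing depth.
#'
#' Defaults emulate a desk-scale growth screen: 50 positions x 21 variants
#' (19 missense + 1 synonymous + 1 nonsense), 3 selection rounds after the
#' baseline, 3 replicates, mean depth 200 reads per variant, position effects
#' centred at -1 (most mutations mildly deleterious), moderate substitution
#' signal, and residual standard deviations of 0.2-0.55 per position.
#'
#' @param n_positions Number of residue positions. Default 50.
#' @param variants_per_position Variants per position including the
#'   synonymous/nonsense/deletion variants when present. Default 21.
#' @param include_syn,include_ter,include_del Include a synonymous / nonsense /
#'   single-residue deletion variant at each position. Defaults `TRUE`,
#'   `TRUE`, `FALSE` (synonymous, missense and nonsense counts are the
#'   canonical inputs of a growth screen; deletions are optional).
#' @param T Last selection round (rounds are `0..T`). Default 3.
#' @param R Replicates. Default 3.
#' @param phi_mean,phi_sd Position-effect distribution. Defaults -1, 1.
#' @param rho_shape1,rho_shape2 Beta parameters of the activation scores.
#'   Defaults 2, 2. Set `rho_fixed` to pin all activations instead.
#' @param rho_fixed Optional fixed activation value in `[0, 1]`.
#' @param nu_scale Scale of substitution-group effects; 0 switches the
#'   substitution signal off. Default 1.
#' @param sigma2_range Range of per-position residual variances, drawn
#'   uniformly. Default `c(0.04, 0.3)`.
#' @param eps_range Range of mean-group error scales (most-depleted group
#'   noisiest). Default `c(0.2, 0.4)`.
#' @param n_eps_groups Number of error-scale groups. Default 5.
#' @param b_sd Spread of round-0 intercepts. Default 0.3.
#' @param depth Mean sequencing depth per variant per column. Default 200.
#' @param missing_frac Fraction of count cells masked as missing. Default 0.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_positions = 50, variants_per_position = 21,
                       include_syn = TRUE, include_ter = TRUE, include_del = FALSE,
                       T = 3, R = 3,
                       phi_mean = -1, phi_sd = 1,
                       rho_shape1 = 2, rho_shape2 = 2, rho_fixed = NULL,
                       nu_scale = 1,
                       sigma2_range = c(0.04, 0.3),
                       eps_range = c(0.2, 0.4), n_eps_groups = 5,
                       b_sd = 0.3, depth = 200, missing_frac = 0) {
  n_mis <- variants_per_position - include_syn - include_ter - include_del
  stopifnot(n_mis >= 1, n_mis <= 19, T >= 1, R >= 1,
            missing_frac >= 0, missing_frac < 1,
            diff(sigma2_range) >= 0, diff(eps_range) >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw ground-truth parameters for a synthetic screen
#'
#' Generates the variant library (random wild-type sequence, sampled missense
#' substitutions per position), builds the position map and BLOSUM grouping,
#' and draws all generative parameters. Substitution-group effects decrease
#' with the group's BLOSUM score (conservative swaps more tolerated) and are
#' projected onto the weighted sum-to-zero space, so the constraint holds
#' exactly at generation. Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_truth`: variant tibble, skeleton assay with
#'   maps, `substitution_scheme`, and the true `phi`, `rho`, `sigma2`, `nu`,
#'   `beta`, `b`, `eps`, `gmap`.
#' @export
simulate_truth <- function(config, seed) {
  set.seed(as.integer(seed))
  cfg <- config
  wt <- sample(AA_CODES, cfg$n_positions, replace = TRUE)
  vars <- purrr::map_dfr(seq_len(cfg$n_positions), function(i) {
    muts <- sample(setdiff(AA_CODES, wt[i]), cfg$n_mis)
    ids <- paste0(wt[i], i, muts)
    if (cfg$include_syn) ids <- c(ids, paste0(wt[i], i, "="))
    if (cfg$include_ter) ids <- c(ids, paste0(wt[i], i, "*"))
    if (cfg$include_del) ids <- c(ids, paste0(wt[i], i, "del"))
    tibble(variant_id = ids)
  })
  n <- nrow(vars)
  K <- (cfg$T + 1) * cfg$R
  skeleton <- dms_assay(
    tibble(variant = vars$variant_id) |>
      dplyr::bind_cols(as.data.frame(matrix(1, n, K)) |>
                         stats::setNames(sprintf("c_%d_%d",
                                                 rep(0:cfg$T, each = cfg$R),
                                                 rep(seq_len(cfg$R), cfg$T + 1))))
  )
  skeleton <- build_position_map(skeleton, preprocess_config())
  scheme <- build_groups(skeleton)

  P <- nrow(skeleton$position_groups)
  ptype <- skeleton$position_groups$type
  phi <- stats::rnorm(P, cfg$phi_mean, cfg$phi_sd)
  phi[ptype == "control"] <- 0
  rho <- if (!is.null(cfg$rho_fixed)) rep(cfg$rho_fixed, P)
    else stats::rbeta(P, cfg$rho_shape1, cfg$rho_shape2)
  sigma2 <- stats::runif(P, cfg$sigma2_range[1L], cfg$sigma2_range[2L])

  A <- scheme$A
  if (cfg$nu_scale > 0) {
    sc <- scheme$groups$score_max[-A]
    ord <- rank(ifelse(is.na(sc), min(sc, na.rm = TRUE) - 1L, sc)) # indels/nonsense most severe
    raw <- cfg$nu_scale * as.numeric(scale(ord)) + stats::rnorm(A - 1L, 0, 0.1 * cfg$nu_scale)
    w <- scheme$w
    nu <- raw - w * sum(w * raw) / sum(w^2) # project onto sum(w * nu) == 0
  } else {
    nu <- rep(0, A - 1L)
  }

  pm <- skeleton$pmap
  am <- scheme$amap
  mu <- prior_mean_beta(phi, nu, rho, pm, am, model = 3)
  beta <- stats::rnorm(n, mu, sqrt(sigma2[pm]))
  b <- stats::rnorm(n, 0, cfg$b_sd)
  G <- cfg$n_eps_groups
  qb <- stats::quantile(beta, probs = seq(0, 1, length.out = G + 1L), type = 7)
  qb[1L] <- -Inf; qb[G + 1L] <- Inf
  gmap <- as.integer(cut(beta, qb, labels = FALSE))
  eps <- seq(cfg$eps_range[2L], cfg$eps_range[1L], length.out = G) # depleted = noisy

  structure(
    list(variants = skeleton$variants, skeleton = skeleton, scheme = scheme,
         phi = phi, rho = rho, sigma2 = sigma2, nu = nu,
         beta = beta, b = b, eps = eps, gmap = gmap, config = cfg),
    class = "sim_truth"
  )
}

#' Simulate raw counts from ground truth
#'
#' Draws aligned log counts from the linear-growth likelihood and inverts the
#' normalisation: each column's counts are the rounded exponentiated values
#' scaled to the target library size, so preprocessing the simulated raw
#' counts recovers the aligned counts up to the per-column centring constant.
#' Optionally masks a fraction of cells as missing.
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param seed Integer seed.
#' @return A raw `dms_assay` (counts only; run [preprocess_assay()] next).
#' @export
simulate_assay <- function(truth, seed) {
  set.seed(as.integer(seed))
  cfg <- truth$config
  n <- length(truth$beta)
  tt <- rep(0:cfg$T, each = cfg$R) / cfg$T
  K <- length(tt)
  eps_v <- truth$eps[truth$gmap]
  m <- outer(truth$beta, tt) + truth$b +
    matrix(stats::rnorm(n * K, 0, eps_v), n, K)
  e <- exp(m)
  L <- cfg$depth * n
  cnt <- round(sweep(e, 2L, colSums(e) / L, "/"))
  if (cfg$missing_frac > 0) {
    mask <- matrix(stats::runif(n * K) < cfg$missing_frac, n, K)
    cnt[mask] <- NA_real_
  }
  df <- tibble(variant = truth$variants$variant_id) |>
    dplyr::bind_cols(as.data.frame(cnt) |>
                       stats::setNames(sprintf("c_%d_%d",
                                               rep(0:cfg$T, each = cfg$R),
                                               rep(seq_len(cfg$R), cfg$T + 1))))
  dms_assay(df, meta = list(simulated = TRUE))
}

#' Simulate a complete screen
#'
#' Convenience wrapper: [simulate_truth()] then [simulate_assay()] (seeds
#' `seed` and `seed + 1`).
#'
#' @inheritParams simulate_truth
#' @return List with `truth` and raw `assay`.
#' @export
simulate_screen <- function(config = sim_config(), seed) {
  truth <- simulate_truth(config, seed)
  list(truth = truth, assay = simulate_assay(truth, seed + 1L))
}

#' Parameter-recovery metrics of a fit against simulation truth
#'
#' Scores a fit on its own simulated data: Pearson and Spearman correlation,
#' RMSE and 90% credible-interval coverage of the truth, per parameter
#' family (`beta` by variant; `phi`, `sigma2` and, for model 3, `rho` by
#' residue position; `nu` by substitution group).
#'
#' @param truth A `sim_truth`.
#' @param fit A `dms_fit` on data simulated from `truth`.
#' @return A tibble with one row per parameter family.
#' @export
recovery_report <- function(truth, fit) {
  fam <- list()

  ix <- match(fit$scores$variant_id, truth$variants$variant_id)
  if (anyNA(ix)) abort("fit and truth variant sets do not align")
  bd <- flat_draws(fit$draws$beta)
  fam$beta <- list(truth = truth$beta[ix], est = fit$scores$beta_mean,
                   lo = fit$scores$beta_q05, hi = fit$scores$beta_q95)

  # positions align by label (same construction rules on the same library)
  tp <- truth$skeleton$position_groups
  fp <- fit$positions
  pj <- match(fp$label, tp$label)
  if (anyNA(pj)) abort("position groups do not align between truth and fit")
  res <- fp$type == "residue"
  phd <- flat_draws(fit$draws$phi)
  qs <- apply(phd, 2L, stats::quantile, probs = c(0.05, 0.95))
  fam$phi <- list(truth = truth$phi[pj][res], est = fp$phi_mean[res],
                  lo = qs[1L, res], hi = qs[2L, res])
  fam$sigma2 <- list(truth = truth$sigma2[pj][res], est = fp$sigma2_mean[res])
  if (fit$model == 3) {
    fam$rho <- list(truth = truth$rho[pj][res], est = fp$rho_mean[res])
  }
  if (fit$model >= 2) {
    if (fit$scheme$A != truth$scheme$A) abort("substitution schemes differ")
    # groups seen at a single position group (indel pseudo-positions) are
    # additively confounded with that position's phi; score only the rest
    npos <- tapply(truth$skeleton$pmap, truth$scheme$amap,
                   function(x) length(unique(x)))
    ident <- which(npos[as.character(seq_len(fit$scheme$A - 1L))] >= 2L)
    fam$nu <- list(truth = truth$nu[ident],
                   est = nu_summary(fit)$nu_mean[ident])
  }

  purrr::imap_dfr(fam, function(f, name) {
    tibble(
      family = name,
      n = length(f$truth),
      cor_pearson = suppressWarnings(stats::cor(f$truth, f$est)),
      cor_spearman = suppressWarnings(stats::cor(f$truth, f$est, method = "spearman")),
      rmse = sqrt(mean((f$truth - f$est)^2)),
      coverage90 = if (!is.null(f$lo)) mean(f$truth >= f$lo & f$truth <= f$hi)
        else NA_real_
    )
  })
}
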