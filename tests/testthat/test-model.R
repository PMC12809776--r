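test_that("likelihood matches a direct Normal density computation", {
  set.seed(4)
  m <- matrix(stats::rnorm(12), 3, 4)
  tt <- c(0, 1, 2, 2) / 2
  beta <- c(2, -1, 0.5); b <- c(0.1, 0, -0.2); eps <- c(0.3, 0.3, 0.5)
  # independent oracle: elementwise dnorm over a dense loop
  ref <- 0
  for (v in 1:3) for (k in 1:4) {
    ref <- ref + stats::dnorm(m[v, k], beta[v] * tt[k] + b[v], eps[v], log = TRUE)
  }
  expect_equal(log_likelihood(m, beta, b, eps, tt), ref, tolerance = 1e-10)
  # round 0: the mean is the intercept regardless of the slope
  expect_equal(log_likelihood(m[, 1, drop = FALSE], beta, b, eps, 0),
               log_likelihood(m[, 1, drop = FALSE], -beta, b, eps, 0))
  expect_error(log_likelihood(m, beta, b, c(-1, 1, 1), tt), "positive")
})

test_that("prior means follow the nested model structure", {
  phi <- c(-1, 0.5); nu <- c(-2, 1); rho <- c(0.5, 1)
  pmap <- c(1L, 1L, 2L); amap <- c(1L, 3L, 2L) # variant 2 is synonymous (A = 3)
  expect_equal(prior_mean_beta(phi, pmap = pmap, model = 1), c(-1, -1, 0.5))
  expect_equal(prior_mean_beta(phi, nu, pmap = pmap, amap = amap, model = 2),
               c(-3, -1, 1.5))
  expect_equal(prior_mean_beta(phi, nu, rho, pmap, amap, model = 3),
               c(-2, -1, 1.5))
  # model 3 at rho == 1 collapses to model 2
  expect_equal(prior_mean_beta(phi, nu, c(1, 1), pmap, amap, model = 3),
               prior_mean_beta(phi, nu, pmap = pmap, amap = amap, model = 2))
  # synonymous variants sit at the control position effect under every model
  expect_equal(prior_mean_beta(phi, nu, rho, pmap, amap, model = 3)[2], phi[1])
  expect_error(prior_mean_beta(phi, nu, rho, c(1L, 5L, 2L), amap, model = 3),
               "out of range")
})

test_that("local false sign rate counts the minority sign", {
  d <- cbind(c(1, 2, 3, 4), c(-1, 1, 1, 1), c(-2, -1, 1, 2))
  expect_equal(lfsr(d), c(0, 0.25, 0.5))
})

test_that("sub-model joint densities nest inside the full model", {
  scr <- small_screen(seed = 21, n_positions = 5, variants_per_position = 4)
  a <- scr$assay
  sch <- build_groups(a, min_coverage = 0) # one group per score: A >= 4
  expect_gte(sch$A, 4L)
  n <- n_variants(a)
  P <- nrow(a$position_groups)
  set.seed(9)
  pars <- list(
    beta = stats::rnorm(n), b = stats::rnorm(n, 0, 0.2),
    phi = stats::rnorm(P), sigma2 = stats::runif(P, 0.05, 0.3),
    eps = stats::runif(max(a$gmap), 0.2, 0.5),
    nu = dmsvar:::nu_from_z(stats::rnorm(sch$A - 2L), sch)
  )
  # rho pinned at 1: all terms shared with model 2 agree
  lj3 <- log_joint(a, c(pars, list(rho = rep(1, P))), sch, model = 3)
  lj2 <- log_joint(a, pars, sch, model = 2)
  # the Beta prior vanishes at the boundary rho = 1, so the identity is on
  # the terms shared by both models
  shared3 <- with(lj3, likelihood + lp_beta + lp_b + lp_phi + lp_sigma2 +
                    lp_eps + lp_nu)
  expect_equal(shared3, lj2$total, tolerance = 1e-8)
  # nu pinned at 0: shared terms agree with model 1
  pars0 <- pars; pars0$nu <- rep(0, sch$A - 1L)
  lj3n <- log_joint(a, c(pars0, list(rho = stats::runif(P))), sch, model = 3)
  lj1 <- log_joint(a, pars0[c("beta", "b", "phi", "sigma2", "eps")], model = 1)
  expect_equal(lj3n$total - lj3n$lp_rho - lj3n$lp_nu, lj1$total,
               tolerance = 1e-8)
  # the weighted constraint is enforced on input
  bad <- pars; bad$nu <- bad$nu + 1
  expect_error(log_joint(a, c(bad, list(rho = rep(1, P))), sch, model = 3),
               "sum-to-zero")
})

test_that("posterior draws respect every support constraint", {
  scr <- small_screen(seed = 13)
  fit <- fit_dms(scr$assay, scr$scheme, model = 3, chains = 2,
                 warmup = 150, iter = 150, seed = 2)
  rho <- dmsvar:::flat_draws(fit$draws$rho)
  expect_true(all(rho >= 0 & rho <= 1))
  expect_true(all(dmsvar:::flat_draws(fit$draws$sigma2) > 0))
  expect_true(all(dmsvar:::flat_draws(fit$draws$eps) > 0))
  nu <- dmsvar:::flat_draws(fit$draws$nu)
  expect_lt(max(abs(nu %*% scr$scheme$w)), 1e-8)
  # synonymous group effect is a structural zero
  ns <- nu_summary(fit)
  expect_equal(ns$nu_mean[scr$scheme$A], 0)
  expect_equal(ns$nu_sd[scr$scheme$A], 0)
})

test_that("scores at sparse positions shrink toward the position mean", {
  # one position carries a single variant whose naive slope is extreme
  set.seed(31)
  wt <- c("A", "C", "D")
  ids <- c(paste0("A1", c("V", "W", "Y", "F", "G", "H")),
           paste0("C2", c("V", "W", "Y", "F", "G", "H")),
           "D3V", "A1=", "C2=")
  K <- 8 # rounds 0..3, 2 reps
  tt <- rep(0:3, each = 2) / 3
  beta_true <- c(rep(-1, 6), rep(0.5, 6), -3, 0, 0)
  m <- outer(beta_true, tt) + matrix(stats::rnorm(15 * K, 0, 0.2), 15, K)
  cnt <- round(exp(m) * 2000)
  df <- tibble::tibble(variant = ids) |>
    dplyr::bind_cols(stats::setNames(as.data.frame(cnt),
                                     sprintf("c_%d_%d", rep(0:3, each = 2),
                                             rep(1:2, 4))))
  a <- preprocess_assay(dms_assay(df),
                        preprocess_config(min_pos_variants = 1, n_mean_groups = 1))
  fit <- fit_dms(a, model = 1, chains = 2, warmup = 300, iter = 300, seed = 8)
  i <- which(a$variants$variant_id == "D3V")
  naive <- dmsvar:::naive_scores(a)[i]
  post <- fit$scores$beta_mean[i]
  prior_ctr <- fit$positions$phi_mean[a$pmap[i]]
  expect_lt(abs(post - prior_ctr), abs(naive - prior_ctr))
})

test_that("convergence diagnostics flag split chains and stuck chains", {
  x_same <- cbind(stats::rnorm(200), stats::rnorm(200))
  expect_lt(dmsvar:::split_rhat(x_same), 1.1)
  x_split <- cbind(stats::rnorm(200), stats::rnorm(200) + 10)
  expect_gt(dmsvar:::split_rhat(x_split), 2)
  x_const <- cbind(rep(1, 200), rep(2, 200))
  expect_equal(dmsvar:::split_rhat(x_const), Inf)
  expect_equal(dmsvar:::split_rhat(cbind(rep(1, 200), rep(1, 200))), 1)

  scr <- small_screen(seed = 17)
  fit <- fit_dms(scr$assay, scr$scheme, model = 3, chains = 2,
                 warmup = 300, iter = 300, seed = 3)
  rep_ok <- check_convergence(fit, rhat_max = 1.2, min_ess = 10)
  expect_s3_class(rep_ok, "tbl_df")
  expect_gt(attr(rep_ok, "n_checked"), 0)
  fit1 <- fit
  fit1$chains <- 1L
  expect_warning(check_convergence(fit1), "chains")
})

test_that("position-only posterior agrees with an independent Gibbs-free sampler", {
  skip_if_not_installed("rjags")
  scr <- small_screen(seed = 42, n_positions = 8, variants_per_position = 8)
  a <- scr$assay
  fit <- fit_dms(a, model = 1, chains = 2, warmup = 800, iter = 1500, seed = 5)
  y <- a$m; n <- nrow(y); K <- ncol(y)
  dat <- list(
    m = as.vector(y), v = rep(seq_len(n), times = K),
    x = rep(a$rounds$t / a$T, each = n),
    g = rep(a$gmap, times = K), Nobs = n * K, n = n,
    p = a$pmap, P = nrow(a$position_groups), G = max(a$gmap)
  )
  mod <- "model{
    for (i in 1:Nobs) { m[i] ~ dnorm(beta[v[i]] * x[i] + b[v[i]], taueps[g[i]]) }
    for (vv in 1:n) { beta[vv] ~ dnorm(phi[p[vv]], tausig[p[vv]]); b[vv] ~ dnorm(0, 1) }
    for (pp in 1:P) { phi[pp] ~ dnorm(0, 1); isig[pp] ~ dgamma(1, 1); tausig[pp] <- isig[pp] }
    for (gg in 1:G) { ieps[gg] ~ dgamma(1, 1); taueps[gg] <- ieps[gg] * ieps[gg] }
  }"
  jm <- rjags::jags.model(textConnection(mod), data = dat, n.chains = 2,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 7))
  update(jm, 800, progress.bar = "none")
  ss <- rjags::coda.samples(jm, c("beta", "phi"), n.iter = 2000,
                            progress.bar = "none")
  sm <- summary(ss)$statistics
  pick <- function(prefix) {
    rows <- grep(paste0("^", prefix, "\\["), rownames(sm), value = TRUE)
    sm[rows, "Mean"][order(as.integer(gsub("\\D", "", rows)))]
  }
  # JAGS updates (beta, b) single-site, so its chains mix more slowly;
  # bounds reflect the combined Monte-Carlo error
  expect_lt(mean(abs(pick("beta") - fit$scores$beta_mean)), 0.02)
  expect_lt(max(abs(pick("beta") - fit$scores$beta_mean)), 0.08)
  expect_lt(max(abs(pick("phi") - fit$positions$phi_mean)), 0.08)
})
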