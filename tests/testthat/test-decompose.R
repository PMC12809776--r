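# fake fits with point-mass posteriors give exactly known decompositions
test_that("variance shares are exact on constructed posteriors", {
  P <- 4L; A <- 4L
  pmap <- rep(1:P, each = 6L)
  amap <- rep(c(1L, 2L, 3L, 1L, 2L, 4L), times = P) # group 4 = synonymous
  mclass <- ifelse(amap == 4L, "synonymous", "missense")
  phi <- c(-2, -1, 0, 1)

  # beta identical to the position effect: all variance is positional
  f <- fake_fit(beta = phi[pmap], phi = phi, nu = rep(0, 3),
                rho = rep(0.5, P), pmap = pmap, amap = amap, mclass = mclass)
  d <- variance_decomposition(f)
  expect_equal(d$share_position, 1)
  expect_equal(d$share_aa, 0)
  expect_equal(d$share_cross, 0)
  expect_equal(d$share_unexplained, 0)

  # beta identical to the substitution effect at rho = 1
  nu <- c(-1.5, 0, 1.5)
  nu_full <- c(nu, 0)
  f2 <- fake_fit(beta = nu_full[amap], phi = rep(0, P), nu = nu,
                 rho = rep(1, P), pmap = pmap, amap = amap, mclass = mclass)
  d2 <- variance_decomposition(f2)
  expect_equal(d2$share_position, 0)
  expect_equal(d2$share_aa, 1)
  expect_equal(d2$share_unexplained, 0)

  # the four shares always sum to one up to the cross term construction
  set.seed(8)
  f3 <- fake_fit(beta = phi[pmap] + 0.8 * nu_full[amap] + stats::rnorm(length(pmap), 0, 0.3),
                 phi = phi, nu = nu, rho = rep(0.8, P),
                 pmap = pmap, amap = amap, mclass = mclass)
  d3 <- variance_decomposition(f3)
  expect_equal(d3$share_position + d3$share_aa + d3$share_cross +
                 d3$share_unexplained, 1, tolerance = 0.1)

  # degenerate: no score variance
  fz <- fake_fit(beta = rep(1, length(pmap)), phi = rep(0, P), nu = rep(0, 3),
                 rho = rep(0.5, P), pmap = pmap, amap = amap, mclass = mclass)
  expect_error(variance_decomposition(fz), "degenerate")
})

test_that("shares are invariant to score location and substitution relabeling", {
  P <- 5L
  pmap <- rep(1:P, each = 4L)
  amap <- rep(c(1L, 2L, 3L, 4L), times = P)
  mclass <- ifelse(amap == 4L, "synonymous", "missense")
  set.seed(11)
  phi <- stats::rnorm(P); nu <- c(-1, 0.2, 0.8)
  beta <- phi[pmap] + c(nu, 0)[amap] + stats::rnorm(4 * P, 0, 0.2)
  f <- fake_fit(beta, phi, nu, rho = rep(1, P), pmap, amap, mclass)
  d <- variance_decomposition(f)
  # shift every score and position effect by a constant
  f_shift <- fake_fit(beta + 5, phi + 5, nu, rho = rep(1, P), pmap, amap, mclass)
  d_shift <- variance_decomposition(f_shift)
  expect_equal(d[c("share_position", "share_aa", "share_unexplained")],
               d_shift[c("share_position", "share_aa", "share_unexplained")])
  # permute the non-synonymous group labels consistently
  perm <- c(3L, 1L, 2L)
  amap_p <- ifelse(amap == 4L, 4L, perm[amap])
  f_perm <- fake_fit(beta, phi, nu[order(perm)], rho = rep(1, P),
                     pmap, amap_p, mclass)
  expect_equal(variance_decomposition(f_perm)$share_position, d$share_position)
  expect_equal(variance_decomposition(f_perm)$share_aa, d$share_aa)
})

test_that("position summaries track the fitted assay", {
  scr <- small_screen(seed = 19)
  fit <- fit_dms(scr$assay, scr$scheme, model = 3, chains = 2,
                 warmup = 200, iter = 250, seed = 4)
  ps <- fit$positions
  expect_equal(nrow(ps), nrow(scr$assay$position_groups))
  expect_equal(sum(ps$type == "control"), 1L)
  expect_true(all(is.finite(ps$phi_mean)))
  # control position sits near zero: synonymous scores are centred there
  expect_lt(abs(ps$phi_mean[ps$type == "control"]), 0.2)
  # residual variance tracks the within-position moment of beta - prior mean
  pred <- dmsvar:::predict_prior_mean(fit)
  resid2 <- tapply((fit$scores$beta_mean - pred)^2, fit$scores$pos_group, mean)
  res <- ps$type == "residue"
  expect_gt(stats::cor(ps$sigma2_mean[res],
                       as.numeric(resid2)[res], method = "spearman"), 0.3)
})

test_that("shape classification separates the four archetypes", {
  P <- 6L
  pmap <- rep(1:P, each = 4L)
  amap <- rep(c(1L, 2L, 3L, 4L), times = P)
  mclass <- ifelse(amap == 4L, "synonymous", "missense")
  nul <- rep(0, 3)
  flat <- fake_fit(rep(c(0.01, -0.01), 12L), phi = rep(0, P), nu = nul,
                   rho = rep(0.5, P), pmap = pmap, amap = amap, mclass = mclass)
  expect_equal(as.character(classify_shape(flat)$shape_category), "no_effect")
  pos <- fake_fit(beta = seq(-3, 2, length.out = P)[pmap], nu = nul,
                  phi = seq(-3, 2, length.out = P), rho = rep(0.5, P),
                  pmap = pmap, amap = amap, mclass = mclass)
  expect_equal(as.character(classify_shape(pos)$shape_category), "position_only")
  nu <- c(-1.5, 0, 1.5)
  aa <- fake_fit(beta = c(nu, 0)[amap], phi = rep(0, P), nu = nu,
                 rho = rep(1, P), pmap = pmap, amap = amap, mclass = mclass)
  expect_equal(as.character(classify_shape(aa)$shape_category), "aa_only")
  both <- fake_fit(beta = seq(-3, 2, length.out = P)[pmap] + c(nu, 0)[amap],
                   phi = seq(-3, 2, length.out = P), nu = nu, rho = rep(1, P),
                   pmap = pmap, amap = amap, mclass = mclass)
  expect_equal(as.character(classify_shape(both)$shape_category), "both")
})

test_that("cross-condition comparison flags variable positions by variance", {
  scr <- small_screen(seed = 23)
  fit <- fit_dms(scr$assay, scr$scheme, model = 3, chains = 2,
                 warmup = 150, iter = 150, seed = 5)
  same <- replicate(12, fit, simplify = FALSE)
  cc <- compare_conditions(same)
  expect_true(all(cc$category == "consistent"))
  expect_equal(max(cc$var_phi), 0)

  # one condition shifted by +4 at one position: Var = 16 * 11 / 144 >= 1
  shifted <- fit
  shifted$positions$phi_mean[3] <- shifted$positions$phi_mean[3] + 4
  cc2 <- compare_conditions(c(same[1:11], list(shifted)))
  expect_equal(cc2$var_phi[3], 16 * 11 / 144, tolerance = 1e-10)
  expect_equal(cc2$category[3], "phi_variable")
  expect_true(all(cc2$category[-3] == "consistent"))

  # condition-specific activation at three positions
  rho_var <- fit
  old <- rho_var$positions$rho_mean[c(2, 5, 7)]
  rho_var$positions$rho_mean[c(2, 5, 7)] <- ifelse(old < 0.5, old + 0.5, old - 0.5)
  cc3 <- compare_conditions(c(same[1:11], list(rho_var)))
  expect_setequal(which(cc3$category == "rho_variable"), c(2, 5, 7))

  other <- fit
  other$positions <- other$positions[-1, ]
  expect_error(compare_conditions(list(fit, other)), "differ")
  expect_error(compare_conditions(list(fit)), "at least two")
})
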