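# Shared fixtures: all built in code, no stored data.

# Tiny wide-format count table: 3 variants, rounds 0..2, 2 replicates.
toy_counts <- function() {
  tibble::tibble(
    variant = c("A5V", "A5=", "K9*"),
    c_0_1 = c(100, 120, 90), c_0_2 = c(110, 115, 95),
    c_1_1 = c(80, 125, 40), c_1_2 = c(85, 130, 45),
    c_2_1 = c(60, 118, 15), c_2_2 = c(65, 122, 20)
  )
}

# A small fully preprocessed screen plus its truth; cheap enough to fit
# within a test.
small_screen <- function(seed = 42, n_positions = 12,
                         variants_per_position = 10, ...) {
  sim <- simulate_screen(
    sim_config(n_positions = n_positions,
               variants_per_position = variants_per_position, ...),
    seed = seed
  )
  sim$assay <- preprocess_assay(sim$assay)
  sim$scheme <- build_groups(sim$assay)
  sim
}

# Minimal hand-built dms_fit whose posterior is a point mass, for exercising
# the decomposition/design layers against exactly known answers.
fake_fit <- function(beta, phi, nu, rho, pmap, amap, mclass,
                     sigma2 = NULL, model = 3) {
  P <- length(phi)
  A <- length(nu) + 1L
  n <- length(beta)
  sigma2 <- sigma2 %||% rep(0.1, P)
  const_draws <- function(v) array(rep(v, each = 2L), c(2L, length(v), 1L))
  groups <- tibble::tibble(
    group = seq_len(A),
    type = c(rep("missense", A - 1L), "synonymous"),
    score_min = NA_integer_, score_max = NA_integer_,
    n_variants = as.integer(table(factor(amap, levels = seq_len(A))))
  )
  scheme <- structure(
    list(groups = groups, amap = amap, A = A,
         w = rep(1, A - 1L)),
    class = "substitution_scheme"
  )
  positions <- tibble::tibble(
    pos_group = seq_len(P),
    label = as.character(seq_len(P)),
    type = "residue",
    n_variants = as.integer(table(factor(pmap, levels = seq_len(P)))),
    phi_mean = phi, phi_sd = 0,
    sigma2_mean = sigma2, sigma2_sd = 0,
    rho_mean = if (model == 3) rho else NA_real_,
    rho_sd = 0
  )
  scores <- tibble::tibble(
    variant_id = paste0("v", seq_len(n)),
    wt = "A", position = pmap, mut = "V",
    mclass = factor(mclass, levels = dmsvar:::MCLASS_LEVELS),
    pos_group = pmap, mean_group = 1L,
    beta_mean = beta, beta_sd = 0,
    beta_q05 = beta, beta_q50 = beta, beta_q95 = beta,
    lfsr = 0
  )
  structure(
    list(model = model, scheme = scheme, scores = scores,
         positions = positions, chains = 1L, iter = 2L, warmup = 0L,
         rhat_max = 1.05,
         draws = list(nu = const_draws(nu),
                      phi = const_draws(phi),
                      sigma2 = const_draws(sigma2),
                      rho = if (model == 3) const_draws(rho))),
    class = "dms_fit"
  )
}

`%||%` <- rlang::`%||%`
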