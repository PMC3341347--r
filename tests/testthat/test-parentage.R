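## shared toy: 3 adults on a 100 m square, 2 seedlings, 1 locus, e = 0
li1 <- loci_info("L1", 2, 100, 108)
toy3 <- function(e1 = 0, e2 = 0, fec = c(100, 200, 100)) {
  toy_dataset(
    adult_xy = rbind(c(20, 20), c(80, 20), c(50, 80)),
    adult_geno = rbind(c(100, 100), c(102, 104), c(100, 106)),
    seedling_xy = rbind(c(30, 30), c(70, 30)),
    seedling_geno = rbind(c(100, 102), c(100, 106)),
    loci = li1, fec = fec, e1 = e1, e2 = e2)
}

test_that("pair weights match a hand computation on the 3-adult toy", {
  data <- toy3()
  cfg <- mcmc_config(grid_cutoff = 80, grid_spacing = 10,
                     progress_every = 0)
  model <- parentage_model(data, cfg)
  u_s <- 253; u_p <- 2000
  fec <- data$adults$fec_mean
  ## hand-built two-stage law: mother share of seed rain x father share
  ## of pollen rain x Mendelian genotype probability
  K2 <- function(d2, u) u / (pi * (u + d2)^2)
  axy <- cbind(data$adults$x, data$adults$y)
  gxy <- cbind(model$grid$x, model$grid$y)
  cm <- model$cellmass
  d2 <- function(a, b) (a[1] - b[1])^2 + (a[2] - b[2])^2
  pollen_rain <- function(m) {
    sum(fec[-m] * K2(apply(axy[-m, , drop = FALSE], 1, d2,
                           b = axy[m, ]), u_p)) +
      sum(cm * K2(apply(gxy, 1, d2, b = axy[m, ]), u_p))
  }
  sxy <- c(30, 30)
  ## seedling 1 (genotype 100/102): mother A1 (100/100), father A2
  ## (102/104): Mendel gives 1 x 1/2
  w_hand <- fec[1] * K2(d2(axy[1, ], sxy), u_s) *
    fec[2] * K2(d2(axy[2, ], axy[1, ]), u_p) / pollen_rain(1) * 0.5
  w_pkg <- pair_weight(model, 1, 1, 2, u_s, u_p)
  expect_equal(w_pkg, w_hand, tolerance = 1e-12)
  ## incompatible pair excluded by genotype: A1 x A3 cannot make 100/102
  expect_equal(pair_weight(model, 1, 1, 3, u_s, u_p), 0)
  ## a tree cannot be both parents
  expect_equal(pair_weight(model, 1, 2, 2, u_s, u_p), 0)
  ## doubling the mother's fecundity doubles her pair weights
  f2 <- fec; f2[1] <- 2 * fec[1]
  expect_equal(pair_weight(model, 1, 1, 2, u_s, u_p, fec = f2),
               2 * w_pkg, tolerance = 1e-12)
})

test_that("pedigree conditional normalises and matches enumeration", {
  data <- toy3(e1 = 0.05, e2 = 0.05)
  cfg <- mcmc_config(grid_cutoff = 60, grid_spacing = 15,
                     progress_every = 0)
  model <- parentage_model(data, cfg)
  pc <- pedigree_conditional(model, 253, 2000)
  for (k in 1:2) {
    expect_equal(sum(pc[[k]]), 1, tolerance = 1e-12)
    expect_true(all(pc[[k]] >= 0))
    expect_equal(diag(pc[[k]])[1:3], rep(0, 3))
    ## brute force over all slots via pair_weight
    W <- outer(1:4, 1:4, Vectorize(function(m, f)
      pair_weight(model, k, m, f, 253, 2000)))
    expect_equal(pc[[k]], W / sum(W), tolerance = 1e-12)
  }
  ## genotype exclusion at e = 0: seedling 2 (100/106) is compatible
  ## with A1 x A3 or A3 x A1 only, so every other mapped pair carries
  ## exactly zero probability (out-of-plot slots stay open)
  data0 <- toy3()
  cfg0 <- mcmc_config(grid_cutoff = 15, grid_spacing = 15,
                      progress_every = 0)
  model0 <- parentage_model(data0, cfg0)
  pc0 <- pedigree_conditional(model0, 253, 2000)
  inin <- pc0[[2]][1:3, 1:3]
  expect_true(all(inin[-c(3, 7)] == 0))   # entries (1,3) and (3,1)
  expect_gt(inin[3] + inin[7], 0)
})

test_that("Gibbs draw frequencies reproduce the conditional", {
  data <- toy3(e1 = 0.05, e2 = 0.05)
  cfg <- mcmc_config(grid_cutoff = 60, grid_spacing = 15,
                     progress_every = 0)
  model <- parentage_model(data, cfg)
  state <- list(u_s = 253, u_p = 2000, fec = data$adults$fec_mean)
  pc <- pedigree_conditional(model, state$u_s, state$u_p)
  set.seed(77)
  n <- 2e4
  counts <- array(0, c(2, 4, 4))
  cache <- seedshadow:::component_cache(model)
  for (i in seq_len(n)) {
    ped <- gibbs_update_pedigrees(model, state, cache = cache)
    counts[1, ped[1, 1], ped[1, 2]] <- counts[1, ped[1, 1], ped[1, 2]] + 1
    counts[2, ped[2, 1], ped[2, 2]] <- counts[2, ped[2, 1], ped[2, 2]] + 1
  }
  for (k in 1:2) {
    emp <- counts[k, , ] / n
    for (m in 1:4) for (f in 1:4) {
      p <- pc[[k]][m, f]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(emp[m, f] - p), 4 * se + 2e-3)
    }
  }
  ## mother != father preserved in every draw
  set.seed(5)
  for (i in 1:20) {
    ped <- gibbs_update_pedigrees(model, state)
    expect_true(all(ped[, 1] != ped[, 2] | ped[, 1] == 4))
  }
})

test_that("fecundity draws are zero-truncated with correct moments", {
  expect_equal(draw_fecundities(c(10, 20), c(0, 0)), c(10, 20))
  expect_error(draw_fecundities(10, -1), "negative")
  set.seed(6)
  x <- draw_fecundities(rep(948, 1e5), rep(500, 1e5))
  expect_true(all(x >= 0))
  ## closed-form zero-truncated normal mean
  a <- -948 / 500
  m_theo <- 948 + 500 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(x) - m_theo), 3 * sd(x) / sqrt(length(x)))
})

test_that("Metropolis respects the truncation bounds and the prior", {
  data <- toy3()
  cfg <- mcmc_config(grid_cutoff = 60, grid_spacing = 15,
                     progress_every = 0)
  model <- parentage_model(data, cfg)
  state <- list(u_s = 253, u_p = 2000, fec = data$adults$fec_mean)
  state$pedigree <- gibbs_update_pedigrees(model, state)
  b_us <- param_from_distance(c(5, 157))
  b_up <- param_from_distance(c(5, 192))
  set.seed(12)
  for (i in 1:300) {
    state <- metropolis_update_dispersal(model, state, c(1, 1))
    expect_true(state$u_s >= b_us[1] && state$u_s <= b_us[2])
    expect_true(state$u_p >= b_up[1] && state$u_p <= b_up[2])
  }
})

test_that("out-of-plot mother share rises toward the plot edge", {
  ## one adult, one seedling moved from the centre to the edge
  li <- li1
  for (sx in c(50, 25, 5)) {
    data <- toy_dataset(
      adult_xy = rbind(c(50, 50), c(55, 50)),
      adult_geno = rbind(c(100, 100), c(102, 102)),
      seedling_xy = rbind(c(sx, 50)),
      seedling_geno = rbind(c(100, 102)),
      loci = li, e1 = 0.1, e2 = 0.1)
    model <- parentage_model(data, mcmc_config(grid_cutoff = 200,
                                               grid_spacing = 10,
                                               progress_every = 0))
    pc <- pedigree_conditional(model, 253, 2000)[[1]]
    out_share <- sum(pc[3, ]) + sum(pc[, 3]) - pc[3, 3]
    assign(paste0("share_", sx), out_share)
  }
  expect_gt(share_25, share_50)
  expect_gt(share_5, share_25)
})

test_that("single-species analysis assigns weakly more parents outside", {
  ## cross-species true parents: restricting candidates to one species
  ## must push probability mass to the out-of-plot slots
  li <- li1
  data <- toy_dataset(
    adult_xy = rbind(c(40, 50), c(60, 50), c(50, 40)),
    adult_geno = rbind(c(100, 100), c(102, 104), c(104, 106)),
    seedling_xy = rbind(c(50, 50)),
    seedling_geno = rbind(c(100, 104)),
    loci = li, e1 = 0.02, e2 = 0.02)
  data$adults$species <- c("Q.rubra", "Q.velutina", "Q.velutina")
  data$seedlings$species <- "Q.rubra"
  out_share <- function(d) {
    model <- parentage_model(d, mcmc_config(grid_cutoff = 100,
                                            grid_spacing = 10,
                                            progress_every = 0))
    pc <- pedigree_conditional(model, 253, 2000)[[1]]
    N <- model$N
    sum(pc[N + 1, ]) + sum(pc[, N + 1]) - pc[N + 1, N + 1]
  }
  pooled <- out_share(data)
  single <- out_share(subset_species(data, "Q.rubra"))
  expect_gte(single, pooled)
})

test_that("chain schedule, retention and reproducibility", {
  data <- toy3(e1 = 0.05, e2 = 0.05)
  cfg <- mcmc_config(n_steps = 400, burnin = 200, thin = 10,
                     grid_cutoff = 60, grid_spacing = 15,
                     progress_every = 0)
  fit1 <- run_mcmc(data, cfg, seed = 31)
  expect_length(fit1$u_s, 20)
  expect_equal(dim(fit1$pedigrees), c(2, 2, 20))
  ## bit-identical under the same seed
  fit2 <- run_mcmc(data, cfg, seed = 31)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$pedigrees, fit2$pedigrees)
  s <- summarize_posterior(fit1)
  expect_equal(sum(s$categories$seedlings), 2)
  expect_equal(s$dispersal$mean_distance_m,
               expected_distance(s$dispersal$mean))
})

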