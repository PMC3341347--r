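#' MCMC configuration for the parentage-and-dispersal model
#'
#' Defaults follow the analysis this model was designed for: truncated
#' normal priors on the 2D-t dispersal parameters (seed: mean 253, SD
#' 1000, truncated at the `u` values corresponding to mean distances of
#' 5 m and 157 m; pollen: mean 2000, SD 1500, truncated at 5 m and
#' 192 m), a 50,000-step chain with 30,000 burn-in and every 20th
#' post-burn-in draw retained (1,000 samples).
#'
#' @param n_steps,burnin,thin Chain schedule; `(n_steps - burnin) / thin`
#'   samples are retained.
#' @param prior_us,prior_up Lists `(mean, sd, lower_m, upper_m)` and
#'   optionally `scale`: prior mean on the `u` (m^2) scale, truncation
#'   bounds as mean distances in metres (converted via
#'   [param_from_distance()]), and the SD interpreted on the
#'   mean-distance scale (`scale = "distance"`, the default, giving a
#'   weakly-informative truncation-dominated prior) or directly on the
#'   `u` scale (`scale = "u"`).
#' @param grid_cutoff,grid_spacing Exterior integration radius and cell
#'   size, metres (see [build_exterior_grid()]).
#' @param prop_scale_us,prop_scale_up Standard deviations of the Gaussian
#'   random-walk proposals on `log u`.
#' @param adapt Adapt proposal scales toward ~30% acceptance during
#'   burn-in only (the post-burn-in kernel is fixed, preserving
#'   detailed balance).
#' @param store_fecundities Keep the retained per-tree fecundity draws.
#' @param progress_every Emit a progress line every so many iterations
#'   (0 = silent).
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_steps = 50000, burnin = 30000, thin = 20,
                        prior_us = list(mean = 253, sd = 1000,
                                        lower_m = 5, upper_m = 157),
                        prior_up = list(mean = 2000, sd = 1500,
                                        lower_m = 5, upper_m = 192),
                        grid_cutoff = 500, grid_spacing = 10,
                        prop_scale_us = 0.5, prop_scale_up = 0.5,
                        adapt = TRUE, store_fecundities = FALSE,
                        progress_every = 1000) {
  stopifnot(n_steps > burnin, thin >= 1,
            (n_steps - burnin) %% thin == 0)
  cfg <- list(n_steps = n_steps, burnin = burnin, thin = thin,
              prior_us = prior_us, prior_up = prior_up,
              grid_cutoff = grid_cutoff, grid_spacing = grid_spacing,
              prop_scale_us = prop_scale_us, prop_scale_up = prop_scale_up,
              adapt = adapt, store_fecundities = store_fecundities,
              progress_every = progress_every)
  class(cfg) <- "mcmc_config"
  cfg
}

prior_bounds <- function(prior)
  param_from_distance(c(prior$lower_m, prior$upper_m))

## Truncated-normal prior on the dispersal parameter. The printed SDs
## (1000 and 1500) are interpreted on the mean-distance scale, where
## they dwarf the 5-157 m / 5-192 m truncation windows: the prior is
## weakly informative and truncation-dominated. Read on the u scale
## instead ("u"), those SDs would make posterior means several prior
## SDs above the prior mean unreachable — which published analyses of
## this model attain — so the distance-scale reading is the default.
## The density over u includes the distance-transform Jacobian.
log_prior_u <- function(u, prior) {
  b <- prior_bounds(prior)
  scale <- if (is.null(prior$scale)) "distance" else prior$scale
  lp <- if (scale == "u") {
    dnorm(u, prior$mean, prior$sd, log = TRUE)
  } else {
    dnorm(expected_distance(u), expected_distance(prior$mean),
          prior$sd, log = TRUE) + log(pi / (4 * sqrt(u)))
  }
  ifelse(u < b[1] | u > b[2], -Inf, lp)
}

#' Precompute the static structures of the parentage model
#'
#' Builds the exterior-parent grid, all pairwise squared distances, the
#' population allele frequencies, and — the expensive part — one
#' `(N+1) x (N+1)` genotype-probability matrix per seedling giving
#' `P(G^o_k | mother, father)` for every candidate parent pair (row
#' `N+1` = unmapped mother, column `N+1` = unmapped father). These depend
#' only on genotypes and error rates, so they are computed once and
#' reused across all MCMC iterations.
#'
#' @param data A [parentage_data()].
#' @param config An [mcmc_config()].
#' @return A list of class `"parentage_model"`.
#' @export
parentage_model <- function(data, config = mcmc_config()) {
  ad <- data$adults; sl <- data$seedlings
  N <- nrow(ad); K <- nrow(sl)
  area_ha <- polygon_area(data$poly) / 1e4
  density <- N / area_ha
  mean_fec <- mean(ad$fec_mean)
  grid <- build_exterior_grid(data$poly, density, mean_fec,
                              cutoff = config$grid_cutoff,
                              spacing = config$grid_spacing)
  axy <- cbind(ad$x, ad$y)
  sxy <- cbind(sl$x, sl$y)
  gxy <- cbind(grid$x, grid$y)
  d2 <- function(a, b) {
    outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  }
  ## smoothed frequencies: unmapped parents can carry alleles unseen
  ## among the mapped adults, which must not be impossible
  freqs <- allele_frequencies(data$genotypes[ad$id], pseudocount = 0.5)
  G <- genotype_weight_list(data, freqs)
  structure(list(
    data = data, config = config, N = N, K = K,
    grid = grid, cellmass = grid$count * grid$fec,
    fec0 = pmax(ad$fec_mean, 1e-6),
    freqs = freqs, G = G,
    D2_sk = if (K) d2(sxy, axy) else matrix(0, 0, N),
    D2_aa = d2(axy, axy),
    D2_cs = if (K) d2(sxy, gxy) else matrix(0, 0, nrow(grid)),
    D2_ca = d2(gxy, axy),
    D2_cc = d2(gxy, gxy)
  ), class = "parentage_model")
}

## one (N+1) x (N+1) genotype-probability matrix per seedling, as the
## product over loci of T_l Q_{k,l} T_l' where T_l holds each candidate's
## Mendelian transmission probabilities over the allele ladder (row N+1:
## population frequencies for an unmapped parent).
genotype_weight_list <- function(data, freqs) {
  gt <- data$genotypes
  ad_idx <- match(data$adults$id, gt$ids)
  sl_idx <- match(data$seedlings$id, gt$ids)
  N <- length(ad_idx); K <- length(sl_idx)
  G <- lapply(seq_len(K), function(k) matrix(1, N + 1, N + 1))
  if (K == 0) return(G)
  informative <- logical(K)
  for (j in seq_len(nrow(gt$loci))) {
    lad <- ladder(gt$loci, j)
    U <- length(lad)
    f <- freqs[[j]]
    M <- mistype_matrix(lad, data$err$e1[j])
    Tm <- matrix(0, N + 1, U)
    a1 <- match(gt$al1[ad_idx, j], lad)
    a2 <- match(gt$al2[ad_idx, j], lad)
    for (i in seq_len(N)) {
      Tm[i, ] <- if (is.na(a1[i])) f
      else transmission_vector(c(a1[i], a2[i]), f, M, data$err$e2[j])
    }
    Tm[N + 1, ] <- f
    o1 <- match(gt$al1[sl_idx, j], lad)
    o2 <- match(gt$al2[sl_idx, j], lad)
    for (k in seq_len(K)) {
      if (is.na(o1[k])) next
      informative[k] <- TRUE
      Q <- genotype_obs_matrix(c(o1[k], o2[k]), M, data$err$e2[j])
      G[[k]] <- G[[k]] * (Tm %*% Q %*% t(Tm))
    }
  }
  if (K && any(!informative))
    warning("seedling(s) with all loci missing carry no genotype ",
            "information: ",
            paste(data$seedlings$id[!informative], collapse = ", "))
  G
}

## --- dispersal-weight machinery -------------------------------------
##
## The pedigree prior is the two-stage generative law of seed and pollen
## rain: a seedling at x_k has mother i with probability equal to i's
## share of the total seed rain at x_k, and, given the mother, father i'
## with probability equal to i''s share of the total pollen rain at the
## mother's location (self excluded). The normalising totals
##   A_k = total seed rain at seedling k (mapped adults + exterior)
##   B_i = total pollen rain at mother i (other adults + exterior)
##   B_c = total pollen rain at exterior cell c
## depend on the dispersal parameters, so they appear in the Metropolis
## likelihood as well as in the Gibbs weights. Exterior cells always
## carry the mean fecundity — including inside B_c — so the expensive
## exterior cross-product depends only on (u_s, u_p) and is memoised.

## memoised kernel matrices, keyed on the dispersal parameter value.
## Two slots per side, so the current value survives interleaved
## Metropolis proposal evaluations without recomputation.
component_cache <- function(model) {
  env <- new.env(parent = emptyenv())
  cm <- model$cellmass
  env$seed_entries <- list()
  env$pollen_entries <- list()
  env$cross_entry <- NULL
  ## LRU over two slots: a hit moves the entry to the front so the
  ## current parameter value is never evicted by proposal evaluations
  lookup <- function(field, u) {
    entries <- env[[field]]
    for (i in seq_along(entries)) {
      if (identical(entries[[i]]$u, u)) {
        if (i > 1) env[[field]] <- c(entries[i], entries[-i])
        return(entries[[i]])
      }
    }
    NULL
  }
  env$seed <- function(u_s) {
    e <- lookup("seed_entries", u_s)
    if (is.null(e)) {
      Ws0 <- if (model$K)
        kern_r2(model$D2_cs, u_s) * rep(cm, each = model$K)
      else matrix(0, 0, length(cm))
      e <- list(u = u_s, Ks_sk = kern_r2(model$D2_sk, u_s), Ws0 = Ws0,
                rsWs0 = rowSums(Ws0))
      env$seed_entries <- c(list(e), env$seed_entries)[
        seq_len(min(2, length(env$seed_entries) + 1))]
    }
    e
  }
  env$pollen <- function(u_p) {
    e <- lookup("pollen_entries", u_p)
    if (is.null(e)) {
      Kp_ca <- kern_r2(model$D2_ca, u_p)
      PoutIn <- as.numeric(crossprod(Kp_ca, cm))
      Mp <- as.numeric(crossprod(kern_r2(model$D2_cc, u_p), cm))
      Bc <- as.numeric(Kp_ca %*% model$fec0) + Mp
      e <- list(u = u_p, Kp_aa = kern_r2(model$D2_aa, u_p),
                Kp_ca = Kp_ca, PoutIn = PoutIn, Mp = Mp,
                Bc = pmax(Bc, .Machine$double.xmin))
      env$pollen_entries <- c(list(e), env$pollen_entries)[
        seq_len(min(2, length(env$pollen_entries) + 1))]
    }
    e
  }
  env$cross <- function(u_s, u_p) {
    ce <- env$cross_entry
    if (is.null(ce) || !identical(ce$u, c(u_s, u_p))) {
      s <- env$seed(u_s); p <- env$pollen(u_p)
      WsB <- s$Ws0 * rep(1 / p$Bc, each = model$K)
      ce <- list(u = c(u_s, u_p), SP0n = WsB %*% p$Kp_ca,
                 SPoutOut0 = as.numeric(WsB %*% p$Mp))
      env$cross_entry <- ce
    }
    ce
  }
  env
}

colscale <- function(X, v) X * rep(v, each = nrow(X))

## per-iteration weight components given the current fecundity draws;
## everything u-dependent comes from the memoised cache.
model_terms <- function(model, u_s, u_p, fec, cache = NULL) {
  if (is.null(cache)) cache <- component_cache(model)
  s <- cache$seed(u_s)
  p <- cache$pollen(u_p)
  ## pollen rain at each in-plot mother, her own pollen excluded
  B <- as.numeric(p$Kp_aa %*% fec) - fec / (pi * u_p) + p$PoutIn
  bad <- B <= 0
  if (any(bad)) B[bad] <- 1  # isolated mother: numerators are 0 anyway
  Pin <- colscale(p$Kp_aa, fec) * (1 / B)
  if (model$K) {
    Sin <- colscale(s$Ks_sk, fec)
    A <- as.numeric(s$Ks_sk %*% fec) + s$rsWs0
    cr <- cache$cross(u_s, u_p)
    SPoutIn <- colscale(cr$SP0n, fec)
    SPoutOut <- cr$SPoutOut0
  } else {
    Sin <- matrix(0, 0, model$N)
    A <- numeric(0)
    SPoutIn <- matrix(0, 0, model$N)
    SPoutOut <- numeric(0)
  }
  list(Sin = Sin, Pin = Pin, PoutIn = p$PoutIn / B, A = A,
       SPoutIn = SPoutIn, SPoutOut = SPoutOut)
}

#' Unnormalised weight of one candidate parent pair
#'
#' The product of the seed-rain, pollen-rain and genotype factors for a
#' single seedling and a single (mother, father) assignment: the
#' mother's contribution to the seed rain at the seedling, the father's
#' share of the pollen rain at the mother, and the probability of the
#' observed offspring genotype. Out-of-plot candidates are integrated
#' over the exterior grid. [pedigree_conditional()] is this quantity
#' normalised over all pairs.
#'
#' @param model A [parentage_model()].
#' @param k Seedling index.
#' @param mother,father Adult index in `1..N`, or `"out"` (equivalently
#'   `N + 1`) for an unmapped parent.
#' @param u_s,u_p Dispersal parameters, m^2.
#' @param fec Per-adult fecundity vector (defaults to posterior means).
#' @return A nonnegative number; zero when `mother == father`.
#' @export
pair_weight <- function(model, k, mother, father, u_s, u_p,
                        fec = model$data$adults$fec_mean) {
  N <- model$N
  slot <- function(z) if (identical(z, "out")) N + 1L else as.integer(z)
  m <- slot(mother); f <- slot(father)
  stopifnot(k >= 1, k <= model$K, m >= 1, m <= N + 1, f >= 1, f <= N + 1)
  if (m == f && m <= N) return(0)
  tm <- model_terms(model, u_s, u_p, fec)
  g <- model$G[[k]][m, f]
  w <- if (m <= N) {
    tm$Sin[k, m] * (if (f <= N) tm$Pin[m, f] else tm$PoutIn[m])
  } else {
    if (f <= N) tm$SPoutIn[k, f] else tm$SPoutOut[k]
  }
  w * g
}

#' Conditional parent-pair distribution of each seedling
#'
#' Normalises the pair weights of every (mother, father) combination —
#' including the out-of-plot slots — into the categorical distribution
#' the Gibbs sampler draws from.
#'
#' @inheritParams pair_weight
#' @return A list with one `(N+1) x (N+1)` probability matrix per
#'   seedling (row = mother, column = father; slot `N+1` = out-of-plot),
#'   each summing to 1.
#' @export
pedigree_conditional <- function(model, u_s, u_p,
                                 fec = model$data$adults$fec_mean) {
  tm <- model_terms(model, u_s, u_p, fec)
  N <- model$N
  lapply(seq_len(model$K), function(k) {
    W <- matrix(0, N + 1, N + 1)
    W[seq_len(N), seq_len(N)] <- tm$Sin[k, ] * tm$Pin
    W[cbind(seq_len(N), seq_len(N))] <- 0
    W[seq_len(N), N + 1] <- tm$Sin[k, ] * tm$PoutIn
    W[N + 1, seq_len(N)] <- tm$SPoutIn[k, ]
    W[N + 1, N + 1] <- tm$SPoutOut[k]
    W <- W * model$G[[k]]
    tot <- sum(W)
    if (!is.finite(tot) || tot <= 0)
      stop("all parent-pair weights are zero for seedling ",
           model$data$seedlings$id[k],
           " (check error rates and allele ladders)", call. = FALSE)
    W / tot
  })
}

#' Gibbs update of the pedigree
#'
#' Redraws every seedling's (mother, father) pair from its conditional
#' distribution given the current dispersal parameters and fecundity
#' draws.
#'
#' @param model A [parentage_model()].
#' @param state Model state: list with elements `u_s`, `u_p`, `fec`.
#' @param cache Optional [component cache][run_mcmc()] reused across
#'   iterations.
#' @return Integer `K x 2` matrix of parent slots (`N+1` = out-of-plot).
#' @export
gibbs_update_pedigrees <- function(model, state, cache = NULL) {
  tm <- model_terms(model, state$u_s, state$u_p, state$fec,
                    cache = cache)
  gibbs_sample_pairs(model$G, tm$Sin, tm$Pin, tm$PoutIn, tm$SPoutIn,
                     tm$SPoutOut)
}

#' Draw per-tree fecundities
#'
#' One draw per tree from a zero-truncated normal with the tree's
#' posterior mean and SD, mixing the parentage model over fecundity
#' uncertainty. `sd = 0` returns the mean.
#'
#' @param means,sds Numeric vectors, seeds per year; `sds >= 0`.
#' @return Numeric vector of nonnegative fecundities.
#' @export
draw_fecundities <- function(means, sds) {
  stopifnot(length(means) == length(sds))
  if (any(sds < 0)) stop("negative fecundity SD", call. = FALSE)
  out <- means
  pos <- sds > 0
  if (any(pos)) {
    ## inverse-CDF draw from N(mean, sd) truncated to [0, Inf)
    p0 <- pnorm(0, means[pos], sds[pos])
    q <- runif(sum(pos), p0, 1)
    out[pos] <- qnorm(q, means[pos], sds[pos])
  }
  pmax(out, 0)
}

## kernel-dependent part of the log-likelihood under the current
## pedigree: the log seed-rain share of each assigned mother and log
## pollen-rain share of each assigned father. Genotype factors are
## constant in (u_s, u_p) and omitted. Avoids the exterior
## cross-product, so proposal evaluations stay cheap.
loglik_kernel <- function(model, ped, u_s, u_p, fec, cache = NULL) {
  if (model$K == 0) return(0)
  if (is.null(cache)) cache <- component_cache(model)
  s <- cache$seed(u_s)
  p <- cache$pollen(u_p)
  N <- model$N
  m <- ped[, 1]; f <- ped[, 2]
  A <- as.numeric(s$Ks_sk %*% fec) + s$rsWs0
  B <- as.numeric(p$Kp_aa %*% fec) - fec / (pi * u_p) + p$PoutIn
  ll <- -sum(log(A))
  min_ <- m <= N
  idx <- which(min_)
  if (length(idx))
    ll <- ll + sum(log(fec[m[idx]] * s$Ks_sk[cbind(idx, m[idx])]))
  inin <- which(min_ & f <= N)
  if (length(inin))
    ll <- ll + sum(log(fec[f[inin]] *
                         p$Kp_aa[cbind(m[inin], f[inin])] /
                         B[m[inin]]))
  inout <- which(min_ & f > N)
  if (length(inout))
    ll <- ll + sum(log(p$PoutIn[m[inout]] / B[m[inout]]))
  outm <- which(!min_)
  if (length(outm)) {
    WsB <- s$Ws0[outm, , drop = FALSE] *
      rep(1 / p$Bc, each = length(outm))
    fo <- f[outm]
    isin <- fo <= N
    if (any(isin)) {
      Bsel <- p$Kp_ca[, fo[isin], drop = FALSE]
      terms <- colSums(t(WsB[isin, , drop = FALSE]) * Bsel) *
        fec[fo[isin]]
      ll <- ll + sum(log(terms))
    }
    if (any(!isin))
      ll <- ll + sum(log(WsB[!isin, , drop = FALSE] %*% p$Mp))
  }
  ll
}

#' Metropolis update of the dispersal parameters
#'
#' One Gaussian random-walk proposal on `log u` for each of `u_s` and
#' `u_p`, accepted by the kernel likelihood under the current pedigree
#' times the truncated-normal prior (proposals outside the truncation
#' bounds are rejected outright). The log-scale proposal contributes the
#' usual `u'/u` Jacobian to the acceptance ratio.
#'
#' @param model A [parentage_model()].
#' @param state List with `u_s`, `u_p`, `fec`, `pedigree`.
#' @param scales Length-2 proposal SDs on `log u` for (`u_s`, `u_p`).
#' @param cache Optional memoised component cache.
#' @return `state` with updated `u_s`, `u_p` and logical `accepted`
#'   flags.
#' @export
metropolis_update_dispersal <- function(model, state,
                                        scales = c(0.5, 0.5),
                                        cache = NULL) {
  cfg <- model$config
  if (is.null(cache)) cache <- component_cache(model)
  cur_ll <- loglik_kernel(model, state$pedigree, state$u_s, state$u_p,
                          state$fec, cache = cache)
  accepted <- c(us = FALSE, up = FALSE)
  for (par in 1:2) {
    prior <- if (par == 1) cfg$prior_us else cfg$prior_up
    cur <- if (par == 1) state$u_s else state$u_p
    prop <- cur * exp(rnorm(1, 0, scales[par]))
    lp_prop <- log_prior_u(prop, prior)
    if (is.finite(lp_prop)) {
      ll_prop <- if (par == 1)
        loglik_kernel(model, state$pedigree, prop, state$u_p,
                      state$fec, cache = cache)
      else
        loglik_kernel(model, state$pedigree, state$u_s, prop,
                      state$fec, cache = cache)
      lr <- ll_prop - cur_ll + lp_prop - log_prior_u(cur, prior) +
        log(prop) - log(cur)
      if (is.finite(lr) && log(runif(1)) < lr) {
        if (par == 1) state$u_s <- prop else state$u_p <- prop
        cur_ll <- ll_prop
        accepted[par] <- TRUE
      }
    }
  }
  state$accepted <- accepted
  state
}

#' Run the parentage-and-dispersal MCMC
#'
#' Gibbs-within-Metropolis sampler: each sweep draws fecundities from
#' their posteriors, redraws every seedling's parent pair from its full
#' conditional, and updates `u_s` and `u_p` by random-walk Metropolis
#' under the truncated-normal priors. With zero seedlings the sampler
#' reproduces the prior.
#'
#' @param data A [parentage_data()], or a prebuilt [parentage_model()].
#' @param config An [mcmc_config()]; ignored when `data` is already a
#'   model (the model's own config is used).
#' @param seed Optional integer seed for a reproducible chain.
#' @return An object of class `"parentage_fit"`: retained draws of
#'   `u_s`, `u_p` (and optionally fecundities), retained pedigrees
#'   (`K x 2 x n_retained`), the full trace, and acceptance rates.
#' @export
run_mcmc <- function(data, config = mcmc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- if (inherits(data, "parentage_model")) data
           else parentage_model(data, config)
  cfg <- model$config
  n_ret <- (cfg$n_steps - cfg$burnin) %/% cfg$thin
  ad <- model$data$adults
  ## initial state: prior means (clipped into the truncation bounds),
  ## fecundity posterior means, pedigree from one Gibbs draw
  clip <- function(u, prior) {
    b <- prior_bounds(prior)
    min(max(u, b[1] * 1.001), b[2] * 0.999)
  }
  state <- list(u_s = clip(cfg$prior_us$mean, cfg$prior_us),
                u_p = clip(cfg$prior_up$mean, cfg$prior_up),
                fec = pmax(ad$fec_mean, 1e-6))
  cache <- component_cache(model)
  state$pedigree <- if (model$K)
    gibbs_update_pedigrees(model, state, cache = cache)
  else matrix(integer(0), 0, 2)
  scales <- c(cfg$prop_scale_us, cfg$prop_scale_up)
  trace <- matrix(NA_real_, cfg$n_steps, 4,
                  dimnames = list(NULL, c("u_s", "u_p", "acc_us",
                                          "acc_up")))
  ped_draws <- array(NA_integer_, c(model$K, 2, n_ret))
  fec_draws <- if (cfg$store_fecundities)
    matrix(NA_real_, model$N, n_ret) else NULL
  acc_win <- c(0, 0); win_n <- 0
  ret <- 0
  for (iter in seq_len(cfg$n_steps)) {
    state$fec <- pmax(draw_fecundities(ad$fec_mean, ad$fec_sd), 1e-6)
    if (model$K)
      state$pedigree <- gibbs_update_pedigrees(model, state,
                                               cache = cache)
    state <- metropolis_update_dispersal(model, state, scales,
                                         cache = cache)
    acc_win <- acc_win + state$accepted
    win_n <- win_n + 1
    if (cfg$adapt && iter <= cfg$burnin && win_n == 50) {
      scales <- scales * exp((acc_win / win_n - 0.3))
      scales <- pmin(pmax(scales, 0.01), 5)
      acc_win <- c(0, 0); win_n <- 0
    }
    trace[iter, ] <- c(state$u_s, state$u_p, state$accepted)
    if (iter > cfg$burnin && (iter - cfg$burnin) %% cfg$thin == 0) {
      ret <- ret + 1
      if (model$K) ped_draws[, , ret] <- state$pedigree
      if (cfg$store_fecundities) fec_draws[, ret] <- state$fec
    }
    if (cfg$progress_every > 0 && iter %% cfg$progress_every == 0)
      message(sprintf("iter %d/%d  u_s=%.1f u_p=%.1f", iter,
                      cfg$n_steps, state$u_s, state$u_p))
  }
  keep <- cfg$burnin + seq_len(n_ret) * cfg$thin
  structure(list(
    u_s = trace[keep, "u_s"], u_p = trace[keep, "u_p"],
    pedigrees = ped_draws, fecundities = fec_draws,
    trace = trace, retained_iters = keep, model = model,
    acceptance = colMeans(trace[-seq_len(cfg$burnin),
                                c("acc_us", "acc_up"), drop = FALSE]),
    config = cfg
  ), class = "parentage_fit")
}

#' @export
print.parentage_fit <- function(x, ...) {
  cat(sprintf(paste0("parentage_fit: %d retained samples\n",
                     "  u_s posterior mean %.1f (mean distance %.1f m)\n",
                     "  u_p posterior mean %.1f (mean distance %.1f m)\n",
                     "  MH acceptance: u_s %.2f, u_p %.2f\n"),
              length(x$u_s), mean(x$u_s),
              expected_distance(mean(x$u_s)), mean(x$u_p),
              expected_distance(mean(x$u_p)),
              x$acceptance[1], x$acceptance[2]))
  invisible(x)
}

#' Posterior summary of a parentage fit
#'
#' Posterior means, SDs and central 95% credible intervals for the
#' dispersal parameters, their implied mean dispersal distances, the
#' modal parent pair per seedling, and the counts of seedlings falling
#' into the four parentage categories (both parents in-plot, in-plot
#' father only, in-plot mother only, both out-of-plot), classified by
#' each seedling's modal pair.
#'
#' @param fit A [run_mcmc()] result.
#' @return A list of class `"parentage_summary"` with elements
#'   `dispersal` (data frame), `parentage` (per-seedling modal
#'   assignment), and `categories` (counts and percentages).
#' @export
summarize_posterior <- function(fit) {
  if (length(fit$u_s) < 2) stop("need >= 2 retained samples")
  qs <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
  disp <- data.frame(
    parameter = c("u_s", "u_p"),
    mean = c(mean(fit$u_s), mean(fit$u_p)),
    sd = c(sd(fit$u_s), sd(fit$u_p)),
    ci_lower = c(qs(fit$u_s)[1], qs(fit$u_p)[1]),
    ci_upper = c(qs(fit$u_s)[2], qs(fit$u_p)[2]))
  disp$mean_distance_m <- expected_distance(disp$mean)
  disp$dist_ci_lower_m <- expected_distance(disp$ci_lower)
  disp$dist_ci_upper_m <- expected_distance(disp$ci_upper)
  model <- fit$model
  N <- model$N; K <- model$K
  parentage <- NULL
  categories <- NULL
  if (K > 0) {
    slot_name <- function(s) ifelse(s > N, "out",
                                    model$data$adults$id[s])
    modal <- t(vapply(seq_len(K), function(k) {
      pairs <- paste(fit$pedigrees[k, 1, ], fit$pedigrees[k, 2, ])
      tab <- sort(table(pairs), decreasing = TRUE)
      best <- as.integer(strsplit(names(tab)[1], " ")[[1]])
      c(best, tab[1] / length(pairs))
    }, numeric(3)))
    cat4 <- function(m, f) {
      if (m <= N && f <= N) "in_in"
      else if (m > N && f <= N) "in_father_out_mother"
      else if (m <= N && f > N) "in_mother_out_father"
      else "out_out"
    }
    category <- mapply(cat4, modal[, 1], modal[, 2])
    parentage <- data.frame(
      seedling = model$data$seedlings$id,
      mother = slot_name(modal[, 1]), father = slot_name(modal[, 2]),
      support = modal[, 3], category = category,
      stringsAsFactors = FALSE)
    lev <- c("in_in", "in_father_out_mother", "in_mother_out_father",
             "out_out")
    counts <- table(factor(category, levels = lev))
    categories <- data.frame(category = lev,
                             seedlings = as.integer(counts),
                             percent = 100 * as.numeric(counts) / K)
  }
  structure(list(dispersal = disp, parentage = parentage,
                 categories = categories, n_samples = length(fit$u_s)),
            class = "parentage_summary")
}

#' @export
print.parentage_summary <- function(x, ...) {
  cat("Posterior summary (", x$n_samples, " samples)\n", sep = "")
  print(x$dispersal, row.names = FALSE, digits = 4)
  if (!is.null(x$categories)) {
    cat("\nParentage categories (modal assignment):\n")
    print(x$categories, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Trace plot of a parentage fit
#' @param x A `parentage_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.parentage_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trace[, "u_s"], type = "l", xlab = "iteration",
                 ylab = "u_s", ...)
  graphics::abline(v = x$config$burnin, col = "grey", lty = 2)
  graphics::plot(x$trace[, "u_p"], type = "l", xlab = "iteration",
                 ylab = "u_p", ...)
  graphics::abline(v = x$config$burnin, col = "grey", lty = 2)
  invisible(x)
}
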