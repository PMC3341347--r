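#' Configuration for the synthetic stand-and-seedling simulator
#'
#' Defaults emulate a mixed red-oak stand of the kind the analysis is
#' designed for: a 7.5-ha rectangular plot at 26.5 adults/ha (~199
#' adults), right-skewed per-tree fecundities with mean ~948 seeds/yr
#' and maxima near 2,800, six microsatellite loci with 16 alleles each
#' (within the 14-35 alleles/locus range typical of these markers),
#' dropout rates of 0.02-0.08 and mistyping rates of 0.02-0.18 per
#' locus, restricted seed dispersal and extensive wind pollination.
#'
#' @param poly Plot polygon (default 250 x 300 m rectangle, 7.5 ha).
#' @param density_ha Adult density, trees/ha.
#' @param fec_mean Target mean of per-tree fecundity means, seeds/yr.
#' @param fec_shape Gamma shape of the fecundity-mean distribution
#'   (shape 3 puts the observed maxima near 2,800-3,000 seeds/yr for
#'   ~200 trees).
#' @param fec_cv Ratio of each tree's fecundity posterior SD to its mean.
#' @param n_loci,alleles_per_locus,motif Marker panel geometry.
#' @param dirichlet_alpha Concentration of the per-locus Dirichlet draw
#'   of allele frequencies (0.5 gives realistically uneven spectra).
#' @param u_s,u_p True seed and pollen dispersal parameters, m^2.
#' @param n_seedlings Number of in-plot seedlings to generate.
#' @param e1,e2 Per-locus mistyping and dropout rates (recycled across
#'   loci).
#' @param exterior_cutoff Width (m) of the simulated forest belt around
#'   the plot supplying immigrant seed and pollen.
#' @param species Species labels assigned at random to adults and
#'   seedlings (a single interbreeding population, as in mixed stands of
#'   hybridising oaks).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(poly = cbind(c(0, 250, 250, 0), c(0, 0, 300, 300)),
                       density_ha = 26.5, fec_mean = 948, fec_shape = 3,
                       fec_cv = 0.3, n_loci = 6, alleles_per_locus = 16,
                       motif = 2, dirichlet_alpha = 0.5,
                       u_s = 253, u_p = 2000, n_seedlings = 180,
                       e1 = c(0.02, 0.05, 0.08, 0.12, 0.15, 0.18),
                       e2 = c(0.02, 0.03, 0.04, 0.05, 0.06, 0.08),
                       exterior_cutoff = 250,
                       species = c("Q.rubra", "Q.velutina",
                                   "Q.coccinea")) {
  cfg <- as.list(environment())
  stopifnot(cfg$density_ha > 0, cfg$n_loci >= 1,
            cfg$alleles_per_locus >= 2, cfg$n_seedlings >= 0)
  cfg$e1 <- rep_len(e1, n_loci)
  cfg$e2 <- rep_len(e2, n_loci)
  class(cfg) <- "sim_config"
  cfg
}

sim_loci <- function(cfg) {
  loci_info(sprintf("L%02d", seq_len(cfg$n_loci)), motif = cfg$motif,
            min_size = 100,
            max_size = 100 + (cfg$alleles_per_locus - 1) * cfg$motif)
}

## Dirichlet(alpha) allele frequencies per locus over the full ladder
sim_allele_freqs <- function(cfg) {
  loci <- sim_loci(cfg)
  out <- lapply(seq_len(cfg$n_loci), function(j) {
    lad <- ladder(loci, j)
    g <- rgamma(length(lad), cfg$dirichlet_alpha)
    setNames(g / sum(g), as.character(lad))
  })
  names(out) <- loci$locus
  structure(out, class = "allele_freqs")
}

## n Hardy-Weinberg genotypes from the given frequencies
sim_hwe_genotypes <- function(n, freqs, loci, ids, pop = "adult") {
  L <- nrow(loci)
  al1 <- al2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    lad <- ladder(loci, j)
    al1[, j] <- sample(lad, n, replace = TRUE, prob = freqs[[j]])
    al2[, j] <- sample(lad, n, replace = TRUE, prob = freqs[[j]])
  }
  genotype_table(ids, al1, al2, loci, pop = rep(pop, n))
}

#' Simulate a mapped adult stand
#'
#' Poisson tree count at the configured density, uniform locations in
#' the plot, Gamma-distributed fecundity means, and true genotypes drawn
#' from Hardy-Weinberg equilibrium at simulated allele frequencies.
#'
#' @param cfg A [sim_config()].
#' @param freqs Optional [allele_frequencies()]; simulated if omitted.
#' @return List with `adults` (data frame), `genotypes` (true
#'   [genotype_table()]), `freqs`, `loci`.
#' @export
simulate_stand <- function(cfg = sim_config(), freqs = NULL) {
  area_ha <- polygon_area(cfg$poly) / 1e4
  n <- rpois(1, cfg$density_ha * area_ha)
  if (n < 2) stop("expected tree count too low; increase density or plot",
                  call. = FALSE)
  loci <- sim_loci(cfg)
  if (is.null(freqs)) freqs <- sim_allele_freqs(cfg)
  xy <- runif_in_polygon(n, cfg$poly)
  fec <- rgamma(n, shape = cfg$fec_shape,
                scale = cfg$fec_mean / cfg$fec_shape)
  adults <- data.frame(id = sprintf("A%04d", seq_len(n)),
                       x = xy[, 1], y = xy[, 2],
                       species = sample(cfg$species, n, replace = TRUE),
                       dbh = round(10 + fec / 25 + rgamma(n, 2, 0.2), 1),
                       fec_mean = fec, fec_sd = cfg$fec_cv * fec,
                       stringsAsFactors = FALSE)
  geno <- sim_hwe_genotypes(n, freqs, loci, adults$id, pop = "adult")
  ## the reported per-tree fecundity is a posterior (mean, SD); the
  ## realised fecundity the stand actually disperses with is one draw
  ## from it, so inference that mixes over fecundity uncertainty is
  ## coherent with the generated data
  fec_true <- draw_fecundities(adults$fec_mean, adults$fec_sd)
  list(adults = adults, genotypes = geno, freqs = freqs, loci = loci,
       fec_true = fec_true)
}

## exterior forest belt: same density, fecundity and allele frequencies
## as the mapped stand, out to cfg$exterior_cutoff beyond the plot
simulate_exterior <- function(cfg, freqs, loci) {
  p <- as_polygon(cfg$poly)
  cut <- cfg$exterior_cutoff
  bbox_area <- (diff(range(p[, 1])) + 2 * cut) *
    (diff(range(p[, 2])) + 2 * cut)
  annulus_ha <- (bbox_area - polygon_area(p)) / 1e4
  n <- rpois(1, cfg$density_ha * annulus_ha)
  xs <- runif(n, min(p[, 1]) - cut, max(p[, 1]) + cut)
  ys <- runif(n, min(p[, 2]) - cut, max(p[, 2]) + cut)
  ## the belt is the edge-distance annulus, matching the exterior
  ## integration region of the inference model
  keep <- !in_plot(cbind(xs, ys), p) &
    edge_distance(cbind(xs, ys), p) <= cut
  n <- sum(keep)
  fec <- rgamma(n, shape = cfg$fec_shape,
                scale = cfg$fec_mean / cfg$fec_shape)
  ext <- data.frame(id = sprintf("X%05d", seq_len(n)),
                    x = xs[keep], y = ys[keep],
                    fec_mean = fec, stringsAsFactors = FALSE)
  geno <- sim_hwe_genotypes(n, freqs, loci, ext$id, pop = "exterior")
  list(trees = ext, genotypes = geno)
}

#' Simulate seedlings from a stand by the forward dispersal model
#'
#' The generative mirror of the inference model: mothers are chosen
#' proportional to fecundity among all trees (mapped stand plus a
#' simulated forest belt around it, so seed and pollen immigration occur
#' at realistic rates); each seed lands at the mother plus a 2D-t
#' displacement with parameter `u_s` and is kept only if it falls in the
#' plot; the father is chosen among all other trees proportional to
#' pollen output times the pollen kernel at the mother's location.
#' Offspring genotypes are Mendelian draws from the true parental
#' genotypes.
#'
#' @param stand A [simulate_stand()] result.
#' @param cfg The [sim_config()] used for the stand.
#' @param max_attempts Upper bound on seed draws before giving up.
#' @return List with `seedlings` (data frame), `genotypes` (true
#'   [genotype_table()]), `pedigree` (data frame of true mother/father
#'   ids; exterior parents count as `"out"` in `mother_inplot` /
#'   `father_inplot`), and `exterior` (the simulated belt).
#' @export
simulate_offspring <- function(stand, cfg = sim_config(),
                               max_attempts = 1000 * cfg$n_seedlings) {
  ext <- simulate_exterior(cfg, stand$freqs, stand$loci)
  all_xy <- rbind(cbind(stand$adults$x, stand$adults$y),
                  cbind(ext$trees$x, ext$trees$y))
  fec_in <- if (is.null(stand$fec_true)) stand$adults$fec_mean
            else stand$fec_true
  all_fec <- pmax(c(fec_in, ext$trees$fec_mean), 1e-9)
  all_ids <- c(stand$adults$id, ext$trees$id)
  n_in <- nrow(stand$adults)
  n_all <- length(all_ids)
  K <- cfg$n_seedlings
  if (K == 0) stop("n_seedlings must be >= 1 to simulate offspring",
                   call. = FALSE)
  mother <- father <- integer(K)
  sx <- sy <- numeric(K)
  got <- 0; attempts <- 0
  while (got < K) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("no seedling landed inside the plot after max_attempts",
           call. = FALSE)
    m <- sample.int(n_all, 1, prob = all_fec)
    d <- sample_displacements(cfg$u_s, 1)
    pos <- all_xy[m, ] + d[1, ]
    if (!in_plot(rbind(pos), cfg$poly)) next
    d2m <- (all_xy[, 1] - all_xy[m, 1])^2 + (all_xy[, 2] - all_xy[m, 2])^2
    wp <- all_fec * kern_r2(d2m, cfg$u_p)
    wp[m] <- 0  # a tree cannot be both mother and father
    got <- got + 1
    mother[got] <- m
    father[got] <- sample.int(n_all, 1, prob = wp)
    sx[got] <- pos[1]; sy[got] <- pos[2]
  }
  ## Mendelian inheritance from true parental genotypes
  loci <- stand$loci
  L <- nrow(loci)
  geno_all_1 <- rbind(stand$genotypes$al1, ext$genotypes$al1)
  geno_all_2 <- rbind(stand$genotypes$al2, ext$genotypes$al2)
  pick <- function(idx) {
    from1 <- matrix(runif(K * L) < 0.5, K, L)
    ifelse(from1, geno_all_1[idx, , drop = FALSE],
           geno_all_2[idx, , drop = FALSE])
  }
  al1 <- pick(mother); al2 <- pick(father)
  ids <- sprintf("S%04d", seq_len(K))
  seedlings <- data.frame(id = ids, x = sx, y = sy,
                          species = sample(cfg$species, K, replace = TRUE),
                          stringsAsFactors = FALSE)
  pedigree <- data.frame(
    seedling = ids,
    mother = all_ids[mother], father = all_ids[father],
    mother_inplot = mother <= n_in, father_inplot = father <= n_in,
    stringsAsFactors = FALSE)
  list(seedlings = seedlings,
       genotypes = genotype_table(ids, al1, al2, loci,
                                  pop = rep("seedling", K)),
       pedigree = pedigree, exterior = ext)
}

#' Simulate a complete, analysis-ready dataset
#'
#' Runs [simulate_stand()] and [simulate_offspring()], corrupts all
#' genotypes through [apply_genotyping_error()] at the configured
#' per-locus rates, and assembles a validated [parentage_data()]
#' together with the generating truth.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return List: `data` (a [parentage_data()] of observed genotypes),
#'   `truth` (true pedigree, true genotypes, true `u_s`, `u_p`, allele
#'   frequencies).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stand <- simulate_stand(cfg)
  off <- simulate_offspring(stand, cfg)
  err <- error_rates(stand$loci$locus, cfg$e1, cfg$e2)
  true_geno <- genotype_table(
    c(stand$genotypes$ids, off$genotypes$ids),
    rbind(stand$genotypes$al1, off$genotypes$al1),
    rbind(stand$genotypes$al2, off$genotypes$al2),
    stand$loci, pop = c(stand$genotypes$pop, off$genotypes$pop))
  obs_geno <- apply_genotyping_error(true_geno, err)
  data <- parentage_data(stand$adults, off$seedlings, obs_geno,
                         cfg$poly, err)
  list(data = data,
       truth = list(pedigree = off$pedigree, genotypes = true_geno,
                    u_s = cfg$u_s, u_p = cfg$u_p, freqs = stand$freqs,
                    fec_true = stand$fec_true,
                    exterior = off$exterior))
}
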