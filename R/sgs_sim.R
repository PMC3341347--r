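#' Define a spatial-genetic-structure simulation scenario
#'
#' Encodes a stand-history hypothesis as the spatial configuration of the
#' founding seed sources: `"distant"` — recolonisation from several
#' source populations well outside the stand (the farmed-site history);
#' `"scattered"` — regeneration from scattered source trees at a given
#' density within and around the stand (the selectively-logged history);
#' `"mixed"` — distant pools plus a few local source trees. Three
#' cohorts ("generations") are then built: generation 1 receives parents
#' from the sources by kernel-weighted seed and pollen dispersal,
#' generation 2 from sources plus generation 1, generation 3 from all
#' older cohorts.
#'
#' @param kind One of `"distant"`, `"scattered"`, `"mixed"`.
#' @param u_s_values Seed dispersal parameters to sweep (m^2); the
#'   default grid spans mean distances of 7-131 m.
#' @param u_p Pollen dispersal parameter (default 9000, mean 149 m).
#' @param replicates Number of simulation replicates.
#' @param poly Stand polygon used for the cohort maps.
#' @param cohort_n Individuals per generation; cohort locations are
#'   drawn uniformly in the plot each replicate (pass `cohort_xy`, a
#'   list of 2-column matrices, to use mapped stands instead).
#' @param cohort_xy Optional fixed cohort locations.
#' @param generations How many of the three generations to simulate.
#' @param source_density_ha Source-tree density for `"scattered"`
#'   (trees/ha over the plot plus a `margin`-wide belt).
#' @param margin Belt width (m) around the plot over which scattered
#'   sources are placed.
#' @param n_local Number of in-plot source trees added in `"mixed"`.
#' @param n_pools,pool_size,pool_offset,pool_radius Geometry of the
#'   distant source populations: `n_pools` clusters of `pool_size`
#'   unrelated trees, centred `pool_offset` metres beyond the plot edge,
#'   each spread over a disc of `pool_radius` metres.
#' @return A list of class `"sgs_scenario"`.
#' @export
sgs_scenario <- function(kind = c("distant", "scattered", "mixed"),
                         u_s_values = c(20, 100, 800, 3500, 7000),
                         u_p = 9000, replicates = 100,
                         poly = cbind(c(0, 250, 250, 0),
                                      c(0, 0, 300, 300)),
                         cohort_n = c(100, 100, 100),
                         cohort_xy = NULL, generations = 3,
                         source_density_ha = 1.5, margin = 100,
                         n_local = 3, n_pools = 4, pool_size = 25,
                         pool_offset = 250, pool_radius = 30) {
  kind <- match.arg(kind)
  sc <- as.list(environment())
  stopifnot(replicates >= 1, generations %in% 1:3,
            source_density_ha > 0, n_local >= 0)
  class(sc) <- "sgs_scenario"
  sc
}

## simulate founder source-tree locations for one replicate
simulate_sources <- function(sc) {
  p <- as_polygon(sc$poly)
  ctr <- colMeans(p)
  half_diag <- sqrt(sum((apply(p, 2, max) - ctr)^2))
  pools <- function() {
    ang <- pi / 4 + (seq_len(sc$n_pools) - 1) * 2 * pi / sc$n_pools
    do.call(rbind, lapply(ang, function(a) {
      c0 <- ctr + (half_diag + sc$pool_offset) * c(cos(a), sin(a))
      r <- sc$pool_radius * sqrt(runif(sc$pool_size))
      th <- runif(sc$pool_size, 0, 2 * pi)
      cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
    }))
  }
  scattered <- function(density_ha) {
    xr <- range(p[, 1]) + c(-1, 1) * sc$margin
    yr <- range(p[, 2]) + c(-1, 1) * sc$margin
    area_ha <- diff(xr) * diff(yr) / 1e4
    n <- max(rpois(1, density_ha * area_ha), 2)
    cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  }
  switch(sc$kind,
         distant = pools(),
         scattered = scattered(sc$source_density_ha),
         mixed = rbind(pools(),
                       if (sc$n_local > 0)
                         runif_in_polygon(sc$n_local, p)))
}

#' Kernel-weighted parent assignment for one cohort
#'
#' For each cohort location, draws a mother among the candidates with
#' probability proportional to the seed kernel at the candidate-to-tree
#' distance, then a father among the remaining candidates proportional
#' to the pollen kernel at the candidate-to-mother distance.
#'
#' @param candidates_xy 2-column matrix of candidate parent locations
#'   (>= 2 rows).
#' @param cohort_xy 2-column matrix of cohort tree locations.
#' @param u_s,u_p Seed and pollen dispersal parameters, m^2.
#' @return Integer matrix (`nrow(cohort_xy) x 2`) of candidate row
#'   indices (mother, father), with mother != father.
#' @export
assign_generation_parents <- function(candidates_xy, cohort_xy, u_s,
                                      u_p) {
  candidates_xy <- as.matrix(candidates_xy)
  cohort_xy <- as.matrix(cohort_xy)
  n_cand <- nrow(candidates_xy)
  if (n_cand < 2)
    stop("need >= 2 candidate parents (self-pollination is excluded)",
         call. = FALSE)
  d2_ct <- outer(candidates_xy[, 1], cohort_xy[, 1], "-")^2 +
    outer(candidates_xy[, 2], cohort_xy[, 2], "-")^2
  d2_cc <- outer(candidates_xy[, 1], candidates_xy[, 1], "-")^2 +
    outer(candidates_xy[, 2], candidates_xy[, 2], "-")^2
  Kp <- kern_r2(d2_cc, u_p)
  out <- matrix(0L, nrow(cohort_xy), 2,
                dimnames = list(NULL, c("mother", "father")))
  for (t in seq_len(nrow(cohort_xy))) {
    m <- sample.int(n_cand, 1, prob = kern_r2(d2_ct[, t], u_s))
    wf <- Kp[, m]
    wf[m] <- 0
    out[t, ] <- c(m, sample.int(n_cand, 1, prob = wf))
  }
  out
}

#' Additive relatedness from a pedigree
#'
#' Numerator-relationship recursion: founders are pairwise unrelated
#' with self-relatedness 1; for any individual `x` with parents `(m, f)`
#' and any older `y`, `r(x, y) = (r(m, y) + r(f, y)) / 2` and
#' `r(x, x) = 1 + r(m, f) / 2`. Full sibs of founder parents get 0.5,
#' half sibs 0.25, parent-offspring 0.5; values can exceed these when
#' parents are themselves related (up to 2 in the inbred limit).
#'
#' @param mother,father Integer vectors: for each individual, the row
#'   index of its parents, or `NA` for founders. Parents must precede
#'   offspring.
#' @return Symmetric relatedness matrix with diagonal >= 1.
#' @export
pedigree_relatedness <- function(mother, father) {
  n <- length(mother)
  stopifnot(length(father) == n)
  A <- matrix(0, n, n)
  diag(A) <- 1
  for (x in seq_len(n)) {
    m <- mother[x]; f <- father[x]
    if (is.na(m) != is.na(f))
      stop("individuals must have two parents or none", call. = FALSE)
    if (is.na(m)) next
    if (m >= x || f >= x)
      stop("parents must precede offspring (cycle?)", call. = FALSE)
    prev <- seq_len(x - 1)
    ax <- 0.5 * (A[m, prev] + A[f, prev])
    A[x, prev] <- ax
    A[prev, x] <- ax
    A[x, x] <- 1 + 0.5 * A[m, f]
  }
  A
}

#' Run an SGS scenario
#'
#' For each replicate: simulate founder sources, assign parents
#' generation by generation with the configured kernels, compute the
#' pedigree relatedness matrix, and average the coefficient of
#' relatedness over pairs within 10-m distance classes from 0 to 100 m.
#' Profiles are aggregated over replicates as mean, min and max of the
#' per-replicate class means.
#'
#' @param sc An [sgs_scenario()].
#' @return Data frame of class `"sgs_profile"`: `generation`, `u_s`,
#'   `class_lower`, `class_upper`, `mean_cr`, `min_cr`, `max_cr`,
#'   `n_replicates` (replicates contributing pairs to the class; classes
#'   empty in every replicate are reported as `NA`, not zero).
#' @export
run_scenario <- function(sc = sgs_scenario()) {
  edges <- seq(0, 100, by = 10)
  n_cl <- length(edges) - 1
  res <- list()
  for (us in sc$u_s_values) {
    acc <- array(NA_real_, c(sc$replicates, sc$generations, n_cl))
    for (rep_i in seq_len(sc$replicates)) {
      src <- simulate_sources(sc)
      cohorts <- if (is.null(sc$cohort_xy))
        lapply(seq_len(sc$generations),
               function(g) runif_in_polygon(sc$cohort_n[g], sc$poly))
      else sc$cohort_xy[seq_len(sc$generations)]
      mo <- fa <- rep(NA_integer_, nrow(src))
      all_xy <- src
      gen_of <- integer(0)
      for (g in seq_len(sc$generations)) {
        ped <- assign_generation_parents(all_xy, cohorts[[g]], us,
                                         sc$u_p)
        mo <- c(mo, ped[, 1]); fa <- c(fa, ped[, 2])
        gen_of <- c(gen_of, rep(g, nrow(cohorts[[g]])))
        all_xy <- rbind(all_xy, cohorts[[g]])
      }
      gen_of <- c(rep(0L, nrow(src)), gen_of)
      A <- pedigree_relatedness(mo, fa)
      for (g in seq_len(sc$generations)) {
        idx <- which(gen_of == g)
        xy <- all_xy[idx, , drop = FALSE]
        dm <- as.matrix(stats::dist(xy))
        iu <- which(upper.tri(dm), arr.ind = TRUE)
        dd <- dm[iu]
        rr <- A[idx, idx][iu]
        cl <- findInterval(dd, edges, left.open = TRUE,
                           rightmost.closed = FALSE)
        ok <- cl >= 1 & cl <= n_cl
        means <- tapply(rr[ok], factor(cl[ok], levels = seq_len(n_cl)),
                        mean)
        acc[rep_i, g, ] <- as.numeric(means)
      }
    }
    for (g in seq_len(sc$generations)) {
      m <- acc[, g, , drop = FALSE]
      res[[length(res) + 1]] <- data.frame(
        generation = g, u_s = us,
        class_lower = edges[-length(edges)], class_upper = edges[-1],
        mean_cr = apply(m, 3, mean, na.rm = TRUE),
        min_cr = apply(m, 3, function(v) if (all(is.na(v))) NA_real_
                       else min(v, na.rm = TRUE)),
        max_cr = apply(m, 3, function(v) if (all(is.na(v))) NA_real_
                       else max(v, na.rm = TRUE)),
        n_replicates = apply(m, 3, function(v) sum(!is.na(v))))
    }
  }
  out <- do.call(rbind, res)
  out$mean_cr[is.nan(out$mean_cr)] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("sgs_profile", "data.frame")
  out
}

#' Plot relatedness-by-distance profiles
#' @param x An `sgs_profile` from [run_scenario()].
#' @param generation Which generation to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sgs_profile <- function(x, generation = 1, ...) {
  d <- x[x$generation == generation, ]
  us <- sort(unique(d$u_s))
  mid <- (d$class_lower + d$class_upper) / 2
  M <- sapply(us, function(u) d$mean_cr[d$u_s == u])
  graphics::matplot(unique(mid), M, type = "b", pch = 16, lty = 1,
                    xlab = "distance class midpoint (m)",
                    ylab = "mean coefficient of relatedness", ...)
  graphics::legend("topright", legend = paste("u_s =", us), col =
                     seq_along(us), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
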