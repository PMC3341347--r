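## Independent brute-force oracles and small fixture builders shared by
## the unit tests. These deliberately avoid the package's vectorised
## code paths: probabilities are built by exhaustive enumeration of
## error pathways and genotype combinations, and the autocorrelation
## oracle follows the published distance table case by case.

## neighbours of an allele on the ladder (one motif step, inward at the
## boundary), with their mistype probabilities
oracle_mistype_dist <- function(a, e1, lad) {
  i <- match(a, lad)
  stopifnot(!is.na(i))
  if (length(lad) == 1) return(stats::setNames(1, as.character(a)))
  nb <- c(i - 1, i + 1)
  nb <- nb[nb >= 1 & nb <= length(lad)]
  p <- stats::setNames(c(1 - e1, rep(e1 / length(nb), length(nb))),
                       as.character(c(lad[i], lad[nb])))
  tapply(p, names(p), sum)
}

## full distribution over observable unordered genotypes given a true
## genotype, by exhaustive enumeration: dropout outcomes x independent
## per-allele mistyping
oracle_obs_dist <- function(true, e1, e2, lad) {
  a <- true[1]; b <- true[2]
  recorded <- if (a != b)
    list(list(p = 1 - e2, g = c(a, b)),
         list(p = e2 / 2, g = c(a, a)),
         list(p = e2 / 2, g = c(b, b)))
  else list(list(p = 1, g = c(a, a)))
  out <- new.env()
  add <- function(key, p) {
    cur <- if (is.null(out[[key]])) 0 else out[[key]]
    out[[key]] <- cur + p
  }
  for (rec in recorded) {
    d1 <- oracle_mistype_dist(rec$g[1], e1, lad)
    d2 <- oracle_mistype_dist(rec$g[2], e1, lad)
    for (x in names(d1)) for (y in names(d2)) {
      pair <- sort(as.numeric(c(x, y)))
      add(paste(pair, collapse = "/"), rec$p * d1[[x]] * d2[[y]])
    }
  }
  vals <- mget(ls(out), envir = out)
  stats::setNames(as.numeric(vals), names(vals))
}

oracle_obs_prob <- function(true, obs, e1, e2, lad) {
  d <- oracle_obs_dist(true, e1, e2, lad)
  key <- paste(sort(obs), collapse = "/")
  if (is.null(d[key]) || is.na(d[key])) 0 else unname(d[key])
}

## P(observed offspring genotype | parents) by exhaustive enumeration of
## transmitted alleles and error pathways at a single locus; a known
## parent's own observed genotype is integrated over its true genotype
## (Hardy-Weinberg prior x observation model), matching the model
oracle_offspring_prob <- function(gm, gf, gobs, e1, e2, freq, lad,
                                  mother_known = TRUE,
                                  father_known = TRUE) {
  trans <- function(g, known) {
    if (known) {
      v <- stats::setNames(numeric(length(lad)), as.character(lad))
      tot <- 0
      for (x in lad) for (y in lad) {
        fx <- freq[[as.character(x)]]; fy <- freq[[as.character(y)]]
        if (fx == 0 || fy == 0) next
        w <- fx * fy * oracle_obs_prob(c(x, y), g, e1, e2, lad)
        if (w == 0) next
        v[as.character(x)] <- v[as.character(x)] + w / 2
        v[as.character(y)] <- v[as.character(y)] + w / 2
        tot <- tot + w
      }
      if (tot == 0) {  # face-value fallback, as in the model
        p <- stats::setNames(c(0.5, 0.5), as.character(g))
        return(tapply(p, names(p), sum))
      }
      v <- v / tot
      v[v > 0]
    } else {
      freq[freq > 0]
    }
  }
  tm <- trans(gm, mother_known)
  tf <- trans(gf, father_known)
  tot <- 0
  for (x in names(tm)) for (y in names(tf)) {
    tot <- tot + tm[[x]] * tf[[y]] *
      oracle_obs_prob(as.numeric(c(x, y)), gobs, e1, e2, lad)
  }
  tot
}

## spatial autocorrelation r by direct summation, with the per-locus
## squared distance assigned case by case from the published table
oracle_r_profile <- function(gt, xy, class_edges) {
  n <- length(gt$ids)
  L <- nrow(gt$loci)
  locus_d2 <- function(g1, g2) {
    s1 <- sort(g1); s2 <- sort(g2)
    if (identical(s1, s2)) return(0)
    hom1 <- s1[1] == s1[2]; hom2 <- s2[1] == s2[2]
    shared <- length(intersect(s1, s2)) > 0
    if (hom1 && hom2) return(4)                 # AA vs BB
    if (hom1 != hom2) {                         # one homozygote
      hom <- if (hom1) s1 else s2
      het <- if (hom1) s2 else s1
      return(if (hom[1] %in% het) 1 else 3)     # AA-AB vs AA-BC
    }
    if (shared) 1 else 2                        # AB-AC vs AB-CD
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- 0
    for (l in seq_len(L))
      d <- d + locus_d2(c(gt$al1[i, l], gt$al2[i, l]),
                        c(gt$al1[j, l], gt$al2[j, l]))
    D[i, j] <- d
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- -0.5 * (D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D))
  H <- as.matrix(stats::dist(xy))
  r <- rep(NA_real_, length(class_edges) - 1)
  for (h in seq_along(r)) {
    num <- den <- 0
    np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (H[i, j] > class_edges[h] && H[i, j] <= class_edges[h + 1]) {
        num <- num + C[i, j]
        den <- den + (C[i, i] + C[j, j]) / 2
        np <- np + 1
      }
    }
    if (np >= 2) r[h] <- num / den
  }
  r
}

## tiny hand-buildable parentage dataset: a square plot with adults at
## chosen locations/genotypes and seedlings at chosen locations
toy_dataset <- function(adult_xy, adult_geno, seedling_xy,
                        seedling_geno, loci,
                        poly = cbind(c(0, 100, 100, 0),
                                     c(0, 0, 100, 100)),
                        fec = 100, e1 = 0, e2 = 0) {
  nA <- nrow(adult_xy); nS <- nrow(seedling_xy)
  ids_a <- sprintf("A%d", seq_len(nA))
  ids_s <- sprintf("S%d", seq_len(nS))
  L <- nrow(loci)
  gt <- genotype_table(
    c(ids_a, ids_s),
    rbind(adult_geno[, 2 * seq_len(L) - 1, drop = FALSE],
          seedling_geno[, 2 * seq_len(L) - 1, drop = FALSE]),
    rbind(adult_geno[, 2 * seq_len(L), drop = FALSE],
          seedling_geno[, 2 * seq_len(L), drop = FALSE]),
    loci, pop = c(rep("adult", nA), rep("seedling", nS)))
  adults <- data.frame(id = ids_a, x = adult_xy[, 1], y = adult_xy[, 2],
                       species = "sp", dbh = 30,
                       fec_mean = rep_len(fec, nA), fec_sd = 0)
  seedlings <- data.frame(id = ids_s, x = seedling_xy[, 1],
                          y = seedling_xy[, 2])
  parentage_data(adults, seedlings, gt, poly,
                 error_rates(loci$locus, rep_len(e1, L),
                             rep_len(e2, L)))
}
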