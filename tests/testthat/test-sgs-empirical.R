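test_that("codominant squared genetic distances follow the case table", {
  li <- loci_info("L1", 2, 100, 110)
  g <- function(a, b) list(a, b)
  cases <- list(                       # genotype pair -> d^2
    list(c(100, 100), c(100, 100), 0),
    list(c(100, 102), c(100, 102), 0),
    list(c(100, 100), c(100, 102), 1),
    list(c(100, 102), c(100, 104), 1),
    list(c(100, 102), c(104, 106), 2),
    list(c(100, 100), c(102, 104), 3),
    list(c(100, 100), c(102, 102), 4))
  for (cs in cases) {
    gt <- genotype_table(c("a", "b"),
                         rbind(cs[[1]][1], cs[[2]][1]),
                         rbind(cs[[1]][2], cs[[2]][2]), li)
    D <- genetic_distance_squared(gt)
    expect_equal(D[1, 2], cs[[3]])
    expect_equal(D[2, 1], cs[[3]])
    expect_equal(diag(D), c(a = 0, b = 0))
  }
})

test_that("autocorrelation r matches the direct-summation oracle", {
  ## 5 individuals x 2 loci, fixed genotypes and coordinates
  li <- loci_info(c("L1", "L2"), 2, 100, 110)
  gt <- genotype_table(
    sprintf("i%d", 1:5),
    al1 = cbind(c(100, 100, 102, 104, 100), c(100, 102, 102, 106, 108)),
    al2 = cbind(c(102, 100, 104, 106, 102), c(104, 104, 102, 108, 110)),
    loci = li)
  xy <- cbind(c(0, 3, 8, 25, 40), c(0, 4, 0, 5, 0))
  edges <- c(0, 10, 30, 50)
  res <- autocorrelation_r(gt, xy, class_edges = edges, n_boot = 0,
                           n_perm = 0)
  r_oracle <- oracle_r_profile(gt, xy, edges)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  ## invariance to locus order and to rigid motion of the coordinates
  gt_swap <- genotype_table(gt$ids, gt$al1[, 2:1], gt$al2[, 2:1],
                            loci_info(c("L2", "L1"), 2, 100, 110))
  res_swap <- autocorrelation_r(gt_swap, xy, class_edges = edges,
                                n_boot = 0, n_perm = 0)
  expect_equal(res_swap$r, res$r, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  res_rot <- autocorrelation_r(gt, xy %*% R + 100, class_edges = edges,
                               n_boot = 0, n_perm = 0)
  expect_equal(res_rot$r, res$r, tolerance = 1e-12)
})

test_that("random coordinates stay inside the permutation envelope", {
  set.seed(61)
  cfg <- sim_config(n_loci = 4, alleles_per_locus = 10, n_seedlings = 1,
                    poly = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                    density_ha = 60)
  st <- simulate_stand(cfg)
  gt <- st$genotypes
  xy <- cbind(st$adults$x, st$adults$y)
  res <- autocorrelation_r(gt, xy, n_boot = 99, n_perm = 499)
  ok <- !is.na(res$r)
  expect_gt(sum(ok), 5)
  ## genotypes are spatially random by construction: observed r within
  ## the null envelope in (essentially) every class
  inside <- res$r[ok] >= res$perm_lower[ok] &
    res$r[ok] <= res$perm_upper[ok]
  expect_gte(mean(inside), 0.8)
  ## and centred: null envelopes bracket zero
  expect_true(all(res$perm_lower[ok] < 0 & res$perm_upper[ok] > 0))
})

test_that("full-sib clusters produce significant short-range structure", {
  ## positive control: families planted in tight clusters
  set.seed(62)
  li <- loci_info(sprintf("L%d", 1:4), 2, 100, 130)
  freqs <- structure(lapply(1:4, function(j) {
    lad <- seq(100, 130, 2)
    p <- rgamma(length(lad), 0.5); setNames(p / sum(p),
                                            as.character(lad))
  }), class = "allele_freqs", names = sprintf("L%d", 1:4))
  n_fam <- 12; fam_size <- 5
  hw_draw <- function() sapply(1:4, function(j)
    sample(seq(100, 130, 2), 2, TRUE, prob = freqs[[j]]))
  a1 <- a2 <- matrix(NA_integer_, n_fam * fam_size, 4)
  xy <- matrix(NA_real_, n_fam * fam_size, 2)
  row <- 0
  for (f in seq_len(n_fam)) {
    mum <- hw_draw(); dad <- hw_draw()
    ctr <- runif(2, 20, 180)
    for (s in seq_len(fam_size)) {
      row <- row + 1
      pickm <- mum[cbind(sample(1:2, 4, TRUE), 1:4)]
      pickf <- dad[cbind(sample(1:2, 4, TRUE), 1:4)]
      a1[row, ] <- pickm; a2[row, ] <- pickf
      xy[row, ] <- ctr + rnorm(2, 0, 2)   # sibs within a few metres
    }
  }
  gt <- genotype_table(sprintf("s%d", seq_len(row)), a1, a2, li)
  res <- autocorrelation_r(gt, xy, n_boot = 99, n_perm = 499)
  ## 0-10 m class: strongly positive and outside the null envelope
  expect_gt(res$r[1], 0.2)
  expect_gt(res$r[1], res$perm_upper[1])
})

test_that("cohort partition splits at the median with ties small", {
  ad <- data.frame(id = c("a", "b", "c"), dbh = c(10, 33, 50))
  p <- partition_cohorts(ad, data.frame(id = "s1"))
  expect_equal(p$large, "c")
  expect_equal(sort(p$small), c("a", "b"))
  expect_equal(p$median_dbh, 33)
  expect_equal(p$seedlings, "s1")
  ## even n of distinct values -> equal cohorts
  ad2 <- data.frame(id = letters[1:4], dbh = c(10, 20, 30, 40))
  p2 <- partition_cohorts(ad2)
  expect_equal(length(p2$large), 2)
  expect_equal(length(p2$small), 2)
  ## a supplied split point is honoured
  p3 <- partition_cohorts(ad2, median_dbh = 33)
  expect_equal(p3$large, c("d"))
  expect_warning(partition_cohorts(
    data.frame(id = 1:2, dbh = c(NA, 5))), "missing DBH")
})
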