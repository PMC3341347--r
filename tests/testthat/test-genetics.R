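li2 <- loci_info(c("La", "Lb"), motif = 2, min_size = 100,
                 max_size = 110)

test_that("genotype tables normalise pairs and police the ladder", {
  gt <- genotype_table(c("i1", "i2"),
                       al1 = cbind(c(104, 102), c(100, 0)),
                       al2 = cbind(c(100, 102), c(110, 106)),
                       loci = li2)
  ## unordered pair stored sorted
  expect_equal(unname(gt$al1[1, 1]), 100)
  expect_equal(unname(gt$al2[1, 1]), 104)
  ## 0 is missing, and a half-call becomes locus-missing
  expect_true(is.na(gt$al1[2, 2]) && is.na(gt$al2[2, 2]))
  expect_error(genotype_table("x", cbind(103, 100), cbind(104, 102), li2),
               "ladder")
  expect_error(genotype_table(c("a", "a"), cbind(c(100, 100)),
                              cbind(c(100, 100)),
                              loci_info("L", 2, 100, 104)),
               "duplicate")
})

test_that("allele frequencies count alleles and sum to one", {
  li <- loci_info("L1", 2, 100, 104)
  gt <- genotype_table(c("i1", "i2"), cbind(c(100, 100)),
                       cbind(c(102, 100)), li)
  fr <- allele_frequencies(gt)
  expect_equal(unname(fr$L1[c("100", "102")]), c(0.75, 0.25))
  expect_equal(sum(fr$L1), 1)
  gt2 <- genotype_table("i1", cbind(NA), cbind(NA), li)
  expect_error(allele_frequencies(gt2), "no non-missing")
})

test_that("GenAlEx round trip is exact", {
  set.seed(5)
  cfg <- sim_config(n_seedlings = 1)
  st <- simulate_stand(cfg)
  gt <- st$genotypes
  gt$al1[3, 2] <- NA; gt$al2[3, 2] <- NA  # include missingness
  f <- tempfile(fileext = ".csv")
  write_genalex(gt, f)
  gt2 <- read_genalex(f, gt$loci)
  expect_identical(gt$al1, gt2$al1)
  expect_identical(gt$al2, gt2$al2)
  expect_identical(gt$ids, gt2$ids)
  expect_identical(gt$pop, gt2$pop)
  unlink(f)
})

test_that("observation model matches exhaustive pathway enumeration", {
  lad <- seq(100, 110, 2)
  ## identity at zero error
  expect_equal(observation_model(c(100, 102), c(100, 102), 0, 0, lad), 1)
  expect_equal(observation_model(c(100, 102), c(100, 100), 0, 0, lad), 0)
  ## pure dropout: AB observed as AA with probability e2/2
  expect_equal(observation_model(c(100, 102), c(100, 100), 0, 0.1, lad),
               0.05)
  ## against the enumeration oracle across rate combinations and
  ## genotype shapes (het, hom, boundary alleles)
  genos <- list(c(100, 102), c(104, 104), c(100, 110), c(108, 110))
  for (e1 in c(0.02, 0.18)) for (e2 in c(0.02, 0.08)) {
    for (g in genos) {
      dist <- oracle_obs_dist(g, e1, e2, lad)
      expect_equal(sum(dist), 1, tolerance = 1e-12)
      for (key in names(dist)) {
        obs <- as.numeric(strsplit(key, "/")[[1]])
        expect_equal(observation_model(g, obs, e1, e2, lad),
                     unname(dist[key]), tolerance = 1e-12)
      }
    }
  }
  expect_error(observation_model(c(99, 100), c(100, 100), 0, 0, lad),
               "ladder")
})

test_that("observation model conserves probability over observables", {
  lad <- seq(120, 148, 4)
  set.seed(8)
  pairs <- replicate(10, sort(sample(lad, 2, replace = TRUE)))
  all_obs <- expand.grid(a = lad, b = lad)
  all_obs <- all_obs[all_obs$a <= all_obs$b, ]
  for (i in seq_len(ncol(pairs))) {
    tot <- sum(apply(all_obs, 1, function(o)
      observation_model(pairs[, i], as.numeric(o), 0.12, 0.06, lad)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("offspring genotype probability: Mendelian limits and oracle", {
  li <- loci_info("L1", 2, 100, 108)
  lad <- ladder(li, 1)
  fr <- structure(list(L1 = setNames(c(0.5, 0.25, 0.25, 0, 0),
                                     as.character(lad))),
                  class = "allele_freqs")
  er0 <- error_rates("L1", 0, 0)
  g <- function(a, b) matrix(c(a, b), 1)
  ## Mendelian exacts at zero error
  expect_equal(offspring_genotype_prob(g(100, 100), g(100, 100),
                                       g(100, 100), er0, fr, li), 1)
  expect_equal(offspring_genotype_prob(g(100, 102), g(100, 102),
                                       g(100, 100), er0, fr, li), 0.25)
  expect_equal(offspring_genotype_prob(g(100, 102), g(100, 102),
                                       g(100, 102), er0, fr, li), 0.5)
  ## exclusion: allele absent from both known parents
  expect_equal(offspring_genotype_prob(g(100, 100), g(100, 102),
                                       g(104, 104), er0, fr, li), 0)
  ## unknown father transmits from the population: AA mother always
  ## gives 100, the 102 must come from the population (freq 0.25)
  expect_equal(offspring_genotype_prob(g(100, 100), g(100, 100),
                                       g(100, 102), er0, fr, li,
                                       father_known = FALSE),
               0.25)
  ## degenerate frequencies make the unknown parent deterministic
  fr1 <- structure(list(L1 = setNames(c(1, 0, 0, 0, 0),
                                      as.character(lad))),
                   class = "allele_freqs")
  expect_equal(offspring_genotype_prob(g(100, 100), g(100, 100),
                                       g(100, 100), er0, fr1, li,
                                       father_known = FALSE), 1)
  ## nonzero error: equals the exhaustive oracle for every parent-
  ## knowledge case
  er <- error_rates("L1", 0.1, 0.06)
  cases <- expand.grid(mk = c(TRUE, FALSE), fk = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    p_pkg <- offspring_genotype_prob(g(100, 102), g(102, 104),
                                     g(100, 104), er, fr, li,
                                     mother_known = cases$mk[i],
                                     father_known = cases$fk[i])
    p_orc <- oracle_offspring_prob(c(100, 102), c(102, 104),
                                   c(100, 104), 0.1, 0.06, fr$L1, lad,
                                   cases$mk[i], cases$fk[i])
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
  ## incompatible known pair: zero at e = 0, strictly increasing in
  ## each error rate
  p00 <- offspring_genotype_prob(g(100, 100), g(100, 100), g(102, 104),
                                 er0, fr, li)
  p10 <- offspring_genotype_prob(g(100, 100), g(100, 100), g(102, 104),
                                 error_rates("L1", 0.1, 0), fr, li)
  p11 <- offspring_genotype_prob(g(100, 100), g(100, 100), g(102, 104),
                                 error_rates("L1", 0.1, 0.05), fr, li)
  expect_equal(p00, 0)
  expect_gt(p10, 0)
  ## all-missing offspring: probability 1 with a warning
  expect_warning(
    p <- offspring_genotype_prob(g(100, 100), g(100, 100), g(NA, NA),
                                 er0, fr, li),
    "missing")
  expect_equal(p, 1)
})

test_that("genotype corruption matches the observation model in law", {
  li <- loci_info("L1", 2, 100, 106)
  lad <- ladder(li, 1)
  n <- 2e4
  gt <- genotype_table(sprintf("i%d", 1:n),
                       matrix(100, n, 1), matrix(102, n, 1), li)
  er <- error_rates("L1", 0.15, 0.3)
  set.seed(21)
  obs <- apply_genotyping_error(gt, er)
  emp <- table(paste(obs$al1[, 1], obs$al2[, 1], sep = "/")) / n
  theo <- oracle_obs_dist(c(100, 102), 0.15, 0.3, lad)
  for (key in names(theo)) {
    if (theo[key] < 1e-4) next
    se <- sqrt(theo[key] * (1 - theo[key]) / n)
    emp_p <- if (key %in% names(emp)) emp[[key]] else 0
    expect_lt(abs(emp_p - theo[key]), 4 * se + 1e-9)
  }
  ## limits: identity at zero error, all-homozygous at e2 = 1 is not
  ## representable (rates < 1), but e = 0 must be exact
  obs0 <- apply_genotyping_error(gt, error_rates("L1", 0, 0))
  expect_identical(obs0$al1, gt$al1)
  expect_identical(obs0$al2, gt$al2)
})

test_that("error-rate estimation recovers known rates from repeats", {
  li <- loci_info("L1", 2, 100, 130)
  ## counting definition: 1 dropout among 10 repeated heterozygotes
  ref <- genotype_table(sprintf("h%d", 1:10), matrix(100, 10, 1),
                        matrix(104, 10, 1), li)
  ret_a1 <- matrix(100, 10, 1); ret_a2 <- matrix(104, 10, 1)
  ret_a2[1, 1] <- 100  # one heterozygote came back homozygous
  ret <- genotype_table(sprintf("h%d", 1:10), ret_a1, ret_a2, li)
  est <- estimate_error_rates(ref, ret)
  expect_equal(est$e2, 0.1)
  expect_equal(est$e1, 0)
  ## concordant repeats give zero rates
  est0 <- estimate_error_rates(ref, ref)
  expect_equal(est0$e1, 0)
  expect_equal(est0$e2, 0)
  ## recovery on simulated corruption at n = 500
  set.seed(31)
  cfg <- sim_config(n_loci = 1, alleles_per_locus = 16)
  freqs <- seedshadow:::sim_allele_freqs(cfg)
  li16 <- seedshadow:::sim_loci(cfg)
  truth <- seedshadow:::sim_hwe_genotypes(500, freqs, li16,
                                          sprintf("r%d", 1:500))
  er <- error_rates(li16$locus, 0.10, 0.05)
  obs <- apply_genotyping_error(truth, er)
  est <- estimate_error_rates(truth, obs)
  expect_lt(abs(est$e1 - 0.10), 0.03)
  expect_lt(abs(est$e2 - 0.05), 0.03)
})
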