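#' Per-locus genotyping error rates
#'
#' Two error channels are modelled. *Allelic dropout* (`e2`): one allele of
#' a heterozygote fails to amplify, so the genotype is recorded as a
#' homozygote for one of its two alleles (equal split). *Mistyping*
#' (`e1`): stutter during amplification records an allele as one of
#' adjacent fragment length; each recorded allele independently moves one
#' motif step up or down the ladder (equal split; at a ladder boundary the
#' whole mistype mass moves inward). The channels compose dropout first,
#' then mistyping on the recorded alleles.
#'
#' @param locus Character vector of locus names.
#' @param e1 Mistyping probability per recorded allele, in `[0, 1)`.
#' @param e2 Allelic dropout probability per heterozygous call, `[0, 1)`.
#' @return Data frame of class `"error_rates"`.
#' @export
error_rates <- function(locus, e1, e2) {
  er <- data.frame(locus = as.character(locus), e1 = as.numeric(e1),
                   e2 = as.numeric(e2), stringsAsFactors = FALSE)
  if (any(er$e1 < 0 | er$e1 >= 1 | er$e2 < 0 | er$e2 >= 1))
    stop("error rates must lie in [0, 1)", call. = FALSE)
  class(er) <- c("error_rates", "data.frame")
  er
}

## mistype transition matrix over a ladder: M[a, x] = P(record x | true a)
mistype_matrix <- function(lad, e1) {
  U <- length(lad)
  M <- diag(1 - e1, U)
  if (U == 1) return(matrix(1, 1, 1, dimnames = list(lad, lad)))
  for (a in seq_len(U)) {
    nb <- c(a - 1, a + 1)
    nb <- nb[nb >= 1 & nb <= U]
    M[a, nb] <- e1 / length(nb)
  }
  dimnames(M) <- list(lad, lad)
  M
}

## P(observed unordered pair | recorded ordered pair (a,b)), columns of M
pair_obs_prob <- function(M, ia, ib, ix, iy) {
  if (ix == iy) M[ia, ix] * M[ib, ix]
  else M[ia, ix] * M[ib, iy] + M[ia, iy] * M[ib, ix]
}

#' Probability of an observed genotype given the true genotype
#'
#' Evaluates the two-channel observation model `P(observed | true)` at one
#' locus: dropout (heterozygote recorded as one of its homozygotes with
#' probability `e2`, equal split) followed by independent per-allele
#' adjacent-size mistyping at rate `e1`. Probabilities over all
#' observable genotypes sum to 1 for any true genotype.
#'
#' @param true,observed Length-2 numeric vectors of allele sizes (bp);
#'   order within the pair is irrelevant.
#' @param e1,e2 Mistyping and dropout rates for this locus.
#' @param lad Integer vector: the locus allele-size ladder (see
#'   [ladder()]).
#' @return A single probability.
#' @examples
#' lad <- seq(100, 120, 2)
#' observation_model(c(100, 102), c(100, 100), e1 = 0, e2 = 0.1, lad = lad)
#' # 0.05: dropout of the 102 allele
#' @export
observation_model <- function(true, observed, e1, e2, lad) {
  stopifnot(length(true) == 2, length(observed) == 2)
  idx <- match(c(true, observed), lad)
  if (anyNA(idx))
    stop("allele outside the locus's size ladder", call. = FALSE)
  M <- mistype_matrix(lad, e1)
  ia <- idx[1]; ib <- idx[2]; ix <- idx[3]; iy <- idx[4]
  p_mis <- function(ja, jb) pair_obs_prob(M, ja, jb, ix, iy)
  if (ia == ib) p_mis(ia, ib)
  else (1 - e2) * p_mis(ia, ib) +
    (e2 / 2) * p_mis(ia, ia) + (e2 / 2) * p_mis(ib, ib)
}

## Q[a, b] = P(observed pair | true genotype {lad[a], lad[b]}) for one
## observed call; the workhorse for the vectorised pedigree likelihood.
## obs = length-2 indices into the ladder, or NULL for a missing call
## (Q = 1, no information).
genotype_obs_matrix <- function(obs_idx, M, e2) {
  U <- nrow(M)
  if (is.null(obs_idx)) return(matrix(1, U, U))
  ix <- obs_idx[1]; iy <- obs_idx[2]
  Mx <- M[, ix]; My <- M[, iy]
  P <- if (ix == iy) outer(Mx, Mx) else outer(Mx, My) + outer(My, Mx)
  d <- diag(P)
  Q <- (1 - e2) * P + (e2 / 2) * (outer(d, rep(1, U)) +
                                  outer(rep(1, U), d))
  diag(Q) <- d
  Q
}

## transmission vector over the ladder for a parent at one locus: the
## distribution of the allele a parent passes on, integrating over the
## parent's *true* genotype given its observed one (posterior
## proportional to Hardy-Weinberg prior x observation model). At zero
## error this is 1/2 at each observed allele. A parent with a missing
## call, or an unmapped parent, transmits from the population allele
## frequencies.
transmission_vector <- function(geno_idx, freq, M = NULL, e2 = 0) {
  if (is.null(geno_idx)) return(freq)
  if (is.null(M)) {  # take the observed genotype at face value
    v <- numeric(length(freq))
    v[geno_idx[1]] <- v[geno_idx[1]] + 0.5
    v[geno_idx[2]] <- v[geno_idx[2]] + 0.5
    return(v)
  }
  Q <- genotype_obs_matrix(geno_idx, M, e2)  # P(observed | true pair)
  post <- outer(freq, freq) * Q              # ordered true pairs
  tot <- sum(post)
  if (tot <= 0) {
    ## observed alleles absent from the population table: fall back to
    ## face value rather than returning an undefined distribution
    return(transmission_vector(geno_idx, freq))
  }
  rowSums(post) / tot
}

#' Probability of an offspring genotype given two (possibly unknown)
#' parents
#'
#' The pedigree-likelihood kernel of the parentage model: for each locus,
#' sums Mendelian transmission over all true offspring genotypes and
#' passes each through the genotyping-error observation model, then takes
#' the product over loci (loci are treated as independent). A parent
#' flagged unknown (out-of-plot, hence ungenotyped) transmits an allele
#' drawn from the population allele frequencies; with both parents
#' unknown this reduces to the Hardy-Weinberg genotype probability
#' convolved with error.
#'
#' @param mother,father `L x 2` matrices of allele sizes (rows = loci,
#'   `NA` = missing call). Ignored for a parent whose `*_known` flag is
#'   `FALSE`.
#' @param offspring `L x 2` matrix of *observed* offspring allele sizes.
#' @param err An [error_rates()] table matching `loci`.
#' @param freqs An [allele_frequencies()] object.
#' @param loci A [loci_info()] object.
#' @param mother_known,father_known Logical: is the parent a mapped,
#'   genotyped tree?
#' @param parent_error Integrate over genotyping error in the *parents'*
#'   observed genotypes as well (posterior over each parent's true
#'   genotype under a Hardy-Weinberg prior), the default. `FALSE` takes
#'   parental genotypes at face value.
#' @return A single probability. Loci with a missing offspring call are
#'   skipped; if every locus is missing the probability is 1 (no
#'   information) with a warning.
#' @examples
#' li <- loci_info("L1", 2, 100, 104)
#' fr <- structure(list(L1 = c(`100` = 0.5, `102` = 0.25, `104` = 0.25)),
#'                 class = "allele_freqs")
#' er <- error_rates("L1", 0, 0)
#' m <- matrix(c(100, 102), 1)
#' offspring_genotype_prob(m, m, matrix(c(100, 100), 1), er, fr, li)
#' # 0.25: Mendelian AA from AB x AB
#' @export
offspring_genotype_prob <- function(mother, father, offspring, err, freqs,
                                    loci, mother_known = TRUE,
                                    father_known = TRUE,
                                    parent_error = TRUE) {
  L <- nrow(loci)
  stopifnot(nrow(offspring) == L)
  prob <- 1
  any_info <- FALSE
  for (j in seq_len(L)) {
    o <- offspring[j, ]
    if (anyNA(o)) next
    any_info <- TRUE
    lad <- ladder(loci, j)
    oi <- match(o, lad)
    if (anyNA(oi))
      stop("offspring allele outside the locus's size ladder",
           call. = FALSE)
    M <- mistype_matrix(lad, err$e1[j])
    Q <- genotype_obs_matrix(oi, M, err$e2[j])
    gm <- if (mother_known && !anyNA(mother[j, ]))
      match(mother[j, ], lad) else NULL
    gf <- if (father_known && !anyNA(father[j, ]))
      match(father[j, ], lad) else NULL
    if ((!is.null(gm) && anyNA(gm)) || (!is.null(gf) && anyNA(gf)))
      stop("parent allele outside the locus's size ladder", call. = FALSE)
    Mp <- if (parent_error) M
    tm <- transmission_vector(gm, freqs[[j]], Mp, err$e2[j])
    tf <- transmission_vector(gf, freqs[[j]], Mp, err$e2[j])
    prob <- prob * as.numeric(tm %*% Q %*% tf)
  }
  if (!any_info) {
    warning("all loci missing for offspring; probability set to 1")
  }
  prob
}

#' Estimate per-locus error rates from repeat genotyping
#'
#' Compares a reference genotyping run against an independent re-typing
#' run of the same individuals. Dropout `e2` is the fraction of
#' reference-heterozygous comparisons recorded in the repeat as a
#' homozygote for one of the reference alleles; mistyping `e1` is the
#' fraction of allele comparisons differing by exactly one motif step.
#' Estimates are clipped to `[0, 0.5)`.
#'
#' @param reference,retyped Two [genotype_table()]s over the same loci;
#'   individuals are matched by id (ids present in both are used).
#' @param default Rate assigned to a locus with no usable comparisons
#'   (flagged by a warning).
#' @return An [error_rates()] table.
#' @export
estimate_error_rates <- function(reference, retyped, default = 0.05) {
  common <- intersect(reference$ids, retyped$ids)
  if (length(common) == 0)
    stop("no shared individuals between runs", call. = FALSE)
  a <- reference[common]; b <- retyped[common]
  L <- nrow(a$loci)
  e1 <- e2 <- numeric(L)
  for (j in seq_len(L)) {
    motif <- a$loci$motif[j]
    ok <- !is.na(a$al1[, j]) & !is.na(b$al1[, j])
    if (!any(ok)) {
      warning(sprintf("locus %s: no repeat comparisons; default rate used",
                      a$loci$locus[j]))
      e1[j] <- default; e2[j] <- default
      next
    }
    r1 <- a$al1[ok, j]; r2 <- a$al2[ok, j]
    t1 <- b$al1[ok, j]; t2 <- b$al2[ok, j]
    het <- r1 != r2
    drop_disc <- het & t1 == t2 & (t1 == r1 | t1 == r2)
    e2[j] <- if (any(het)) sum(drop_disc) / sum(het) else 0
    ## allele-wise comparison on sorted pairs, dropout discordances
    ## excluded so the two channels are not conflated
    use <- !drop_disc
    adj <- (abs(r1[use] - t1[use]) == motif) +
           (abs(r2[use] - t2[use]) == motif)
    e1[j] <- sum(adj) / (2 * sum(use))
  }
  error_rates(a$loci$locus, pmin(pmax(e1, 0), 0.499),
              pmin(pmax(e2, 0), 0.499))
}

#' Corrupt true genotypes through the observation model
#'
#' Forward-simulates the same dropout-then-mistyping channels the
#' likelihood assumes, producing an "observed" genotype table from a true
#' one. Sampling is exact with respect to [observation_model()].
#'
#' @param gt A [genotype_table()] of true genotypes.
#' @param err An [error_rates()] table matching `gt$loci`.
#' @return A [genotype_table()] of corrupted calls.
#' @export
apply_genotyping_error <- function(gt, err) {
  stopifnot(nrow(err) == nrow(gt$loci))
  n <- length(gt$ids)
  a1 <- gt$al1; a2 <- gt$al2
  for (j in seq_len(nrow(gt$loci))) {
    lad <- ladder(gt$loci, j)
    U <- length(lad)
    i1 <- match(a1[, j], lad); i2 <- match(a2[, j], lad)
    ok <- which(!is.na(i1))
    if (length(ok) == 0) next
    ## dropout
    het <- ok[i1[ok] != i2[ok]]
    dropped <- het[runif(length(het)) < err$e2[j]]
    keep_first <- runif(length(dropped)) < 0.5
    i2[dropped[keep_first]] <- i1[dropped[keep_first]]
    i1[dropped[!keep_first]] <- i2[dropped[!keep_first]]
    ## mistyping, per recorded allele (no neighbour exists when U == 1)
    if (U > 1) for (mat in 1:2) {
      ii <- if (mat == 1) i1 else i2
      hit <- ok[runif(length(ok)) < err$e1[j]]
      if (length(hit)) {
        up <- runif(length(hit)) < 0.5
        shift <- ifelse(up, 1L, -1L)
        ## boundary: all mistype mass moves inward
        shift[ii[hit] == 1L] <- 1L
        shift[ii[hit] == U] <- -1L
        ii[hit] <- ii[hit] + shift
      }
      if (mat == 1) i1 <- ii else i2 <- ii
    }
    a1[, j] <- lad[i1]; a2[, j] <- lad[i2]
  }
  genotype_table(gt$ids, a1, a2, gt$loci, pop = gt$pop)
}
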