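#' Squared codominant genotypic distance matrix
#'
#' The multiallelic squared genetic distance between diploid genotypes
#' used by the spatial autocorrelation analysis: writing each single-
#' locus genotype as its allele-count vector `y` (entries summing to 2),
#' the per-locus squared distance is `||y_i - y_j||^2 / 2` — 0 between
#' identical genotypes, 1 between `AA`/`AB` or `AB`/`AC`, 2 between
#' `AB`/`CD`, 3 between `AA`/`BC`, 4 between `AA`/`BB` — summed over
#' loci.
#'
#' @param gt A [genotype_table()] with complete genotypes (individuals
#'   with any missing call are rejected; filter first).
#' @return Symmetric `n x n` matrix of squared distances.
#' @export
genetic_distance_squared <- function(gt) {
  if (anyNA(gt$al1))
    stop("genetic_distance_squared requires complete genotypes; ",
         "drop individuals with missing calls first", call. = FALSE)
  n <- length(gt$ids)
  D <- matrix(0, n, n)
  for (j in seq_len(nrow(gt$loci))) {
    lad <- ladder(gt$loci, j)
    Y <- matrix(0, n, length(lad))
    i1 <- cbind(seq_len(n), match(gt$al1[, j], lad))
    i2 <- cbind(seq_len(n), match(gt$al2[, j], lad))
    Y[i1] <- Y[i1] + 1
    Y[i2] <- Y[i2] + 1
    sq <- rowSums(Y^2)
    D <- D + 0.5 * (outer(sq, sq, "+") - 2 * tcrossprod(Y))
  }
  dimnames(D) <- list(gt$ids, gt$ids)
  pmax(D, 0)
}

## Gower-centred covariance matrix from a squared-distance matrix
gower_center <- function(D) {
  rm <- rowMeans(D)
  -0.5 * (D - outer(rm, rm, "+") + mean(D))
}

#' Multilocus spatial genetic autocorrelation by distance class
#'
#' Computes the genetic correlation coefficient `r` of the multiallelic
#' codominant autocorrelation analysis: squared genotypic distances are
#' summed over loci, converted to a covariance matrix by Gower
#' centering, and for each geographic distance class
#' \deqn{r(h) = \frac{\sum_{i<j \in h} c_{ij}}
#'                   {\sum_{i<j \in h} (c_{ii}+c_{jj})/2}.}
#' Uncertainty is quantified two ways: a bootstrap over the pairs within
#' each class gives a confidence interval for `r`, and random
#' permutation of genotypes across locations gives a null envelope
#' around `r = 0` for significance.
#'
#' @param gt A [genotype_table()] (complete genotypes).
#' @param xy `n x 2` coordinate matrix, metres.
#' @param class_edges Distance class breaks in metres (default 10-m
#'   classes, 0-100 m). A pair at distance `d` falls in class
#'   `(lower, upper]`; pairs beyond the last edge are ignored.
#' @param n_boot Bootstrap resamples per class (0 to skip).
#' @param n_perm Permutations for the null envelope (0 to skip).
#' @param conf Confidence level for both interval types.
#' @return Data frame: `class_lower`, `class_upper`, `n_pairs`, `r`,
#'   `boot_lower`, `boot_upper`, `perm_lower`, `perm_upper`. Classes
#'   with fewer than 2 pairs get `NA` estimates.
#' @export
autocorrelation_r <- function(gt, xy, class_edges = seq(0, 100, 10),
                              n_boot = 999, n_perm = 999, conf = 0.95) {
  xy <- as.matrix(xy)
  n <- length(gt$ids)
  stopifnot(nrow(xy) == n, n >= 3)
  C <- gower_center(genetic_distance_squared(gt))
  H <- as.matrix(stats::dist(xy))
  iu <- which(upper.tri(H), arr.ind = TRUE)
  cl <- findInterval(H[upper.tri(H)], class_edges, left.open = TRUE)
  n_cl <- length(class_edges) - 1
  alpha <- (1 - conf) / 2
  dC <- diag(C)
  r_of <- function(ii, jj) sum(C[cbind(ii, jj)]) /
    sum((dC[ii] + dC[jj]) / 2)
  out <- data.frame(class_lower = class_edges[-length(class_edges)],
                    class_upper = class_edges[-1],
                    n_pairs = NA_integer_, r = NA_real_,
                    boot_lower = NA_real_, boot_upper = NA_real_,
                    perm_lower = NA_real_, perm_upper = NA_real_)
  for (h in seq_len(n_cl)) {
    sel <- which(cl == h)
    out$n_pairs[h] <- length(sel)
    if (length(sel) < 2) next
    ii <- iu[sel, 1]; jj <- iu[sel, 2]
    out$r[h] <- r_of(ii, jj)
    if (n_boot > 0) {
      bs <- replicate(n_boot, {
        s <- sample.int(length(ii), replace = TRUE)
        r_of(ii[s], jj[s])
      })
      qb <- quantile(bs, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
      out$boot_lower[h] <- qb[1]; out$boot_upper[h] <- qb[2]
    }
    if (n_perm > 0) {
      ps <- replicate(n_perm, {
        pm <- sample.int(n)
        r_of(pm[ii], pm[jj])
      })
      qp <- quantile(ps, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
      out$perm_lower[h] <- qp[1]; out$perm_upper[h] <- qp[2]
    }
  }
  class(out) <- c("sgs_autocorr", "data.frame")
  out
}

#' Split adults into large and small cohorts at the median DBH
#'
#' Size is used as a proxy for age: adults with DBH above the median
#' form the "large" (older) cohort, those at or below it the "small"
#' cohort (ties go to the small cohort); seedlings form the third
#' cohort. Individuals with missing DBH are excluded with a warning.
#'
#' @param adults Data frame with `id` and `dbh` (cm) columns.
#' @param seedlings Data frame with an `id` column (may be empty).
#' @param median_dbh Split point; defaults to the median of the supplied
#'   DBHs (site-specific published values can be passed directly).
#' @return List of class `"cohort_partition"`: `large`, `small`,
#'   `seedlings` (id vectors) and `median_dbh`.
#' @export
partition_cohorts <- function(adults, seedlings = NULL,
                              median_dbh = NULL) {
  stopifnot(all(c("id", "dbh") %in% names(adults)))
  miss <- is.na(adults$dbh)
  if (any(miss)) {
    warning("excluding ", sum(miss), " adult(s) with missing DBH")
    adults <- adults[!miss, , drop = FALSE]
  }
  if (is.null(median_dbh)) median_dbh <- median(adults$dbh)
  structure(list(
    large = adults$id[adults$dbh > median_dbh],
    small = adults$id[adults$dbh <= median_dbh],
    seedlings = if (is.null(seedlings)) character(0)
                else as.character(seedlings$id),
    median_dbh = median_dbh), class = "cohort_partition")
}
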