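#' Assemble and validate a parentage dataset
#'
#' Bundles the mapped adult table, seedling table, genotypes, plot
#' polygon and per-locus error rates, and cross-validates them: ids must
#' be unique and every mapped individual must have a genotype row; all
#' coordinates must fall inside (or on) the plot polygon; fecundities
#' must be nonnegative. Per-locus missingness is recorded in the
#' `missingness` element.
#'
#' @param adults Data frame with columns `id`, `x`, `y`, `fec_mean`,
#'   `fec_sd` and optionally `species` and `dbh` (cm).
#' @param seedlings Data frame with columns `id`, `x`, `y` and optionally
#'   `species`.
#' @param genotypes A [genotype_table()] covering all adult and seedling
#'   ids.
#' @param poly Plot polygon, 2-column (x, y) matrix in metres.
#' @param err An [error_rates()] table for the genotype loci.
#' @return An object of class `"parentage_data"`.
#' @export
parentage_data <- function(adults, seedlings, genotypes, poly, err) {
  poly <- as_polygon(poly)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  need(adults, c("id", "x", "y", "fec_mean", "fec_sd"), "adult")
  need(seedlings, c("id", "x", "y"), "seedling")
  adults$id <- as.character(adults$id)
  seedlings$id <- as.character(seedlings$id)
  if (anyDuplicated(c(adults$id, seedlings$id)))
    stop("duplicate ids across adult and seedling tables", call. = FALSE)
  if (!inherits(genotypes, "genotype_table"))
    stop("'genotypes' must be a genotype_table", call. = FALSE)
  no_geno <- setdiff(c(adults$id, seedlings$id), genotypes$ids)
  if (length(no_geno))
    stop("no genotype row for id(s): ", paste(no_geno, collapse = ", "),
         call. = FALSE)
  if (!is.null(err)) {
    if (!inherits(err, "error_rates") ||
        !identical(err$locus, genotypes$loci$locus))
      stop("'err' must be an error_rates table matching the genotype loci",
           call. = FALSE)
  }
  tol <- 1e-9
  chk_inside <- function(df, what) {
    xy <- cbind(df$x, df$y)
    ok <- in_plot(xy, poly) | edge_distance(xy, poly) <= tol
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("%s %s at (%.1f, %.1f) lies outside the plot polygon",
                   what, df$id[i], df$x[i], df$y[i]), call. = FALSE)
    }
  }
  chk_inside(adults, "adult")
  if (nrow(seedlings) > 0) chk_inside(seedlings, "seedling")
  if (any(adults$fec_mean < 0) || any(adults$fec_sd < 0))
    stop("fecundity means and SDs must be nonnegative", call. = FALSE)
  if (is.null(adults$species)) adults$species <- "sp"
  seedlings$edge_dist <- if (nrow(seedlings) > 0)
    edge_distance(cbind(seedlings$x, seedlings$y), poly) else numeric(0)
  miss <- colMeans(is.na(genotypes$al1[match(
    c(adults$id, seedlings$id), genotypes$ids), , drop = FALSE]))
  structure(list(adults = adults, seedlings = seedlings,
                 genotypes = genotypes, poly = poly, err = err,
                 missingness = miss),
            class = "parentage_data")
}

#' @export
print.parentage_data <- function(x, ...) {
  cat(sprintf(paste0("parentage_data: %d adults, %d seedlings, %d loci, ",
                     "plot %.2f ha\n"),
              nrow(x$adults), nrow(x$seedlings), nrow(x$genotypes$loci),
              polygon_area(x$poly) / 1e4))
  invisible(x)
}

#' Restrict a dataset to one species
#'
#' Implements the no-hybridisation (single-species) analysis mode: only
#' conspecific adults are candidate parents of conspecific seedlings, and
#' the exterior parent density drops to that species' in-plot density
#' (computed automatically from the subset). Allele frequencies for
#' unmapped parents are likewise recomputed from the conspecific adults.
#'
#' @param data A [parentage_data()].
#' @param species Species label to keep.
#' @return A [parentage_data()] restricted to the species.
#' @export
subset_species <- function(data, species) {
  ad <- data$adults[data$adults$species == species, , drop = FALSE]
  sl <- data$seedlings
  if (!is.null(sl$species)) sl <- sl[sl$species == species, , drop = FALSE]
  if (nrow(ad) == 0) stop("no adults of species ", species, call. = FALSE)
  parentage_data(ad, sl, data$genotypes, data$poly, data$err)
}
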