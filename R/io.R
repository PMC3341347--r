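## On-disk dataset layout (all plain UTF-8 CSV with header rows):
##   adults.csv       id,x,y,species,dbh,fec_mean,fec_sd
##   seedlings.csv    id,x,y[,species]
##   genotypes.csv    GenAlEx dialect (see read_genalex)
##   polygon.csv      x,y vertices of the plot ring, metres
##   error_rates.csv  locus,e1,e2,motif,min_size,max_size
## Loci metadata (motif and ladder bounds) travels with the error-rate
## table since GenAlEx files carry neither.

#' Read a parentage dataset from a directory
#'
#' Loads the five CSV files described in the package README, validates
#' them jointly via [parentage_data()], and reports per-locus
#' missingness. Errors name the offending file, id or coordinate.
#'
#' @param dir Directory containing `adults.csv`, `seedlings.csv`,
#'   `genotypes.csv`, `polygon.csv`, `error_rates.csv`.
#' @return A [parentage_data()].
#' @export
read_dataset <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  er <- utils::read.csv(path("error_rates.csv"))
  need <- c("locus", "e1", "e2", "motif", "min_size", "max_size")
  if (!all(need %in% names(er)))
    stop("error_rates.csv must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  loci <- loci_info(er$locus, er$motif, er$min_size, er$max_size)
  err <- error_rates(er$locus, er$e1, er$e2)
  geno <- read_genalex(path("genotypes.csv"), loci)
  adults <- utils::read.csv(path("adults.csv"), stringsAsFactors = FALSE)
  seedlings <- utils::read.csv(path("seedlings.csv"),
                               stringsAsFactors = FALSE)
  poly <- as.matrix(utils::read.csv(path("polygon.csv")))
  parentage_data(adults, seedlings, geno, poly, err)
}

#' Write a parentage dataset to a directory
#'
#' Inverse of [read_dataset()]; a write-then-read round trip reproduces
#' the dataset.
#'
#' @param data A [parentage_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, quote = FALSE)
  ad <- data$adults
  w(ad, "adults.csv")
  sl <- data$seedlings
  sl$edge_dist <- NULL
  w(sl, "seedlings.csv")
  li <- data$genotypes$loci
  w(data.frame(locus = li$locus, e1 = data$err$e1, e2 = data$err$e2,
               motif = li$motif, min_size = li$min_size,
               max_size = li$max_size), "error_rates.csv")
  w(data.frame(x = data$poly[, 1], y = data$poly[, 2]), "polygon.csv")
  write_genalex(data$genotypes, file.path(dir, "genotypes.csv"))
  invisible(dir)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: the echoed
#' configuration, the RNG seed, MD5 checksums of the input files, the
#' package version and a timestamp. Written as JSON next to the run's
#' outputs.
#'
#' @param path Output JSON path.
#' @param config Configuration list to echo.
#' @param seed RNG seed used.
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  manifest <- list(
    package = "seedshadow",
    version = as.character(utils::packageVersion("seedshadow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a run configuration YAML
#'
#' Maps a plain YAML file onto [mcmc_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return An [mcmc_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(mcmc_config))
  extra <- setdiff(names(y), c(known, "seed"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  seed <- y$seed
  y$seed <- NULL
  cfg <- do.call(mcmc_config, y)
  attr(cfg, "seed") <- seed
  cfg
}
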