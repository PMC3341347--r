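#' Locus metadata: motif size and allele-size ladder
#'
#' Microsatellite alleles live on a discrete "ladder" of fragment sizes
#' separated by the repeat-motif length. The ladder defines which allele
#' sizes are legal at a locus and which sizes are *adjacent* — the
#' neighbourhood into which stutter mistyping can move a call.
#'
#' @param locus Character vector of locus names.
#' @param motif Integer repeat-motif size in bp (per locus, recycled).
#' @param min_size,max_size Smallest and largest allele size (bp) on the
#'   ladder; `max_size - min_size` must be a multiple of `motif`.
#' @return A data frame of class `"loci_info"` with one row per locus.
#' @examples
#' loci_info(c("qA", "qB"), motif = 2, min_size = 100, max_size = 140)
#' @export
loci_info <- function(locus, motif, min_size, max_size) {
  li <- data.frame(locus = as.character(locus),
                   motif = as.integer(motif),
                   min_size = as.integer(min_size),
                   max_size = as.integer(max_size),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(li$locus)) stop("duplicate locus names", call. = FALSE)
  if (any(li$motif <= 0)) stop("motif must be positive", call. = FALSE)
  if (any(li$max_size < li$min_size))
    stop("max_size < min_size", call. = FALSE)
  if (any((li$max_size - li$min_size) %% li$motif != 0))
    stop("ladder span must be a multiple of the motif", call. = FALSE)
  class(li) <- c("loci_info", "data.frame")
  li
}

#' Allele-size ladder of one locus
#'
#' @param loci A [loci_info()] object.
#' @param l Locus index or name.
#' @return Integer vector of legal allele sizes, in bp.
#' @export
ladder <- function(loci, l) {
  i <- if (is.character(l)) match(l, loci$locus) else l
  if (is.na(i) || i < 1 || i > nrow(loci)) stop("unknown locus: ", l)
  seq.int(loci$min_size[i], loci$max_size[i], by = loci$motif[i])
}

#' Diploid microsatellite genotype table
#'
#' Container for unordered diploid allele-size calls at a common set of
#' loci. Pairs are stored sorted (`AB` and `BA` are the same genotype) and
#' a half-missing call (one allele recorded, the other not) is treated as
#' missing for the whole locus, since the error model is defined on full
#' diploid calls.
#'
#' @param ids Character vector of individual ids (unique).
#' @param al1,al2 `n x L` matrices of allele sizes in bp (columns are loci
#'   in the order of `loci`); `NA` or 0 denotes a missing allele.
#' @param loci A [loci_info()] object with `L` rows.
#' @param pop Optional population/cohort label per individual.
#' @return An object of class `"genotype_table"`.
#' @export
genotype_table <- function(ids, al1, al2, loci, pop = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate individual ids", call. = FALSE)
  al1 <- as.matrix(al1); al2 <- as.matrix(al2)
  storage.mode(al1) <- "integer"; storage.mode(al2) <- "integer"
  if (!inherits(loci, "loci_info")) stop("'loci' must be a loci_info object")
  L <- nrow(loci)
  if (ncol(al1) != L || ncol(al2) != L || nrow(al1) != length(ids) ||
      nrow(al2) != length(ids))
    stop("allele matrices must be n x L, matching ids and loci",
         call. = FALSE)
  al1[al1 %in% 0L] <- NA_integer_
  al2[al2 %in% 0L] <- NA_integer_
  ## half-calls -> locus missing
  half <- xor(is.na(al1), is.na(al2))
  al1[half] <- NA_integer_; al2[half] <- NA_integer_
  ## unordered pair: store sorted
  swap <- !is.na(al1) & al1 > al2
  tmp <- al1[swap]; al1[swap] <- al2[swap]; al2[swap] <- tmp
  for (j in seq_len(L)) {
    lad <- ladder(loci, j)
    bad <- !is.na(al1[, j]) & (!(al1[, j] %in% lad) | !(al2[, j] %in% lad))
    if (any(bad))
      stop(sprintf("locus %s: allele outside the size ladder for ids: %s",
                   loci$locus[j], paste(ids[bad], collapse = ", ")),
           call. = FALSE)
  }
  dimnames(al1) <- dimnames(al2) <- list(ids, loci$locus)
  structure(list(ids = ids, al1 = al1, al2 = al2, loci = loci,
                 pop = if (is.null(pop)) rep("1", length(ids))
                       else as.character(pop)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$ids), nrow(x$loci),
              100 * mean(is.na(x$al1))))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  idx <- if (is.character(i)) match(i, x$ids) else i
  if (anyNA(idx)) stop("unknown ids in subset", call. = FALSE)
  genotype_table(x$ids[idx], x$al1[idx, , drop = FALSE],
                 x$al2[idx, , drop = FALSE], x$loci, pop = x$pop[idx])
}

## genotype of one individual as an L x 2 matrix of allele sizes
genotype_of <- function(gt, id) {
  i <- if (is.character(id)) match(id, gt$ids) else id
  cbind(gt$al1[i, ], gt$al2[i, ])
}

#' Empirical allele frequencies per locus
#'
#' Counts alleles per locus over all non-missing calls and normalises.
#' These are the Hardy-Weinberg transmission probabilities used for
#' unmapped (out-of-plot) parents.
#'
#' @param gt A [genotype_table()].
#' @param pseudocount Count added to every ladder position before
#'   normalising (default 0: pure empirical frequencies). The parentage
#'   model uses a small pseudocount so that an allele carried into the
#'   plot by an unmapped parent but absent from the mapped adults does
#'   not receive probability exactly zero.
#' @return A list of class `"allele_freqs"`, one element per locus: a
#'   named numeric vector over the locus ladder (zeros for unobserved
#'   sizes when `pseudocount = 0`), summing to 1.
#' @export
allele_frequencies <- function(gt, pseudocount = 0) {
  L <- nrow(gt$loci)
  out <- vector("list", L)
  names(out) <- gt$loci$locus
  for (j in seq_len(L)) {
    lad <- ladder(gt$loci, j)
    calls <- c(gt$al1[, j], gt$al2[, j])
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0)
      stop(sprintf("locus %s has no non-missing calls", gt$loci$locus[j]),
           call. = FALSE)
    tab <- as.numeric(table(factor(calls, levels = lad))) + pseudocount
    out[[j]] <- tab / sum(tab)
    names(out[[j]]) <- as.character(lad)
  }
  structure(out, class = "allele_freqs")
}

#' Read a GenAlEx-dialect genotype CSV
#'
#' Format: first row `n_loci, n_individuals, n_pops`; second row column
#' headers (`id`, `pop`, then each locus name over its pair of allele
#' columns); then one row per individual with two allele-size columns per
#' locus, `0` meaning missing.
#'
#' @param path CSV file path.
#' @param loci A [loci_info()] object describing the loci in file order.
#' @return A [genotype_table()].
#' @export
read_genalex <- function(path, loci) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 1,
                         stringsAsFactors = FALSE)
  n_loci <- as.integer(hdr[[1]]); n_ind <- as.integer(hdr[[2]])
  if (n_loci != nrow(loci))
    stop(sprintf("%s: file declares %d loci, loci_info has %d",
                 path, n_loci, nrow(loci)), call. = FALSE)
  dat <- utils::read.csv(path, header = FALSE, skip = 2,
                         stringsAsFactors = FALSE)
  if (nrow(dat) != n_ind)
    stop(sprintf("%s: file declares %d individuals, found %d rows",
                 path, n_ind, nrow(dat)), call. = FALSE)
  if (ncol(dat) < 2 + 2 * n_loci)
    stop(path, ": too few allele columns", call. = FALSE)
  a_cols <- 2 + 2 * seq_len(n_loci) - 1
  genotype_table(ids = dat[[1]],
                 al1 = as.matrix(dat[, a_cols, drop = FALSE]),
                 al2 = as.matrix(dat[, a_cols + 1, drop = FALSE]),
                 loci = loci, pop = dat[[2]])
}

#' Write a GenAlEx-dialect genotype CSV
#'
#' Inverse of [read_genalex()]; missing calls are written as 0. A
#' write-then-read round trip reproduces the table exactly.
#'
#' @param gt A [genotype_table()].
#' @param path Output CSV path.
#' @export
write_genalex <- function(gt, path) {
  L <- nrow(gt$loci)
  n <- length(gt$ids)
  con <- file(path, "w")
  on.exit(close(con))
  pad <- function(x, len) c(x, rep("", len - length(x)))
  width <- 2 + 2 * L
  writeLines(paste(pad(c(L, n, length(unique(gt$pop))), width),
                   collapse = ","), con)
  hdr <- c("id", "pop", as.vector(rbind(gt$loci$locus, "")))
  writeLines(paste(pad(hdr, width), collapse = ","), con)
  a1 <- gt$al1; a2 <- gt$al2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  inter <- cbind(a1, a2)[, rep(seq_len(L), each = 2) + c(0L, L),
                         drop = FALSE]
  body <- data.frame(gt$ids, gt$pop, inter, stringsAsFactors = FALSE)
  utils::write.table(body, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
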