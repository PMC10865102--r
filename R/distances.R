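#' Encode aligned sequences as an integer matrix
#'
#' `A`,`C`,`G`,`T` map to 1..4; gaps, `N` and every IUPAC ambiguity code
#' become `NA` so that they are excluded from pairwise comparisons
#' (pairwise deletion).
#' @param x A `barcode_alignment`.
#' @return Integer matrix, records x columns, rownames = record labels.
#' @keywords internal
encode_alignment <- function(x) {
  if (n_records(x) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = x$n_columns))
  }
  chars <- matrix(unlist(strsplit(x$seq, ""), use.names = FALSE),
                  nrow = n_records(x), byrow = TRUE)
  code <- match(chars, c("A", "C", "G", "T"))
  dim(code) <- dim(chars)
  rownames(code) <- names(x$seq)
  code
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The p-distance is the fraction of differing nucleotide positions among
#' the pairwise-comparable sites, with no substitution-model correction.
#' Sites where either sequence carries a gap, an `N` or any IUPAC ambiguity
#' code are excluded (pairwise deletion); ambiguity codes are treated as
#' missing data, never as partial matches.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return A list with `distance` (in `[0, 1]`) and `comparable_sites`.
#'   A pair with no comparable site at all is an error: the caller decides
#'   how to treat an undefined distance.
#' @examples
#' p_distance("ACGT", "ACGA")     # 0.25 over 4 sites
#' p_distance("AC-TN", "ACGTA")   # gap and N excluded: 0 over 3 sites
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  ca <- match(strsplit(toupper(a), "")[[1]], c("A", "C", "G", "T"))
  cb <- match(strsplit(toupper(b), "")[[1]], c("A", "C", "G", "T"))
  ok <- !is.na(ca) & !is.na(cb)
  m <- sum(ok)
  if (m == 0L) {
    stop("no comparable sites between the two sequences", call. = FALSE)
  }
  list(distance = sum(ca[ok] != cb[ok]) / m, comparable_sites = m)
}

#' Full pairwise p-distance matrix of an alignment
#'
#' Computes every pairwise uncorrected p-distance under pairwise deletion
#' (see [p_distance()]) via per-base indicator matrices, so the cost is a
#' handful of dense matrix products rather than an explicit double loop.
#'
#' @param x A `barcode_alignment` with at least 2 records.
#' @return A `pdist_matrix`: list with `d` (symmetric p-distance matrix,
#'   zero diagonal, `NA` where a pair shares no comparable site), `m`
#'   (comparable-site counts) and `labels`.
#' @export
distance_matrix <- function(x) {
  if (n_records(x) < 2L) {
    stop("need at least 2 records for a distance matrix", call. = FALSE)
  }
  code <- encode_alignment(x)
  n <- nrow(code)
  valid <- !is.na(code)
  storage.mode(valid) <- "double"
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- (code == b) & !is.na(code)
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  comparable <- tcrossprod(valid)
  d <- (comparable - matches) / comparable
  d[comparable == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(code), rownames(code))
  m <- comparable
  storage.mode(m) <- "integer"
  dimnames(m) <- dimnames(d)
  obj <- list(d = d, m = m, labels = rownames(code))
  class(obj) <- "pdist_matrix"
  obj
}

#' @export
print.pdist_matrix <- function(x, ...) {
  cat("pdist_matrix:", length(x$labels), "records; max distance",
      format(max(x$d, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

cross_distances <- function(dm, identities, sp_a, sp_b) {
  ia <- which(identities$species_key == sp_a)
  ib <- which(identities$species_key == sp_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("species not present in the distance matrix: ",
         if (length(ia) == 0L) sp_a else sp_b, call. = FALSE)
  }
  as.vector(dm$d[ia, ib, drop = FALSE])
}

#' Distance summary between two species
#'
#' Minimum, mean and maximum p-distance over all cross-species record
#' pairs (within-species pairs never enter).  Pairs without comparable
#' sites are dropped.
#'
#' @param sp_a,sp_b Species keys.
#' @param dm A `pdist_matrix` over the alignment.
#' @param identities Identity data frame aligned with `dm$labels`
#'   (typically `alignment$identity`).
#' @return A list with `species_a`, `species_b`, `min_dist`, `mean_dist`,
#'   `max_dist` and `n_pairs`.
#' @export
species_pair_summary <- function(sp_a, sp_b, dm, identities) {
  v <- cross_distances(dm, identities, sp_a, sp_b)
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no defined cross-pair distance between ", sp_a, " and ", sp_b,
         call. = FALSE)
  }
  list(species_a = sp_a, species_b = sp_b,
       min_dist = min(v), mean_dist = mean(v), max_dist = max(v),
       n_pairs = length(v))
}

#' Maximum intraspecific p-distance of a species
#'
#' @inheritParams species_pair_summary
#' @param sp Species key.
#' @return Largest p-distance among within-species record pairs, or `NA`
#'   for singleton species.
#' @export
max_intraspecific <- function(sp, dm, identities) {
  idx <- which(identities$species_key == sp)
  if (length(idx) < 2L) return(NA_real_)
  sub <- dm$d[idx, idx]
  max(sub[upper.tri(sub)], na.rm = TRUE)
}

#' Render a p-distance as a percent value, one decimal, half-up
#'
#' Report tables print distances in percent with one decimal; ties round
#' away from zero (0.0225 -> 2.3), unlike R's banker's rounding.
#' @param d Numeric p-distance(s) in `[0, 1]`.
#' @return Numeric percent value(s) rounded to one decimal.
#' @export
percent1 <- function(d) {
  floor(d * 1000 + 0.5) / 10
}

#' Export a distance matrix as text
#'
#' @param dm A `pdist_matrix`.
#' @param path Output path.
#' @param format `"tsv"` for a square tab-separated matrix with a header
#'   row, or `"phylip"` for the square PHYLIP distance format.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$labels)), con)
    for (i in seq_along(dm$labels)) {
      writeLines(paste(c(sprintf("%-10s", dm$labels[i]),
                         sprintf("%.6f", dm$d[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}
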