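#' Single-linkage MOTU partition at a p-distance threshold
#'
#' Two records fall into the same molecular operational taxonomic unit
#' (MOTU) when they are connected by a chain of pairwise distances at or
#' below the threshold — i.e. MOTUs are the connected components of the
#' graph whose edges are pairs with `d <= threshold`.  This is the
#' partition rule barcode-gap methods share; the probability model of any
#' particular partitioning programme is deliberately not reproduced here.
#'
#' @param dm A `pdist_matrix`; must be complete (no `NA`) on the records
#'   being partitioned.
#' @param threshold p-distance threshold in `[0, 1]`.
#' @return A `motu_partition`: list with `threshold`, `linkage`
#'   (`"single"`), `membership` (named integer vector record -> MOTU id)
#'   and `motus` (list of record-label sets).
#' @export
single_linkage_partition <- function(dm, threshold) {
  if (anyNA(dm$d)) {
    idx <- which(is.na(dm$d) & upper.tri(dm$d), arr.ind = TRUE)
    pairs <- paste(dm$labels[idx[, 1]], dm$labels[idx[, 2]], sep = " ~ ")
    stop("undefined distances for pair(s): ",
         paste(utils::head(pairs, 5L), collapse = ", "), call. = FALSE)
  }
  adj <- (dm$d <= threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- dm$labels
  obj <- list(threshold = threshold, linkage = "single",
              membership = membership,
              motus = split(dm$labels, membership))
  class(obj) <- "motu_partition"
  obj
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition:", length(x$motus), "MOTUs over",
      length(x$membership), "records at threshold", x$threshold, "\n")
  invisible(x)
}

#' Read an externally produced partition file
#'
#' Adapter for scoring partitions computed outside this package (e.g. by a
#' threshold-search programme): a tab-separated file with columns
#' `record_id` and `motu_id`.
#'
#' @param path Path to the partition TSV.
#' @return A `motu_partition` with `threshold = NA`.
#' @export
read_partition_file <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("record_id", "motu_id") %in% names(tab))) {
    stop("partition file needs columns record_id and motu_id", call. = FALSE)
  }
  membership <- as.integer(factor(tab$motu_id))
  names(membership) <- tab$record_id
  obj <- list(threshold = NA_real_, linkage = "external",
              membership = membership,
              motus = split(tab$record_id, membership))
  class(obj) <- "motu_partition"
  obj
}

#' Write a partition as a record-to-MOTU table
#' @param partition A `motu_partition`.
#' @param path Output TSV path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(record_id = names(partition$membership),
               motu_id = unname(partition$membership)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concordance of a MOTU partition with morphospecies
#'
#' A morphospecies is correctly assigned when its record set coincides
#' exactly with one MOTU (one-to-one: neither split over several MOTUs nor
#' lumped with another species).  `n_wrong_taxa` counts morphospecies
#' failing this; by default `n_wrong_seqs` counts every record belonging to
#' a wrongly assigned morphospecies, with `seq_count = "misplaced"`
#' available to count only records lying outside their species' plurality
#' MOTU.
#'
#' @param partition A `motu_partition`.
#' @param identities Identity data frame whose `raw_label` matches the
#'   partition's record labels; each record needs a `species_key`.
#' @param seq_count `"affected"` (default: all records of wrong taxa) or
#'   `"misplaced"`.
#' @return List with `n_morphospecies`, `n_motus`, `n_wrong_taxa`,
#'   `n_wrong_seqs`, `pct_wrong_seqs` (whole percent of all records) and
#'   `wrong_taxa` (keys).
#' @export
concordance <- function(partition, identities,
                        seq_count = c("affected", "misplaced")) {
  seq_count <- match.arg(seq_count)
  sp <- identities$species_key[match(names(partition$membership),
                                     identities$raw_label)]
  if (anyNA(sp)) {
    stop("records without species identity: ",
         paste(utils::head(names(partition$membership)[is.na(sp)], 5L),
               collapse = ", "), call. = FALSE)
  }
  motu <- unname(partition$membership)
  species_records <- split(seq_along(sp), sp)
  motu_of <- function(idx) unique(motu[idx])
  wrong <- vapply(species_records, function(idx) {
    ms <- motu_of(idx)
    if (length(ms) != 1L) return(TRUE)          # split over several MOTUs
    sum(motu == ms) != length(idx)              # lumped with another taxon
  }, logical(1))
  wrong_taxa <- names(species_records)[wrong]
  n_wrong_seqs <- if (seq_count == "affected") {
    sum(lengths(species_records[wrong]))
  } else {
    sum(vapply(species_records[wrong], function(idx) {
      counts <- table(motu[idx])
      length(idx) - max(counts)
    }, numeric(1)))
  }
  n_total <- length(sp)
  list(
    n_morphospecies = length(species_records),
    n_motus = length(partition$motus),
    n_wrong_taxa = sum(wrong),
    n_wrong_seqs = as.integer(n_wrong_seqs),
    pct_wrong_seqs = as.integer(round(100 * n_wrong_seqs / n_total)),
    wrong_taxa = wrong_taxa
  )
}

#' Concordance across a set of thresholds
#'
#' Partitions the records at every threshold and evaluates each partition
#' against the morphospecies, answering whether any single threshold can
#' match the morphological species limits — and which one comes closest.
#'
#' @param dm A `pdist_matrix`.
#' @param identities Identity data frame (see [concordance()]).
#' @param thresholds Non-empty numeric vector of p-distance thresholds.
#' @param seq_count Passed to [concordance()].
#' @return List with `sweep` (data frame: threshold, n_motus,
#'   n_wrong_taxa, n_wrong_seqs, pct_wrong_seqs), `best_by_taxa` and
#'   `best_by_seqs` (the threshold attaining the fewest wrongly assigned
#'   taxa / the lowest wrong-sequence percentage; earliest on ties).
#' @export
threshold_sweep <- function(dm, identities, thresholds,
                            seq_count = c("affected", "misplaced")) {
  seq_count <- match.arg(seq_count)
  if (length(thresholds) == 0L) {
    stop("thresholds must be non-empty", call. = FALSE)
  }
  reports <- lapply(thresholds, function(t) {
    concordance(single_linkage_partition(dm, t), identities, seq_count)
  })
  sweep <- data.frame(
    threshold = thresholds,
    n_motus = vapply(reports, `[[`, numeric(1), "n_motus"),
    n_wrong_taxa = vapply(reports, `[[`, numeric(1), "n_wrong_taxa"),
    n_wrong_seqs = vapply(reports, `[[`, numeric(1), "n_wrong_seqs"),
    pct_wrong_seqs = vapply(reports, `[[`, numeric(1), "pct_wrong_seqs")
  )
  list(sweep = sweep,
       best_by_taxa = thresholds[which.min(sweep$n_wrong_taxa)],
       best_by_seqs = thresholds[which.min(sweep$pct_wrong_seqs)],
       reports = reports)
}
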