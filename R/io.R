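ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read an aligned barcode FASTA file
#'
#' Reads a multiple sequence alignment of CO1 barcodes whose record labels
#' encode the taxon identity (see [default_label_scheme()]), checks that all
#' records share one alignment length and that sequences use only
#' nucleotides, IUPAC ambiguity codes, `N` and the gap character `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @param scheme Label scheme passed to [parse_label()].
#' @return A `barcode_alignment`: a list with elements
#'   \describe{
#'     \item{seq}{named uppercase character vector of aligned sequences,
#'       input order preserved}
#'     \item{identity}{data frame from [parse_label()], one row per record}
#'     \item{n_columns}{alignment length}
#'   }
#' @seealso [write_alignment()], [dataset_summary()]
#' @export
read_alignment <- function(path, scheme = default_label_scheme()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  barcode_alignment(seqs, scheme = scheme)
}

#' Construct a barcode alignment from named sequences
#'
#' @param seq Named character vector: aligned sequences, names are record
#'   labels under `scheme`.
#' @param scheme Label scheme passed to [parse_label()].
#' @return A `barcode_alignment` object; see [read_alignment()].
#' @export
barcode_alignment <- function(seq, scheme = default_label_scheme()) {
  if (length(seq) == 0L) {
    obj <- list(seq = character(0),
                identity = parse_label(character(0), scheme),
                n_columns = 0L)
    class(obj) <- "barcode_alignment"
    return(obj)
  }
  if (is.null(names(seq)) || any(names(seq) == "")) {
    stop("all sequences must be named with their record label", call. = FALSE)
  }
  seq <- toupper(seq)
  len <- nchar(seq)
  if (length(unique(len)) > 1L) {
    ref <- as.integer(names(sort(table(len), decreasing = TRUE))[1])
    off <- names(seq)[len != ref]
    stop("unequal aligned lengths; offending record(s): ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  chars <- unique(strsplit(paste(seq, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ALLOWED_CHARS)
  if (length(bad) > 0L) {
    stop("disallowed characters in alignment: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  obj <- list(seq = seq,
              identity = parse_label(names(seq), scheme),
              n_columns = len[[1]])
  class(obj) <- "barcode_alignment"
  obj
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("barcode_alignment:", length(x$seq), "records x",
      x$n_columns, "columns;",
      length(unique(x$identity$species_key[!x$identity$is_qualifier])),
      "qualifier-free species\n")
  invisible(x)
}

#' Number of records in an alignment
#' @param x A `barcode_alignment`.
#' @export
n_records <- function(x) length(x$seq)

#' Ungapped length of every record
#' @param x A `barcode_alignment`.
#' @return Integer vector, named by record label: sequence length after
#'   removing alignment gaps (`-`).
#' @export
ungapped_lengths <- function(x) {
  nchar(gsub("-", "", x$seq, fixed = TRUE))
}

#' Subset an alignment by record index or label
#' @param x A `barcode_alignment`.
#' @param i Integer or logical index, or character vector of labels.
#' @export
subset_alignment <- function(x, i) {
  if (is.character(i)) i <- match(i, names(x$seq))
  obj <- list(seq = x$seq[i],
              identity = x$identity[i, , drop = FALSE],
              n_columns = x$n_columns)
  rownames(obj$identity) <- NULL
  class(obj) <- "barcode_alignment"
  obj
}

#' Drop every record of one species from an alignment
#' @param x A `barcode_alignment`.
#' @param species_key Species to remove.
#' @export
drop_species <- function(x, species_key) {
  keep <- x$identity$species_key != species_key
  if (all(keep)) stop("species not present: ", species_key, call. = FALSE)
  subset_alignment(x, keep)
}

#' Write an alignment as wrapped FASTA
#'
#' @param x A `barcode_alignment`.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.  Round-trips with [read_alignment()] up to
#'   line wrapping and case.
#' @export
write_alignment <- function(x, path, width = 80L) {
  set <- Biostrings::BStringSet(x$seq)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read the per-species curation table
#'
#' The annotation table carries the curator's species-level metadata used by
#' the distance statistics: which genus and subfamily a species belongs to,
#' its confidence group (1 = morphologically uncontroversial reference
#' species, 2 = usable only as congener, 3 = excluded), whether it is an
#' island taxon, and the maximum linear extent of its distribution in km.
#'
#' @param path Path to a tab-separated file with header columns
#'   `species_key`, `genus`, `subfamily`, `confidence_group`, `island`,
#'   `range_km`.
#' @return Data frame with those columns; unknown subfamilies are carried
#'   through as `"other"`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' Validate an annotation table
#'
#' @param ann Data frame of per-species annotations (see
#'   [read_annotations()]).
#' @return The validated data frame, with `subfamily` normalised so that
#'   values outside the supported set become `"other"` and `island` coerced
#'   to logical.
#' @export
validate_annotations <- function(ann) {
  required <- c("species_key", "genus", "subfamily", "confidence_group",
                "island", "range_km")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    stop("annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- ann$species_key[duplicated(ann$species_key)]
  if (length(dup) > 0L) {
    stop("duplicated species_key in annotations: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(ann$confidence_group %in% c(1L, 2L, 3L))) {
    bad <- ann$species_key[!ann$confidence_group %in% c(1L, 2L, 3L)]
    stop("confidence_group must be 1, 2 or 3; offending species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(ann$range_km < 0, na.rm = TRUE)) {
    stop("range_km must be nonnegative", call. = FALSE)
  }
  known <- c("Cryptorhynchinae", "Apioninae", "Ceutorhynchinae")
  ann$subfamily <- ifelse(ann$subfamily %in% known, ann$subfamily, "other")
  ann$island <- as.logical(ann$island)
  ann$confidence_group <- as.integer(ann$confidence_group)
  ann
}

#' Write the per-species annotation table
#' @param ann Annotation data frame.
#' @param path Output path (tab-separated, header row).
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dataset composition summary
#'
#' Counts sequences and species the way barcode releases report them:
#' species are counted on `species_key` excluding open-nomenclature
#' (`cf.`/`sp.`) records, a singleton is a species with exactly one
#' sequenced specimen, and the sampling-depth distribution is summarised by
#' its median.
#'
#' @param x A `barcode_alignment`.
#' @return A list with `n_sequences`, `n_species`, `n_qualifier_records`,
#'   `n_singleton_species`, `singleton_seq_fraction` (fraction of
#'   *sequences* that are the sole representative of their species),
#'   `median_specimens_per_species` and the full `specimens_per_species`
#'   table.
#' @export
dataset_summary <- function(x) {
  id <- x$identity
  valid <- id[!id$is_qualifier, , drop = FALSE]
  per_species <- table(valid$species_key)
  n_singleton <- sum(per_species == 1L)
  list(
    n_sequences = nrow(id),
    n_species = length(per_species),
    n_qualifier_records = sum(id$is_qualifier),
    n_singleton_species = n_singleton,
    singleton_seq_fraction =
      if (nrow(id) == 0L) 0 else n_singleton / nrow(id),
    median_specimens_per_species =
      if (length(per_species) == 0L) 0 else stats::median(as.integer(per_species)),
    specimens_per_species = per_species
  )
}
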