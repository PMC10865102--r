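IUPAC_RESOLUTIONS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

stop_codon_set <- function(code) {
  switch(code,
    "invert-mito" = c("TAA", "TAG"),  # AGA/AGG encode Ser here, not stops
    "standard" = c("TAA", "TAG", "TGA"),
    stop("unknown genetic code id: ", code, call. = FALSE)
  )
}

#' Locate in-frame stop codons
#'
#' Scans an ungapped nucleotide sequence codon by codon in one reading frame
#' and returns the positions of stop codons.  The default genetic code is
#' the invertebrate mitochondrial code, under which only `TAA` and `TAG`
#' terminate (`AGA`/`AGG` encode serine).  A codon containing IUPAC
#' ambiguity codes counts as a stop only if *every* resolution of the
#' ambiguity is a stop (e.g. `TAR` is, `TAN` is not), so uncertain bases
#' never produce a pseudogene flag on their own.  An incomplete terminal
#' codon is ignored.
#'
#' @param sequence Ungapped nucleotide string (case-insensitive).
#' @param frame Reading frame offset: 0, 1 or 2 skipped leading bases.
#' @param code Genetic code id: `"invert-mito"` (default) or `"standard"`.
#' @return Integer vector of 0-based codon indices of stop codons.
#' @examples
#' find_stop_codons("ATGTAAATT", frame = 0)       # TAA at codon 1
#' find_stop_codons("ATGAGAAGG", frame = 0)       # AGA/AGG are not stops
#' @export
find_stop_codons <- function(sequence, frame = 0L, code = "invert-mito") {
  if (!frame %in% c(0L, 1L, 2L)) {
    stop("frame must be 0, 1 or 2", call. = FALSE)
  }
  stops <- stop_codon_set(code)
  s <- toupper(sequence)
  if (grepl("-", s, fixed = TRUE)) {
    stop("sequence must be ungapped; remove '-' first", call. = FALSE)
  }
  s <- substring(s, frame + 1L)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return(integer(0))
  starts <- (seq_len(n_codons) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  plain <- codons %in% stops
  ambiguous <- grepl("[^ACGT]", codons)
  all_stop <- vapply(codons[ambiguous], function(cd) {
    parts <- strsplit(cd, "")[[1]]
    res <- IUPAC_RESOLUTIONS[parts]
    if (any(vapply(res, is.null, logical(1)))) return(FALSE)
    combos <- expand.grid(res, stringsAsFactors = FALSE)
    all(do.call(paste0, combos) %in% stops)
  }, logical(1))
  hit <- plain
  hit[ambiguous] <- all_stop
  which(hit) - 1L
}

#' Screen an alignment for pseudogene signals and barcode length
#'
#' Pseudogene copies of the barcode (NUMTs) accumulate frame-disrupting
#' mutations and typically reveal themselves through in-frame stop codons;
#' this screen flags them for curator review rather than deleting them,
#' and produces the release's barcode-length accounting (full-length
#' records, shorter records, records below the commonly required 500 bp
#' minimum).
#'
#' @param x A `barcode_alignment`.
#' @param frame Reading frame of the (primer-trimmed) barcode in this
#'   dataset; a dataset property the caller supplies.
#' @param code Genetic code id (see [find_stop_codons()]).
#' @param full_length Full barcode length in nt (default 658).
#' @param min_length Minimum acceptable barcode length in nt (default 500).
#' @return A list with a per-record data frame `records` (columns
#'   `raw_label`, `ungapped_length`, `is_full_length`, `below_min_length`,
#'   `n_stop_codons`, `flagged_numt`), the stop positions per flagged record
#'   in `stop_positions`, and summary `counts` (`n_records`, `n_full_length`,
#'   `n_shorter`, `n_below_min`, `n_flagged_numt`).
#' @export
qc_screen <- function(x, frame = 0L, code = "invert-mito",
                      full_length = 658L, min_length = 500L) {
  ungapped <- gsub("-", "", x$seq, fixed = TRUE)
  len <- nchar(ungapped)
  stop_positions <- lapply(ungapped, find_stop_codons,
                           frame = frame, code = code)
  n_stops <- lengths(stop_positions)
  records <- data.frame(
    raw_label = names(x$seq),
    ungapped_length = unname(len),
    is_full_length = unname(len == full_length),
    below_min_length = unname(len < min_length),
    n_stop_codons = unname(n_stops),
    flagged_numt = unname(n_stops > 0L),
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    stop_positions = stop_positions[n_stops > 0L],
    counts = list(
      n_records = nrow(records),
      n_full_length = sum(records$is_full_length),
      n_shorter = sum(!records$is_full_length),
      n_below_min = sum(records$below_min_length),
      n_flagged_numt = sum(records$flagged_numt)
    )
  )
}
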