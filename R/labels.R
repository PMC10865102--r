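#' Default FASTA label scheme
#'
#' Barcode libraries commonly encode the taxon identity, the voucher/specimen
#' id and (optionally) a GenBank accession directly in the FASTA header, with
#' fields separated by underscores.  The default scheme accepts
#' `Genus_epithet[_subepithet]_specimenID[_accession]` together with the open
#' nomenclature qualifiers `cf` (identification uncertain) and `sp`
#' (unnamed species), i.e. `Genus_cf_epithet_specimenID` and
#' `Genus_sp_specimenID`.
#'
#' A scheme is a PCRE pattern with the named capture groups `genus`,
#' `species`, `subspecies`, `qualifier`, `specimen_id` and `accession`
#' (`genus` and `specimen_id` are required by the default scheme; any group a
#' custom scheme omits is returned as `NA`).  Pass a different pattern to
#' [parse_label()] / [read_alignment()] to override.
#'
#' @return A character scalar: the default label pattern.
#' @examples
#' parse_label("Acalles_pilula_1234-PST_MG000001")
#' @export
default_label_scheme <- function() {
  paste0(
    "^(?<genus>[A-Z][a-z]+)_",
    "(?:(?<qualifier>cf|sp)_)?",
    "(?:(?<species>[a-z][a-z-]*)_)?",
    "(?:(?<subspecies>[a-z][a-z-]*)_)?",
    "(?<specimen_id>[0-9][0-9A-Za-z]*-[A-Za-z]+)",
    "(?:_(?<accession>[A-Za-z][A-Za-z0-9.]*))?$"
  )
}

#' Parse a structured FASTA label into a taxon identity
#'
#' @param raw_label Character vector of FASTA record labels.
#' @param scheme PCRE pattern with named capture groups (see
#'   [default_label_scheme()]).
#' @return A data frame with one row per label and columns `raw_label`,
#'   `genus`, `species`, `subspecies`, `qualifier`, `specimen_id`,
#'   `accession`, `species_key` and `is_qualifier`.  `species_key`
#'   (genus + species epithet) is the unit of all per-species statistics:
#'   subspecies collapse into the parent species, while `cf.`/`sp.` records
#'   keep the qualifier inside the key so that they never merge with the
#'   species they resemble.
#' @details Records whose label does not match the scheme raise an error
#'   naming the offending label.  Qualifier-free records must carry a genus
#'   and a species epithet.
#' @export
parse_label <- function(raw_label, scheme = default_label_scheme()) {
  m <- regexpr(scheme, raw_label, perl = TRUE)
  bad <- which(m == -1L)
  if (length(bad) > 0L) {
    stop("label(s) not matching the label scheme: ",
         paste(utils::head(raw_label[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  groups <- c("genus", "qualifier", "species", "subspecies",
              "specimen_id", "accession")
  out <- data.frame(raw_label = raw_label, stringsAsFactors = FALSE)
  for (g in groups) {
    if (g %in% colnames(starts)) {
      v <- substr(raw_label, starts[, g], starts[, g] + lens[, g] - 1L)
      v[lens[, g] == 0L] <- NA_character_
    } else {
      v <- rep(NA_character_, length(raw_label))
    }
    out[[g]] <- v
  }
  out$is_qualifier <- !is.na(out$qualifier)
  incomplete <- !out$is_qualifier & (is.na(out$genus) | is.na(out$species))
  if (any(incomplete)) {
    stop("label(s) without genus or species epithet: ",
         paste(utils::head(raw_label[incomplete], 5L), collapse = ", "),
         call. = FALSE)
  }
  key <- ifelse(out$is_qualifier,
                paste(out$genus, out$qualifier,
                      ifelse(is.na(out$species), out$specimen_id, out$species),
                      sep = "_"),
                paste(out$genus, out$species, sep = "_"))
  out$species_key <- key
  out
}
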