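#' Assign a species to a geographic distribution group
#'
#' Reference species are binned by the maximum linear extent of their
#' distribution so that interspecific distances can be compared among
#' species of similar range size.  Island taxa form their own group
#' regardless of extent; continental taxa split at 50 km
#' (narrow endemics) and at a subfamily-specific upper cutoff: 500 km for
#' Cryptorhynchinae (mostly flightless, narrow ranges), 2000 km for
#' Apioninae and Ceutorhynchinae (widely distributed fliers).  Boundaries
#' are inclusive on the left-hand class: C1 = (0, 50], C2 = (50, U],
#' C3 = (U, Inf).
#'
#' @param subfamily One of `"Cryptorhynchinae"`, `"Apioninae"`,
#'   `"Ceutorhynchinae"` (vectorised).
#' @param island Logical: island/archipelago distribution.
#' @param range_km Nonnegative maximum distribution extent in km.
#' @return Character vector over `{"ISL", "C1", "C2", "C3"}`.
#' @examples
#' assign_distribution_group("Cryptorhynchinae", FALSE, 400)  # "C2"
#' assign_distribution_group("Apioninae", FALSE, 400)         # "C2"
#' assign_distribution_group("Apioninae", TRUE, 3000)         # "ISL"
#' @export
assign_distribution_group <- function(subfamily, island, range_km) {
  supported <- c(Cryptorhynchinae = 500, Apioninae = 2000,
                 Ceutorhynchinae = 2000)
  if (!all(subfamily %in% names(supported))) {
    stop("unsupported subfamily for distribution groups: ",
         paste(unique(subfamily[!subfamily %in% names(supported)]),
               collapse = ", "), call. = FALSE)
  }
  upper <- supported[subfamily]
  out <- ifelse(island, "ISL",
                ifelse(range_km <= 50, "C1",
                       ifelse(range_km <= upper, "C2", "C3")))
  unname(out)
}

#' Split annotated species into reference and congener sets
#'
#' Only confidence groups 1 and 2 enter the distance statistics: group 1
#' species ("good species") are the references whose closest-congener
#' distances are tabulated; group 2 species additionally serve as potential
#' closest congeners but never contribute their own rows; group 3 is
#' excluded entirely.
#'
#' @param ann Annotation data frame (see [read_annotations()]).
#' @return List with character vectors `reference_set` (group 1) and
#'   `congener_set` (groups 1 and 2).  Warns when the reference set is
#'   empty.
#' @export
select_statistics_set <- function(ann) {
  reference <- ann$species_key[ann$confidence_group == 1L]
  congener <- ann$species_key[ann$confidence_group %in% c(1L, 2L)]
  if (length(reference) == 0L) {
    warning("no confidence-group-1 species: reference set is empty")
  }
  list(reference_set = reference, congener_set = congener)
}

congener_genus <- function(genus, genus_alias = NULL) {
  if (is.null(genus_alias)) return(genus)
  out <- genus_alias[genus]
  ifelse(is.na(out), genus, unname(out))
}

species_min_dist <- function(dm, identities, sp_a, sp_b) {
  v <- cross_distances(dm, identities, sp_a, sp_b)
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  min(v)
}

#' Closest congener of one reference species
#'
#' The species-to-species distance is the minimum p-distance over all
#' cross-species record pairs; the closest congener is the same-genus
#' species in the congener set (reference excluded) attaining the smallest
#' such distance.  Ties are retained and the lexicographically first tied
#' species is reported.
#'
#' @param ref Reference species key (must be in the congener set's genus
#'   scope and present in the data).
#' @param dm A `pdist_matrix`.
#' @param identities Identity data frame aligned with `dm$labels`.
#' @param congener_set Character vector of species usable as congeners.
#' @param genus_alias Optional named character vector merging genera that
#'   curators treat as one congener pool (names = annotated genus, values
#'   = pooled genus label).
#' @param annotations Optional annotation table; when supplied, genus
#'   membership is taken from it instead of the parsed labels.
#' @return A list (`CongenerStatRow`): `reference_species`, `genus`,
#'   `closest_congener`, `min_dist`, `tied_congeners`; or `NULL` when no
#'   congener of the genus is present (the caller logs the omission).
#' @export
closest_congener <- function(ref, dm, identities, congener_set,
                             genus_alias = NULL, annotations = NULL) {
  genus_of <- function(keys) {
    if (!is.null(annotations)) {
      g <- annotations$genus[match(keys, annotations$species_key)]
    } else {
      g <- identities$genus[match(keys, identities$species_key)]
    }
    congener_genus(g, genus_alias)
  }
  present <- unique(identities$species_key[!identities$is_qualifier])
  candidates <- setdiff(intersect(congener_set, present), ref)
  candidates <- candidates[genus_of(candidates) == genus_of(ref)]
  if (length(candidates) == 0L) return(NULL)
  d <- vapply(candidates, function(sp)
    species_min_dist(dm, identities, ref, sp), numeric(1))
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NULL)
  dmin <- min(d)
  tied <- sort(names(d)[d == dmin])
  list(reference_species = ref,
       genus = genus_of(ref),
       closest_congener = tied[1],
       min_dist = dmin,
       tied_congeners = tied)
}

#' Closest-congener statistics for every reference species
#'
#' Runs [closest_congener()] over the whole reference set and attaches each
#' species' geographic distribution group.  Reference species without any
#' same-genus congener in the data are omitted; their keys are returned in
#' the `"omitted"` attribute.
#'
#' @param dm A `pdist_matrix`.
#' @param identities Identity data frame aligned with `dm$labels`.
#' @param ann Annotation data frame; reference and congener sets are
#'   derived from its confidence groups via [select_statistics_set()].
#' @param genus_alias Optional genus alias map (see [closest_congener()]).
#' @return Data frame with one row per tabulated reference species:
#'   `reference_species`, `genus`, `distribution_group`,
#'   `closest_congener`, `min_dist` (p-distance), `min_dist_pct` (percent,
#'   one decimal), `tied_congeners` (comma-separated).
#' @export
congener_stat_table <- function(dm, identities, ann, genus_alias = NULL) {
  sets <- select_statistics_set(ann)
  present <- unique(identities$species_key[!identities$is_qualifier])
  refs <- sort(intersect(sets$reference_set, present))
  rows <- lapply(refs, closest_congener, dm = dm, identities = identities,
                 congener_set = sets$congener_set,
                 genus_alias = genus_alias, annotations = ann)
  omitted <- refs[vapply(rows, is.null, logical(1))]
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- data.frame(
    reference_species = vapply(rows, `[[`, character(1), "reference_species"),
    genus = vapply(rows, `[[`, character(1), "genus"),
    closest_congener = vapply(rows, `[[`, character(1), "closest_congener"),
    min_dist = vapply(rows, `[[`, numeric(1), "min_dist"),
    tied_congeners = vapply(rows, function(r)
      paste(r$tied_congeners, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    i <- match(out$reference_species, ann$species_key)
    out$distribution_group <- assign_distribution_group(
      ann$subfamily[i], ann$island[i], ann$range_km[i])
    out$min_dist_pct <- percent1(out$min_dist)
    out <- out[, c("reference_species", "genus", "distribution_group",
                   "closest_congener", "min_dist", "min_dist_pct",
                   "tied_congeners")]
  }
  attr(out, "omitted") <- omitted
  out
}

#' Genus x distribution-group summary of closest-congener distances
#'
#' Aggregates the per-species rows the way the release's genus lists print
#' them: per genus and distribution group, the minimum and the arithmetic
#' mean of the species' closest-congener distances, rendered in percent to
#' one decimal.  Cells without any reference species are simply absent.
#'
#' @param rows Output of [congener_stat_table()].
#' @return Data frame with `genus`, `distribution_group`, `min_of_min`,
#'   `avg_of_min` (both percent, one decimal) and `n_reference_species`.
#' @export
genus_distribution_table <- function(rows) {
  if (nrow(rows) == 0L) {
    return(data.frame(genus = character(0), distribution_group = character(0),
                      min_of_min = numeric(0), avg_of_min = numeric(0),
                      n_reference_species = integer(0)))
  }
  key <- interaction(rows$genus, rows$distribution_group, drop = TRUE)
  parts <- split(rows, key)
  out <- do.call(rbind, lapply(parts, function(p) data.frame(
    genus = p$genus[1],
    distribution_group = p$distribution_group[1],
    min_of_min = percent1(min(p$min_dist)),
    avg_of_min = percent1(mean(p$min_dist)),
    n_reference_species = nrow(p),
    stringsAsFactors = FALSE
  )))
  out <- out[order(out$genus, out$distribution_group), ]
  rownames(out) <- NULL
  out
}

#' Reshape the genus table into one row per genus
#'
#' @param tab Output of [genus_distribution_table()].
#' @return Data frame with columns `genus`, then `<grp>_min`, `<grp>_avg`
#'   for each of ISL, C1, C2, C3 (`NA` where the cell is empty), mirroring
#'   the wide per-subfamily report layout.
#' @export
genus_table_wide <- function(tab) {
  genera <- sort(unique(tab$genus))
  groups <- c("ISL", "C1", "C2", "C3")
  out <- data.frame(genus = genera, stringsAsFactors = FALSE)
  for (g in groups) {
    i <- match(genera, tab$genus[tab$distribution_group == g])
    sub <- tab[tab$distribution_group == g, , drop = FALSE]
    j <- match(genera, sub$genus)
    out[[paste0(g, "_min")]] <- sub$min_of_min[j]
    out[[paste0(g, "_avg")]] <- sub$avg_of_min[j]
  }
  out
}

#' Leave-one-out sensitivity of the closest-congener statistics
#'
#' Removes every record of one species and recomputes the per-species rows
#' and the genus table, reporting which reference species changed their
#' closest congener or its distance.  Because removing a species can only
#' take candidate congeners away, no remaining species' minimum distance
#' can decrease.
#'
#' @param excluded Species key to remove.
#' @param x A `barcode_alignment`.
#' @param ann Annotation data frame.
#' @param genus_alias Optional genus alias map.
#' @return List with `rows` and `genus_table` (recomputed without the
#'   species) and `delta`: a data frame of reference species whose closest
#'   congener or minimum distance changed, with before/after columns.
#' @export
leave_one_out <- function(excluded, x, ann, genus_alias = NULL) {
  dm0 <- distance_matrix(x)
  before <- congener_stat_table(dm0, x$identity, ann, genus_alias)
  x1 <- drop_species(x, excluded)
  ann1 <- ann[ann$species_key != excluded, , drop = FALSE]
  dm1 <- distance_matrix(x1)
  after <- congener_stat_table(dm1, x1$identity, ann1, genus_alias)
  shared <- intersect(before$reference_species, after$reference_species)
  b <- before[match(shared, before$reference_species), ]
  a <- after[match(shared, after$reference_species), ]
  changed <- b$closest_congener != a$closest_congener |
    abs(b$min_dist - a$min_dist) > 0
  delta <- data.frame(
    reference_species = shared[changed],
    congener_before = b$closest_congener[changed],
    congener_after = a$closest_congener[changed],
    min_dist_before = b$min_dist[changed],
    min_dist_after = a$min_dist[changed],
    stringsAsFactors = FALSE
  )
  list(rows = after, genus_table = genus_distribution_table(after),
       delta = delta,
       dropped_rows = setdiff(before$reference_species,
                              c(shared, excluded)))
}

#' Run the closest-congener pipeline on input files
#'
#' Convenience driver tying the stages together for a curated alignment on
#' disk: read, summarise, QC-screen, compute distances and the per-genus
#' closest-congener tables (optionally restricted to one subfamily).
#'
#' @param alignment_path Aligned FASTA path.
#' @param annotations_path Annotation TSV path.
#' @param subfamily Optional subfamily to restrict the statistics to.
#' @param frame Reading frame for the NUMT screen.
#' @param genus_alias Optional genus alias map.
#' @param scheme Label scheme for [read_alignment()].
#' @return List with `alignment`, `summary`, `qc`, `dm`, `rows`,
#'   `genus_table`.
#' @export
run_congener_pipeline <- function(alignment_path, annotations_path,
                                  subfamily = NULL, frame = 0L,
                                  genus_alias = NULL,
                                  scheme = default_label_scheme()) {
  x <- read_alignment(alignment_path, scheme)
  ann <- read_annotations(annotations_path)
  if (!is.null(subfamily)) {
    ann <- ann[ann$subfamily == subfamily, , drop = FALSE]
    keep <- x$identity$species_key %in% ann$species_key
    x_sub <- subset_alignment(x, keep)
  } else {
    x_sub <- x
  }
  dm <- distance_matrix(x_sub)
  rows <- congener_stat_table(dm, x_sub$identity, ann, genus_alias)
  list(alignment = x,
       summary = dataset_summary(x),
       qc = qc_screen(x, frame = frame),
       dm = dm,
       rows = rows,
       genus_table = genus_distribution_table(rows))
}
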