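#' Configuration for the synthetic barcode-library generator
#'
#' The generator emulates the statistical structure of a curated,
#' genus-structured CO1 barcode release: per genus an ancestral haplotype,
#' species derived from it by independent per-site substitution, specimens
#' derived from each species haplotype the same way, a realistic sampling
#' depth (many singleton species, right-skewed specimen counts) and an
#' annotation table with confidence groups, island flags and distribution
#' ranges.
#'
#' @param seed Integer seed; the whole simulation is determined by it.
#' @param n_genera Number of genera.
#' @param species_per_genus Integer vector sampled from uniformly per
#'   genus.
#' @param singleton_prob Probability that a species is represented by a
#'   single specimen.  The default 0.43, combined with
#'   `specimens_extra_mu`, makes roughly 16% of *sequences* singletons.
#' @param specimens_extra_mu For non-singleton species the specimen count
#'   is `2 + rnbinom(size = 1, mu = specimens_extra_mu)`.
#' @param seq_length Barcode length in nt (default 658, the standard CO1
#'   amplicon).
#' @param intra_divergence Per-site substitution probability specimen vs
#'   its species haplotype.
#' @param inter_divergence Per-site substitution probability species vs
#'   its genus ancestor; the expected p-distance between two congeners is
#'   [expected_pairwise_divergence()] of this.
#' @param confidence_group_probs Probabilities of confidence groups 1-3.
#' @param island_fraction Probability a species is an island taxon.
#' @param range_meanlog,range_sdlog Log-normal parameters of the maximum
#'   distribution extent (km) of continental taxa.
#' @param ambiguity_rate,gap_rate Per-site probability of replacing a
#'   specimen base with `N` / with an alignment gap (default 0: the study
#'   data are pre-aligned full-length barcodes).
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 10L,
                       species_per_genus = 2:8,
                       singleton_prob = 0.43,
                       specimens_extra_mu = 2,
                       seq_length = 658L,
                       intra_divergence = 0.01,
                       inter_divergence = 0.08,
                       confidence_group_probs = c(0.65, 0.20, 0.15),
                       island_fraction = 0.4,
                       range_meanlog = log(150),
                       range_sdlog = 1.2,
                       ambiguity_rate = 0,
                       gap_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_genera = as.integer(n_genera),
              species_per_genus = as.integer(species_per_genus),
              singleton_prob = singleton_prob,
              specimens_extra_mu = specimens_extra_mu,
              seq_length = as.integer(seq_length),
              intra_divergence = intra_divergence,
              inter_divergence = inter_divergence,
              confidence_group_probs = confidence_group_probs,
              island_fraction = island_fraction,
              range_meanlog = range_meanlog, range_sdlog = range_sdlog,
              ambiguity_rate = ambiguity_rate, gap_rate = gap_rate)
  probs <- c(cfg$singleton_prob, cfg$intra_divergence, cfg$inter_divergence,
             cfg$island_fraction, cfg$ambiguity_rate, cfg$gap_rate,
             cfg$confidence_group_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$seq_length <= 0L) stop("seq_length must be positive", call. = FALSE)
  if (cfg$n_genera < 1L) stop("need at least one genus", call. = FALSE)
  if (any(cfg$species_per_genus < 1L)) {
    stop("species_per_genus must be positive", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Expected p-distance between two independently derived sequences
#'
#' When two sequences are derived from a common ancestor by independent
#' per-site substitution with probability `q` (substituting base drawn
#' uniformly from the three alternatives), a site differs between them
#' with probability `2q(1-q) + (2/3)q^2`: exactly one lineage substituted,
#' or both did and picked different bases.  This closed form is what the
#' recovery tests compare estimated congener distances against.
#'
#' @param q Per-site substitution probability per lineage.
#' @return Expected pairwise p-distance.
#' @export
expected_pairwise_divergence <- function(q) {
  2 * q * (1 - q) + (2 / 3) * q^2
}

STOP_CODONS_MITO <- c("TAA", "TAG")

# ancestor drawn codon-wise from the 62 non-stop codons of the
# invertebrate mitochondrial code (frame 0), trailing partial codon uniform
random_coding_chars <- function(len) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS_MITO)
  n_codons <- len %/% 3L
  chars <- unlist(strsplit(sample(codons, n_codons, replace = TRUE), ""),
                  use.names = FALSE)
  c(chars, sample(bases, len - 3L * n_codons, replace = TRUE))
}

# purifying selection on the reading frame: any codon a mutation turned
# into a stop is reverted to the parent's codon
repair_stops <- function(chars, parent_chars, frame = 0L) {
  n_codons <- (length(chars) - frame) %/% 3L
  if (n_codons < 1L) return(chars)
  starts <- frame + (seq_len(n_codons) - 1L) * 3L + 1L
  for (s in starts) {
    codon <- paste(chars[s:(s + 2L)], collapse = "")
    if (codon %in% STOP_CODONS_MITO) {
      chars[s:(s + 2L)] <- parent_chars[s:(s + 2L)]
    }
  }
  chars
}

mutate_sites <- function(seq_chars, rate) {
  n <- length(seq_chars)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      seq_chars[i] <- sample(setdiff(bases, seq_chars[i]), 1L)
    }
  }
  seq_chars
}

spell_index <- function(i) {
  # 1 -> "a", 26 -> "z", 27 -> "aa" ... (lower-case only, scheme-safe)
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Simulate a genus-structured barcode library
#'
#' Per genus an ancestral haplotype is drawn codon-wise without in-frame
#' stop codons (barcodes are protein-coding, so a clean library carries no
#' pseudogene signal); each species substitutes every site independently
#' with probability `inter_divergence`, each specimen substitutes its
#' species haplotype with probability `intra_divergence` (a
#' generation-level Jukes-Cantor scheme chosen for its closed-form
#' expected p-distance, see [expected_pairwise_divergence()]).  Mutations
#' that would create an in-frame stop are reverted, mimicking purifying
#' selection; this biases realised divergence below the closed form by
#' well under one part in fifty, far inside the binomial noise the
#' recovery tests allow.  Labels follow the default label scheme; the
#' annotation table and a truth table with each species' expected congener
#' divergence are generated alongside.
#'
#' @param config A [sim_config()].
#' @return List with `alignment` (a `barcode_alignment`), `annotations`
#'   (data frame as read by [read_annotations()]) and `truth` (per
#'   species: genus, n_specimens, expected divergences).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  subfams <- c("Cryptorhynchinae", "Apioninae", "Ceutorhynchinae")
  seqs <- character(0)
  specimen_counter <- 0L
  ann <- list()
  truth <- list()
  for (g in seq_len(config$n_genera)) {
    genus <- paste0("Genus", spell_index(g))
    subfam <- subfams[(g - 1L) %% 3L + 1L]
    ancestor <- random_coding_chars(config$seq_length)
    n_sp <- if (length(config$species_per_genus) == 1L) {
      config$species_per_genus
    } else {
      sample(config$species_per_genus, 1L)
    }
    for (s in seq_len(n_sp)) {
      epithet <- paste0("taxon", spell_index(s))
      key <- paste(genus, epithet, sep = "_")
      sp_seq <- repair_stops(mutate_sites(ancestor, config$inter_divergence),
                             ancestor)
      n_spec <- if (stats::runif(1) < config$singleton_prob) 1L else {
        2L + stats::rnbinom(1L, size = 1, mu = config$specimens_extra_mu)
      }
      for (k in seq_len(n_spec)) {
        specimen_counter <- specimen_counter + 1L
        chars <- repair_stops(mutate_sites(sp_seq, config$intra_divergence),
                              sp_seq)
        if (config$ambiguity_rate > 0) {
          chars[stats::runif(length(chars)) < config$ambiguity_rate] <- "N"
        }
        if (config$gap_rate > 0) {
          chars[stats::runif(length(chars)) < config$gap_rate] <- "-"
        }
        label <- paste0(genus, "_", epithet, "_",
                        sprintf("%04d-SIM", specimen_counter))
        seqs[label] <- paste(chars, collapse = "")
      }
      ann[[key]] <- data.frame(
        species_key = key, genus = genus, subfamily = subfam,
        confidence_group = sample(1:3, 1L,
                                  prob = config$confidence_group_probs),
        island = stats::runif(1) < config$island_fraction,
        range_km = round(stats::rlnorm(1, config$range_meanlog,
                                       config$range_sdlog)),
        stringsAsFactors = FALSE
      )
      truth[[key]] <- data.frame(
        species_key = key, genus = genus, n_specimens = n_spec,
        expected_congener_divergence =
          expected_pairwise_divergence(config$inter_divergence),
        expected_intraspecific_divergence =
          expected_pairwise_divergence(config$intra_divergence),
        n_congeners = n_sp - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  list(alignment = barcode_alignment(seqs),
       annotations = validate_annotations(do.call(rbind, c(ann, list(make.row.names = FALSE)))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Plant one in-frame stop codon into a record
#'
#' Test fixture for the pseudogene screen: replaces exactly one non-stop
#' codon of the chosen record (in the given frame) with `TAA` and logs the
#' position.
#'
#' @param x A `barcode_alignment` (records assumed ungapped).
#' @param record_id Record label.
#' @param seed Seed for the codon choice.
#' @param frame Reading frame (0, 1 or 2).
#' @return The modified alignment; attribute `"numt_log"` carries
#'   `record_id` and the 0-based `codon_index` replaced.
#' @export
inject_numt <- function(x, record_id, seed = 1L, frame = 0L) {
  if (!record_id %in% names(x$seq)) {
    stop("no such record: ", record_id, call. = FALSE)
  }
  set.seed(seed)
  s <- x$seq[[record_id]]
  n_codons <- (nchar(s) - frame) %/% 3L
  if (n_codons < 1L) stop("record has no complete codon", call. = FALSE)
  starts <- frame + (seq_len(n_codons) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  eligible <- which(!codons %in% c("TAA", "TAG"))
  if (length(eligible) == 0L) stop("record is all stop codons", call. = FALSE)
  pick <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  substr(s, starts[pick], starts[pick] + 2L) <- "TAA"
  x$seq[[record_id]] <- s
  attr(x, "numt_log") <- list(record_id = record_id,
                              codon_index = pick - 1L)
  x
}

#' Simulate a dataset with a planted barcoding gap
#'
#' Draws datasets until every intraspecific distance is at most `g_lo` and
#' every interspecific distance is at least `g_hi`, so a threshold between
#' the two recovers the species exactly by construction.  Used to validate
#' the threshold-sweep machinery.
#'
#' @param config Base [sim_config()]; its divergences should make the gap
#'   likely (defaults here: intra 0.004, inter 0.13).
#' @param g_lo Upper bound for intraspecific distances.
#' @param g_hi Lower bound for interspecific distances.
#' @param max_tries Rejection-sampling budget.
#' @return As [simulate_dataset()], plus `observed` (`max_intra`,
#'   `min_inter`) and the bounds.
#' @export
make_gap_scenario <- function(config = sim_config(intra_divergence = 0.004,
                                                  inter_divergence = 0.13,
                                                  n_genera = 4L,
                                                  species_per_genus = 3L),
                              g_lo = 0.02, g_hi = 0.08, max_tries = 50L) {
  if (g_lo >= g_hi) stop("need g_lo < g_hi", call. = FALSE)
  for (try in seq_len(max_tries)) {
    cfg <- config
    cfg$seed <- config$seed + (try - 1L)
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(ds$alignment)
    same <- outer(ds$alignment$identity$species_key,
                  ds$alignment$identity$species_key, "==")
    off <- upper.tri(dm$d)
    max_intra <- suppressWarnings(max(dm$d[off & same], na.rm = TRUE))
    if (!is.finite(max_intra)) max_intra <- 0
    min_inter <- min(dm$d[off & !same], na.rm = TRUE)
    if (max_intra <= g_lo && min_inter >= g_hi) {
      ds$observed <- list(max_intra = max_intra, min_inter = min_inter)
      ds$g_lo <- g_lo
      ds$g_hi <- g_hi
      return(ds)
    }
  }
  stop("no gapped dataset found in ", max_tries, " tries; ",
       "widen the divergence separation", call. = FALSE)
}
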