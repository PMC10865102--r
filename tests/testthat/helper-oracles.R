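# Brute-force oracles kept deliberately independent of the implementation:
# character-by-character loops, boolean transitive closure, explicit set
# comparison, and Biostrings' genetic-code table for translation.

oracle_pdist <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  plain <- c("A", "C", "G", "T")
  diffs <- 0L
  comp <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% plain && cb[i] %in% plain) {
      comp <- comp + 1L
      if (ca[i] != cb[i]) diffs <- diffs + 1L
    }
  }
  list(distance = if (comp > 0) diffs / comp else NA_real_,
       comparable_sites = comp)
}

# connected components of d <= thr via boolean matrix closure
oracle_components <- function(d, thr) {
  n <- nrow(d)
  reach <- d <= thr
  diag(reach) <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# per-species exact set comparison against MOTUs
oracle_concordance <- function(membership, species) {
  wrong <- character(0)
  for (sp in unique(species)) {
    recs <- which(species == sp)
    motus <- unique(membership[recs])
    ok <- length(motus) == 1L &&
      setequal(which(membership == motus), recs)
    if (!ok) wrong <- c(wrong, sp)
  }
  list(n_wrong_taxa = length(wrong),
       n_wrong_seqs = sum(species %in% wrong),
       wrong_taxa = wrong)
}

# stop positions by explicit per-codon translation with Biostrings' table
oracle_stop_codons <- function(seq, frame, code_id = "5") {
  tab <- Biostrings::getGeneticCode(code_id)
  s <- substring(toupper(seq), frame + 1)
  n <- nchar(s) %/% 3
  out <- integer(0)
  for (k in seq_len(n)) {
    codon <- substr(s, (k - 1) * 3 + 1, (k - 1) * 3 + 3)
    if (!grepl("[^ACGT]", codon) && tab[[codon]] == "*") {
      out <- c(out, k - 1L)
    }
  }
  out
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny alignment builder: named character vector -> barcode_alignment
make_aln <- function(...) {
  barcode_alignment(c(...))
}

# annotation row builder with sensible defaults
make_ann <- function(species_key, genus,
                     subfamily = "Cryptorhynchinae",
                     confidence_group = 1L, island = FALSE,
                     range_km = 100) {
  data.frame(species_key = species_key, genus = genus,
             subfamily = subfamily, confidence_group = confidence_group,
             island = island, range_km = range_km,
             stringsAsFactors = FALSE)
}
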