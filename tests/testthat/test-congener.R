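test_that("distribution groups follow the subfamily-specific cutoffs", {
  expect_equal(assign_distribution_group("Cryptorhynchinae", FALSE, 400), "C2")
  expect_equal(assign_distribution_group("Apioninae", FALSE, 400), "C2")
  expect_equal(assign_distribution_group("Ceutorhynchinae", FALSE, 400), "C2")
  expect_equal(assign_distribution_group("Cryptorhynchinae", FALSE, 600), "C3")
  expect_equal(assign_distribution_group("Apioninae", FALSE, 600), "C2")
  expect_equal(assign_distribution_group("Apioninae", TRUE, 3000), "ISL")
  # boundary convention: "up to" includes the endpoint
  expect_equal(assign_distribution_group("Cryptorhynchinae", FALSE, 50), "C1")
  expect_equal(assign_distribution_group("Cryptorhynchinae", FALSE, 500), "C2")
  expect_equal(assign_distribution_group("Ceutorhynchinae", FALSE, 2000), "C2")
  expect_equal(assign_distribution_group("Ceutorhynchinae", FALSE, 2001), "C3")
  expect_error(assign_distribution_group("Entiminae", FALSE, 100),
               "unsupported")
  # vectorised
  expect_equal(
    assign_distribution_group(rep("Apioninae", 3), c(TRUE, FALSE, FALSE),
                              c(10, 10, 10000)),
    c("ISL", "C1", "C3"))
})

test_that("statistics sets keep group 1 as references, 1+2 as congeners", {
  ann <- rbind(make_ann("Gena_a", "Gena", confidence_group = 1L),
               make_ann("Gena_b", "Gena", confidence_group = 2L),
               make_ann("Gena_c", "Gena", confidence_group = 3L),
               make_ann("Genb_d", "Genb", confidence_group = 1L),
               make_ann("Genb_e", "Genb", confidence_group = 2L),
               make_ann("Genb_f", "Genb", confidence_group = 3L))
  sets <- select_statistics_set(ann)
  expect_setequal(sets$reference_set, c("Gena_a", "Genb_d"))
  expect_setequal(sets$congener_set, c("Gena_a", "Gena_b", "Genb_d", "Genb_e"))
  expect_warning(select_statistics_set(transform(ann, confidence_group = 3L)),
                 "empty")
})

two_genus_fixture <- function() {
  # Gena: three species with staged distances; Genb: far-away singleton pair
  a <- make_aln(
    "Gena_taxona_0001-SIM" = "AAAAAAAAAAAAAAAAAAAA",
    "Gena_taxona_0002-SIM" = "AAAAAAAAAAAAAAAAAAAC",
    "Gena_taxonb_0003-SIM" = "AAAAAAAAAAAAAAAACCCC",
    "Gena_taxonc_0004-SIM" = "AAAAAAAAAACCCCCCCCCC",
    "Genb_taxona_0005-SIM" = "CCCCCCCCCCGGGGGGGGGG",
    "Genb_taxonb_0006-SIM" = "CCCCCCCGGGGGGGGGGGGG")
  ann <- rbind(
    make_ann("Gena_taxona", "Gena", island = TRUE),
    make_ann("Gena_taxonb", "Gena", confidence_group = 2L),
    make_ann("Gena_taxonc", "Gena", range_km = 30),
    make_ann("Genb_taxona", "Genb", range_km = 700),
    make_ann("Genb_taxonb", "Genb", range_km = 700))
  list(a = a, ann = ann)
}

test_that("closest congener is the argmin of species-level minimum distance", {
  fx <- two_genus_fixture()
  dm <- distance_matrix(fx$a)
  sets <- select_statistics_set(fx$ann)
  row <- closest_congener("Gena_taxona", dm, fx$a$identity,
                          sets$congener_set, annotations = fx$ann)
  # nearest record pair: taxona_0002 vs taxonb_0003 at 3/20
  expect_equal(row$closest_congener, "Gena_taxonb")
  expect_equal(row$min_dist, 3 / 20)
  # a group-2 species can be the closest congener but never a reference
  rows <- congener_stat_table(dm, fx$a$identity, fx$ann)
  expect_false("Gena_taxonb" %in% rows$reference_species)
  expect_true("Gena_taxonb" %in% rows$closest_congener)
  # two single-specimen species: distance is the single pair
  rowb <- closest_congener("Genb_taxona", dm, fx$a$identity,
                           sets$congener_set, annotations = fx$ann)
  expect_equal(rowb$min_dist, 3 / 20)
  expect_equal(rowb$closest_congener, "Genb_taxonb")
})

test_that("closest congener equals brute-force argmin on random genera", {
  set.seed(33)
  for (rep in 1:10) {
    ds <- simulate_dataset(sim_config(seed = 400 + rep, n_genera = 1,
                                      species_per_genus = 5, seq_length = 120,
                                      intra_divergence = 0.02,
                                      inter_divergence = 0.06))
    a <- ds$alignment
    dm <- distance_matrix(a)
    keys <- unique(a$identity$species_key)
    ref <- keys[1]
    # oracle: enumerate all cross pairs per candidate species
    cand <- setdiff(keys, ref)
    mins <- sapply(cand, function(sp) {
      ii <- which(a$identity$species_key == ref)
      jj <- which(a$identity$species_key == sp)
      min(dm$d[ii, jj])
    })
    row <- closest_congener(ref, dm, a$identity, keys)
    expect_equal(row$min_dist, min(mins))
    expect_true(row$closest_congener %in% cand[mins == min(mins)])
    expect_equal(row$closest_congener, sort(cand[mins == min(mins)])[1])
  }
})

test_that("ties are retained and reported lexicographically first", {
  a <- make_aln("Gena_taxonc_0001-SIM" = "AAAAAAAAAA",
                "Gena_taxonb_0002-SIM" = "AAAAAAAACC",
                "Gena_taxond_0003-SIM" = "CCAAAAAAAA")
  ann <- rbind(make_ann("Gena_taxonc", "Gena"),
               make_ann("Gena_taxonb", "Gena"),
               make_ann("Gena_taxond", "Gena"))
  dm <- distance_matrix(a)
  row <- closest_congener("Gena_taxonc", dm, a$identity,
                          ann$species_key, annotations = ann)
  expect_equal(row$tied_congeners, c("Gena_taxonb", "Gena_taxond"))
  expect_equal(row$closest_congener, "Gena_taxonb")
})

test_that("genus table aggregates min and mean per distribution cell", {
  # 4 reference species with known minima 2,4,6,8 percent in one cell
  rows <- data.frame(
    reference_species = paste0("Gena_t", 1:4),
    genus = "Gena",
    distribution_group = "C2",
    closest_congener = "Gena_x",
    min_dist = c(0.02, 0.04, 0.06, 0.08),
    min_dist_pct = c(2, 4, 6, 8),
    tied_congeners = "",
    stringsAsFactors = FALSE)
  tab <- genus_distribution_table(rows)
  expect_equal(tab$min_of_min, 2.0)
  expect_equal(tab$avg_of_min, 5.0)
  expect_equal(tab$n_reference_species, 4L)
  # single-species cell: min equals avg
  tab1 <- genus_distribution_table(rows[1, ])
  expect_equal(tab1$min_of_min, tab1$avg_of_min)
  # wide layout carries each cell into its column pair
  rows2 <- rows
  rows2$distribution_group <- c("ISL", "ISL", "C1", "C3")
  wide <- genus_table_wide(genus_distribution_table(rows2))
  expect_equal(wide$ISL_min, 2.0)
  expect_equal(wide$ISL_avg, 3.0)
  expect_equal(wide$C1_min, 6.0)
  expect_true(is.na(wide$C2_min))
})

test_that("cell minimum equals the global minimum over its reference species", {
  ds <- simulate_dataset(sim_config(seed = 21, n_genera = 3,
                                    species_per_genus = 4, seq_length = 150))
  a <- ds$alignment
  dm <- distance_matrix(a)
  rows <- congener_stat_table(dm, a$identity, ds$annotations)
  tab <- genus_distribution_table(rows)
  for (i in seq_len(nrow(tab))) {
    cell <- rows[rows$genus == tab$genus[i] &
                 rows$distribution_group == tab$distribution_group[i], ]
    expect_equal(tab$min_of_min[i], percent1(min(cell$min_dist)))
    expect_equal(tab$avg_of_min[i], percent1(mean(cell$min_dist)))
    expect_lte(tab$min_of_min[i], tab$avg_of_min[i])
  }
})

test_that("genus aliases pool congeners across merged genera", {
  a <- make_aln("Gena_taxona_0001-SIM" = "AAAAAAAAAA",
                "Genb_taxonb_0002-SIM" = "AAAAAAAACC")
  ann <- rbind(make_ann("Gena_taxona", "Gena"),
               make_ann("Genb_taxonb", "Genb"))
  dm <- distance_matrix(a)
  rows0 <- congener_stat_table(dm, a$identity, ann)
  expect_equal(nrow(rows0), 0L)  # different genera: no congener
  alias <- c(Gena = "GenaGenb", Genb = "GenaGenb")
  rows1 <- congener_stat_table(dm, a$identity, ann, genus_alias = alias)
  expect_equal(nrow(rows1), 2L)
  expect_equal(rows1$min_dist, c(0.2, 0.2))
})

test_that("leave-one-out recomputes rows and never decreases any minimum", {
  fx <- two_genus_fixture()
  # removing Gena_taxonb (closest to taxona): taxona's min rises to taxonc
  loo <- leave_one_out("Gena_taxonb", fx$a, fx$ann)
  expect_true("Gena_taxona" %in% loo$delta$reference_species)
  d <- loo$delta[loo$delta$reference_species == "Gena_taxona", ]
  expect_equal(d$congener_before, "Gena_taxonb")
  expect_equal(d$congener_after, "Gena_taxonc")
  expect_equal(d$min_dist_after, 9 / 20)
  expect_gte(d$min_dist_after, d$min_dist_before)
  # removing a species that is nobody's closest congener: empty delta
  loo2 <- leave_one_out("Genb_taxona", fx$a, fx$ann)
  expect_equal(nrow(loo2$delta), 0L)

  # property: across simulated datasets no remaining minimum decreases
  ds <- simulate_dataset(sim_config(seed = 77, n_genera = 2,
                                    species_per_genus = 4, seq_length = 120))
  before <- congener_stat_table(distance_matrix(ds$alignment),
                                ds$alignment$identity, ds$annotations)
  expect_gte(nrow(before), 2)
  for (sp in utils::head(unique(before$closest_congener), 3)) {
    loo3 <- leave_one_out(sp, ds$alignment, ds$annotations)
    shared <- intersect(before$reference_species,
                        loo3$rows$reference_species)
    b <- before$min_dist[match(shared, before$reference_species)]
    a2 <- loo3$rows$min_dist[match(shared, loo3$rows$reference_species)]
    expect_true(all(a2 >= b - 1e-12))
  }
})
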