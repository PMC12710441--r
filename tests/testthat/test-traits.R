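mk_traits <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

base_traits <- mk_traits(
  species_id = c("a", "b", "c", "d"),
  genus = c("G1", "G1", "G1", "G2"),
  family = c("F1", "F1", "F1", "F1"),
  WD = c(0.62, 0.5, NA, NA)
)

base_stems <- tiny_stems(data.frame(
  plot_id = "P1", life_stage = "adult",
  species_id = c("a", "c", "d"), genus = c("G1", "G1", "G2"),
  family = "F1", n = c(1, 1, 1), stringsAsFactors = FALSE))

test_that("imputation walks species -> genus -> family with correct values", {
  imp <- impute_trait(base_stems, base_traits, "WD")
  a <- imp$assignments
  expect_equal(a$value[a$species_id == "a"], 0.62) # direct species hit
  expect_equal(as.character(a$provenance[a$species_id == "a"]), "species")
  # species c: mean of congeneric species-level values {0.62, 0.5}
  expect_equal(a$value[a$species_id == "c"], 0.56)
  expect_equal(as.character(a$provenance[a$species_id == "c"]), "genus")
  # species d: no congener with data -> family mean
  expect_equal(a$value[a$species_id == "d"], 0.56)
  expect_equal(as.character(a$provenance[a$species_id == "d"]), "family")
})

test_that("genus means average species, not stems", {
  traits <- mk_traits(species_id = c("a", "b", "x"), genus = "G1",
                      family = "F1", WD = c(0.5, 0.7, NA))
  # species a very abundant: 10 stems; must not tilt the genus mean
  stems <- tiny_stems(data.frame(plot_id = "P1", life_stage = "adult",
                                 species_id = c("a", "b", "x"), genus = "G1",
                                 family = "F1", n = c(10, 1, 1),
                                 stringsAsFactors = FALSE))
  imp <- impute_trait(stems, traits, "WD")
  expect_equal(unique(imp$assignments$value[imp$assignments$species_id == "x"]),
               0.6)
})

test_that("coverage fractions sum to 1 and count stems", {
  imp <- impute_trait(base_stems, base_traits, "WD")
  expect_equal(sum(imp$coverage), 1)
  expect_equal(unname(imp$coverage["species"]), 1 / 3)
})

test_that("imputation is idempotent on a complete table", {
  traits <- mk_traits(species_id = c("a", "b"), genus = "G1", family = "F1",
                      WD = c(0.4, 0.8))
  stems <- tiny_stems(data.frame(plot_id = "P1", life_stage = "adult",
                                 species_id = c("a", "b"), genus = "G1",
                                 family = "F1", n = c(2, 2),
                                 stringsAsFactors = FALSE))
  imp1 <- impute_trait(stems, traits, "WD")
  expect_true(all(imp1$assignments$provenance == "species"))
  # feed the imputed values back in: nothing changes
  traits2 <- traits
  traits2$WD <- imp1$assignments$value[match(traits2$species_id,
                                             imp1$assignments$species_id)]
  imp2 <- impute_trait(stems, traits2, "WD")
  expect_equal(imp1$assignments$value, imp2$assignments$value)
})

test_that("removing the only congeneric donor demotes dependent stems", {
  imp_before <- impute_trait(base_stems, base_traits, "WD")
  traits2 <- base_traits
  traits2$WD[traits2$species_id %in% c("a", "b")] <- c(0.62, NA)
  imp_after <- impute_trait(base_stems, traits2, "WD")
  # c was genus-imputed from {a, b}; with b gone it still has donor a
  expect_equal(as.character(
    imp_after$assignments$provenance[imp_after$assignments$species_id == "c"]),
    "genus")
  traits3 <- base_traits
  traits3$WD <- c(NA, NA, NA, NA)
  traits3$WD[4] <- 0.7 # only species d (other genus) retains a value
  imp_none <- impute_trait(base_stems, traits3, "WD")
  a <- imp_none$assignments
  expect_equal(as.character(a$provenance[a$species_id == "c"]), "family")
})

test_that("stems without a family cap at genus-level provenance", {
  stems <- tiny_stems(data.frame(plot_id = "P1", life_stage = "adult",
                                 species_id = "c", genus = "G9", family = NA,
                                 n = 1, stringsAsFactors = FALSE))
  imp <- impute_trait(stems, base_traits, "WD")
  expect_equal(as.character(imp$assignments$provenance), "missing")
})

test_that("seed-limitation classification follows SL-first strict thresholds", {
  expect_equal(classify_seed_limitation(50, 5),
               data.frame(limited = TRUE, rule_used = "SL>18mm",
                          stringsAsFactors = FALSE))
  expect_false(classify_seed_limitation(18.0, NA)$limited) # strict boundary
  out <- classify_seed_limitation(NA, 13)
  expect_true(out$limited)
  expect_equal(out$rule_used, "SW>12mm")
  expect_false(classify_seed_limitation(NA, 12.0)$limited)
  expect_error(classify_seed_limitation(NA_real_, NA_real_), "at least one")
})

test_that("limited-species counts are over species, not stems", {
  traits <- mk_traits(
    species_id = c("a", "a", "b", "c", "d"),
    dispersal_mode = c("endozoochory", "endozoochory", "endozoochory",
                       "abiotic", "endozoochory"),
    SL = c(30, 30, 10, 99, NA), SW = c(NA, NA, NA, NA, NA))
  out <- count_limited_species(traits)
  expect_equal(out$n_limited, 1L)       # only a (duplicated row counts once)
  expect_equal(out$n_endozoochorous, 2L) # d unclassifiable, c not endo
  expect_equal(out$fraction, 0.5)
})

test_that("limited-species edge cases: empty guild and saturated threshold", {
  none <- count_limited_species(mk_traits(species_id = "x",
                                          dispersal_mode = "abiotic",
                                          SL = 30, SW = NA))
  expect_equal(none$n_limited, 0L)
  expect_true(is.na(none$fraction))
  sat <- count_limited_species(mk_traits(species_id = c("x", "y"),
                                         dispersal_mode = "endozoochory",
                                         SL = c(30, 30), SW = NA))
  expect_equal(sat$fraction, 1)
})
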