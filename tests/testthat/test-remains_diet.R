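rec <- function(taxon, group, kind = "bone", marks = FALSE, color = NA,
                len = NA, nest = "N1", year = 2012, element = NA, side = NA,
                count = 1L, moment = "during_breeding") {
  data.frame(nest_id = nest, year = year, sampling_moment = moment,
             taxon = taxon, taxon_group = group, item_kind = kind,
             element = as.character(element), side = as.character(side),
             butchery_marks = marks, hair_color = as.character(color),
             hair_length_class = as.character(len), count = count,
             stringsAsFactors = FALSE)
}

test_that("origin-assignment rule cascade matches the published rules", {
  cases <- rbind(
    rec("sheep", "ungulate", marks = TRUE),                        # landfill
    rec("sheep", "ungulate", marks = FALSE),                       # livestock
    rec("rabbit", "small_medium_vertebrate", marks = TRUE),        # landfill
    rec("rabbit", "small_medium_vertebrate"),                      # wild herb
    rec("rabbit", "small_medium_vertebrate", kind = "hair",
        color = "white"),                                          # livestock
    rec("rabbit", "small_medium_vertebrate", kind = "hair",
        color = "brown", len = "wild_long"),                       # wild herb
    rec("rabbit", "small_medium_vertebrate", kind = "hair",
        color = "brown", len = "domestic_short"),                  # livestock
    rec("rabbit", "small_medium_vertebrate", kind = "hair",
        color = "brown"),                                          # undetermined
    rec("boar", "ungulate", kind = "hair", color = "black"),       # wild herb
    rec("pig_domestic", "ungulate", kind = "hair", color = "white"), # undet.
    rec("fox", "carnivore"),                                       # carnivores
    rec("pigeon", "bird"),                                         # birds
    rec("vole", "other"),                                          # others
    rec("beetle", "invertebrate"),                                 # others
    rec("lizard", "small_medium_vertebrate"))                      # others
  expect_equal(classify_remains(cases),
               c("landfill", "livestock", "landfill", "wild_herbivores",
                 "livestock", "wild_herbivores", "livestock", "undetermined",
                 "wild_herbivores", "undetermined", "carnivores", "birds",
                 "others", "others", "others"))
})

test_that("classification is total, deterministic and order-independent", {
  set.seed(11)
  st <- simulate_study(simulation_config(seed = 11))
  cats <- classify_remains(st$remains)
  expect_true(all(cats %in% c(REMAINS_CATEGORIES, "undetermined")))
  perm <- sample(nrow(st$remains))
  expect_equal(classify_remains(st$remains[perm, ]), cats[perm])
  bad <- rec("x", "mystery_group")
  expect_error(classify_remains(bad), "taxon_group")
})

test_that("distal limb parts of one limb collapse to one skeletal fragment", {
  limb <- rbind(
    rec("fox", "carnivore", kind = "distal_limb_part", element = "tarsus",
        side = "left"),
    rec("fox", "carnivore", kind = "distal_limb_part", element = "metatarsus",
        side = "left"),
    rec("fox", "carnivore", kind = "distal_limb_part", element = "digits",
        side = "left"))
  counts <- count_items(limb)
  expect_equal(counts$carnivores, 1)
  # a fourth distal element on the same side starts a second fragment
  limb2 <- rbind(limb, rec("fox", "carnivore", kind = "distal_limb_part",
                           element = "tarsus", side = "left"))
  expect_equal(count_items(limb2)$carnivores, 2)
  # but a different limb (other side) is its own fragment
  limb3 <- rbind(limb, rec("fox", "carnivore", kind = "distal_limb_part",
                           element = "tarsus", side = "right"))
  expect_equal(count_items(limb3)$carnivores, 2)
  # plain bones count one fragment each; skull fragments are pre-collapsed
  bones <- rbind(rec("deer", "ungulate", element = "femur"),
                 rec("deer", "ungulate", element = "rib"),
                 rec("deer", "ungulate", kind = "skull_fragment",
                     element = "skull"))
  expect_equal(count_items(bones)$wild_herbivores, 3)
})

test_that("MNI uses the most frequent diagnostic element", {
  mand <- rbind(
    rec("rabbit", "small_medium_vertebrate", element = "mandible",
        side = "left", count = 5L),
    rec("rabbit", "small_medium_vertebrate", element = "mandible",
        side = "right", count = 3L))
  expect_equal(count_items(mand)$wild_herbivores, 5)
  # a single occurrence still counts one individual
  single <- rec("lizard", "other", element = NA)
  expect_equal(count_items(single)$others, 1)
})

test_that("both sampling moments of a nest-year pool into one observation", {
  recs <- rbind(
    rec("sheep", "ungulate", marks = TRUE, moment = "during_breeding"),
    rec("sheep", "ungulate", marks = TRUE, moment = "post_breeding"),
    rec("pigeon", "bird", moment = "post_breeding"))
  counts <- count_items(recs)
  expect_equal(nrow(counts), 1)
  expect_equal(counts$landfill, 2)
  expect_equal(counts$birds, 1)
  expect_equal(counts$total, 3)
})

test_that("counting never exceeds raw record multiplicity and ignores order", {
  set.seed(21)
  st <- simulate_study(simulation_config(seed = 21))
  counts <- count_items(st$remains)
  raw <- table(paste(st$remains$nest_id, st$remains$year))
  for (r in seq_len(nrow(counts))) {
    expect_lte(counts$total[r],
               raw[[paste(counts$nest_id[r], counts$year[r])]])
  }
  perm <- sample(nrow(st$remains))
  counts2 <- count_items(st$remains[perm, ])
  expect_equal(counts2, counts)
})

test_that("diet_proportions divides, renormalizes and flags", {
  counts <- data.frame(nest_id = "N1", year = 2012, landfill = 10,
                       livestock = 10, wild_herbivores = 10, carnivores = 10,
                       birds = 10, others = 0)
  p5 <- diet_proportions(counts, exclude_others = TRUE)
  expect_equal(unlist(p5[, DIET_CATEGORIES], use.names = FALSE), rep(0.2, 5))
  counts2 <- data.frame(nest_id = "N1", year = 2012, landfill = 5,
                        livestock = 0, wild_herbivores = 0, carnivores = 0,
                        birds = 0, others = 5)
  p <- diet_proportions(counts2, exclude_others = TRUE)
  expect_equal(p$landfill, 1)
  p6 <- diet_proportions(data.frame(nest_id = "N1", year = 2012, landfill = 3,
                                    livestock = 2, wild_herbivores = 1,
                                    carnivores = 1, birds = 1, others = 2),
                         exclude_others = FALSE)
  expect_equal(unlist(p6[, REMAINS_CATEGORIES], use.names = FALSE),
               c(0.3, 0.2, 0.1, 0.1, 0.1, 0.2))
  expect_equal(rowSums(p6[, REMAINS_CATEGORIES]), 1)
  # zero-total nest-years are dropped with a warning
  z <- rbind(counts2, data.frame(nest_id = "N2", year = 2012, landfill = 0,
                                 livestock = 0, wild_herbivores = 0,
                                 carnivores = 0, birds = 0, others = 3))
  expect_warning(pz <- diet_proportions(z, exclude_others = TRUE), "zero")
  expect_equal(nrow(pz), 1)
})

test_that("population summary is mean/SD of per-nest proportions", {
  props <- data.frame(nest_id = c("A", "B"), year = 2012,
                      landfill = c(0.1, 0.3), livestock = c(0.4, 0.2),
                      wild_herbivores = c(0.2, 0.2), carnivores = c(0.2, 0.2),
                      birds = c(0.1, 0.1))
  out <- population_conventional_summary(props)
  lf <- out[out$category == "landfill", ]
  expect_equal(lf$mean_pct, 20)
  expect_equal(lf$sd_pct, 100 * sd(c(0.1, 0.3)))
  # brute-force check on a synthetic table
  set.seed(31)
  st <- simulate_study(simulation_config(seed = 31))
  pr <- diet_proportions(count_items(st$remains))
  out <- population_conventional_summary(pr)
  for (cat in DIET_CATEGORIES) {
    expect_equal(out$mean_pct[out$category == cat], 100 * mean(pr[[cat]]))
    expect_equal(out$sd_pct[out$category == cat], 100 * sd(pr[[cat]]))
  }
})
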