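#' Taxa lookup tables for the origin-assignment rules
#'
#' Keyword sets used by [classify_remains()] to resolve a record's taxon
#' to an origin.  `livestock_taxa` are domestic ungulates and farmed
#' animals whose unbutchered remains are read as extensive-livestock
#' carcasses; `wild_herbivore_taxa` are wild herbivores (rabbit, boar,
#' deer and kin); `pig_family_taxa` trigger the hair-colour rule that
#' separates wild boar from domestic pig.
#'
#' @name remains_taxa
#' @export
livestock_taxa <- c("sheep", "goat", "cattle", "cow", "horse", "donkey",
                    "pig_domestic", "chicken_farm")

#' @rdname remains_taxa
#' @export
wild_herbivore_taxa <- c("rabbit", "hare", "boar", "wild_boar", "deer",
                         "roe_deer", "ibex", "chamois")

#' @rdname remains_taxa
#' @export
pig_family_taxa <- c("pig", "boar", "wild_boar", "pig_domestic")

#' Classify food remains into diet categories
#'
#' Deterministic rule cascade assigning each identified remain to one of
#' `landfill`, `livestock`, `wild_herbivores`, `carnivores`, `birds`,
#' `others` or `undetermined`:
#'
#' 1. Cut bones, or bones with butchery or cooking traces, of livestock
#'    taxa — or of rabbit/boar, otherwise read as wild individuals — are
#'    assumed to come from landfills.
#' 2. Rabbit hair: white is domestic (livestock; there are no white wild
#'    rabbits); brown is resolved by hair length class (`wild_long` ->
#'    wild herbivores, `domestic_short` -> livestock), and is
#'    undetermined when the length class is missing.
#' 3. Pig-family hair: black is wild boar (no black domestic pigs in the
#'    study system); other colours are undetermined.
#' 4. Unmarked remains of livestock taxa -> livestock; of wild-herbivore
#'    taxa -> wild herbivores.
#' 5. Carnivore taxa -> carnivores; bird taxa -> birds; invertebrates,
#'    micro-mammals, reptiles, amphibians and fish -> others.
#' 6. Anything unresolved -> undetermined.
#'
#' @param records data frame with columns `taxon`, `taxon_group` (one of
#'   `invertebrate`, `small_medium_vertebrate`, `carnivore`, `ungulate`,
#'   `bird`, `other`), `item_kind`, `butchery_marks` (logical), and
#'   optional `hair_color`, `hair_length_class` (used only when
#'   `item_kind == "hair"`).
#' @return character vector of categories, one per record.
#' @export
classify_remains <- function(records) {
  check_columns(records, c("taxon", "taxon_group", "item_kind", "butchery_marks"),
                "remains table")
  groups <- c("invertebrate", "small_medium_vertebrate", "carnivore",
              "ungulate", "bird", "other")
  bad <- !(records$taxon_group %in% groups)
  if (any(bad))
    stop_input("unknown taxon_group: ",
               paste(unique(records$taxon_group[bad]), collapse = ", "))
  hair_color <- records$hair_color %||% rep(NA_character_, nrow(records))
  hair_len <- records$hair_length_class %||% rep(NA_character_, nrow(records))
  taxon <- tolower(as.character(records$taxon))
  n <- nrow(records)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    out[i] <- classify_one(taxon[i], records$taxon_group[i],
                           records$item_kind[i],
                           isTRUE(records$butchery_marks[i]),
                           hair_color[i], hair_len[i])
  }
  out
}

classify_one <- function(taxon, group, kind, marked, color, len_class) {
  is_bone <- kind %in% c("bone", "skull_fragment", "distal_limb_part", "whole")
  # butchery/cooking traces mark landfill origin for livestock taxa and
  # for rabbit/boar (which are otherwise read as wild individuals)
  butchery_applies <- group == "ungulate" ||
    taxon %in% c(livestock_taxa, "rabbit", "hare", "boar", "wild_boar")
  if (marked && is_bone && butchery_applies) return("landfill")
  if (kind == "hair") {
    if (taxon %in% c("rabbit", "hare")) {
      if (identical(color, "white")) return("livestock")
      if (identical(color, "brown")) {
        if (identical(len_class, "wild_long")) return("wild_herbivores")
        if (identical(len_class, "domestic_short")) return("livestock")
      }
      return("undetermined")
    }
    if (taxon %in% pig_family_taxa) {
      if (identical(color, "black")) return("wild_herbivores")
      return("undetermined")
    }
    # other hair falls through to the taxon rules
  }
  if (group == "carnivore") return("carnivores")
  if (group == "bird") {
    if (taxon %in% livestock_taxa) return("livestock") # farmed poultry
    return("birds")
  }
  if (group %in% c("invertebrate", "other")) return("others")
  if (taxon %in% livestock_taxa) return("livestock")
  if (taxon %in% wild_herbivore_taxa) return("wild_herbivores")
  if (group == "small_medium_vertebrate") return("others")
  "undetermined"
}

#' Count classified remains per nest-year and category
#'
#' Applies the field's counting rules:
#' * invertebrates and small/medium vertebrates are counted as a minimum
#'   number of individuals (MNI) per (nest-year, taxon, category): the
#'   maximum total count over diagnostic (element, side) combinations,
#'   with a floor of one individual per occurring taxon;
#' * carnivores and ungulates are counted as skeletal fragments: the
#'   three distal limb parts of one limb (tarsus/carpus, metatarsus/
#'   metacarpus, digits) collapse to a single fragment (grouped by nest,
#'   year, taxon and side; `ceiling(elements / 3)` fragments), as do
#'   connected skull bones (one fragment per `skull_fragment` record);
#' * the two sampling moments (during and after breeding) of one
#'   nest-year pool into a single observation.
#'
#' @param records remains data frame (columns as in [classify_remains()]
#'   plus `nest_id`, `year`, and optional `element`, `side`, `count`).
#' @param category optional pre-computed classification; defaults to
#'   `classify_remains(records)`.
#' @param drop_undetermined drop `undetermined` records before counting
#'   (default `TRUE`; the reported scheme has six categories only).
#' @return data frame, one row per (nest_id, year), with one integer
#'   column per category in [REMAINS_CATEGORIES] and a `total` column.
#' @export
count_items <- function(records, category = NULL, drop_undetermined = TRUE) {
  check_columns(records, c("nest_id", "year"), "remains table")
  if (is.null(category)) category <- classify_remains(records)
  stopifnot(length(category) == nrow(records))
  records$category <- category
  if (drop_undetermined)
    records <- records[records$category != "undetermined", , drop = FALSE]
  records$count <- records$count %||% rep(1L, nrow(records))
  records$count[is.na(records$count)] <- 1L
  records$element <- as.character(records$element %||% rep(NA, nrow(records)))
  records$side <- as.character(records$side %||% rep(NA, nrow(records)))
  records$element[is.na(records$element)] <- "unspecified"
  records$side[is.na(records$side)] <- "unspecified"

  nest_years <- unique(records[, c("nest_id", "year")])
  nest_years <- nest_years[order(nest_years$nest_id, nest_years$year), ,
                           drop = FALSE]
  fragment_groups <- c("carnivore", "ungulate")
  distal <- c("distal_limb_part", "tarsus", "carpus", "metatarsus",
              "metacarpus", "digits")
  rows <- lapply(seq_len(nrow(nest_years)), function(r) {
    sub <- records[records$nest_id == nest_years$nest_id[r] &
                     records$year == nest_years$year[r], , drop = FALSE]
    counts <- setNames(integer(length(REMAINS_CATEGORIES)), REMAINS_CATEGORIES)
    for (cat in unique(sub$category)) {
      if (!cat %in% REMAINS_CATEGORIES) next
      sc <- sub[sub$category == cat, , drop = FALSE]
      total <- 0L
      for (tx in unique(sc$taxon)) {
        st <- sc[sc$taxon == tx, , drop = FALSE]
        if (st$taxon_group[1] %in% fragment_groups) {
          total <- total + count_fragments(st)
        } else {
          total <- total + count_mni(st)
        }
      }
      counts[cat] <- total
    }
    cbind(data.frame(nest_id = nest_years$nest_id[r],
                     year = nest_years$year[r], stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  out <- do.call(rbind, rows)
  out$total <- rowSums(out[, REMAINS_CATEGORIES, drop = FALSE])
  rownames(out) <- NULL
  out
}

# MNI: max over (element, side) of summed counts, at least 1
count_mni <- function(st) {
  key <- paste(st$element, st$side)
  max(1L, max(tapply(st$count, key, sum)))
}

# Skeletal fragments: distal limb parts of one limb (same side) collapse
# three elements to one fragment; other bone records count one fragment
# each (skull_fragment records already represent connected bones).
count_fragments <- function(st) {
  is_distal <- st$item_kind == "distal_limb_part" |
    st$element %in% c("tarsus", "carpus", "metatarsus", "metacarpus", "digits")
  frags <- 0L
  if (any(is_distal)) {
    d <- st[is_distal, , drop = FALSE]
    per_limb <- tapply(d$count, d$side, sum)
    frags <- frags + sum(ceiling(per_limb / 3))
  }
  rest <- st[!is_distal, , drop = FALSE]
  frags + sum(rest$count)
}

#' Diet proportions from category counts
#'
#' @param counts output of [count_items()].
#' @param exclude_others drop the `others` category and renormalize over
#'   the five isotope-model categories (default `TRUE`, matching the
#'   five-source mixing model which has no `others` source).
#' @return data frame, one row per nest-year with per-category
#'   proportions summing to 1 and a `others_excluded` flag.  Nest-years
#'   with zero total (after exclusion) are dropped with a warning.
#' @export
diet_proportions <- function(counts, exclude_others = TRUE) {
  cats <- if (exclude_others) DIET_CATEGORIES else REMAINS_CATEGORIES
  check_columns(counts, c("nest_id", "year", cats), "counts table")
  tot <- rowSums(counts[, cats, drop = FALSE])
  if (any(tot == 0)) {
    warning(sprintf("dropping %d nest-year(s) with zero countable items",
                    sum(tot == 0)))
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(counts) == 0) stop_input("no nest-years with positive counts")
  props <- sweep(counts[, cats, drop = FALSE], 1, tot, "/")
  out <- cbind(counts[, c("nest_id", "year"), drop = FALSE], props)
  out$others_excluded <- exclude_others
  rownames(out) <- NULL
  out
}

#' Population-level conventional diet summary
#'
#' Arithmetic mean and SD across nest-years of the per-nest-year diet
#' proportions (not of pooled counts), reported as percentages — the
#' standard per-nest summary whose SD measures between-nest spread.
#'
#' @param props output of [diet_proportions()].
#' @return data frame with columns `category`, `mean_pct`, `sd_pct`.
#' @export
population_conventional_summary <- function(props) {
  cats <- intersect(REMAINS_CATEGORIES, names(props))
  rows <- lapply(cats, function(cat) {
    v <- props[[cat]]
    data.frame(category = cat, mean_pct = 100 * mean(v),
               sd_pct = if (length(v) > 1) 100 * sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname io_read
#' @export
read_remains <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("nest_id", "year", "taxon", "taxon_group",
                      "item_kind", "butchery_marks"), "remains table")
  if (is.character(df$butchery_marks))
    df$butchery_marks <- toupper(df$butchery_marks) %in% c("TRUE", "T", "1", "YES")
  df
}
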