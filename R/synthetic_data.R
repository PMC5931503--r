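#' Configuration for a synthetic vulture-diet study
#'
#' The defaults mirror the scale of a NE-Iberian Egyptian Vulture
#' monitoring study: 19 breeding territories followed over 2012--2015,
#' one to two sampled nestlings per successful nest-year, feather
#' isotopes generated from the five-source geometry of
#' [default_sources()] with the [default_tef()] enrichment, and prey
#' remains collected in 2012--2014 only (as in the field campaign), at
#' about 46 identifiable items per nest-year.
#'
#' True diet proportions are Dirichlet-distributed per nest-year.
#' `detectability_bias` multiplies each category's chance of appearing
#' among remains (e.g. `c(1, 2, 1, 1, 1)` mimics over-detection of
#' large, persistent livestock bones); `ambiguous_rate` converts a
#' random fraction of items into records the rule cascade cannot resolve
#' (undetermined); `others_rate` adds items outside the five modelled
#' sources.
#'
#' @param n_territories number of breeding territories (default 19).
#' @param years sampled years (default 2012:2015).
#' @param p_sampled probability a territory yields a successful,
#'   sampled nest in a given year (default 0.5).
#' @param siblings_range inclusive range of sampled chicks per nest
#'   (default c(1, 2)).
#' @param dirichlet_alpha Dirichlet concentration for true diet
#'   proportions (default rep(1, 5), uniform on the simplex).
#' @param sources a [source_spec()] (default [default_sources()]).
#' @param tef a [tef_spec()] (default [default_tef()]).
#' @param residual_sd per-isotope residual SD in permil beyond source and
#'   TEF spread (default c(0.5, 0.5): measurement error plus
#'   within-category ecological variation).
#' @param remains_per_nest Poisson mean of identifiable items per
#'   nest-year (default 46).
#' @param detectability_bias length-5 positive multipliers (default 1s).
#' @param others_rate fraction of items outside the five sources
#'   (default 0.05).
#' @param ambiguous_rate fraction of items that classify to
#'   undetermined (default 0.05).
#' @param remains_years years with remains collections (default
#'   2012:2014).
#' @param seed master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_territories = 19L, years = 2012:2015,
                              p_sampled = 0.5, siblings_range = c(1L, 2L),
                              dirichlet_alpha = rep(1, 5),
                              sources = default_sources(),
                              tef = default_tef(),
                              residual_sd = c(0.5, 0.5),
                              remains_per_nest = 46,
                              detectability_bias = rep(1, 5),
                              others_rate = 0.05, ambiguous_rate = 0.05,
                              remains_years = 2012:2014,
                              seed = 1L) {
  stopifnot(length(dirichlet_alpha) == nrow(sources),
            all(dirichlet_alpha > 0),
            length(detectability_bias) == nrow(sources),
            all(detectability_bias > 0),
            length(residual_sd) == 2, all(residual_sd >= 0),
            others_rate >= 0, others_rate < 1,
            ambiguous_rate >= 0, ambiguous_rate < 1,
            p_sampled > 0, p_sampled <= 1)
  structure(list(n_territories = as.integer(n_territories), years = years,
                 p_sampled = p_sampled,
                 siblings_range = as.integer(siblings_range),
                 dirichlet_alpha = dirichlet_alpha, sources = sources,
                 tef = tef, residual_sd = residual_sd,
                 remains_per_nest = remains_per_nest,
                 detectability_bias = detectability_bias,
                 others_rate = others_rate, ambiguous_rate = ambiguous_rate,
                 remains_years = remains_years, seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Draw true diet proportions for every sampled nest-year
#'
#' Per nest-year, p ~ Dirichlet(alpha).  Which territory-years are
#' sampled is itself random (probability `p_sampled`), with at least one
#' nest-year guaranteed.  Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return data frame of class `ground_truth`: `territory_id`, `year`,
#'   and `true_<category>` columns summing to 1 per row.
#' @export
simulate_diet_proportions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1))
  grid <- expand.grid(territory_id = sprintf("T%02d", seq_len(config$n_territories)),
                      year = config$years, stringsAsFactors = FALSE)
  grid <- grid[order(grid$territory_id, grid$year), , drop = FALSE]
  keep <- runif(nrow(grid)) < config$p_sampled
  if (!any(keep)) keep[1] <- TRUE
  grid <- grid[keep, , drop = FALSE]
  p <- rdirichlet(nrow(grid), config$dirichlet_alpha)
  colnames(p) <- paste0("true_", config$sources$name)
  out <- cbind(grid, as.data.frame(p))
  rownames(out) <- NULL
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Generate feather isotope samples from ground truth
#'
#' For each nest-year, draws the number of sampled siblings uniformly
#' from `siblings_range` and, per sibling and isotope j, a value from
#' \deqn{N\!\Big(\sum_k p_k(\mu_{kj}+\mu_{TEF,j}),\;
#'   \sum_k p_k^2(\sigma_{kj}^2+\sigma_{TEF,j}^2) + \tau_j^2\Big)}
#' — the exact generative model the mixing model inverts.
#'
#' @param truth a `ground_truth` from [simulate_diet_proportions()].
#' @param config the same [simulation_config()].
#' @return data frame of feather samples (`territory_id`, `year`,
#'   `delta13C`, `delta15N`), one row per sibling.
#' @export
simulate_consumers <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2))
  P <- as.matrix(truth[, paste0("true_", config$sources$name)])
  mu <- cbind(config$sources$mu13C + config$tef$mu13C,
              config$sources$mu15N + config$tef$mu15N)
  sd2 <- cbind(config$sources$sd13C^2 + config$tef$sd13C^2,
               config$sources$sd15N^2 + config$tef$sd15N^2)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    n_sib <- if (config$siblings_range[1] == config$siblings_range[2])
      config$siblings_range[1]
    else sample(seq(config$siblings_range[1], config$siblings_range[2]), 1)
    m <- as.vector(P[i, ] %*% mu)
    v <- as.vector(P[i, ]^2 %*% sd2) + config$residual_sd^2
    data.frame(territory_id = truth$territory_id[i], year = truth$year[i],
               delta13C = rnorm(n_sib, m[1], sqrt(v[1])),
               delta15N = rnorm(n_sib, m[2], sqrt(v[2])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Record templates per intended category: attributes are chosen so the
# rule cascade maps each record back to its generating category and each
# record counts as exactly one item under the counting rules.
remain_templates <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(category = "landfill", taxon = c("sheep", "cattle", "pig_domestic"),
       taxon_group = "ungulate", item_kind = "bone", butchery_marks = TRUE,
       hair_color = NA, hair_length_class = NA,
       element = c("femur", "rib", "vertebra"), side = NA),
    df(category = "livestock",
       taxon = c("sheep", "goat", "cattle", "rabbit"),
       taxon_group = c(rep("ungulate", 3), "small_medium_vertebrate"),
       item_kind = c(rep("bone", 3), "hair"), butchery_marks = FALSE,
       hair_color = c(NA, NA, NA, "white"),
       hair_length_class = c(NA, NA, NA, "domestic_short"),
       element = c("femur", "humerus", "rib", "hair"), side = NA),
    df(category = "wild_herbivores", taxon = c("rabbit", "boar", "deer"),
       taxon_group = c("small_medium_vertebrate", "ungulate", "ungulate"),
       item_kind = c("bone", "hair", "bone"), butchery_marks = FALSE,
       hair_color = c(NA, "black", NA), hair_length_class = NA,
       element = c("mandible", "hair", "femur"), side = c("left", NA, NA)),
    df(category = "carnivores", taxon = c("fox", "marten", "badger"),
       taxon_group = "carnivore", item_kind = "bone", butchery_marks = FALSE,
       hair_color = NA, hair_length_class = NA,
       element = c("femur", "skull", "rib"), side = NA),
    df(category = "birds", taxon = c("pigeon", "magpie", "starling"),
       taxon_group = "bird", item_kind = c("bone", "feather", "bone"),
       butchery_marks = FALSE, hair_color = NA, hair_length_class = NA,
       element = "remains", side = NA),
    df(category = "others", taxon = c("lizard", "vole", "frog"),
       taxon_group = "other", item_kind = "bone", butchery_marks = FALSE,
       hair_color = NA, hair_length_class = NA, element = "remains",
       side = NA),
    df(category = "ambiguous", taxon = "rabbit",
       taxon_group = "small_medium_vertebrate", item_kind = "hair",
       butchery_marks = FALSE, hair_color = "brown", hair_length_class = NA,
       element = "hair", side = NA))
}

#' Generate prey-remains records from ground truth
#'
#' For each nest-year within `remains_years`, the number of items is
#' Poisson(`remains_per_nest`); each item's category is multinomial on
#' the true proportions times `detectability_bias` (renormalized), with
#' an `others_rate` share of out-of-model items.  Independently, a
#' fraction `ambiguous_rate` of items is replaced by records the rule
#' cascade classifies as undetermined (uniform thinning, so five-category
#' proportions stay unbiased).  Every non-ambiguous record is constructed
#' to classify back to its generating category and to count as exactly
#' one item under the counting rules.
#'
#' @inheritParams simulate_consumers
#' @return remains data frame (one row per item) with the columns
#'   expected by [classify_remains()] and [count_items()], plus
#'   `true_category` (the generating category, for validation).
#' @export
simulate_remains <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 3))
  cats <- config$sources$name
  keep <- truth$year %in% config$remains_years
  tr <- truth[keep, , drop = FALSE]
  if (nrow(tr) == 0) return(NULL)
  P <- as.matrix(tr[, paste0("true_", cats)])
  templates <- remain_templates()
  tpl_rows <- split(seq_len(nrow(templates)), templates$category)
  rows <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    n_items <- rpois(1, config$remains_per_nest)
    if (n_items == 0) next
    pb <- P[i, ] * config$detectability_bias
    pb <- pb / sum(pb) * (1 - config$others_rate)
    probs <- c(pb, others = config$others_rate)
    item_cat <- sample(c(cats, "others"), n_items, replace = TRUE, prob = probs)
    ambiguous <- runif(n_items) < config$ambiguous_rate
    gen_cat <- ifelse(ambiguous, "ambiguous", item_cat)
    # pick a template variant uniformly within each item's category
    variant <- vapply(tpl_rows[gen_cat], function(idx)
      idx[sample.int(length(idx), 1L)], integer(1))
    tpl <- templates[variant, , drop = FALSE]
    rows[[i]] <- data.frame(
      nest_id = tr$territory_id[i], year = tr$year[i],
      sampling_moment = ifelse(seq_len(n_items) %% 2 == 0,
                               "post_breeding", "during_breeding"),
      taxon = tpl$taxon, taxon_group = tpl$taxon_group,
      item_kind = tpl$item_kind, element = tpl$element, side = tpl$side,
      butchery_marks = tpl$butchery_marks, hair_color = tpl$hair_color,
      hair_length_class = tpl$hair_length_class, count = 1L,
      true_category = ifelse(ambiguous, "undetermined", item_cat),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete dual-method study
#'
#' Convenience wrapper running [simulate_diet_proportions()],
#' [simulate_consumers()] and [simulate_remains()] under one config and
#' seed.
#'
#' @param config a [simulation_config()].
#' @return list with `truth`, `consumers`, `remains`, `sources`, `tef`
#'   and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  truth <- simulate_diet_proportions(config)
  list(truth = truth,
       consumers = simulate_consumers(truth, config),
       remains = simulate_remains(truth, config),
       sources = config$sources, tef = config$tef, config = config)
}
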