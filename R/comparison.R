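#' Rank diet categories by consumption
#'
#' Rank 1 is the most consumed category; ties get average ranks (so a
#' two-way tie for first yields 1.5, 1.5).
#'
#' @param props numeric vector of proportions for one nest-year.
#' @return numeric vector of ranks, same length.
#' @export
rank_categories <- function(props) {
  stopifnot(is.numeric(props), all(is.finite(props)))
  rank(-props, ties.method = "average")
}

#' Weighted Cohen's kappa for ordinal agreement
#'
#' Chance-corrected agreement between two ordinal ratings with
#' distance-dependent disagreement weights: linear
#' (`1 - |vi - vj| / range`) or quadratic (`1 - ((vi - vj)/range)^2`)
#' agreement weights on the shared ordinal grid.  Tied ranks are kept at
#' their average-rank values (half steps on a 1..K grid).  The
#' significance test uses the large-sample null standard error
#' (Fleiss-Cohen-Everitt) and a two-sided normal approximation for
#' `Kw = 0`.
#'
#' @param ranks_a,ranks_b numeric vectors of equal length `>= 2` on a
#'   shared ordinal scale.
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @return list with `kappa`, `se0`, `z`, `p_value`, `weighting`, `n`,
#'   and `undefined` (TRUE when marginals are degenerate).
#' @export
weighted_kappa <- function(ranks_a, ranks_b,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(ranks_a) != length(ranks_b) || length(ranks_a) < 2)
    stop_input("rank vectors must have equal length >= 2")
  levels <- sort(unique(c(ranks_a, ranks_b)))
  if (length(levels) == 1) {
    # both raters used a single identical level everywhere
    return(list(kappa = NA_real_, se0 = NA_real_, z = NA_real_,
                p_value = NA_real_, weighting = weighting,
                n = length(ranks_a), undefined = TRUE))
  }
  n <- length(ranks_a)
  tab <- table(factor(ranks_a, levels = levels),
               factor(ranks_b, levels = levels))
  P <- tab / n
  rng <- max(levels) - min(levels)
  d <- outer(levels, levels, function(a, b) abs(a - b) / rng)
  W <- if (weighting == "linear") 1 - d else 1 - d^2
  pi_ <- rowSums(P); pj_ <- colSums(P)
  po <- sum(W * P)
  pe <- sum(W * outer(pi_, pj_))
  if (pe >= 1 - 1e-12) {
    return(list(kappa = NA_real_, se0 = NA_real_, z = NA_real_,
                p_value = NA_real_, weighting = weighting, n = n,
                undefined = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  wi <- as.vector(W %*% pj_)   # row-wise expected weight
  wj <- as.vector(pi_ %*% W)   # column-wise expected weight
  wsum <- outer(wi, wj, "+")
  var0 <- (sum(outer(pi_, pj_) * (W - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  list(kappa = kappa, se0 = se0, z = z,
       p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
       weighting = weighting, n = n, undefined = FALSE)
}

#' Intraclass correlation between two measurement methods
#'
#' Absolute-agreement ICC for paired quantitative estimates.  The default
#' one-way random-effects single-rater form ICC(1) is
#' `(MSB - MSW)/(MSB + (k-1) MSW)` with `k = 2` raters; the two-way
#' absolute-agreement form ICC(A,1) (McGraw & Wong) is selectable.  The
#' F test uses the standard degrees of freedom; the reported p-value is
#' two-sided (twice the smaller F tail).
#'
#' @param values_a,values_b numeric vectors of equal length `>= 3`.
#' @param type `"oneway"` (ICC(1), default) or `"agreement"` (ICC(A,1)).
#' @return list with `icc`, `F`, `df1`, `df2`, `p_value`, `type`, `n`,
#'   `undefined`.
#' @export
icc <- function(values_a, values_b, type = c("oneway", "agreement")) {
  type <- match.arg(type)
  if (length(values_a) != length(values_b) || length(values_a) < 3)
    stop_input("value vectors must have equal length >= 3")
  n <- length(values_a); k <- 2
  X <- cbind(values_a, values_b)
  if (var(as.vector(X)) == 0) {
    return(list(icc = NA_real_, F = NA_real_, df1 = NA, df2 = NA,
                p_value = NA_real_, type = type, n = n, undefined = TRUE))
  }
  row_means <- rowMeans(X); grand <- mean(X)
  MSB <- k * sum((row_means - grand)^2) / (n - 1)
  MSW <- sum((X - row_means)^2) / (n * (k - 1))
  if (type == "oneway") {
    icc_val <- (MSB - MSW) / (MSB + (k - 1) * MSW)
    Fv <- MSB / MSW; df1 <- n - 1; df2 <- n * (k - 1)
  } else {
    col_means <- colMeans(X)
    MSC <- n * sum((col_means - grand)^2) / (k - 1)
    SSE <- sum((X - outer(row_means, rep(1, k)) -
                  outer(rep(1, n), col_means) + grand)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    icc_val <- (MSB - MSE) / (MSB + (k - 1) * MSE + k / n * (MSC - MSE))
    Fv <- MSB / MSE; df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  }
  p <- min(1, 2 * min(pf(Fv, df1, df2, lower.tail = FALSE),
                      pf(Fv, df1, df2)))
  list(icc = icc_val, F = Fv, df1 = df1, df2 = df2, p_value = p,
       type = type, n = n, undefined = FALSE)
}

#' Pair conventional and isotope-based diet estimates
#'
#' Inner-joins nest-years present in both a mixing-model fit summary and
#' a conventional proportions table, on (territory/nest id, year).
#'
#' @param summary a `fit_summary` from [summarize_posterior()].
#' @param props output of [diet_proportions()] with `exclude_others =
#'   TRUE` (five categories matching the mixing model).
#' @return data frame with one row per matched nest-year: `nest_id`,
#'   `year`, then `sia_<category>` (posterior mean proportions) and
#'   `conv_<category>` columns in canonical category order.
#' @export
paired_diet_table <- function(summary, props) {
  cats <- DIET_CATEGORIES
  check_columns(props, c("nest_id", "year", cats), "conventional proportions")
  sia_wide <- stats::reshape(
    summary[, c("territory_id", "year", "source", "mean")],
    idvar = c("territory_id", "year"), timevar = "source",
    direction = "wide")
  names(sia_wide) <- sub("^mean\\.", "sia_", names(sia_wide))
  names(sia_wide)[names(sia_wide) == "territory_id"] <- "nest_id"
  conv <- props[, c("nest_id", "year", cats)]
  names(conv)[-(1:2)] <- paste0("conv_", cats)
  merged <- merge(sia_wide, conv, by = c("nest_id", "year"))
  if (nrow(merged) == 0) stop_input("no nest-years present in both methods")
  # renormalize SIA means (posterior means of a simplex need not sum to
  # exactly 1; in practice they do to numerical precision)
  sia_cols <- paste0("sia_", cats)
  merged[sia_cols] <- merged[sia_cols] / rowSums(merged[sia_cols])
  merged <- merged[order(merged$nest_id, merged$year),
                   c("nest_id", "year", sia_cols, paste0("conv_", cats))]
  rownames(merged) <- NULL
  merged
}

#' Posterior-resampling difference test between methods
#'
#' For each nest-year and category, draws `n_draws` values with
#' replacement from the nest's retained posterior draws, subtracts the
#' conventional proportion, and reports the fraction of differences
#' below zero.  Across nest-years, a symmetric distribution of these
#' fractions with median near 0.5 indicates agreement; medians skewed
#' towards 0 or 1 indicate systematic disagreement.
#'
#' Two sign conventions are in circulation.  The default,
#' `"sia_minus_conventional"`, takes diff = posterior draw minus
#' conventional proportion, so P(diff < 0) is large when the
#' conventional method estimates more.  The published vulture-diet
#' comparison prints the opposite convention,
#' `"conventional_minus_sia"`, equal to the probability that the
#' mixing-model estimate exceeds the conventional one (its medians —
#' e.g. livestock near 0, carnivores near 1 — are on that scale).
#'
#' @param post a `diet_posterior`.
#' @param props conventional [diet_proportions()] (five-category).
#' @param n_draws posterior draws resampled per nest (default 1000).
#' @param seed integer seed; the test is deterministic given it.
#' @param direction sign convention for the difference, see Details.
#' @return list with `per_nest` (long data frame: `nest_id`, `year`,
#'   `category`, `p_below_0`) and `summary` (per category: `median`,
#'   `q25`, `q75`, `n`).
#' @export
posterior_difference_test <- function(post, props, n_draws = 1000L, seed = 1L,
                                      direction = c("sia_minus_conventional",
                                                    "conventional_minus_sia")) {
  direction <- match.arg(direction)
  stopifnot(inherits(post, "diet_posterior"))
  cats <- DIET_CATEGORIES
  check_columns(props, c("nest_id", "year", cats), "conventional proportions")
  key_post <- paste(post$consumers$territory_id, post$consumers$year)
  key_conv <- paste(props$nest_id, props$year)
  matched <- intersect(key_post, key_conv)
  dropped <- setdiff(union(key_post, key_conv), matched)
  if (length(dropped))
    message(sprintf("posterior_difference_test: %d nest-year(s) present in only one method were excluded",
                    length(dropped)))
  if (!length(matched)) stop_input("no matched nest-years")
  k_idx <- match(cats, post$source_names)
  if (any(is.na(k_idx)))
    stop_input("posterior sources do not cover the five diet categories")
  rows <- vector("list", length(matched))
  for (m in seq_along(matched)) {
    i <- match(matched[m], key_post)
    j <- match(matched[m], key_conv)
    arr <- post$draws[[i]]
    set.seed(derive_seed(seed, m))
    take <- sample.int(dim(arr)[1] * dim(arr)[2], n_draws, replace = TRUE)
    pb <- vapply(seq_along(cats), function(c0) {
      v <- as.vector(arr[, , k_idx[c0]])[take]
      d <- v - props[[cats[c0]]][j]
      if (direction == "conventional_minus_sia") d <- -d
      mean(d < 0)
    }, numeric(1))
    rows[[m]] <- data.frame(nest_id = props$nest_id[j], year = props$year[j],
                            category = cats, p_below_0 = pb,
                            stringsAsFactors = FALSE)
  }
  per_nest <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(cats, function(cat) {
    v <- per_nest$p_below_0[per_nest$category == cat]
    data.frame(category = cat, median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_nest = per_nest, summary = summary)
}

#' Mean differences between methods
#'
#' Per category, the arithmetic mean of per-nest differences (SIA minus
#' conventional) and its standard error `SD / sqrt(n)`.
#'
#' @param paired a [paired_diet_table()].
#' @return data frame: `category`, `mean_diff`, `se`, `n`.
#' @export
mean_differences <- function(paired) {
  if (nrow(paired) < 2) stop_input("need at least two paired nest-years")
  rows <- lapply(DIET_CATEGORIES, function(cat) {
    d <- paired[[paste0("sia_", cat)]] - paired[[paste0("conv_", cat)]]
    data.frame(category = cat, mean_diff = mean(d),
               se = sd(d) / sqrt(length(d)), n = length(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full three-way method-agreement report
#'
#' Runs, per diet category: weighted kappa on within-nest consumption
#' ranks (the two vectors compared are that category's rank under each
#' method, across nest-years), ICC on the paired proportions, the
#' posterior-resampling difference test, and mean differences.
#'
#' @param post a `diet_posterior`.
#' @param summary its [summarize_posterior()] output.
#' @param props conventional [diet_proportions()] (five-category).
#' @param kappa_weighting `"linear"` (default) or `"quadratic"`.
#' @param icc_type `"oneway"` (default) or `"agreement"`.
#' @param n_draws posterior draws for the difference test.
#' @param seed seed for the difference test.
#' @param direction sign convention for the difference test, see
#'   [posterior_difference_test()].
#' @return list of class `agreement_report` with elements `by_category`
#'   (data frame: `category`, `kappa`, `kappa_p`, `icc`, `icc_p`,
#'   `median_p_below_0`, `mean_diff`, `se_diff`, `n`), `per_nest`
#'   (difference-test long table) and `paired`.
#' @export
compare_methods <- function(post, summary, props,
                            kappa_weighting = "linear",
                            icc_type = "oneway",
                            n_draws = 1000L, seed = 1L,
                            direction = "sia_minus_conventional") {
  paired <- paired_diet_table(summary, props)
  cats <- DIET_CATEGORIES
  sia <- as.matrix(paired[, paste0("sia_", cats)])
  conv <- as.matrix(paired[, paste0("conv_", cats)])
  ranks_sia <- t(apply(sia, 1, rank_categories))
  ranks_conv <- t(apply(conv, 1, rank_categories))
  pdt <- posterior_difference_test(post, props, n_draws = n_draws, seed = seed,
                                   direction = direction)
  md <- mean_differences(paired)
  rows <- lapply(seq_along(cats), function(k) {
    kw <- weighted_kappa(ranks_conv[, k], ranks_sia[, k],
                         weighting = kappa_weighting)
    ic <- icc(conv[, k], sia[, k], type = icc_type)
    data.frame(category = cats[k],
               kappa = kw$kappa, kappa_p = kw$p_value,
               icc = ic$icc, icc_p = ic$p_value,
               median_p_below_0 = pdt$summary$median[pdt$summary$category == cats[k]],
               mean_diff = md$mean_diff[md$category == cats[k]],
               se_diff = md$se[md$category == cats[k]],
               n = nrow(paired), stringsAsFactors = FALSE)
  })
  by_category <- do.call(rbind, rows)
  rownames(by_category) <- NULL
  structure(list(by_category = by_category, per_nest = pdt$per_nest,
                 paired = paired,
                 settings = list(kappa_weighting = kappa_weighting,
                                 icc_type = icc_type, n_draws = n_draws,
                                 seed = seed, direction = direction)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Method-agreement report (SIA vs conventional), per category:\n")
  print(x$by_category, row.names = FALSE, digits = 3)
  invisible(x)
}
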