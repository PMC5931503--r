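# Shared fixtures built in code: tiny deterministic studies and a
# hand-rollable diet_posterior for tests that need known draws.

make_samples <- function() {
  # 3 nests x 2 years x 3 siblings with hand-checkable values
  grid <- expand.grid(territory_id = c("A", "B", "C"), year = c(2012, 2013),
                      sib = 1:3, stringsAsFactors = FALSE)
  grid$delta13C <- -24 + as.integer(factor(grid$territory_id)) + 0.1 * grid$sib
  grid$delta15N <- 8 + grid$year - 2012 + 0.2 * grid$sib
  grid[, c("territory_id", "year", "delta13C", "delta15N")]
}

# diet_posterior with draws supplied directly (chains x iters x K per consumer)
fake_posterior <- function(draw_list, consumers, source_names) {
  structure(list(draws = draw_list,
                 sigma = lapply(draw_list, function(a)
                   array(0.1, c(dim(a)[1], dim(a)[2], 2))),
                 consumers = consumers, source_names = source_names,
                 accept_rates = matrix(0.3, length(draw_list), dim(draw_list[[1]])[1]),
                 n_chains = dim(draw_list[[1]])[1],
                 n_iter = dim(draw_list[[1]])[2], n_burnin = 0L,
                 seed = 1L, rhat_threshold = 1.1),
            class = "diet_posterior")
}

small_fit <- function(consumers, seed = 1, n_iter = 1500, n_burnin = 500,
                      sources = default_sources(), tef = default_tef()) {
  spec <- mixing_model_spec(sources, tef, consumers, n_chains = 4,
                            n_iter = n_iter, n_burnin = n_burnin, seed = seed)
  sample_posterior(spec)
}
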