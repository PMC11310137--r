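# Independent oracles and small fixture builders shared across tests.

# Random alignment-block instance for one scaffold (small n, possibly
# spanning two target contigs and both strands).
random_block_instance <- function(n, two_targets = TRUE) {
  qstart <- sort(sample.int(2000, n))
  qspan <- sample.int(300, n)
  tibble::tibble(
    block_id = seq_len(n),
    qname = "scaf",
    qstart = qstart,
    qend = qstart + qspan,
    tname = if (two_targets) sample(c("tigA", "tigB"), n, replace = TRUE)
            else "tigA",
    tstart = sample.int(2000, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    qspan = qspan) |>
    dplyr::mutate(tend = tstart + sample.int(300, n))
}

# Exhaustive maximum chain score: enumerate every non-empty increasing
# subsequence (in the DP's sort order) and score it by definition.
brute_force_chain_score <- function(blocks, cfg = hapblend::chain_config()) {
  ord <- order(blocks$qstart, blocks$tstart, -blocks$qspan)
  b <- blocks[ord, ]
  n <- nrow(b)
  rows <- lapply(seq_len(n), function(i) as.list(b[i, ]))
  P <- matrix(0, n, n)
  if (n > 1) for (j in seq_len(n - 1)) for (i in (j + 1):n)
    P[j, i] <- hapblend::pair_penalty(rows[[j]], rows[[i]], cfg)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sc <- sum(b$qspan[idx])
    if (length(idx) > 1)
      sc <- sc + sum(P[cbind(idx[-length(idx)], idx[-1])])
    if (sc > best) best <- sc
  }
  best
}

# Recompute a chain score from its definition (sum of spans + penalties).
score_by_definition <- function(blocks, ids, cfg = hapblend::chain_config()) {
  b <- blocks[match(ids, blocks$block_id), ]
  sc <- sum(b$qspan)
  if (nrow(b) > 1) for (i in seq_len(nrow(b) - 1))
    sc <- sc + hapblend::pair_penalty(as.list(b[i, ]), as.list(b[i + 1, ]),
                                      cfg)
  sc
}

# Exhaustive switch-error minimum over all 2^n orientation assignments.
brute_force_switch <- function(match, long_penalty = 5) {
  n <- length(match)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  mism <- sweep(grid, 2, as.integer(!match), function(o, m)
    ifelse(o == 0, m, 1 - m))
  short <- rowSums(mism)
  long <- if (n > 1) rowSums(abs(grid[, -1, drop = FALSE] -
                                   grid[, -n, drop = FALSE])) else 0
  min(long_penalty * long + short)
}

# Small diploid fixture used by several suites.
small_fixture <- function(seed = 101L, genome = 60000L, n_small = 20L,
                          n_large = 2L, ...) {
  cfg <- hapblend::sim_config(genome_size = genome, tgs_n_small = n_small,
                              tgs_n_large = n_large,
                              slr_fragment_mean = 20000L, seed = seed, ...)
  truth <- hapblend::simulate_diploid(cfg)
  list(cfg = cfg, truth = truth,
       tgs = hapblend::simulate_tgs_assembly(truth, cfg),
       slr = hapblend::simulate_slr_assembly(truth$hapA, cfg))
}
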