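# Shared fixtures and independent oracles used across test files.

# Small, fast transcriptome spec for unit tests (defaults elsewhere).
small_transcriptome_spec <- function(seed = 1, ...) {
  transcriptome_sim_spec(
    n_genes = 400, n_planted_up = 30, n_planted_down = 15,
    samples_per_group = 4, seed = seed, ...
  )
}

small_faers_spec <- function(seed = 1, ...) {
  faers_sim_spec(n_cases = 5000, seed = seed, ...)
}

# Independent brute-force BH step-up: sort, p*m/rank, cumulative minimum from
# the largest rank, clip to [0, 1], restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(stepped)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Independent exhaustive running-sum enrichment oracle (scalar loop).
es_oracle <- function(scores, query) {
  genes <- names(scores)
  ord <- order(-scores, genes)
  genes <- genes[ord]
  scores <- scores[ord]
  n <- length(genes)
  nh <- length(query)
  denom <- sum(abs(scores[genes %in% query]))
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (genes[i] %in% query) {
      running <- running + abs(scores[i]) / denom
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(best) + 1e-12 ||
      (abs(abs(running) - abs(best)) <= 1e-12 && running > best)) {
      best <- running
    }
  }
  unname(best)
}

# Independent log-space ROR + Woolf interval evaluation.
ror_oracle <- function(a, b, c_, d, z = 1.959964) {
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5
    b <- b + 0.5
    c_ <- c_ + 0.5
    d <- d + 0.5
  }
  lr <- (log(a) + log(d)) - (log(b) + log(c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  c(ror = exp(lr), ci_low = exp(lr - z * se), ci_high = exp(lr + z * se))
}

# Exact hypergeometric upper-tail oracle via combinatorial sums.
hyper_tail_oracle <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Re-count a contingency table by exhaustive per-case iteration.
contingency_oracle <- function(cohort, co_drug, reaction) {
  cells <- c(d1r1 = 0, d1r0 = 0, d0r1 = 0, d0r0 = 0)
  for (i in seq_len(nrow(cohort))) {
    d <- co_drug %in% cohort$drugs[[i]]
    r <- reaction %in% cohort$reactions[[i]]
    cell <- paste0("d", as.integer(d), "r", as.integer(r))
    cells[cell] <- cells[cell] + 1
  }
  cells
}
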