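# Independent oracles used across tests. These deliberately take different
# code paths from the package implementation.

# Binomial fractions by exhaustive enumeration of {0,1}^n allele states.
brute_force_binomial <- function(p, n) {
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  k <- rowSums(states)
  prob <- p^k * (1 - p)^(n - k)
  vapply(0:n, function(c_) sum(prob[k == c_]), numeric(1))
}

# Implied contact probability by numerical integration of the mixture
# distance densities below the threshold (half-normal + Rayleigh).
integrate_contact_prob <- function(p_loop, loc, scale, free_scale,
                                   threshold = 0.27) {
  dhalfnorm <- function(x) {
    ifelse(x < loc, 0, 2 * stats::dnorm(x - loc, 0, scale))
  }
  drayleigh <- function(x) x / free_scale^2 * exp(-x^2 / (2 * free_scale^2))
  p_l <- stats::integrate(dhalfnorm, 0, threshold, rel.tol = 1e-10)$value
  p_f <- stats::integrate(drayleigh, 0, threshold, rel.tol = 1e-10)$value
  p_loop * p_l + (1 - p_loop) * p_f
}

# Greedy ascending one-to-one matching re-implemented via full pair
# enumeration and an explicit sort (vs the package's iterative matrix-min).
oracle_greedy_match <- function(ax, ay, bx, by, cap) {
  if (!length(ax) || !length(bx)) return(numeric(0))
  grid <- expand.grid(i = seq_along(ax), j = seq_along(bx))
  grid$d <- sqrt((ax[grid$i] - bx[grid$j])^2 + (ay[grid$i] - by[grid$j])^2)
  grid <- grid[order(grid$d), ]
  used_i <- used_j <- integer(0)
  out <- numeric(0)
  for (r in seq_len(nrow(grid))) {
    if (grid$i[r] %in% used_i || grid$j[r] %in% used_j) next
    used_i <- c(used_i, grid$i[r]); used_j <- c(used_j, grid$j[r])
    out <- c(out, grid$d[r])
  }
  out[out < cap]
}

# Run the quantification pipeline stages on a generated dataset.
quantify <- function(ds, acfg) {
  kept <- ploidy_filter(qc_filter_nuclei(ds$nuclei, acfg)$kept, ds$spots,
                        acfg)
  sp <- ds$spots[ds$spots$nucleus_id %in% kept$nucleus_id, , drop = FALSE]
  pairs <- call_contacts(match_spots_by_nucleus(sp, acfg), acfg)
  cells <- summarize_cells(kept, pairs,
                           sp[sp$channel == "rna", , drop = FALSE])
  list(kept = kept, pairs = pairs, cells = cells)
}
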