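# Independent brute-force oracles used to validate the exact tests, plus
# small fixture builders. These never call the implementations they check.

# two-sided minlike binomial p by full pmf enumeration
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# rank-sum p by enumeration over all subsets of ranks assigned to x
oracle_mw_p <- function(x, y, alternative = "two_sided") {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(length(r), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# signed-rank p by enumeration over all 2^n sign assignments
oracle_wsr_p <- function(x, y, alternative = "two_sided") {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs); p_ge <- mean(vs >= v_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# hand-built event stream: one dyad, explicit bout structure
toy_events <- function(times, actors, behaviors, dyad = "d1", day = 1) {
  tibble::tibble(dyad_id = dyad, day = day, time_s = times,
                 actor_id = actors, behavior = behaviors)
}

toy_reads <- function(times, tubes, sides, tag = "m1") {
  tibble::tibble(time_s = times, tube = tubes, side = sides, tag_id = tag)
}

# same enclosure trajectories at a given detection probability (the
# generator draws the detection uniforms either way, so trajectories match
# across p_detect for a fixed seed)
rfid_metrics_of <- function(p_detect, seed) {
  sim <- simulate_enclosure(n_mice = c(CB = 5, MC = 5), duration_h = 48,
                            p_detect = p_detect, seed = seed)
  rfid_metrics(sim$reads, sim$manifest, 0, 48 * 3600)
}

# tiny two-population genotype set with known counts
toy_genotypes <- function() {
  g <- list()
  add <- function(id, a1, a2) {
    g[[length(g) + 1L]] <<- tibble::tibble(
      individual_id = id, locus = c("L1", "L2"), a1 = a1, a2 = a2)
  }
  add("A1", c(1L, 3L), c(1L, 3L))
  add("A2", c(1L, 3L), c(2L, 4L))
  add("B1", c(2L, 4L), c(2L, 4L))
  add("B2", c(2L, 4L), c(2L, 4L))
  dplyr::bind_rows(g)
}
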