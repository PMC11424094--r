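# Independent brute-force oracles used across the suite.

## O(N^2) union-find over polymers: stickers connect if same chain or
## within cutoff (minimum image, any type)
brute_cluster <- function(state, cutoff = 1) {
  n <- nrow(state$pos)
  npoly <- max(state$mol)
  parent <- seq_len(npoly)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- state$pos[i, ] - state$pos[j, ]
    d <- d - state$box * round(d / state$box)
    if (sum(d^2) < cutoff^2) {
      ra <- find(state$mol[i]); rb <- find(state$mol[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(npoly), find, integer(1))
  sizes <- table(roots)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  ranks <- seq_along(ord)
  names(ranks) <- names(sizes)[ord]
  as.integer(ranks[as.character(roots)])
}

## O(N^2) unbound-sticker scan
brute_unbound <- function(state, cutoff = 1) {
  n <- nrow(state$pos)
  bound <- rep(FALSE, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (state$type[i] == state$type[j]) next
    d <- state$pos[i, ] - state$pos[j, ]
    d <- d - state$box * round(d / state$box)
    if (sum(d^2) < cutoff^2) bound[i] <- bound[j] <- TRUE
  }
  bound
}

## Free-particle BAOAB pair dynamics in R (no forces): the relative
## coordinate is an AR(1) velocity process integrated by half steps.
## Returns completed bonded-interval durations (r < r0, minimum image),
## matching the conventions of the compiled pair-lifetime simulation.
free_pair_lifetimes_R <- function(n_steps, dt = 1e-3, kBT = 1, gamma = 1,
                                  mass = 1, boxL = 8, r0 = 1, seed = 1) {
  set.seed(seed)
  c1 <- exp(-gamma * dt / mass)
  c2 <- sqrt(kBT / mass * (1 - c1^2))
  rel <- matrix(0, n_steps + 1, 3)
  rel[1, ] <- c(0.3 * r0, 0, 0)
  for (a in 1:3) {
    ## relative velocity of two independent particles: AR(1) with
    ## doubled noise variance
    xi <- stats::rnorm(n_steps, 0, sqrt(2) * c2)
    v <- stats::filter(xi, c1, method = "recursive")
    v0 <- sum(stats::rnorm(2, 0, sqrt(kBT / mass)) * c(1, -1))
    v <- as.numeric(v) + c1^(seq_len(n_steps)) * v0
    vprev <- c(v0, v[-n_steps])
    rel[-1, a] <- rel[1, a] + cumsum(dt / 2 * (vprev + v))
  }
  dmin <- rel - boxL * round(rel / boxL)
  r <- sqrt(rowSums(dmin^2))
  bonded <- r < r0
  runs <- rle(bonded)
  ends <- cumsum(runs$lengths)
  keep <- runs$values & (ends < length(bonded))  # completed intervals only
  runs$lengths[keep] * dt
}

## quick small A6B6 slab simulation shared by integration tests
small_slab_run <- function(U0, n_polymers = 80, box = c(140, 25, 25),
                           seed = 7, equil_steps = 60000, prod_steps = 40000,
                           record_every = 2000, dt = 5e-3) {
  ff <- force_field(U0 = U0)
  sp <- polymer_spec("A6B6", n_polymers, box, geometry = "slab")
  st <- build_system(sp, ff, seed = seed, dense_frac = 0.18)
  eq <- run_langevin(st, ff, n_steps = equil_steps, dt = dt, seed = seed + 1,
                     record_every = equil_steps)
  run_langevin(eq$final_state, ff, n_steps = prod_steps, dt = dt,
               seed = seed + 2, record_every = record_every)
}
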