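# Independent brute-force oracle for the partially paired permutation test.
# Deliberately naive: explicit loops over every swap pattern and every
# unpaired-label reassignment, with its own midrank routine. Used to freeze
# expected values and to cross-check the package's exact enumeration.

oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_ranksum <- function(a, b) {
  r <- oracle_midranks(c(a, b))
  sum(r[seq_along(a)])
}

# peer, listed: named numeric vectors keyed by survivor id
oracle_partially_paired <- function(peer, listed) {
  ids <- intersect(names(peer), names(listed))
  po <- setdiff(names(peer), ids)
  lo <- setdiff(names(listed), ids)
  k <- length(ids)
  unpaired <- c(unname(peer[po]), unname(listed[lo]))
  n_po <- length(po)

  swaps <- if (k > 0) {
    as.matrix(expand.grid(rep(list(0:1), k)))
  } else {
    matrix(0L, 1, 0)
  }
  combos <- if (length(unpaired) > 0 && n_po > 0 && n_po < length(unpaired)) {
    utils::combn(length(unpaired), n_po, simplify = FALSE)
  } else if (length(unpaired) > 0 && n_po == 0) {
    list(integer(0))
  } else if (length(unpaired) > 0) {
    list(seq_along(unpaired))
  } else {
    list(integer(0))
  }

  obs <- oracle_ranksum(c(unname(peer[ids]), unname(peer[po])),
                        c(unname(listed[ids]), unname(listed[lo])))
  stats <- numeric(0)
  for (si in seq_len(nrow(swaps))) {
    s <- swaps[si, ]
    pv <- lv <- numeric(k)
    for (j in seq_len(k)) {
      if (s[j] == 1) {
        pv[j] <- listed[[ids[j]]]; lv[j] <- peer[[ids[j]]]
      } else {
        pv[j] <- peer[[ids[j]]]; lv[j] <- listed[[ids[j]]]
      }
    }
    for (cmb in combos) {
      pu <- unpaired[cmb]
      lu <- unpaired[setdiff(seq_along(unpaired), cmb)]
      stats <- c(stats, oracle_ranksum(c(pv, pu), c(lv, lu)))
    }
  }
  e <- mean(stats)
  list(obs = obs,
       stats = stats,
       p_one = mean(stats <= obs + 1e-9),
       p_two = mean(abs(stats - e) >= abs(obs - e) - 1e-9),
       p_tie = mean(abs(stats - obs) <= 1e-9))
}

# random small fixture with paired and unpaired survivors, enumerable exactly
random_fixture <- function(seed, max_paired = 8) {
  set.seed(seed)
  k <- sample(2:max_paired, 1)
  n_po <- sample(0:3, 1)
  n_lo <- sample(0:3, 1)
  if (n_po + n_lo == 1) n_lo <- n_lo + 1 # avoid a degenerate 1-element pool
  mk <- function(n) round(stats::rgamma(n, shape = 1.2, scale = 3), 1)
  peer <- stats::setNames(mk(k + n_po), c(sprintf("b%02d", seq_len(k)),
                                          if (n_po) sprintf("p%02d", seq_len(n_po))))
  listed <- stats::setNames(mk(k + n_lo), c(sprintf("b%02d", seq_len(k)),
                                            if (n_lo) sprintf("l%02d", seq_len(n_lo))))
  list(peer = peer, listed = listed)
}
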