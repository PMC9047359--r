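# Independent oracles and small fixture generators used across tests.
# These deliberately re-derive quantities by brute force (enumeration,
# closed form) and never call the package code paths they check.

rand_spectrum <- function(id, n_peaks, prec = runif(1, 300, 800),
                          mz_range = c(60, 280), mode = "positive") {
  spectrum(id, prec,
           cbind(runif(n_peaks, mz_range[1], mz_range[2]),
                 runif(n_peaks, 1, 100)),
           rt = runif(1, 0, 10), mode = mode)
}

# Exhaustive maximum-weight one-to-one assignment for the modified cosine:
# candidate weight matrix W (NA = pair not allowed), recursion over rows
# trying every available column or none. Returns best score and the
# largest match count among score-optimal assignments.
oracle_best_assignment <- function(W) {
  na_ <- nrow(W); nb <- ncol(W)
  best <- list(score = 0, n = 0L)
  rec <- function(i, used, score, n) {
    if (i > na_) {
      if (score > best$score + 1e-15 ||
          (abs(score - best$score) <= 1e-15 && n > best$n))
        best <<- list(score = score, n = n)
      return(invisible())
    }
    rec(i + 1L, used, score, n)
    for (j in seq_len(nb)) {
      if (!used[j] && !is.na(W[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, score + W[i, j], n + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nb), 0, 0L)
  best
}

oracle_modified_cosine <- function(a, b, fragment_tol = 0.02) {
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0)
    return(list(score = 0, n_matched = 0L))
  wa <- sqrt(a$peaks[, 2]); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$peaks[, 2]); wb <- wb / sqrt(sum(wb^2))
  delta <- a$precursor_mz - b$precursor_mz
  W <- outer(wa, wb)
  dm <- outer(a$peaks[, 1], b$peaks[, 1], "-")
  allowed <- abs(dm) <= fragment_tol | abs(dm - delta) <= fragment_tol
  W[!allowed] <- NA
  r <- oracle_best_assignment(W)
  list(score = min(1, r$score), n_matched = r$n)
}

# Brute-force Mk1 likelihood: sum the joint probability over every
# internal-node labelling (uniform root prior).
oracle_mk_loglik <- function(tree, states, q) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  pflip <- function(t) 0.5 - 0.5 * exp(-2 * q * t)
  full <- numeric(ntip + nint)
  full[seq_len(ntip)] <- states[tree$tip.label]
  tot <- 0
  for (code in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(nint)]
    full[ntip + seq_len(nint)] <- lab
    pr <- 0.5
    for (k in seq_len(nrow(tree$edge))) {
      p <- pflip(tree$edge.length[k])
      same <- full[tree$edge[k, 1]] == full[tree$edge[k, 2]]
      pr <- pr * if (same) 1 - p else p
    }
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force marginal posterior P(node = 1 | tips) by enumeration.
oracle_mk_marginal <- function(tree, states, q, node) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  pflip <- function(t) 0.5 - 0.5 * exp(-2 * q * t)
  full <- numeric(ntip + nint)
  full[seq_len(ntip)] <- states[tree$tip.label]
  tot <- 0; hit <- 0
  for (code in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(nint)]
    full[ntip + seq_len(nint)] <- lab
    pr <- 0.5
    for (k in seq_len(nrow(tree$edge))) {
      p <- pflip(tree$edge.length[k])
      same <- full[tree$edge[k, 1]] == full[tree$edge[k, 2]]
      pr <- pr * if (same) 1 - p else p
    }
    tot <- tot + pr
    if (node <= ntip) { if (full[node] == 1) hit <- hit + pr }
    else if (lab[node - ntip] == 1) hit <- hit + pr
  }
  hit / tot
}

# Step-up Benjamini-Hochberg from its definition:
# adj p_(i) = min_{j >= i} min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, m * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

random_bl_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}
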