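#' Read a rooted phylogeny from a newick file
#'
#' Tips must be uniquely labelled; zero or negative branch lengths are
#' replaced by a small epsilon with a warning so that transition
#' probabilities stay well-defined.
#'
#' @param path newick file.
#' @param epsilon replacement for non-positive branch lengths.
#' @return an \pkg{ape} `phylo` tree.
#' @export
read_newick_tree <- function(path, epsilon = 1e-8) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse newick file %s", path)
  validate_tree(tr, epsilon)
}

validate_tree <- function(tr, epsilon = 1e-8) {
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stopf("tree has unlabeled tips")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) stopf("tree has no branch lengths")
  bad <- tr$edge.length <= 0
  if (any(bad)) {
    warnf("%d non-positive branch lengths replaced by %g", sum(bad), epsilon)
    tr$edge.length[bad] <- epsilon
  }
  tr
}

#' Mk1 transition probability matrix
#'
#' Two-state symmetric Markov model with a single rate q: over a branch of
#' length t, P(stay) = 1/2 + exp(-2qt)/2 and P(flip) = 1/2 - exp(-2qt)/2.
#'
#' @param q substitution rate (> 0).
#' @param t branch length (>= 0).
#' @return 2x2 matrix with rows/cols `c("0", "1")`.
#' @export
mk_transition <- function(q, t) {
  stopifnot(q > 0, t >= 0)
  e <- exp(-2 * q * t)
  same <- 0.5 + 0.5 * e; diff <- 0.5 - 0.5 * e
  matrix(c(same, diff, diff, same), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Postorder edge traversal cached pieces shared by the likelihood and
# marginal routines.
tree_index <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(tree = tree, edge = tree$edge, len = tree$edge.length,
       ntip = length(tree$tip.label), root = length(tree$tip.label) + 1L,
       nnode = length(tree$tip.label) + tree$Nnode)
}

# Conditional (up) likelihoods under Mk1 for a matrix of characters.
# states: ntip x nchar binary matrix, rownames = tip labels.
# Returns list(L = nnode x nchar x 2 array, logscale = nchar vector).
up_likelihood <- function(ti, states, q) {
  nchar_ <- ncol(states)
  L0 <- matrix(1, ti$nnode, nchar_)
  L1 <- matrix(1, ti$nnode, nchar_)
  tips <- match(ti$tree$tip.label, rownames(states))
  if (anyNA(tips)) stopf("tip state(s) missing for: %s",
                         paste(ti$tree$tip.label[is.na(tips)], collapse = ", "))
  s <- states[tips, , drop = FALSE]
  L0[seq_len(ti$ntip), ] <- 1 - s
  L1[seq_len(ti$ntip), ] <- s
  logscale <- numeric(nchar_)
  e <- exp(-2 * q * ti$len)
  for (k in seq_len(nrow(ti$edge))) {
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    same <- 0.5 + 0.5 * e[k]; diff <- 0.5 - 0.5 * e[k]
    m0 <- same * L0[ch, ] + diff * L1[ch, ]
    m1 <- diff * L0[ch, ] + same * L1[ch, ]
    L0[p, ] <- L0[p, ] * m0
    L1[p, ] <- L1[p, ] * m1
    if (ti$edge[min(k + 1, nrow(ti$edge)), 1] != p || k == nrow(ti$edge)) {
      sc <- pmax(L0[p, ], L1[p, ])
      sc[sc == 0] <- 1
      L0[p, ] <- L0[p, ] / sc; L1[p, ] <- L1[p, ] / sc
      logscale <- logscale + log(sc)
    }
  }
  list(L0 = L0, L1 = L1, logscale = logscale)
}

#' Mk1 log-likelihood of binary characters on a tree
#'
#' Felsenstein's pruning algorithm with a uniform (1/2, 1/2) root prior.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states either a named binary vector (one character; names = tip
#'   labels) or a tips x characters binary matrix with tip rownames.
#' @param q Mk rate (> 0).
#' @return log-likelihood (vector, one per character).
#' @export
character_likelihood <- function(tree, states, q) {
  stopifnot(q > 0)
  if (is.null(dim(states)))
    states <- matrix(states, ncol = 1, dimnames = list(names(states), NULL))
  if (!all(states %in% c(0, 1))) stopf("tip states must be 0/1 (no ambiguity codes)")
  ti <- tree_index(tree)
  up <- up_likelihood(ti, states, q)
  log(0.5 * (up$L0[ti$root, ] + up$L1[ti$root, ])) + up$logscale
}

#' Maximum-likelihood Mk1 rate estimate
#'
#' One-dimensional bounded ML optimisation of the pruning log-likelihood
#' over log(q). By default each character gets its own rate (the behaviour
#' of single-character Mk1 fits); with `per_character = FALSE` a single
#' rate is fitted to the summed log-likelihood of all characters.
#' Characters invariant across tips carry no rate information and are
#' returned at the lower bound with `boundary = TRUE`.
#'
#' @param tree rooted `phylo`.
#' @param states binary matrix (tips x characters) or named vector.
#' @param per_character fit one rate per character (default TRUE).
#' @param q_min,q_max search bounds.
#' @param tol optimisation tolerance on log(q).
#' @return data frame with columns `character`, `q`, `loglik`, `boundary`
#'   (or a single-row data frame when `per_character = FALSE`).
#' @export
estimate_rate <- function(tree, states, per_character = TRUE,
                          q_min = 1e-8, q_max = 100, tol = 1e-9) {
  if (inherits(states, "character_matrix")) states <- states$states
  if (is.null(dim(states)))
    states <- matrix(states, ncol = 1, dimnames = list(names(states), "char1"))
  cn <- colnames(states) %||% paste0("char", seq_len(ncol(states)))
  variable <- apply(states, 2, function(v) length(unique(v)) > 1)
  fit_one <- function(sub) {
    f <- function(lq) -sum(character_likelihood(tree, sub, exp(lq)))
    opt <- stats::optimize(f, interval = log(c(q_min, q_max)), tol = tol)
    if (!is.finite(opt$objective))
      stopf("rate optimisation failed on bracket [%g, %g]", q_min, q_max)
    list(q = exp(opt$minimum), loglik = -opt$objective)
  }
  if (!per_character) {
    if (!any(variable)) stopf("need at least one variable character")
    fit <- fit_one(states[, variable, drop = FALSE])
    const_ll <- if (any(!variable))
      sum(character_likelihood(tree, states[, !variable, drop = FALSE], fit$q))
    else 0
    return(data.frame(character = "shared", q = fit$q,
                      loglik = fit$loglik + const_ll,
                      boundary = FALSE))
  }
  res <- lapply(seq_len(ncol(states)), function(j) {
    if (!variable[j])
      return(data.frame(character = cn[j], q = q_min,
                        loglik = character_likelihood(
                          tree, states[, j, drop = FALSE], q_min),
                        boundary = TRUE))
    fit <- fit_one(states[, j, drop = FALSE])
    data.frame(character = cn[j], q = fit$q, loglik = fit$loglik,
               boundary = FALSE)
  })
  do.call(rbind, res)
}

#' Marginal ancestral state reconstruction under Mk1
#'
#' Standard two-pass (up/down) computation of per-node marginal posterior
#' state probabilities given the tip states, a rate q and a uniform root
#' prior, plus the maximum-a-posteriori state per node. An exact 0.5/0.5
#' marginal maps to state 0 and is flagged.
#'
#' @param tree rooted `phylo`.
#' @param states named binary tip-state vector.
#' @param q Mk rate (> 0).
#' @return list with `marginal` (nodes x 2 matrix, rows sum to 1), `map`
#'   (integer node states), `ties` (node indices at exactly 0.5) and
#'   `loglik`. Nodes follow \pkg{ape} numbering (tips first, then root).
#' @export
marginal_asr <- function(tree, states, q) {
  stopifnot(q > 0)
  st <- matrix(states, ncol = 1, dimnames = list(names(states), NULL))
  if (!all(st %in% c(0, 1))) stopf("tip states must be 0/1")
  ti <- tree_index(tree)
  up <- up_likelihood(ti, st, q)
  L <- cbind(up$L0[, 1], up$L1[, 1])
  e <- exp(-2 * q * ti$len)
  # edge-lifted child likelihood seen from the parent: M[k, i] =
  # sum_j P(i -> j; t_k) L_child(j)
  M <- cbind((0.5 + 0.5 * e) * L[ti$edge[, 2], 1] +
             (0.5 - 0.5 * e) * L[ti$edge[, 2], 2],
             (0.5 - 0.5 * e) * L[ti$edge[, 2], 1] +
             (0.5 + 0.5 * e) * L[ti$edge[, 2], 2])
  D <- matrix(NA_real_, ti$nnode, 2)
  D[ti$root, ] <- c(0.5, 0.5)
  children <- split(seq_len(nrow(ti$edge)), ti$edge[, 1])
  for (k in rev(seq_len(nrow(ti$edge)))) {  # reverse postorder = preorder
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    sibs <- setdiff(children[[as.character(p)]], k)
    outer_p <- D[p, ]
    for (s in sibs) outer_p <- outer_p * M[s, ]
    D[ch, 1] <- (0.5 + 0.5 * e[k]) * outer_p[1] + (0.5 - 0.5 * e[k]) * outer_p[2]
    D[ch, 2] <- (0.5 - 0.5 * e[k]) * outer_p[1] + (0.5 + 0.5 * e[k]) * outer_p[2]
    sc <- max(D[ch, ])
    if (sc > 0) D[ch, ] <- D[ch, ] / sc
  }
  post <- D * L
  post <- post / rowSums(post)
  colnames(post) <- c("0", "1")
  map <- as.integer(post[, 2] > 0.5)
  ties <- which(abs(post[, 2] - 0.5) < 1e-12)
  map[ties] <- 0L
  list(marginal = post, map = map, ties = ties,
       loglik = log(0.5 * (up$L0[ti$root, 1] + up$L1[ti$root, 1])) + up$logscale)
}

#' Count state gains and losses on a labelled tree
#'
#' Given one state per node (tips and internals), gains are edges whose
#' parent is 0 and child 1; losses the reverse.
#'
#' @param tree rooted `phylo`.
#' @param node_states integer vector of 0/1 states indexed by \pkg{ape}
#'   node number (tips `1..N`, then internals).
#' @return list with `gains` and `losses`.
#' @export
count_origins <- function(tree, node_states) {
  p <- node_states[tree$edge[, 1]]; ch <- node_states[tree$edge[, 2]]
  list(gains = sum(p == 0 & ch == 1), losses = sum(p == 1 & ch == 0))
}

# Number of independent origins of state s given a full node labelling:
# transitions into s plus one if the root itself carries s.
origins_of_state <- function(tree, node_states, s) {
  root <- length(tree$tip.label) + 1L
  p <- node_states[tree$edge[, 1]]; ch <- node_states[tree$edge[, 2]]
  sum(p != s & ch == s) + as.integer(node_states[root] == s)
}

#' Classify a character's fit to a clade
#'
#' Cladistic reading of a reconstructed character: the clade must be
#' uniform for some state s at its tips; a call requires a stem change
#' (clade MRCA reconstructed as s, its parent as not-s). If s originates
#' exactly once on the whole tree the character is a synapomorphy of the
#' clade (present or absent according to s); if s also arises elsewhere it
#' is a homoplasy; anything else is uninformative.
#'
#' @param tree rooted `phylo`.
#' @param tip_states named binary vector over the tree's tips.
#' @param node_states full node labelling (e.g. MAP states from
#'   [marginal_asr()]).
#' @param clade_tips tip labels of the (monophyletic) clade.
#' @return one of `"synapomorphy_present"`, `"synapomorphy_absent"`,
#'   `"homoplasy_present"`, `"homoplasy_absent"`, `"uninformative"`.
#' @export
classify_character <- function(tree, tip_states, node_states, clade_tips) {
  if (!all(clade_tips %in% tree$tip.label))
    stopf("clade tips missing from tree: %s",
          paste(setdiff(clade_tips, tree$tip.label), collapse = ", "))
  if (length(clade_tips) > 1 &&
      !ape::is.monophyletic(tree, clade_tips))
    stopf("clade is not monophyletic on the tree")
  s_vals <- unique(tip_states[clade_tips])
  if (length(s_vals) != 1) return("uninformative")
  s <- s_vals
  mrca <- if (length(clade_tips) == 1) match(clade_tips, tree$tip.label)
          else ape::getMRCA(tree, clade_tips)
  root <- length(tree$tip.label) + 1L
  if (mrca == root) return("uninformative")
  parent <- tree$edge[tree$edge[, 2] == mrca, 1]
  if (node_states[mrca] != s || node_states[parent] != (1 - s))
    return("uninformative")
  n_orig <- origins_of_state(tree, node_states, s)
  kind <- if (n_orig == 1) "synapomorphy" else "homoplasy"
  paste0(kind, "_", if (s == 1) "present" else "absent")
}

# Fitch small-parsimony node states with a parent-preference top-down
# refinement (root ambiguity resolved toward state 0). Offered as the
# parsimony-style alternative to ML MAP labelling.
fitch_states <- function(tree, tip_states) {
  ti <- tree_index(tree)
  sets <- integer(ti$nnode)  # bitmask: 1 = {0}, 2 = {1}, 3 = {0,1}
  tips <- match(ti$tree$tip.label, names(tip_states))
  sets[seq_len(ti$ntip)] <- ifelse(tip_states[tips] == 1, 2L, 1L)
  acc <- rep(3L, ti$nnode)
  for (p in unique(ti$edge[, 1])) acc[p] <- 0L
  for (k in seq_len(nrow(ti$edge))) {
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    if (acc[p] == 0L) acc[p] <- sets[ch]
    else {
      inter <- bitwAnd(acc[p], sets[ch])
      acc[p] <- if (inter > 0L) inter else bitwOr(acc[p], sets[ch])
    }
    sets[p] <- acc[p]
  }
  states <- integer(ti$nnode)
  root <- ti$root
  states[root] <- if (sets[root] == 2L) 1L else 0L
  for (k in rev(seq_len(nrow(ti$edge)))) {
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    pmask <- if (states[p] == 0L) 1L else 2L
    states[ch] <- if (bitwAnd(sets[ch], pmask) > 0L) states[p]
                  else if (sets[ch] == 2L) 1L else 0L
  }
  states
}

#' Full ancestral-state reconstruction over a character matrix
#'
#' Prunes the tree to the sampled genera, fits an Mk1 rate and computes
#' marginal reconstructions per character, counts gains and losses from
#' the MAP node labelling, and classifies every character against every
#' named clade. Characters present in every genus are reported as
#' ubiquitous and receive no clade calls.
#'
#' @param tree rooted `phylo`; tips must cover the matrix genera.
#' @param cm a [character_matrix()].
#' @param clades named list of tip-label vectors (clade definitions;
#'   intersected with the sampled genera, clades with < 1 sampled genus
#'   are dropped).
#' @param method node labelling for origin counting: `"ml"` (MAP from the
#'   marginal reconstruction, default) or `"parsimony"` (Fitch
#'   refinement).
#' @param per_character fit one Mk rate per character (default) or share.
#' @param q_min,q_max rate search bounds.
#' @return an object of class `"asr_result"`: per-character list
#'   (`rate`, `loglik`, `marginal`, `map`, `gains`, `losses`, `calls`),
#'   `report` data frame, `clade_table` (per-clade present/absent class
#'   summary), `ubiquitous` characters and the pruned `tree`.
#' @export
run_asr <- function(tree, cm, clades = list(), method = c("ml", "parsimony"),
                    per_character = TRUE, q_min = 1e-8, q_max = 100) {
  method <- match.arg(method)
  genera <- rownames(cm$states)
  missing <- setdiff(genera, tree$tip.label)
  if (length(missing))
    stopf("matrix genera missing from tree: %s", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, genera)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree <- validate_tree(tree)
  clades <- lapply(clades, function(tp) intersect(tp, tree$tip.label))
  clades <- clades[lengths(clades) >= 1]
  states <- cm$states  # genera (tips) x characters
  chars <- colnames(states)
  rates <- estimate_rate(tree, states, per_character = per_character,
                         q_min = q_min, q_max = q_max)
  shared_q <- if (!per_character) rates$q[1] else NA_real_
  per_char <- stats::setNames(vector("list", length(chars)), chars)
  ubiquitous <- character(0)
  rows <- list()
  for (j in seq_along(chars)) {
    v <- states[, j]
    qj <- if (per_character) rates$q[j] else shared_q
    if (all(v == 1)) ubiquitous <- c(ubiquitous, chars[j])
    if (length(unique(v)) == 1) {
      n_all <- length(tree$tip.label) + tree$Nnode
      node_states <- rep(v[1], n_all)
      per_char[[chars[j]]] <- list(
        rate = qj, loglik = rates$loglik[min(j, nrow(rates))],
        marginal = NULL, map = node_states,
        gains = 0L, losses = 0L,
        calls = stats::setNames(rep("uninformative", length(clades)),
                                names(clades)),
        constant = TRUE)
    } else {
      asr <- marginal_asr(tree, v, qj)
      ns <- if (method == "parsimony") fitch_states(tree, v) else asr$map
      oc <- count_origins(tree, ns)
      calls <- vapply(clades, function(tp)
        classify_character(tree, v, ns, tp), character(1))
      per_char[[chars[j]]] <- list(
        rate = qj, loglik = asr$loglik, marginal = asr$marginal,
        map = ns, gains = oc$gains, losses = oc$losses,
        calls = calls, constant = FALSE)
    }
    pc <- per_char[[chars[j]]]
    rows[[j]] <- data.frame(
      character = chars[j], rate = pc$rate, loglik = pc$loglik,
      gains = pc$gains, losses = pc$losses,
      ubiquitous = chars[j] %in% ubiquitous,
      provenance = if (!is.null(cm$provenance)) cm$provenance[chars[j]]
                   else NA_character_,
      row.names = NULL)
  }
  report <- do.call(rbind, rows)
  clade_table <- if (length(clades)) {
    do.call(rbind, lapply(names(clades), function(cl) {
      calls <- vapply(per_char, function(pc)
        unname(pc$calls[cl]) %||% "uninformative", character(1))
      data.frame(
        clade = cl,
        classes_present = paste(chars[calls %in%
          c("synapomorphy_present", "homoplasy_present")], collapse = "; "),
        classes_absent = paste(chars[calls %in%
          c("synapomorphy_absent", "homoplasy_absent")], collapse = "; "),
        synapomorphies = paste(chars[startsWith(calls, "synapomorphy")],
                               collapse = "; "),
        row.names = NULL)
    }))
  } else NULL
  structure(list(characters = per_char, report = report,
                 clade_table = clade_table, ubiquitous = ubiquitous,
                 tree = tree, method = method),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("<asr_result> %d characters on %d genera (%s labelling); %d ubiquitous\n",
              nrow(x$report), length(x$tree$tip.label), x$method,
              length(x$ubiquitous)))
  invisible(x)
}
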