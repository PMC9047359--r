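#' Bray-Curtis distances between samples
#'
#' D_xy = sum|x_i - y_i| / sum(x_i + y_i) over features, computed on the
#' samples of a feature table (columns).
#'
#' @param table a [feature_table()] or a samples x features numeric matrix.
#' @return a `dist` object with attribute `metric = "braycurtis"`.
#' @export
bray_curtis <- function(table) {
  x <- sample_matrix(table)
  zero <- rowSums(x) == 0
  if (any(zero))
    stopf("all-zero sample(s): %s", paste(rownames(x)[zero], collapse = ", "))
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "metric") <- "braycurtis"
  d
}

#' Canberra distances between samples
#'
#' D_xy = sum over features with x_i + y_i > 0 of |x_i - y_i| / (x_i + y_i);
#' features at zero in both samples are skipped and no renormalisation by
#' feature count is applied (the plain ecological definition; note that
#' some implementations divide by the number of non-zero pairs).
#'
#' @inheritParams bray_curtis
#' @return a `dist` object with attribute `metric = "canberra"`.
#' @export
canberra <- function(table) {
  x <- sample_matrix(table)
  d <- stats::dist(x, method = "canberra")
  attr(d, "metric") <- "canberra"
  d
}

# Accept a feature_table (features x samples) or a samples x features matrix.
sample_matrix <- function(table) {
  if (inherits(table, "feature_table")) t(table$areas)
  else as.matrix(table)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' squared-distance matrix. Axes are ordered by decreasing eigenvalue;
#' axes with negative eigenvalues are reported but carry no coordinates,
#' and the proportion of variance explained is taken over the positive
#' eigenvalues only (no Lingoes/Cailliez correction).
#'
#' @param D a `dist` object or symmetric distance matrix (n >= 3 samples).
#' @return list with `coordinates` (n x k matrix), `eigenvalues` (all n)
#'   and `prop_explained` (per positive axis).
#' @export
pcoa <- function(D) {
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  if (n < 3) stopf("PCoA needs at least 3 samples, got %d", n)
  # cmdscale warns when k exceeds the positive-eigenvalue count; negative
  # eigenvalues are expected with semimetric distances and reported as-is
  fit <- suppressWarnings(stats::cmdscale(Dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       prop_explained = eig[pos] / sum(eig[pos]))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F from the partition of squared inter-point distances:
#' SS_total = sum over all pairs of D^2 / N, SS_within the analogous
#' per-group sum, F = (SS_between/(a-1)) / (SS_within/(N-a)). Significance
#' is assessed by unrestricted permutation of the group labels;
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param D a `dist` or symmetric matrix over samples.
#' @param groups factor-like group labels, aligned to `D`'s samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream (optional).
#' @return list of class `"permanova_result"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `df`, `ss`, `groups`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  B <- as.matrix(D)^2
  n <- nrow(B)
  g <- as.factor(groups)
  if (length(g) != n) stopf("groups length %d != %d samples", length(g), n)
  a <- nlevels(g)
  if (a < 2) stopf("need at least 2 groups")
  sizes <- tabulate(g)
  if (any(sizes < 1)) stopf("every group needs at least 1 sample")
  ss_t <- sum(B) / (2 * n)
  ss_w_for <- function(lab) {
    s <- 0
    for (l in seq_len(a)) {
      idx <- lab == l
      s <- s + sum(B[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  gi <- as.integer(g)
  ss_w <- ss_w_for(gi)
  f_of <- function(ssw) ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ss_w)
  p <- NA_real_
  if (n_perm > 0) {
    perms <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) sample(gi), integer(n)))
    ssw_perm <- numeric(n_perm)
    for (l in seq_len(a)) {
      M <- perms == l
      storage.mode(M) <- "double"
      ssw_perm <- ssw_perm + colSums((B %*% M) * M) / (2 * sizes[l])
    }
    f_perm <- f_of(ssw_perm)
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_perm,
                 df = c(between = a - 1, within = n - a),
                 ss = c(total = ss_t, between = ss_t - ss_w, within = ss_w),
                 groups = levels(g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Partition samples into two groups by 2-medoid clustering
#'
#' Operationalises the two chemical-profile clusters read off a PCoA plot:
#' partitioning around medoids with k = 2 on the distance matrix. The group
#' containing the lexicographically first sample id is labelled "A". If
#' between-group separation is no better than within-group spread
#' (silhouette <= 0) the result is flagged low-separation.
#'
#' @param D a `dist` or symmetric matrix over >= 4 samples.
#' @return list with `labels` (named "A"/"B" vector), `medoids` and
#'   `low_separation` flag.
#' @export
cluster_two_groups <- function(D) {
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  if (n < 4) stopf("need at least 4 samples, got %d", n)
  ids <- rownames(Dm) %||% as.character(seq_len(n))
  ord <- order(ids)
  fit <- cluster::pam(stats::as.dist(Dm[ord, ord]), k = 2, diss = TRUE)
  cl <- fit$clustering
  first_grp <- cl[1]  # ids are sorted, so element 1 is the lexicographic first
  lab <- ifelse(cl == first_grp, "A", "B")
  names(lab) <- ids[ord]
  lab <- lab[ids]
  sil <- mean(cluster::silhouette(fit)[, "sil_width"])
  list(labels = lab, medoids = ids[ord][fit$id.med],
       low_separation = !is.finite(sil) || sil <= 0)
}
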