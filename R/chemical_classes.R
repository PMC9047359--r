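#' Construct a chemical classification table
#'
#' Per-feature chemical taxonomy (superclass / class / subclass, lower
#' levels may be `NA`) and a binary molecular fingerprint per feature.
#' A non-null subclass implies a non-null class, which implies a non-null
#' superclass (hierarchical consistency).
#'
#' @param feature_id character vector of feature ids (unique).
#' @param superclass,class,subclass character vectors (`NA` allowed).
#' @param fingerprints binary matrix, one row per feature, uniform width;
#'   `NULL` if unavailable.
#' @return an object of class `"classification_table"`.
#' @export
classification_table <- function(feature_id, superclass, class = NA,
                                 subclass = NA, fingerprints = NULL) {
  n <- length(feature_id)
  if (anyDuplicated(feature_id)) stopf("duplicate feature ids")
  df <- data.frame(feature_id = as.character(feature_id),
                   superclass = rep_len(as.character(superclass), n),
                   class = rep_len(as.character(class), n),
                   subclass = rep_len(as.character(subclass), n),
                   stringsAsFactors = FALSE)
  bad <- (!is.na(df$subclass) & is.na(df$class)) |
         (!is.na(df$class) & is.na(df$superclass))
  if (any(bad))
    stopf("non-hierarchical classification for: %s",
          paste(utils::head(df$feature_id[bad], 5), collapse = ", "))
  if (!is.null(fingerprints)) {
    fingerprints <- as.matrix(fingerprints)
    if (nrow(fingerprints) != n) stopf("fingerprint rows != features")
    if (!all(fingerprints %in% c(0, 1))) stopf("fingerprints must be binary")
    rownames(fingerprints) <- df$feature_id
  }
  structure(list(taxonomy = df, fingerprints = fingerprints),
            class = "classification_table")
}

#' Hierarchical chemistry tree from molecular fingerprints
#'
#' Euclidean pairwise distances between binary fingerprint vectors,
#' agglomeratively clustered (average linkage by default) into a rooted
#' tree whose leaves are feature ids.
#'
#' @param cls a [classification_table()] with fingerprints (>= 2 features).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return a rooted `phylo` tree.
#' @export
build_chemistry_tree <- function(cls, linkage = "average") {
  fp <- cls$fingerprints
  if (is.null(fp) || nrow(fp) < 2)
    stopf("need fingerprints for at least 2 features")
  d <- stats::dist(fp, method = "euclidean")
  if (all(d == 0)) warnf("all fingerprints identical; tree is a star at height 0")
  hc <- stats::hclust(d, method = linkage)
  tr <- ape::as.phylo(hc)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Prune a chemistry tree to superclass-classified leaves
#'
#' Removes leaves whose feature has no superclass annotation; internal
#' degree-2 nodes left behind are contracted with their branch lengths
#' summed, so leaf-to-leaf path lengths are preserved.
#'
#' @param tree a `phylo` whose tip labels are feature ids.
#' @param cls a [classification_table()] covering the tips.
#' @return the pruned `phylo`.
#' @export
prune_to_superclass <- function(tree, cls) {
  tax <- cls$taxonomy
  unknown <- setdiff(tree$tip.label, tax$feature_id)
  if (length(unknown))
    stopf("tips missing from classification: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  drop <- tree$tip.label[is.na(tax$superclass[match(tree$tip.label,
                                                    tax$feature_id)])]
  if (length(drop) == length(tree$tip.label))
    stopf("no tips classified to superclass level")
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Per-sample relative abundance of chemical classes
#'
#' For each sample, the class value is the summed area of the features
#' assigned to that class divided by the sample's total area over all
#' features, so values lie in \[0, 1\] and sum to at most 1 per sample
#' (unclassified features contribute to the denominator only).
#'
#' @param table a [feature_table()].
#' @param cls a [classification_table()].
#' @param level taxonomy level to aggregate (`"class"`, `"superclass"`,
#'   `"subclass"`).
#' @return samples x classes matrix of relative abundances.
#' @export
class_abundance_table <- function(table, cls, level = "class") {
  level <- match.arg(level, c("superclass", "class", "subclass"))
  lab <- cls$taxonomy[[level]][match(rownames(table$areas),
                                     cls$taxonomy$feature_id)]
  tot <- colSums(table$areas)
  if (any(tot == 0))
    stopf("zero total area in sample(s): %s",
          paste(colnames(table$areas)[tot == 0], collapse = ", "))
  keep <- !is.na(lab)
  if (!any(keep)) stopf("no features classified at the %s level", level)
  agg <- rowsum(table$areas[keep, , drop = FALSE], lab[keep])
  out <- t(agg) / tot
  out[, order(colnames(out)), drop = FALSE]
}

#' Clade-level enrichment of chemical classes
#'
#' Relative class abundances are arcsine-square-root transformed and each
#' class tested for a clade effect with a one-way ANOVA across the tested
#' clades; raw p-values are Benjamini-Hochberg adjusted across classes,
#' pairwise clade differences assessed with Tukey's HSD, and the magnitude
#' of enrichment reported as log2 fold changes of untransformed mean
#' relative abundances between clade pairs. Classes constant across all
#' samples carry no information and are skipped with a note.
#'
#' @param abund samples x classes relative-abundance matrix
#'   (from [class_abundance_table()]).
#' @param meta a [sample_metadata()] for the rows of `abund`.
#' @param clades_tested clades to include (default: all in `meta`).
#' @param alpha adjusted-p cutoff for the heatmap matrix (default 0.05).
#' @return list of class `"enrichment_result"`: `stats` (per-class data
#'   frame with F, p, adjusted p), `tukey` (named list of pairwise p
#'   matrices), `log2fc` (class x clade-pair matrix), `heatmap` (mean
#'   relative abundance, significant classes x clades), `skipped`.
#' @export
enrichment_anova <- function(abund, meta, clades_tested = NULL,
                             alpha = 0.05) {
  meta <- sample_metadata(meta)
  m <- meta[match(rownames(abund), meta$sample_id), ]
  if (anyNA(m$sample_id)) stopf("metadata missing for some samples")
  clades_tested <- clades_tested %||% sort(unique(m$clade))
  keep <- m$clade %in% clades_tested
  abund <- abund[keep, , drop = FALSE]
  clade <- factor(m$clade[keep], levels = sort(clades_tested))
  if (any(table(clade) < 2)) stopf("each tested clade needs >= 2 samples")
  if (any(abund < 0 | abund > 1)) stopf("abundances must lie in [0, 1]")
  y <- asin(sqrt(abund))
  classes <- colnames(abund)
  skipped <- character(0)
  Fv <- pv <- stats::setNames(rep(NA_real_, length(classes)), classes)
  tukey <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    if (stats::var(y[, cl]) == 0) { skipped <- c(skipped, cl); next }
    fit <- stats::aov(y[, cl] ~ clade)
    tab <- summary(fit)[[1]]
    Fv[cl] <- tab$`F value`[1]
    pv[cl] <- tab$`Pr(>F)`[1]
    tukey[[cl]] <- stats::TukeyHSD(fit)$clade
  }
  tested <- !is.na(pv)
  padj <- stats::setNames(rep(NA_real_, length(classes)), classes)
  padj[tested] <- stats::p.adjust(pv[tested], method = "BH")
  means <- apply(abund, 2, function(v) tapply(v, clade, mean))
  means <- matrix(means, nrow = nlevels(clade),
                  dimnames = list(levels(clade), classes))
  pairs <- utils::combn(levels(clade), 2)
  l2fc <- matrix(NA_real_, length(classes), ncol(pairs),
                 dimnames = list(classes,
                                 paste(pairs[1, ], pairs[2, ], sep = "/")))
  for (k in seq_len(ncol(pairs)))
    l2fc[, k] <- log2(means[pairs[1, k], ] / means[pairs[2, k], ])
  sig <- classes[tested & !is.na(padj) & padj < alpha]
  structure(list(
    stats = data.frame(class = classes, mean_abundance = colMeans(abund),
                       F = Fv, p = pv, p_adj = padj, row.names = NULL),
    tukey = tukey[tested], log2fc = l2fc,
    heatmap = t(means[, sig, drop = FALSE]),
    clade_means = means, skipped = skipped, alpha = alpha),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  nsig <- sum(!is.na(x$stats$p_adj) & x$stats$p_adj < x$alpha)
  cat(sprintf("<enrichment_result> %d classes tested, %d significant at adj p < %g, %d skipped\n",
              sum(!is.na(x$stats$p)), nsig, x$alpha, length(x$skipped)))
  invisible(x)
}
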