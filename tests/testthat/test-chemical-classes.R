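fp_table <- function(fp, superclass = "SC", class = "C", subclass = NA) {
  classification_table(rownames(fp), superclass, class, subclass, fp)
}

test_that("classification tables enforce hierarchical levels", {
  expect_error(classification_table("f1", superclass = NA, class = "C"),
               "non-hierarchical")
  expect_error(classification_table("f1", superclass = "S", class = NA,
                                    subclass = "sub"), "non-hierarchical")
  ok <- classification_table(c("f1", "f2"), c("S", NA), c("C", NA))
  expect_s3_class(ok, "classification_table")
})

test_that("chemistry tree clusters fingerprints by Euclidean distance", {
  fp <- rbind(f1 = c(0, 0, 0, 0), f2 = c(0, 0, 0, 1),
              f3 = c(1, 1, 1, 1))
  tr <- build_chemistry_tree(fp_table(fp))
  expect_s3_class(tr, "phylo")
  # outlier joins last: f1/f2 form a cherry
  cherry <- ape::extract.clade(tr, ape::getMRCA(tr, c("f1", "f2")))
  expect_setequal(cherry$tip.label, c("f1", "f2"))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))

  dup <- rbind(f1 = c(1, 0), f2 = c(1, 0), f3 = c(0, 1))
  tr2 <- build_chemistry_tree(fp_table(dup))
  h <- ape::node.depth.edgelength(tr2)
  depth <- max(h)
  mrca12 <- ape::getMRCA(tr2, c("f1", "f2"))
  expect_equal(depth - h[mrca12], 0)  # identical fingerprints merge at 0

  expect_warning(build_chemistry_tree(fp_table(rbind(f1 = c(1, 0),
                                                     f2 = c(1, 0)))),
                 "identical")
})

test_that("chemistry tree topology ignores input row order", {
  set.seed(31)
  fp <- matrix(rbinom(8 * 16, 1, 0.5), 8,
               dimnames = list(paste0("f", 1:8), NULL))
  t1 <- build_chemistry_tree(fp_table(fp))
  t2 <- build_chemistry_tree(fp_table(fp[sample(8), ]))
  expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE))
})

test_that("superclass pruning drops unclassified leaves, keeps path lengths", {
  set.seed(32)
  fp <- matrix(rbinom(4 * 16, 1, 0.5), 4,
               dimnames = list(paste0("f", 1:4), NULL))
  cls_all <- fp_table(fp)
  tr <- build_chemistry_tree(cls_all)
  expect_identical(prune_to_superclass(tr, cls_all)$tip.label, tr$tip.label)

  cls <- classification_table(paste0("f", 1:4),
                              c("S", "S", NA, "S"), c("C", "C", NA, "C"),
                              fingerprints = fp)
  pruned <- prune_to_superclass(tr, cls)
  expect_setequal(pruned$tip.label, c("f1", "f2", "f4"))
  expect_equal(as.matrix(ape::cophenetic.phylo(pruned))[pruned$tip.label,
                                                        pruned$tip.label],
               as.matrix(ape::cophenetic.phylo(tr))[pruned$tip.label,
                                                    pruned$tip.label],
               tolerance = 1e-10)
  # no unary nodes survive contraction
  expect_true(all(tabulate(pruned$edge[, 1]) != 1))

  none <- classification_table(paste0("f", 1:4), NA, fingerprints = fp)
  expect_error(prune_to_superclass(tr, none), "no tips")
})

test_that("class abundance is a per-sample relative sum", {
  areas <- matrix(c(10, 10, 0,   30, 10, 0), 3, 2,
                  dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  tb <- feature_table(areas, data.frame(feature_id = rownames(areas),
                                        mz = 1:3, rt = 1:3))
  cls <- classification_table(c("f1", "f2", "f3"), "S",
                              c("C1", "C2", "C2"))
  ab <- class_abundance_table(tb, cls)
  expect_equal(ab["s1", ], c(C1 = 0.5, C2 = 0.5))
  expect_equal(ab["s2", ], c(C1 = 0.75, C2 = 0.25))
  expect_true(all(rowSums(ab) <= 1 + 1e-12))

  # unclassified features dilute the classified share
  cls2 <- classification_table(c("f1", "f2", "f3"), c("S", NA, NA),
                               c("C1", NA, NA))
  ab2 <- class_abundance_table(tb, cls2)
  expect_equal(ab2["s1", "C1"], 0.5)

  # scale invariance per sample
  tb10 <- feature_table(areas * 10, tb$feature_meta)
  expect_equal(class_abundance_table(tb10, cls), ab)

  zero <- feature_table(areas * c(1, 1, 1, 0, 0, 0), tb$feature_meta)
  expect_error(class_abundance_table(zero, cls), "s2")
})

test_that("enrichment ANOVA applies the arcsine-sqrt transform and log2FC", {
  expect_equal(asin(sqrt(0)), 0)
  expect_equal(asin(sqrt(1)), pi / 2)
  set.seed(41)
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:12), species = paste0("sp", 1:12),
    genus = paste0("G", 1:12), clade = rep(c("A", "B"), each = 6)))
  ab <- cbind(up = c(rep(0.2, 6), rep(0.1, 6)),
              flat = rep(0.3, 12),
              noise = runif(12, 0.1, 0.2))
  rownames(ab) <- meta$sample_id
  enr <- enrichment_anova(ab, meta)
  expect_identical(enr$skipped, "flat")
  expect_equal(enr$log2fc["up", "A/B"], 1)  # means 0.2 vs 0.1
  expect_equal(enr$log2fc["noise", "A/B"],
               log2(enr$clade_means["A", "noise"] /
                    enr$clade_means["B", "noise"]))
  st <- enr$stats[enr$stats$class == "up", ]
  expect_lt(st$p_adj, 0.05)
  expect_true(all(enr$stats$p_adj >= enr$stats$p, na.rm = TRUE))
  expect_true("up" %in% rownames(enr$heatmap))
  # Tukey p-values present for tested classes
  expect_true(all(c("up", "noise") %in% names(enr$tukey)))
})

test_that("BH adjustment matches p.adjust and the step-up definition", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("a planted clade-exclusive class is flagged in repeated simulations", {
  hits <- 0
  n_runs <- 50
  for (s in seq_len(n_runs)) {
    cfg <- simulation_config(seed = 1000 + s, n_genera = 8, clades = 2,
                             n_compound_families = 4,
                             planted_class_by_clade = c(A = "Flavonoids"))
    fam <- simulate_compound_families(cfg)
    tc <- simulate_tree(cfg)
    ft <- simulate_feature_table(cfg, fam$truth, tc$clades)
    cls <- classification_table(fam$truth$feature_id, "S", fam$truth$class)
    ab <- class_abundance_table(ft$table, cls)
    enr <- enrichment_anova(ab, ft$meta)
    st <- enr$stats[enr$stats$class == "Flavonoids", ]
    means <- enr$clade_means[, "Flavonoids"]
    if (!is.na(st$p_adj) && st$p_adj < 0.05 && which.max(means) == 1)
      hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})
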