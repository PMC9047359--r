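make_table <- function(ids, samples, areas) {
  feature_table(matrix(areas, length(ids), length(samples),
                       dimnames = list(ids, samples)),
                data.frame(feature_id = ids, mz = seq_along(ids) * 100,
                           rt = seq_along(ids)))
}

make_meta <- function(samples, clades) {
  sample_metadata(data.frame(sample_id = samples,
                             species = paste0("sp_", samples),
                             genus = paste0("G_", samples),
                             clade = clades))
}

test_that("pairwise scores honour both edge thresholds", {
  set.seed(3)
  fam <- simulate_compound_families(simulation_config(seed = 3,
                                                      n_compound_families = 3))
  sc <- pairwise_scores(fam$spectra)
  fam_of <- setNames(fam$truth$family, fam$truth$feature_id)
  expect_gt(nrow(sc), 0)
  expect_true(all(fam_of[sc$u] == fam_of[sc$v]))  # only within-family edges
  expect_true(all(sc$cosine > 0.7 & sc$n_matched >= 4))

  strict <- pairwise_scores(fam$spectra, similarity_params(min_cosine = 1 + 1e-9))
  expect_equal(nrow(strict), 0)

  dup <- list(spectrum("d1", 400, cbind(c(100, 150, 200, 250), rep(1, 4))),
              spectrum("d2", 400, cbind(c(100, 150, 200, 250), rep(1, 4))))
  sd <- pairwise_scores(dup)
  expect_equal(sd$cosine, 1, tolerance = 1e-12)
})

test_that("raising min_cosine never adds edges", {
  set.seed(13)
  spectra <- lapply(1:8, function(i) rand_spectrum(paste0("s", i), 6))
  spectra <- c(spectra, list({s <- spectra[[1]]; s$feature_id <- "s9"; s}))
  lo <- pairwise_scores(spectra, similarity_params(min_cosine = 0.5,
                                                   min_matched_peaks = 1))
  hi <- pairwise_scores(spectra, similarity_params(min_cosine = 0.9,
                                                   min_matched_peaks = 1))
  key <- function(df) paste(df$u, df$v)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("network nodes carry clade pies, sizes, and singleton components", {
  samples <- c("s1", "s2", "s3")
  meta <- make_meta(samples, c("A", "A", "B"))
  tb <- make_table(c("f1", "f2", "f3"), samples,
                   c(10, 10, 0,   20, 20, 0,   0, 0, 0))
  scores <- data.frame(u = "f1", v = "f2", cosine = 0.95, n_matched = 5L)
  net <- build_network(scores, tb, meta)
  expect_equal(net$clade_abundance["f1", ], c(A = 1, B = 0))
  expect_equal(net$nodes$node_size[net$nodes$feature_id == "f2"], 30)
  expect_true(net$nodes$zero_abundance[net$nodes$feature_id == "f3"])
  expect_equal(length(unique(net$component)), 2)  # f1-f2 plus singleton f3
  expect_error(build_network(data.frame(u = "zz", v = "f1", cosine = 1,
                                        n_matched = 5L), tb, meta),
               "zz")
})

test_that("planted families come back as network components", {
  cfg <- simulation_config(seed = 5, n_compound_families = 4)
  fam <- simulate_compound_families(cfg)
  ftab <- simulate_feature_table(cfg, fam$truth,
                                 simulate_tree(cfg)$clades)
  net <- build_network(pairwise_scores(fam$spectra), ftab$table, ftab$meta)
  expect_equal(length(unique(net$component)), 4)
  ari <- mclust::adjustedRandIndex(
    net$nodes$component,
    fam$truth$family[match(net$nodes$feature_id, fam$truth$feature_id)])
  expect_equal(ari, 1)
})

test_that("library search returns the best passing hit", {
  base <- spectrum("LIBA", 400, cbind(c(100, 150, 200, 250), c(5, 9, 2, 7)))
  base$compound <- "cmpdA"; base$class <- "Flavonoids"
  near <- spectrum("LIBB", 400.005,
                   cbind(c(100, 150, 200, 250.3), c(5, 9, 2, 7)))
  near$compound <- "cmpdB"; near$class <- "Lipids"
  q <- base; q$feature_id <- "Q1"
  hits <- library_search(list(q), list(near, base))
  expect_equal(nrow(hits), 1)
  expect_identical(hits$library_compound_id, "cmpdA")
  expect_equal(hits$score, 1, tolerance = 1e-12)
  expect_identical(hits$class, "Flavonoids")

  # below-threshold scores yield no hit
  far <- spectrum("Q2", 400, cbind(c(101.3, 151.7, 222, 260), c(1, 1, 1, 1)))
  expect_equal(nrow(library_search(list(far), list(base))), 0)
  expect_equal(nrow(library_search(list(q), list())), 0)

  # precursor tolerance gates candidates
  off <- base; off$feature_id <- "Q3"; off$precursor_mz <- 405
  expect_equal(nrow(library_search(list(off), list(base))), 0)
})

test_that("extraction overlap computes Venn counts and percentages", {
  tbA <- make_table(c("f1", "f2", "f3"), "s1", c(1, 1, 1))
  tbB0 <- make_table(c("f1", "f2", "f3", "f4"), "s1", c(0, 1, 1, 1))
  ov <- extraction_overlap(list(hydroethanolic = tbA, ethyl_acetate = tbB0))
  expect_equal(unname(ov$counts["shared"]), 2)
  expect_equal(unname(ov$counts["total"]), 4)
  expect_equal(unname(ov$percent["shared"]), 50)

  same <- extraction_overlap(list(a = tbA, b = tbA))
  expect_equal(unname(same$percent["shared"]), 100)
  disj <- extraction_overlap(list(a = make_table("f1", "s1", 1),
                                  b = make_table("f9", "s1", 1)))
  expect_equal(unname(disj$percent["shared"]), 0)
})

test_that("network exports round-trip through GraphML and TSV", {
  samples <- c("s1", "s2")
  meta <- make_meta(samples, c("A", "B"))
  tb <- make_table(c("f1", "f2", "f3"), samples, runif(6, 1, 100))
  scores <- data.frame(u = c("f1", "f2"), v = c("f2", "f3"),
                       cosine = c(0.912345, 0.876543), n_matched = c(5L, 4L))
  net <- build_network(scores, tb, meta)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g, "graphml")
  back <- read_network(g)
  expect_setequal(paste(back$edges$u, back$edges$v),
                  paste(net$edges$u, net$edges$v))
  expect_equal(sort(back$edges$cosine), sort(net$edges$cosine),
               tolerance = 1e-6)
  expect_setequal(back$nodes$feature_id, net$nodes$feature_id)
  ord <- match(net$nodes$feature_id, back$nodes$feature_id)
  expect_equal(back$nodes$node_size[ord], net$nodes$node_size,
               tolerance = 1e-6)
  expect_equal(back$nodes$clade_A[ord], net$clade_abundance[, "A"],
               tolerance = 1e-6, ignore_attr = TRUE)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "edge_tsv")
  e <- read.delim(tsv)
  expect_equal(e$cosine, net$edges$cosine)
  expect_error(write_network(net, tsv, "dot"))

  empty <- build_network(scores[0, ], tb, meta)
  write_network(empty, g, "graphml")
  expect_equal(nrow(read_network(g)$edges), 0)
})
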