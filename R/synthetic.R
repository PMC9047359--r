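#' Simulation configuration for the synthetic chemotaxonomy study
#'
#' Collects every knob of the ground-truthed generator: taxon sampling,
#' compound families related by neutral-loss shifts (defaults: hexoside
#' 162.053, deoxyhexoside 146.058, pentoside 132.042 and water 18.011 Da),
#' clade-structured abundances with a planted clade-exclusive class,
#' and binary characters evolved under the Mk1 model on a pure-birth tree.
#' A single master seed drives a derived per-stage stream, so each stage
#' is reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param n_genera number of genera (tree tips).
#' @param species_per_genus species sampled per genus (one sample each).
#' @param clades either an integer number of clades to carve from the
#'   simulated tree, or a named list of genus vectors (checked for
#'   monophyly, tree redrawn up to `clade_retry` times).
#' @param n_compound_families,members_per_family molecular-family layout.
#' @param peaks_per_spectrum fragment peaks per spectrum (>= 4).
#' @param neutral_losses Da shifts relating family members.
#' @param class_labels chemical class names, recycled over families.
#' @param planted_class_by_clade named map clade -> class; features of that
#'   class get nonzero areas only in that clade's samples.
#' @param abundance_meanlog,abundance_sdlog lognormal peak-area parameters.
#' @param dropout_prob per-cell probability of a missing (zero) area.
#' @param solvent_feature_loss probability that a feature is missed
#'   entirely by the second extraction solvent (protocol selectivity).
#' @param mk_rate Mk1 rate q used for character simulation.
#' @param n_characters number of Mk characters simulated.
#' @param intensity_jitter_sdlog lognormal jitter on member peak
#'   intensities (0 = identical spectra within a family).
#' @param clade_retry redraws allowed when user clades are non-monophyletic.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1, n_genera = 12, species_per_genus = 2,
                              clades = 4, n_compound_families = 6,
                              members_per_family = 4, peaks_per_spectrum = 12,
                              neutral_losses = c(162.053, 146.058, 132.042, 18.011),
                              class_labels = c("Flavonoids", "Terpenoids",
                                               "Alkaloids", "Phenylpropanoids",
                                               "Lipids", "Iridoids"),
                              planted_class_by_clade = c(A = "Flavonoids"),
                              abundance_meanlog = 11, abundance_sdlog = 1,
                              dropout_prob = 0.1, solvent_feature_loss = 0.25,
                              mk_rate = 1,
                              n_characters = 50,
                              intensity_jitter_sdlog = 0.1,
                              clade_retry = 100) {
  stopifnot(n_genera >= 2, species_per_genus >= 1,
            dropout_prob >= 0, dropout_prob <= 1, mk_rate > 0)
  if (peaks_per_spectrum < 4)
    stopf("peaks_per_spectrum must be >= 4 to satisfy the matched-peak floor")
  structure(as.list(environment()), class = "simulation_config")
}

genus_names <- function(n) sprintf("Genus%02d", seq_len(n))

#' Simulate a pure-birth phylogeny with named clades
#'
#' Yule tree over the configured genera, ultrametric with root age
#' normalised to 1. Clades are either carved from the drawn tree (an
#' integer `cfg$clades` cuts the dendrogram into that many monophyletic
#' groups, labelled "A", "B", ... in tip order) or taken from a user map,
#' with redraws until every user clade is monophyletic.
#'
#' @param cfg a [simulation_config()].
#' @return list with `tree` (`phylo`) and `clades` (named list of tips).
#' @export
simulate_tree <- function(cfg) {
  draw <- function(attempt) {
    tr <- with_seed(derive_seed(cfg$seed, 11 + attempt),
                    ape::rphylo(cfg$n_genera, birth = 1, death = 0))
    tr$tip.label <- genus_names(cfg$n_genera)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
  }
  if (is.list(cfg$clades)) {
    for (a in seq_len(cfg$clade_retry)) {
      tr <- draw(a)
      ok <- all(vapply(cfg$clades, function(tp)
        length(tp) == 1 || ape::is.monophyletic(tr, tp), logical(1)))
      if (ok) return(list(tree = tr, clades = cfg$clades))
    }
    stopf("no tree with all user clades monophyletic after %d draws",
          cfg$clade_retry)
  }
  tr <- draw(0)
  k <- as.integer(cfg$clades)
  if (k < 1 || k > cfg$n_genera) stopf("clades must be in [1, n_genera]")
  grp <- stats::cutree(stats::as.hclust(tr), k = k)
  # stable clade letters: order groups by their first tip name
  first <- vapply(split(names(grp), grp), min, character(1))
  relab <- stats::setNames(LETTERS[order(order(first))], names(first))
  clades <- split(names(grp), relab[as.character(grp)])
  list(tree = tr, clades = clades[order(names(clades))])
}

#' Number of lineages of a pure-birth process at a fixed time
#'
#' Forward simulation of a Yule process started from one lineage;
#' E\[N(t)\] = exp(lambda t).
#'
#' @param lambda birth rate.
#' @param time elapsed time.
#' @param seed optional seed.
#' @return integer lineage count.
#' @export
pure_birth_size <- function(lambda, time, seed = NULL) {
  with_seed(seed, {
    n <- 1L; t <- 0
    repeat {
      t <- t + stats::rexp(1, rate = n * lambda)
      if (t > time) break
      n <- n + 1L
    }
    n
  })
}

#' Simulate MS/MS spectra of neutral-loss-related compound families
#'
#' Each family starts from a base spectrum; derivative members shift the
#' precursor and a random subset of fragment peaks by a sampled neutral
#' loss, so within-family modified cosines stay high (>= 0.7 with at
#' least 4 matched peaks by construction) while between-family spectra
#' share no aligned fragments.
#'
#' @param cfg a [simulation_config()].
#' @param mode ionization mode tag for the emitted spectra.
#' @param stage internal stream offset (lets positive and negative mode
#'   draws differ).
#' @param class_offset rotation of the class-label assignment, so the two
#'   ionization modes carry partially overlapping class inventories.
#' @return list with `spectra` and `truth` (data frame: `feature_id`,
#'   `family`, `class`).
#' @export
simulate_compound_families <- function(cfg, mode = "positive", stage = 21,
                                       class_offset = 0) {
  if (cfg$peaks_per_spectrum < 4)
    stopf("peaks_per_spectrum must be >= 4")
  with_seed(derive_seed(cfg$seed, stage), {
    spectra <- list(); rows <- list(); idx <- 0
    labels <- cfg$class_labels
    if (class_offset > 0)
      labels <- c(labels[-seq_len(class_offset)], labels[seq_len(class_offset)])
    classes <- rep_len(labels, cfg$n_compound_families)
    for (f in seq_len(cfg$n_compound_families)) {
      prec <- stats::runif(1, 350, 800)
      npk <- cfg$peaks_per_spectrum
      mz <- sort(stats::runif(npk, 60, prec - 20))
      int <- stats::rlnorm(npk, 0, 1)
      int <- int / max(int) * 100
      for (m in seq_len(cfg$members_per_family)) {
        idx <- idx + 1
        id <- sprintf("%s%03d", if (mode == "positive") "P" else "N", idx)
        if (m == 1) {
          p_mz <- mz; p_prec <- prec
        } else {
          loss <- sample(cfg$neutral_losses, 1)
          shift <- stats::runif(npk) < 0.5
          p_mz <- mz + ifelse(shift, loss, 0)
          p_prec <- prec + loss
        }
        p_int <- int * stats::rlnorm(npk, 0, cfg$intensity_jitter_sdlog)
        spectra[[idx]] <- spectrum(id, p_prec, cbind(p_mz, p_int),
                                   rt = stats::runif(1, 0.5, 12), mode = mode)
        rows[[idx]] <- data.frame(feature_id = id, family = f,
                                  class = classes[f])
      }
    }
    list(spectra = spectra, truth = do.call(rbind, rows))
  })
}

#' Simulate a clade-structured feature table with metadata
#'
#' Per-sample areas are lognormal with Bernoulli dropout. Features of a
#' clade's planted class are present in every sample of that clade and in
#' no sample outside it; all other classes occur across clades.
#'
#' @param cfg a [simulation_config()].
#' @param truth feature truth table from [simulate_compound_families()].
#' @param clades named list of genus vectors (from [simulate_tree()]).
#' @param mode ionization mode recorded in the metadata.
#' @param solvent extraction solvent recorded in the metadata.
#' @param stage internal stream offset.
#' @return list with `table` (a [feature_table()]) and `meta`
#'   (a [sample_metadata()]).
#' @export
simulate_feature_table <- function(cfg, truth, clades, mode = "positive",
                                   solvent = "hydroethanolic", stage = 31) {
  genera <- unlist(clades, use.names = FALSE)
  clade_of <- rep(names(clades), lengths(clades))
  names(clade_of) <- genera
  species <- as.vector(t(outer(genera, seq_len(cfg$species_per_genus),
                               function(g, s) sprintf("%s_sp%d", g, s))))
  meta <- sample_metadata(data.frame(
    sample_id = paste0(species, "_", substr(mode, 1, 3)),
    species = species,
    genus = rep(genera, each = cfg$species_per_genus),
    clade = rep(clade_of[genera], each = cfg$species_per_genus),
    solvent = solvent, mode = mode))
  nf <- nrow(truth); ns <- nrow(meta)
  with_seed(derive_seed(cfg$seed, stage), {
    areas <- matrix(stats::rlnorm(nf * ns, cfg$abundance_meanlog,
                                  cfg$abundance_sdlog), nf, ns,
                    dimnames = list(truth$feature_id, meta$sample_id))
    drop <- matrix(stats::runif(nf * ns) < cfg$dropout_prob, nf, ns)
    areas[drop] <- 0
    for (cl in names(cfg$planted_class_by_clade)) {
      if (!cl %in% names(clades)) next
      planted <- truth$class == cfg$planted_class_by_clade[[cl]]
      inside <- meta$clade == cl
      areas[planted, !inside] <- 0
      redraw <- sum(planted) * sum(inside)
      areas[planted, inside] <- stats::rlnorm(redraw, cfg$abundance_meanlog,
                                              cfg$abundance_sdlog)
    }
    # keep every sample detectable without touching planted exclusivity
    planted_any <- truth$class %in% unlist(cfg$planted_class_by_clade)
    free <- which(!planted_any)
    if (!length(free)) free <- seq_len(nf)
    for (j in which(colSums(areas) == 0))
      areas[sample(free, 1), j] <- stats::rlnorm(1, cfg$abundance_meanlog,
                                                 cfg$abundance_sdlog)
    rt <- stats::runif(nf, 0.5, 12)
    mz <- stats::runif(nf, 100, 900)
    list(table = feature_table(areas,
           data.frame(feature_id = truth$feature_id, mz = mz, rt = rt)),
         meta = meta)
  })
}

#' Simulate binary characters under the Mk1 model on a tree
#'
#' Root states are uniform on \{0, 1\}; along each branch of length t the
#' state flips with probability 1/2 - exp(-2qt)/2. Returns tip states,
#' the true internal node states and true origin counts per character.
#'
#' @param tree rooted `phylo`.
#' @param q Mk rate (> 0).
#' @param n_characters number of independent characters.
#' @param seed optional seed.
#' @return list with `matrix` (a [character_matrix()], genera x
#'   characters), `node_states` (nodes x characters) and `origins`
#'   (data frame of true gains/losses per character).
#' @export
simulate_characters_mk <- function(tree, q, n_characters, seed = NULL) {
  stopifnot(q > 0, n_characters >= 1)
  ti <- tree_index(tree)
  with_seed(seed, {
    node_states <- matrix(NA_integer_, ti$nnode, n_characters)
    node_states[ti$root, ] <- stats::rbinom(n_characters, 1, 0.5)
    flip_p <- 0.5 - 0.5 * exp(-2 * q * ti$len)
    for (k in rev(seq_len(nrow(ti$edge)))) {  # preorder
      p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
      flip <- stats::rbinom(n_characters, 1, flip_p[k])
      node_states[ch, ] <- bitwXor(node_states[p, ], flip)
    }
    tips <- node_states[seq_len(ti$ntip), , drop = FALSE]
    rownames(tips) <- ti$tree$tip.label
    colnames(tips) <- sprintf("mk%03d", seq_len(n_characters))
    origins <- do.call(rbind, lapply(seq_len(n_characters), function(j) {
      oc <- count_origins(ti$tree, node_states[, j])
      data.frame(character = colnames(tips)[j], gains = oc$gains,
                 losses = oc$losses)
    }))
    list(matrix = character_matrix(tips[order(rownames(tips)), , drop = FALSE]),
         node_states = node_states, origins = origins,
         tree = ti$tree)
  })
}

#' Simulate per-feature chemical classifications and fingerprints
#'
#' Stand-in for in-silico structure annotation: each chemical class gets a
#' random binary fingerprint prototype; features inherit their class
#' prototype with independent bit flips, so fingerprint distances mirror
#' the class structure. Classes are nested under synthetic superclasses
#' and a fraction of features is left unclassified (all levels `NA`), so
#' superclass pruning has something to remove. Fingerprints are labelled
#' synthetic stand-ins throughout.
#'
#' @param cfg a [simulation_config()].
#' @param truth feature truth table from [simulate_compound_families()].
#' @param fingerprint_length bits per fingerprint.
#' @param flip_prob per-bit deviation from the class prototype.
#' @param unclassified_prob fraction of features with no classification.
#' @param stage internal stream offset.
#' @return a [classification_table()].
#' @export
simulate_classification <- function(cfg, truth, fingerprint_length = 64,
                                    flip_prob = 0.05,
                                    unclassified_prob = 0.1, stage = 61) {
  with_seed(derive_seed(cfg$seed, stage), {
    classes <- unique(truth$class)
    proto <- matrix(stats::rbinom(length(classes) * fingerprint_length, 1, 0.5),
                    length(classes), fingerprint_length,
                    dimnames = list(classes, NULL))
    super_of <- stats::setNames(
      paste0("Superclass_", ((seq_along(classes) - 1) %/% 2) + 1), classes)
    fp <- proto[truth$class, , drop = FALSE]
    flips <- stats::rbinom(length(fp), 1, flip_prob)
    fp <- matrix(bitwXor(as.integer(fp), flips), nrow(fp))
    unclass_ <- stats::runif(nrow(truth)) < unclassified_prob
    classification_table(
      feature_id = truth$feature_id,
      superclass = ifelse(unclass_, NA, super_of[truth$class]),
      class = ifelse(unclass_, NA, truth$class),
      subclass = ifelse(unclass_, NA, paste0(truth$class, "_sub",
                                             truth$family %% 2 + 1)),
      fingerprints = fp)
  })
}

#' Generate a complete synthetic study
#'
#' Draws the phylogeny and clade map, positive- and negative-mode spectra
#' and feature tables (two solvents in positive mode for the extraction
#' overlap), an annotated reference library (a subset of the spectra,
#' relabelled), and Mk characters on the tree. When `dir` is given, all
#' artifacts are written to disk (MGF, CSV, TSV, newick, JSON ground
#' truth) in the package's standard formats.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory.
#' @return list with `tree`, `clades`, per-mode `spectra`, `truth`,
#'   `table`, `meta`, a second-solvent positive table `table_pos_etoac`,
#'   `library`, `characters`, and `paths` when written.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = NULL) {
  tc <- simulate_tree(cfg)
  pos <- simulate_compound_families(cfg, mode = "positive", stage = 21)
  neg <- simulate_compound_families(cfg, mode = "negative", stage = 22,
                                    class_offset = 1)
  ft_pos <- simulate_feature_table(cfg, pos$truth, tc$clades,
                                   mode = "positive", stage = 31)
  ft_neg <- simulate_feature_table(cfg, neg$truth, tc$clades,
                                   mode = "negative", stage = 32)
  # second extraction solvent: independent detection draw, and a fraction
  # of features entirely missed (solvent selectivity), so the two
  # protocols overlap only partially
  ft_pos2 <- simulate_feature_table(cfg, pos$truth, tc$clades,
                                    mode = "positive",
                                    solvent = "ethyl_acetate", stage = 33)
  lost <- with_seed(derive_seed(cfg$seed, 34),
                    stats::runif(nrow(ft_pos2$table$areas)) <
                      cfg$solvent_feature_loss)
  ft_pos2$table$areas[lost, ] <- 0
  lib_idx <- with_seed(derive_seed(cfg$seed, 41),
                       sample(seq_along(pos$spectra),
                              max(2, length(pos$spectra) %/% 3)))
  library <- lapply(lib_idx, function(i) {
    s <- pos$spectra[[i]]
    s$compound <- sprintf("ref_%s", s$feature_id)
    s$feature_id <- sprintf("LIB_%s", s$feature_id)
    s$class <- pos$truth$class[i]
    s
  })
  chars <- simulate_characters_mk(tc$tree, cfg$mk_rate, cfg$n_characters,
                                  seed = derive_seed(cfg$seed, 51))
  cls_pos <- simulate_classification(cfg, pos$truth, stage = 61)
  cls_neg <- simulate_classification(cfg, neg$truth, stage = 62)
  out <- list(tree = tc$tree, clades = tc$clades,
              classification_pos = cls_pos, classification_neg = cls_neg,
              spectra_pos = pos$spectra, truth_pos = pos$truth,
              spectra_neg = neg$spectra, truth_neg = neg$truth,
              table_pos = ft_pos$table, meta_pos = ft_pos$meta,
              table_neg = ft_neg$table, meta_neg = ft_neg$meta,
              table_pos_etoac = ft_pos2$table, meta_pos_etoac = ft_pos2$meta,
              library = library, characters = chars, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      mgf_pos = file.path(dir, "spectra_pos.mgf"),
      mgf_neg = file.path(dir, "spectra_neg.mgf"),
      features_pos = file.path(dir, "features_pos.csv"),
      features_neg = file.path(dir, "features_neg.csv"),
      metadata = file.path(dir, "metadata.tsv"),
      tree = file.path(dir, "tree.nwk"),
      truth = file.path(dir, "ground_truth.json"))
    write_mgf(pos$spectra, paths$mgf_pos)
    write_mgf(neg$spectra, paths$mgf_neg)
    write_feature_table(ft_pos$table, paths$features_pos)
    write_feature_table(ft_neg$table, paths$features_neg)
    write_sample_metadata(rbind(ft_pos$meta, ft_neg$meta), paths$metadata)
    ape::write.tree(tc$tree, paths$tree)
    jsonlite::write_json(list(
      clades = tc$clades,
      family_of_feature = stats::setNames(as.list(c(pos$truth$family,
                                                    neg$truth$family)),
                                          c(pos$truth$feature_id,
                                            neg$truth$feature_id)),
      class_of_feature = stats::setNames(as.list(c(pos$truth$class,
                                                   neg$truth$class)),
                                         c(pos$truth$feature_id,
                                           neg$truth$feature_id)),
      planted_class_by_clade = as.list(cfg$planted_class_by_clade),
      true_origin_counts = chars$origins,
      mk_rate = cfg$mk_rate),
      paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
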