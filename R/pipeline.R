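#' Run the full chemotaxonomic pipeline
#'
#' Orchestrates the workflow from raw inputs to ancestral state
#' reconstruction: ingest (MGF + feature CSV + metadata), MS/MS filter,
#' molecular networking with library search, ordination and PERMANOVA,
#' chemical hierarchy and clade enrichment, genus-level character coding
#' with mode merging, and Mk1 ASR with synapomorphy/homoplasy calls.
#' Each stage's outputs land in `out_dir` together with a JSON run
#' manifest (config hash, seed, per-stage row counts, file checksums).
#'
#' @param config either a YAML file path or a config list. Recognised
#'   fields: `mgf_pos`, `mgf_neg`, `features_pos`, `features_neg`,
#'   `metadata`, `tree`, `dialect`, `similarity` (list of
#'   [similarity_params()] arguments), `metric` (`"braycurtis"` or
#'   `"canberra"`), `group_by` (metadata column for PERMANOVA),
#'   `clades` (named list of genus vectors), `clades_tested`, `alpha`,
#'   `n_perm`, `seed`, `out_dir`, and logical stage switches under
#'   `stages` (`network`, `ordination`, `enrichment`, `asr`).
#' @param classification optional list with per-mode
#'   [classification_table()] objects (`pos`, `neg`); required for the
#'   enrichment/coding/ASR stages.
#' @param library optional annotated spectral library (list of spectra).
#' @return list with all stage results and the manifest (invisibly the
#'   same list written to `out_dir`).
#' @export
run_pipeline <- function(config, classification = NULL, library = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(dialect = "plain", metric = "braycurtis",
                   group_by = "clade", alpha = 0.05, n_perm = 999,
                   seed = 1, similarity = list(),
                   stages = list(network = TRUE, ordination = TRUE,
                                 enrichment = TRUE, asr = TRUE))
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("mgf_pos", "features_pos", "metadata", "tree"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stopf("config field '%s' missing or file not found", f)
  out_dir <- cfg$out_dir %||% tempfile("chemophylo_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(similarity_params, cfg$similarity)
  manifest <- list(package_version = as.character(utils::packageVersion("chemophylo")),
                   seed = cfg$seed, stages = list())
  res <- list(out_dir = out_dir, config = cfg)
  run_stage <- function(name, fun) {
    r <- tryCatch(fun(), error = function(e) {
      writeLines(name, file.path(out_dir, ".partial"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    r
  }

  modes <- c("pos", if (!is.null(cfg$mgf_neg)) "neg")
  ingest <- run_stage("ingest", function() {
    meta <- read_sample_metadata(cfg$metadata)
    out <- list(meta = meta)
    for (m in modes) {
      spectra <- read_mgf(cfg[[paste0("mgf_", m)]])
      tb <- read_feature_table(cfg[[paste0("features_", m)]], cfg$dialect)
      out[[m]] <- list(spectra = spectra,
                       table = filter_features_with_ms2(tb, spectra))
    }
    out
  })
  res$ingest <- ingest
  manifest$stages$ingest <- list(
    n_samples = nrow(ingest$meta),
    n_features = lapply(ingest[modes], function(x) nrow(x$table$areas)))

  tree <- read_newick_tree(cfg$tree)
  clades <- cfg$clades %||% split(ingest$meta$genus, ingest$meta$clade)
  clades <- lapply(clades, unique)

  if (isTRUE(cfg$stages$network)) {
    res$network <- run_stage("network", function() {
      lapply(stats::setNames(modes, modes), function(m) {
        sp <- ingest[[m]]$spectra
        meta_m <- ingest$meta[ingest$meta$sample_id %in%
                                colnames(ingest[[m]]$table$areas), ]
        scores <- pairwise_scores(sp, params)
        net <- build_network(scores, ingest[[m]]$table, meta_m, params)
        if (!is.null(library)) {
          hits <- library_search(sp, library, params)
          net$nodes$annotation[match(hits$feature_id,
                                     net$nodes$feature_id)] <-
            hits$library_compound_id
          net$library_hits <- hits
        }
        write_network(net, file.path(out_dir, paste0("network_", m, ".graphml")))
        net
      })
    })
    manifest$stages$network <- lapply(res$network, function(n)
      list(nodes = nrow(n$nodes), edges = nrow(n$edges),
           components = length(unique(n$component)),
           library_hits = if (!is.null(n$library_hits)) nrow(n$library_hits)))
  }

  if (isTRUE(cfg$stages$ordination)) {
    res$ordination <- run_stage("ordination", function() {
      lapply(stats::setNames(modes, modes), function(m) {
        tb <- ingest[[m]]$table
        D <- if (cfg$metric == "canberra") canberra(tb) else bray_curtis(tb)
        ord <- pcoa(D)
        meta_m <- ingest$meta[match(colnames(tb$areas), ingest$meta$sample_id), ]
        pm <- permanova(D, meta_m[[cfg$group_by]], n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, 71))
        utils::write.table(
          data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, seq_len(min(3, ncol(ord$coordinates))),
                                     drop = FALSE]),
          file.path(out_dir, paste0("pcoa_", m, ".tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
        list(distance = D, pcoa = ord, permanova = pm,
             clusters = cluster_two_groups(D))
      })
    })
    manifest$stages$ordination <- lapply(res$ordination, function(o)
      list(pseudo_F = o$permanova$pseudo_F, p = o$permanova$p_value))
  }

  coded <- NULL
  if (isTRUE(cfg$stages$enrichment)) {
    if (is.null(classification))
      stopf("enrichment stage needs a classification table per mode")
    res$enrichment <- run_stage("enrichment", function() {
      lapply(stats::setNames(modes, modes), function(m) {
        cls <- classification[[m]]
        tb <- ingest[[m]]$table
        meta_m <- ingest$meta[match(colnames(tb$areas), ingest$meta$sample_id), ]
        abund <- class_abundance_table(tb, cls)
        enr <- enrichment_anova(abund, meta_m,
                                clades_tested = cfg$clades_tested,
                                alpha = cfg$alpha)
        tree_chem <- if (!is.null(cls$fingerprints) && nrow(cls$fingerprints) > 2)
          prune_to_superclass(build_chemistry_tree(cls), cls)
        sp_pres <- binarize_classes(abund, meta_m)
        list(abundance = abund, enrichment = enr, chemistry_tree = tree_chem,
             genus_matrix = summarize_to_genus(sp_pres, meta_m, mode = m))
      })
    })
    manifest$stages$enrichment <- lapply(res$enrichment, function(e)
      list(classes = ncol(e$abundance),
           significant = sum(!is.na(e$enrichment$stats$p_adj) &
                               e$enrichment$stats$p_adj < cfg$alpha)))
    coded <- run_stage("character_coding", function() {
      if (length(modes) == 2)
        merge_modes(res$enrichment$pos$genus_matrix,
                    res$enrichment$neg$genus_matrix)
      else res$enrichment$pos$genus_matrix
    })
    res$characters <- coded
    write_character_matrix(coded, file.path(out_dir, "characters.tsv"))
    write_nexus_characters(coded, file.path(out_dir, "characters.nex"))
  }

  if (isTRUE(cfg$stages$asr) && !is.null(coded)) {
    res$asr <- run_stage("asr", function()
      run_asr(tree, coded, clades = clades))
    utils::write.table(res$asr$report, file.path(out_dir, "asr_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$asr$clade_table))
      utils::write.table(res$asr$clade_table,
                         file.path(out_dir, "clade_table.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages$asr <- list(
      characters = nrow(res$asr$report),
      ubiquitous = length(res$asr$ubiquitous))
  }

  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg[order(names(cfg))], cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  unlink(file.path(out_dir, ".partial"))
  invisible(res)
}
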