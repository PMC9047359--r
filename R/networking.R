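#' Pairwise modified-cosine scores for a spectrum collection
#'
#' Scores every unordered spectrum pair and keeps pairs passing the edge
#' thresholds (cosine strictly above `min_cosine` and at least
#' `min_matched_peaks` matched peaks).
#'
#' @param spectra list of [spectrum()] objects.
#' @param params a [similarity_params()].
#' @param clean apply [clean_spectra()] first (default TRUE).
#' @return data frame with columns `u`, `v`, `cosine`, `n_matched`.
#' @export
pairwise_scores <- function(spectra, params = similarity_params(),
                            clean = TRUE) {
  if (clean) spectra <- clean_spectra(spectra, params)
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  ord <- order(ids)
  spectra <- spectra[ord]; ids <- ids[ord]
  n <- length(spectra)
  u <- character(0); v <- character(0); sc <- numeric(0); nm <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      r <- modified_cosine(spectra[[i]], spectra[[j]], params)
      if (r$score > params$min_cosine && r$n_matched >= params$min_matched_peaks) {
        u <- c(u, ids[i]); v <- c(v, ids[j])
        sc <- c(sc, r$score); nm <- c(nm, r$n_matched)
      }
    }
  }
  data.frame(u = u, v = v, cosine = sc, n_matched = nm,
             stringsAsFactors = FALSE)
}

#' Build a feature-based molecular network
#'
#' Nodes are features (all spectra scored, isolated nodes kept as
#' singletons); edges carry the cosine score and matched-peak count. Each
#' node gets its total summed peak area (node size) and the per-clade
#' relative abundance vector used for pie-chart summaries; an all-zero
#' abundance vector is flagged rather than normalised.
#'
#' @param scores edge data frame from [pairwise_scores()].
#' @param table a [feature_table()] covering every scored feature.
#' @param meta a [sample_metadata()] for the table's samples.
#' @param params a [similarity_params()] (recorded in the result).
#' @param blank_fraction optional blank filter: drop features whose mean
#'   area in blank samples is at least this fraction of their mean area in
#'   real samples (`NULL` = off; requires an `is_blank` metadata column).
#' @return an object of class `"molecular_network"` with elements `nodes`
#'   (data frame), `edges` (data frame), `clade_abundance` (matrix),
#'   `component` (named membership vector) and `params`.
#' @export
build_network <- function(scores, table, meta, params = similarity_params(),
                          blank_fraction = NULL) {
  meta <- sample_metadata(meta)
  ids <- rownames(table$areas)
  missing <- setdiff(unique(c(scores$u, scores$v)), ids)
  if (length(missing))
    stopf("features in scores but not in table: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  m <- meta[match(colnames(table$areas), meta$sample_id), ]
  if (anyNA(m$sample_id)) stopf("metadata missing rows for some samples")
  blank <- as.logical(m$is_blank)
  areas <- table$areas
  if (!is.null(blank_fraction) && any(blank)) {
    mb <- rowMeans(areas[, blank, drop = FALSE])
    ms <- rowMeans(areas[, !blank, drop = FALSE])
    drop <- mb >= blank_fraction * pmax(ms, .Machine$double.eps)
    areas <- areas[!drop, , drop = FALSE]
    ids <- rownames(areas)
    scores <- scores[scores$u %in% ids & scores$v %in% ids, , drop = FALSE]
  }
  samp <- !blank
  clades <- sort(unique(m$clade[samp]))
  clade_sum <- sapply(clades, function(cl)
    rowSums(areas[, samp & m$clade == cl, drop = FALSE]))
  clade_sum <- matrix(clade_sum, nrow = nrow(areas),
                      dimnames = list(ids, clades))
  tot <- rowSums(clade_sum)
  rel <- clade_sum
  nz <- tot > 0
  rel[nz, ] <- clade_sum[nz, , drop = FALSE] / tot[nz]
  g <- igraph::graph_from_data_frame(
    scores[, c("u", "v", "cosine", "n_matched")],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  nodes <- data.frame(
    feature_id = ids,
    precursor_mz = table$feature_meta$mz[match(ids, table$feature_meta$feature_id)],
    rt = table$feature_meta$rt[match(ids, table$feature_meta$feature_id)],
    node_size = tot,
    zero_abundance = !nz,
    component = as.integer(comp[ids]),
    annotation = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = scores, clade_abundance = rel,
                 component = comp, params = params),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$component))))
  invisible(x)
}

#' Annotate spectra against a reference spectral library
#'
#' For each query spectrum, library entries whose precursor m/z lies within
#' `precursor_tol` are scored with the modified cosine; the best hit
#' passing the score and matched-peak thresholds is returned (ties broken
#' by higher matched-peak count, then library order).
#'
#' @param spectra list of query [spectrum()] objects.
#' @param library list of [spectrum()] objects carrying `compound` and
#'   `class` fields (extra list elements).
#' @param params a [similarity_params()].
#' @param clean apply [clean_spectra()] to queries and library first.
#' @return data frame of hits: `feature_id`, `library_compound_id`,
#'   `score`, `n_matched`, `class`.
#' @export
library_search <- function(spectra, library, params = similarity_params(),
                           clean = TRUE) {
  empty <- data.frame(feature_id = character(0),
                      library_compound_id = character(0),
                      score = numeric(0), n_matched = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (length(library) == 0) return(empty)
  if (clean) {
    spectra <- clean_spectra(spectra, params)
    lib_clean <- clean_spectra(library, params)
  } else lib_clean <- library
  lib_prec <- vapply(library, function(s) s$precursor_mz, numeric(1))
  rows <- lapply(spectra, function(q) {
    cand <- which(abs(lib_prec - q$precursor_mz) <= params$precursor_tol)
    if (!length(cand)) return(NULL)
    res <- lapply(cand, function(k) modified_cosine(q, lib_clean[[k]], params))
    sc <- vapply(res, `[[`, numeric(1), "score")
    nm <- vapply(res, `[[`, integer(1), "n_matched")
    ok <- sc > params$min_cosine & nm >= params$min_matched_peaks
    if (!any(ok)) return(NULL)
    o <- order(-sc[ok], -nm[ok], cand[ok])[1]
    k <- cand[ok][o]
    data.frame(feature_id = q$feature_id,
               library_compound_id = library[[k]]$compound %||% library[[k]]$feature_id,
               score = sc[ok][o], n_matched = nm[ok][o],
               class = library[[k]]$class %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Feature overlap between extraction protocols
#'
#' Venn-style summary of features detected (area > 0 in at least one
#' sample) in each of two solvent-specific feature tables sharing a common
#' feature alignment.
#'
#' @param tables named list of two [feature_table()] objects
#'   (e.g. `hydroethanolic`, `ethyl_acetate`).
#' @return list with per-solvent detected counts, `shared`, per-solvent
#'   exclusive counts, `total` (union) and the same as percentages.
#' @export
extraction_overlap <- function(tables) {
  stopifnot(length(tables) == 2)
  det <- lapply(tables, function(tb)
    rownames(tb$areas)[rowSums(tb$areas) > 0])
  nm <- names(tables) %||% c("solvent1", "solvent2")
  shared <- intersect(det[[1]], det[[2]])
  total <- union(det[[1]], det[[2]])
  counts <- c(stats::setNames(lengths(det), nm),
              shared = length(shared), total = length(total))
  only <- stats::setNames(c(length(setdiff(det[[1]], det[[2]])),
                            length(setdiff(det[[2]], det[[1]]))),
                          paste0(nm, "_only"))
  pct <- if (length(total))
    100 * c(shared = length(shared), only) / length(total)
  else c(shared = NA_real_, stats::setNames(rep(NA_real_, 2), names(only)))
  list(counts = c(counts, only), percent = pct)
}

#' Write a molecular network to GraphML or a TSV edge list
#'
#' GraphML export (Cytoscape-compatible) carries all node and edge
#' attributes, including per-clade relative abundances as one attribute per
#' clade; the TSV export writes the edge list only.
#'
#' @param net a `"molecular_network"`.
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = cbind(data.frame(name = net$nodes$feature_id),
                     net$nodes[setdiff(names(net$nodes), "feature_id")]))
  for (cl in colnames(net$clade_abundance))
    g <- igraph::set_vertex_attr(g, paste0("clade_", cl),
                                 value = net$clade_abundance[, cl])
  ann <- igraph::vertex_attr(g, "annotation")
  g <- igraph::set_vertex_attr(g, "annotation",
                               value = ifelse(is.na(ann), "", ann))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML path.
#' @return list with `nodes` and `edges` data frames.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  edf <- igraph::as_data_frame(g, what = "edges")
  names(edf)[1:2] <- c("u", "v")
  ndf <- igraph::as_data_frame(g, what = "vertices")
  names(ndf)[names(ndf) == "name"] <- "feature_id"
  list(nodes = ndf, edges = edf)
}
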