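#' Construct a binary character matrix
#'
#' Genera x chemical classes presence/absence matrix used for ancestral
#' state reconstruction. An optional `provenance` attribute records, per
#' character, which ionization mode(s) detected it.
#'
#' @param states binary matrix with genus rownames and character colnames.
#' @param provenance optional character vector per column
#'   (`"pos"`, `"neg"`, `"both"`).
#' @return an object of class `"character_matrix"`.
#' @export
character_matrix <- function(states, provenance = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states)) || is.null(colnames(states)))
    stopf("states must carry genus rownames and character colnames")
  if (anyDuplicated(rownames(states)) || anyDuplicated(colnames(states)))
    stopf("genus and character names must be unique")
  if (!all(states %in% c(0L, 1L))) stopf("states must be binary 0/1")
  if (!is.null(provenance)) {
    stopifnot(length(provenance) == ncol(states))
    names(provenance) <- colnames(states)
  }
  structure(list(states = states, provenance = provenance),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d genera x %d characters\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Binarize class abundances to per-species presence
#'
#' A class is present in a species iff its relative abundance exceeds
#' `min_abundance` (strict `>`) in at least one sample of that species.
#'
#' @param abund samples x classes relative-abundance matrix.
#' @param meta a [sample_metadata()] mapping samples to species.
#' @param min_abundance detection floor (default 0: any nonzero value).
#' @return binary species x classes matrix.
#' @export
binarize_classes <- function(abund, meta, min_abundance = 0) {
  meta <- sample_metadata(meta)
  m <- meta[match(rownames(abund), meta$sample_id), ]
  if (anyNA(m$sample_id)) stopf("metadata missing for some samples")
  pres <- rowsum((abund > min_abundance) + 0, m$species) > 0
  out <- pres + 0L
  out[order(rownames(out)), , drop = FALSE]
}

#' Summarize species presences to a genus-level character matrix
#'
#' Each genus scores the arithmetic mean of its species presences and is
#' coded present iff that mean exceeds `threshold` (strict `>`). The
#' default threshold 0 codes a genus present when any sampled species is.
#'
#' @param species_presence binary species x classes matrix
#'   (from [binarize_classes()]).
#' @param meta a [sample_metadata()] mapping species to genera.
#' @param threshold mean-presence cutoff in \[0, 1) (default 0).
#' @param mode ionization-mode tag recorded as provenance
#'   (`"pos"`, `"neg"`, or `NA`).
#' @return a [character_matrix()].
#' @export
summarize_to_genus <- function(species_presence, meta, threshold = 0,
                               mode = NA_character_) {
  meta <- sample_metadata(meta)
  sp2gen <- unique(meta[, c("species", "genus")])
  gen <- sp2gen$genus[match(rownames(species_presence), sp2gen$species)]
  if (anyNA(gen)) stopf("species without genus mapping: %s",
                        paste(rownames(species_presence)[is.na(gen)], collapse = ", "))
  counts <- table(gen)
  if (any(counts == 0)) stopf("genus with zero species")
  mean_pres <- rowsum(species_presence + 0, gen)
  mean_pres <- mean_pres / as.vector(counts[rownames(mean_pres)])
  states <- (mean_pres > threshold) + 0L
  prov <- if (!is.na(mode)) rep(mode, ncol(states)) else NULL
  character_matrix(states[order(rownames(states)), , drop = FALSE], prov)
}

#' Merge positive- and negative-mode character matrices
#'
#' Takes the union of characters over both ionization modes; the merged
#' state is the logical OR of the mode states (a character absent from one
#' mode's matrix counts as 0 there). Per-character provenance records
#' whether the class was detected in one mode or both. Commutative and
#' idempotent.
#'
#' @param pos,neg [character_matrix()] objects over the same genus set.
#' @return a merged [character_matrix()] with provenance
#'   `"pos"`/`"neg"`/`"both"`.
#' @export
merge_modes <- function(pos, neg) {
  gp <- rownames(pos$states); gn <- rownames(neg$states)
  if (!setequal(gp, gn))
    stopf("genus sets differ; only in pos: %s; only in neg: %s",
          paste(setdiff(gp, gn), collapse = ",") ,
          paste(setdiff(gn, gp), collapse = ","))
  genera <- sort(gp)
  chars <- sort(union(colnames(pos$states), colnames(neg$states)))
  grab <- function(m) {
    out <- matrix(0L, length(genera), length(chars),
                  dimnames = list(genera, chars))
    out[genera, intersect(chars, colnames(m$states))] <-
      m$states[genera, intersect(chars, colnames(m$states))]
    out
  }
  P <- grab(pos); N <- grab(neg)
  merged <- (P | N) + 0L
  in_pos <- colSums(P) > 0; in_neg <- colSums(N) > 0
  prov <- ifelse(in_pos & in_neg, "both", ifelse(in_pos, "pos",
                 ifelse(in_neg, "neg", "none")))
  character_matrix(merged, prov)
}

#' One-character matrix from two-group chemical-profile labels
#'
#' Codes each genus by the majority PCoA cluster ("A"/"B") of its samples;
#' exact ties take the group of the genus's first sample (deterministic)
#' and are flagged.
#'
#' @param groups named "A"/"B" labels per sample
#'   (from [cluster_two_groups()]).
#' @param meta a [sample_metadata()].
#' @param character_name column name for the coded character.
#' @return list with `matrix` (a [character_matrix()], state 1 = group
#'   "B") and `ties` (genera resolved by the tie rule).
#' @export
profile_character <- function(groups, meta,
                              character_name = "chemical_profile") {
  meta <- sample_metadata(meta)
  m <- meta[match(names(groups), meta$sample_id), ]
  if (anyNA(m$sample_id)) stopf("metadata missing for some samples")
  genera <- sort(unique(meta$genus[!meta$is_blank]))
  state <- stats::setNames(integer(length(genera)), genera)
  ties <- character(0)
  for (g in genera) {
    idx <- which(m$genus == g)
    if (!length(idx)) stopf("genus '%s' has no samples", g)
    nb <- sum(groups[idx] == "B"); na_ <- sum(groups[idx] == "A")
    if (nb == na_) {
      ties <- c(ties, g)
      state[g] <- as.integer(groups[idx[1]] == "B")
    } else state[g] <- as.integer(nb > na_)
  }
  mat <- matrix(state, ncol = 1, dimnames = list(genera, character_name))
  list(matrix = character_matrix(mat), ties = ties)
}

#' Write a character matrix as TSV
#' @param cm a [character_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(cm, path) {
  df <- data.frame(genus = rownames(cm$states), cm$states,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a character matrix from TSV
#' @param path TSV written by [write_character_matrix()].
#' @return a [character_matrix()].
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  character_matrix(m)
}

#' Write a character matrix as a NEXUS characters block
#'
#' Mesquite-compatible standard-format NEXUS via \pkg{ape}.
#'
#' @param cm a [character_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_characters <- function(cm, path) {
  x <- lapply(seq_len(nrow(cm$states)),
              function(i) as.character(cm$states[i, ]))
  names(x) <- rownames(cm$states)
  ape::write.nexus.data(x, path, format = "standard", interleaved = FALSE)
  # drop the writer timestamp comment so identical matrices give
  # byte-identical files
  lines <- readLines(path)
  lines <- sub("^\\[Data written by.*\\]$", "[chemophylo character matrix]",
               lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS characters block into a character matrix
#' @param path NEXUS file.
#' @param characters optional character names (defaults to `char1..charK`).
#' @return a [character_matrix()].
#' @export
read_nexus_characters <- function(path, characters = NULL) {
  x <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(x, as.integer))
  rownames(m) <- names(x)
  colnames(m) <- characters %||% paste0("char", seq_len(ncol(m)))
  character_matrix(m)
}
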