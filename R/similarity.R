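#' Spectral similarity / networking parameters
#'
#' Defaults follow the feature-based molecular networking settings used
#' throughout the package: fragment ions within +/- 17 Da of the precursor
#' removed, top 6 fragments kept per +/- 50 Da window, 0.02 Da fragment and
#' precursor tolerances, and network edges admitted at cosine > 0.7 with at
#' least 4 matched peaks.
#'
#' @param precursor_removal_window Da; peaks within this window of the
#'   precursor are removed (closed interval, both sides).
#' @param window_size Da; half-width of the rolling intensity-rank window.
#' @param top_k_in_window peaks kept per window.
#' @param fragment_tol Da; fragment match tolerance.
#' @param precursor_tol Da; precursor match tolerance (library search).
#' @param min_matched_peaks minimum matched peaks for an edge/hit.
#' @param min_cosine minimum cosine (strict `>`) for an edge/hit.
#' @param assignment peak-assignment algorithm in [modified_cosine()]:
#'   `"exact"` (maximum-weight one-to-one assignment) or `"greedy"`.
#' @return a list of class `"similarity_params"`.
#' @export
similarity_params <- function(precursor_removal_window = 17,
                              window_size = 50, top_k_in_window = 6,
                              fragment_tol = 0.02, precursor_tol = 0.02,
                              min_matched_peaks = 4, min_cosine = 0.7,
                              assignment = c("exact", "greedy")) {
  assignment <- match.arg(assignment)
  stopifnot(precursor_removal_window > 0, window_size > 0,
            top_k_in_window >= 1, fragment_tol > 0, precursor_tol > 0,
            min_matched_peaks >= 1)
  structure(as.list(environment()), class = "similarity_params")
}

#' Remove fragment ions near the precursor
#'
#' Drops every peak with |mz - precursor_mz| <= `window` (closed interval,
#' symmetric around the precursor), removing residual precursor ions often
#' seen in QTOF MS/MS spectra. Other peaks and their order are untouched.
#'
#' @param s a [spectrum()].
#' @param window Da half-width (default 17).
#' @return the filtered [spectrum()].
#' @export
precursor_window_filter <- function(s, window = 17) {
  stopifnot(window > 0)
  if (nrow(s$peaks) == 0) return(s)
  keep <- abs(s$peaks[, 1] - s$precursor_mz) > window
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Rolling-window top-k intensity filter
#'
#' A peak is retained iff it ranks among the top `k` by intensity within
#' the +/- `window` Da window centred on its own m/z (closed interval).
#' Intensity ties rank the lower-m/z peak first, so the result is
#' deterministic. The filter is idempotent.
#'
#' @param s a [spectrum()].
#' @param window Da half-width (default 50).
#' @param k peaks kept per window (default 6).
#' @return the filtered [spectrum()].
#' @export
window_filter <- function(s, window = 50, k = 6) {
  stopifnot(window > 0, k >= 1)
  n <- nrow(s$peaks)
  if (n <= k) return(s)
  mz <- s$peaks[, 1]; int <- s$peaks[, 2]
  keep <- logical(n)
  for (i in seq_len(n)) {
    inwin <- abs(mz - mz[i]) <= window
    better <- inwin & (int > int[i] | (int == int[i] & mz < mz[i]))
    keep[i] <- sum(better) < k
  }
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Square-root intensity weights with unit norm
#'
#' Standard cosine preprocessing: weights are sqrt(intensity) scaled to
#' unit Euclidean norm, making the score scale-invariant.
#'
#' @param s a [spectrum()] with at least one peak.
#' @return numeric weight vector, one per peak.
#' @export
normalize_peaks <- function(s) {
  if (nrow(s$peaks) == 0) stopf("cannot normalize a spectrum with no peaks")
  w <- sqrt(s$peaks[, 2])
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stopf("all-zero intensities in feature '%s'", s$feature_id)
  w / nrm
}

# Candidate fragment pairs for the modified cosine: direct matches
# (|mz_a - mz_b| <= tol) or precursor-shifted matches
# (|mz_a - mz_b - (prec_a - prec_b)| <= tol). Returns i, j, weight product.
candidate_pairs <- function(mza, mzb, wa, wb, delta, tol) {
  na <- length(mza); nb <- length(mzb)
  dmat <- abs(outer(mza, mzb, "-"))
  direct <- dmat <= tol
  shifted <- abs(outer(mza, mzb, "-") - delta) <= tol
  hit <- which(direct | shifted, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0),
                      shifted = logical(0)))
  data.frame(i = hit[, 1], j = hit[, 2],
             w = wa[hit[, 1]] * wb[hit[, 2]],
             shifted = !direct[hit] & shifted[hit])
}

# Exact maximum-weight one-to-one assignment over a sparse candidate-pair
# list, by branch-and-bound over pairs sorted by descending weight. Among
# score-ties the larger assignment wins. Candidate lists from 0.02 Da
# tolerances are tiny, so the search is effectively instant.
assign_exact <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0) return(list(score = 0, n = 0L, pairs = integer(0)))
  ord <- order(-pairs$w, pairs$i, pairs$j)
  pw <- pairs$w[ord]; pi_ <- pairs$i[ord]; pj <- pairs$j[ord]
  suffix <- rev(cumsum(rev(pw)))
  best <- new.env(parent = emptyenv())
  best$score <- -1; best$n <- 0L; best$sel <- integer(0)
  used_i <- integer(0); used_j <- integer(0)
  recurse <- function(k, score, n, sel, used_i, used_j) {
    if (k > np) {
      if (score > best$score + 1e-15 ||
          (abs(score - best$score) <= 1e-15 && n > best$n)) {
        best$score <- score; best$n <- n; best$sel <- sel
      }
      return(invisible())
    }
    if (score + suffix[k] < best$score - 1e-15) return(invisible())
    if (!(pi_[k] %in% used_i) && !(pj[k] %in% used_j))
      recurse(k + 1L, score + pw[k], n + 1L, c(sel, k),
              c(used_i, pi_[k]), c(used_j, pj[k]))
    recurse(k + 1L, score, n, sel, used_i, used_j)
  }
  recurse(1L, 0, 0L, integer(0), integer(0), integer(0))
  list(score = best$score, n = best$n, pairs = ord[best$sel])
}

# Greedy assignment by descending weight product (ties broken by lower
# summed m/z, then smaller m/z gap — symmetric in the two spectra).
assign_greedy <- function(pairs, mza, mzb) {
  np <- nrow(pairs)
  if (np == 0) return(list(score = 0, n = 0L, pairs = integer(0)))
  key2 <- mza[pairs$i] + mzb[pairs$j]
  key3 <- abs(mza[pairs$i] - mzb[pairs$j])
  ord <- order(-pairs$w, key2, key3)
  used_i <- logical(max(pairs$i)); used_j <- logical(max(pairs$j))
  sel <- integer(0); score <- 0
  for (k in ord) {
    if (!used_i[pairs$i[k]] && !used_j[pairs$j[k]]) {
      used_i[pairs$i[k]] <- TRUE; used_j[pairs$j[k]] <- TRUE
      sel <- c(sel, k); score <- score + pairs$w[k]
    }
  }
  list(score = score, n = length(sel), pairs = sel)
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Fragment pairs may match either directly (within `fragment_tol`) or
#' offset by the precursor mass difference; a one-to-one assignment of
#' peaks maximising the summed product of sqrt-intensity weights gives the
#' score. Symmetric in its arguments, bounded in \[0, 1\].
#'
#' @param a,b [spectrum()] objects (already filtered).
#' @param params a [similarity_params()].
#' @return list with `score` and `n_matched`.
#' @export
modified_cosine <- function(a, b, params = similarity_params()) {
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0)
    return(list(score = 0, n_matched = 0L))
  wa <- normalize_peaks(a); wb <- normalize_peaks(b)
  delta <- a$precursor_mz - b$precursor_mz
  pairs <- candidate_pairs(a$peaks[, 1], b$peaks[, 1], wa, wb,
                           delta, params$fragment_tol)
  res <- if (params$assignment == "greedy")
    assign_greedy(pairs, a$peaks[, 1], b$peaks[, 1])
  else assign_exact(pairs)
  list(score = min(1, res$score), n_matched = res$n)
}

#' Apply the standard FBMN spectral cleaning to a spectrum collection
#'
#' Precursor-window removal followed by the rolling top-k filter, with the
#' parameters in `params`.
#'
#' @param spectra list of [spectrum()] objects.
#' @param params a [similarity_params()].
#' @return the cleaned spectrum list.
#' @export
clean_spectra <- function(spectra, params = similarity_params()) {
  lapply(spectra, function(s)
    window_filter(precursor_window_filter(s, params$precursor_removal_window),
                  params$window_size, params$top_k_in_window))
}
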