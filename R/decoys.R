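# Ranking a native interface against docking decoys by Rp, Dp and Ncons,
# with residue-overlap stratification.

protein_residue_set <- function(im) {
  r <- filter(im$residues, .data$component == "protein")
  paste0(r$chain, ":", r$residue_number, r$insert)
}

#' Residue-wise overlap of a decoy interface with the native interface
#'
#' Fraction of the native protein-interface residues that also belong to the
#' decoy's protein interface. Both interfaces must reference the same
#' protein chains and numbering.
#'
#' @param native,decoy `pdi_interface` objects of the same protein.
#' @return the overlap fraction in \[0, 1\].
#' @export
interface_overlap <- function(native, decoy) {
  ns <- protein_residue_set(native)
  ds <- protein_residue_set(decoy)
  if (length(ns) == 0) stop("native interface has no protein residues")
  native_chains <- unique(filter(native$residues,
                                 .data$component == "protein")$chain)
  decoy_chains <- unique(filter(decoy$residues,
                                .data$component == "protein")$chain)
  if (length(ds) > 0 && length(intersect(native_chains, decoy_chains)) == 0) {
    stop("native and decoy interfaces share no protein chain; ",
         "numbering mismatch?")
  }
  length(intersect(ns, ds)) / length(ns)
}

competition_rank <- function(native_value, decoy_values) {
  # descending sort; ties share the better (minimum) rank
  1L + sum(decoy_values > native_value)
}

#' Rank the native interface among decoys, per feature
#'
#' Candidates (the native plus all decoys) are ranked in descending order
#' of each feature; ties share the better rank (competition ranking). The
#' native is flagged top-decile when its rank is at most
#' `ceiling(0.10 x number of candidates)` - the "ranked #1" convention of
#' decoy benchmarks.
#'
#' @param native_fv one-row feature tibble (see [interface_features()]).
#' @param decoy_fvs feature tibble with one row per decoy.
#' @param features which columns to rank on.
#' @return a tibble with one row per feature: the native's value, rank,
#'   number of candidates and top-decile flag.
#' @export
rank_native <- function(native_fv, decoy_fvs,
                        features = c("rp", "dp", "ncons")) {
  if (nrow(decoy_fvs) < 1) stop("need at least one decoy")
  n_cand <- nrow(decoy_fvs) + 1L
  purrr::map_dfr(features, function(f) {
    nv <- native_fv[[f]][1]
    dv <- decoy_fvs[[f]]
    if (is.na(nv) || all(is.na(dv))) {
      return(tibble(feature = f, native_value = nv, rank = NA_integer_,
                    n_candidates = n_cand, top_decile = NA))
    }
    rk <- competition_rank(nv, dv[!is.na(dv)])
    tibble(feature = f, native_value = nv, rank = rk, n_candidates = n_cand,
           top_decile = rk <= ceiling(0.10 * n_cand))
  })
}

#' Overlap-stratified decoy ranking summary
#'
#' For each overlap cutoff, decoys whose interface overlaps the native by
#' more than the cutoff are removed, the remaining candidates are re-ranked,
#' and the per-feature rank-1 rate (top-decile convention) and top-3 rate
#' over the entry set are reported.
#'
#' @param entries a list; each element has `native_fv` (one-row feature
#'   tibble), `decoy_fvs` (per-decoy feature tibble) and `overlaps`
#'   (numeric vector, one overlap fraction per decoy).
#' @param cutoffs overlap cutoffs (fractions), default 0.5, 0.2, 0.1, 0.
#' @param features feature columns to rank on.
#' @return a tibble with one row per cutoff x feature: number of entries
#'   ranked, rank-1 rate and top-3 rate.
#' @export
overlap_stratified_summary <- function(entries,
                                       cutoffs = c(0.5, 0.2, 0.1, 0),
                                       features = c("rp", "dp", "ncons")) {
  purrr::map_dfr(cutoffs, function(cut) {
    per_entry <- purrr::map_dfr(seq_along(entries), function(k) {
      e <- entries[[k]]
      keep <- e$overlaps <= cut
      if (!any(keep)) {
        warning("entry ", k, ": no decoys survive overlap cutoff ", cut,
                "; skipped")
        return(NULL)
      }
      rank_native(e$native_fv, e$decoy_fvs[keep, , drop = FALSE],
                  features = features) |>
        mutate(entry = k)
    })
    if (nrow(per_entry) == 0) {
      return(tibble(overlap_cutoff = numeric(), feature = character(),
                    n_entries = integer(), rank1_rate = numeric(),
                    top3_rate = numeric()))
    }
    per_entry |>
      group_by(.data$feature) |>
      summarise(
        n_entries = dplyr::n_distinct(.data$entry),
        rank1_rate = mean(.data$top_decile, na.rm = TRUE),
        top3_rate = mean(.data$rank <= 3, na.rm = TRUE),
        .groups = "drop") |>
      mutate(overlap_cutoff = cut, .before = 1)
  })
}
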