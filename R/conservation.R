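# Sequence conservation from a user-supplied multiple sequence alignment:
# per-column Shannon entropies, interface mean entropy, conserved-residue
# count (Ncons) and core/rim entropy means.

new_alignment <- function(ids, seqs, query_id = ids[1]) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, query_id = query_id,
                 cache = new.env(parent = emptyenv())),
            class = "pdi_alignment")
}

#' @export
print.pdi_alignment <- function(x, ...) {
  cat("<pdi_alignment> ", length(x$ids), " sequences x ", ncol(x$mat),
      " columns; query: ", x$query_id, "\n", sep = "")
  invisible(x)
}

is_gap <- function(ch) ch %in% c("-", ".")

#' Parse an aligned FASTA multiple sequence alignment
#'
#' The first record is taken as the query sequence (a stated convention).
#' All rows must have equal (aligned) length and there must be at least two
#' sequences, otherwise column entropies are undefined.
#'
#' @param input path to an aligned FASTA file, or the FASTA text itself
#'   (a string containing at least one `>` header).
#' @return a `pdi_alignment`: sequence ids, the character matrix of aligned
#'   residues and the query id.
#' @export
read_msa <- function(input) {
  if (length(input) == 1 && !grepl(">", input, fixed = TRUE) &&
      file.exists(input)) {
    path <- input
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(input) == 1) strsplit(input, "\n")[[1]] else input,
               path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) stop("alignment needs at least 2 sequences")
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "))
  }
  new_alignment(names(set), as.character(set))
}

#' Per-sequence identity to the query
#'
#' Fraction of identical residues over columns where both the query and the
#' homolog are ungapped.
#'
#' @param aln a `pdi_alignment`.
#' @return a named numeric vector, one entry per sequence (query = 1).
#' @export
msa_identity <- function(aln) {
  q <- aln$mat[aln$query_id == aln$ids, , drop = TRUE]
  apply(aln$mat, 1, function(row) {
    both <- !is_gap(q) & !is_gap(row)
    if (!any(both)) return(0)
    mean(q[both] == row[both])
  })
}

#' Filter homologs by identity to the query
#'
#' Retains the query plus every homolog with at least `min_identity`
#' sequence identity (default 0.30, the close-homolog convention).
#'
#' @param aln a `pdi_alignment`.
#' @param min_identity identity cutoff as a fraction.
#' @return the filtered `pdi_alignment`.
#' @export
filter_homologs <- function(aln, min_identity = 0.30) {
  idents <- msa_identity(aln)
  keep <- idents >= min_identity | aln$ids == aln$query_id
  if (sum(keep) < 2) {
    stop("fewer than 2 sequences survive the ", min_identity,
         " identity cutoff")
  }
  new_alignment(aln$ids[keep], apply(aln$mat[keep, , drop = FALSE], 1, paste,
                                     collapse = ""),
                query_id = aln$query_id)
}

#' Shannon entropy of an alignment column
#'
#' `s = -sum_k f_k ln f_k` over the 20 amino-acid classes among the non-gap
#' symbols of the column (natural log, so entropies are in nats; an all-gap
#' column is undefined and returns `NA` with a warning).
#'
#' @param aln a `pdi_alignment`.
#' @param column column index (1-based).
#' @return the entropy in nats, or `NA` for an all-gap column.
#' @export
column_entropy <- function(aln, column) {
  if (column < 1 || column > ncol(aln$mat)) {
    stop("column ", column, " out of range 1..", ncol(aln$mat))
  }
  col <- aln$mat[, column]
  col <- col[!is_gap(col) & col %in% AA3]
  if (length(col) == 0) {
    warning("all-gap column ", column, ": entropy undefined")
    return(NA_real_)
  }
  f <- table(col) / length(col)
  -sum(f * log(f))
}

all_column_entropies <- function(aln) {
  if (!is.null(aln$cache) && !is.null(aln$cache$entropies)) {
    return(aln$cache$entropies)
  }
  ent <- vapply(seq_len(ncol(aln$mat)), function(j) {
    col <- aln$mat[, j]
    col <- col[!is_gap(col) & col %in% AA3]
    if (length(col) == 0) return(NA_real_)
    f <- tabulate(factor(col, levels = AA3)) / length(col)
    f <- f[f > 0]
    -sum(f * log(f))
  }, numeric(1))
  if (!is.null(aln$cache)) aln$cache$entropies <- ent
  ent
}

# map the residues of one chain (in residue-number order) onto the non-gap
# columns of the query row
map_chain_to_columns <- function(aln, chain_residues) {
  q <- aln$mat[aln$ids == aln$query_id, , drop = TRUE]
  cols <- which(!is_gap(q))
  n_res <- nrow(chain_residues)
  if (n_res > length(cols)) {
    stop("chain has ", n_res, " residues but the query row has only ",
         length(cols), " ungapped columns")
  }
  chain_residues$column <- cols[seq_len(n_res)]
  # sanity: residue types should match the query sequence where standard
  one <- aa_one_letter(chain_residues$residue_name)
  qres <- q[chain_residues$column]
  mism <- !is.na(one) & one != qres
  if (mean(mism) > 0.2) {
    warning("chain sequence disagrees with the query row at ",
            round(100 * mean(mism)), "% of positions; check the alignment")
  }
  chain_residues
}

#' Entropy profile of the interface residues of one protein chain
#'
#' Maps the chain's residues onto the ungapped columns of the query row,
#' computes the column entropy `s(i)` for every interface residue, the
#' interface mean `<s>_int = sum(s(i))/n`, and `Ncons`, the number of
#' interface residues with `s(i)` strictly below `<s>_int`. Core, rim and
#' whole-chain mean entropies are reported alongside.
#'
#' @param aln a `pdi_alignment` (already filtered to close homologs if
#'   desired; see [filter_homologs()]).
#' @param im a `pdi_interface`.
#' @param protein the protein component structure (for the chain residue
#'   listing).
#' @param chain chain identifier of the analysed subunit; defaults to the
#'   first protein chain of the interface.
#' @return a `pdi_entropy_profile`: a tibble with one row per mapped
#'   interface residue (`s`, `region`, `conserved`) carrying the summary
#'   (`mean_interface`, `n`, `n_cons`, `mean_core`, `mean_rim`,
#'   `mean_chain`) as attributes; see [glance()].
#' @export
interface_entropy_profile <- function(aln, im, protein, chain = NULL) {
  pres <- structure_residues(protein)
  if (is.null(chain)) chain <- pres$chain[1]
  chain_res <- pres |>
    filter(.data$chain == .env$chain) |>
    arrange(.data$residue_number, .data$insert)
  if (nrow(chain_res) == 0) stop("no protein residues in chain ", chain)
  mapped <- map_chain_to_columns(aln, chain_res)
  ent <- all_column_entropies(aln)
  mapped$s <- ent[mapped$column]

  ires <- im$residues |>
    filter(.data$component == "protein", .data$chain == .env$chain) |>
    select(all_of(RESIDUE_KEY), "region")
  prof <- inner_join(mapped, ires, by = RESIDUE_KEY)
  n_unmapped <- nrow(ires) - nrow(prof)
  if (n_unmapped > 0) {
    warning(n_unmapped, " interface residue(s) of chain ", chain,
            " could not be mapped to an alignment column; excluded from n")
  }
  prof <- filter(prof, !is.na(.data$s))

  mean_int <- if (nrow(prof) > 0) sum(prof$s) / nrow(prof) else NA_real_
  prof$conserved <- prof$s < mean_int

  out <- prof |>
    select(all_of(RESIDUE_KEY), "residue_name", "column", "s", "region",
           "conserved")
  attr(out, "chain") <- chain
  attr(out, "n") <- nrow(prof)
  attr(out, "mean_interface") <- mean_int
  attr(out, "n_cons") <- sum(prof$conserved)
  attr(out, "mean_core") <- mean(prof$s[prof$region == "core"])
  attr(out, "mean_rim") <- mean(prof$s[prof$region == "rim"])
  attr(out, "mean_chain") <- mean(mapped$s, na.rm = TRUE)
  attr(out, "n_homologs") <- length(aln$ids)
  class(out) <- c("pdi_entropy_profile", class(out))
  out
}

#' @export
glance.pdi_entropy_profile <- function(x, ...) {
  tibble(
    chain = attr(x, "chain"),
    n_homologs = attr(x, "n_homologs"),
    n_interface = attr(x, "n"),
    mean_interface = attr(x, "mean_interface"),
    n_cons = attr(x, "n_cons"),
    mean_core = attr(x, "mean_core"),
    mean_rim = attr(x, "mean_rim"),
    mean_chain = attr(x, "mean_chain")
  )
}
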