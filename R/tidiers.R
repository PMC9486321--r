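# Broom-style tidiers and ggplot2 methods for the result objects.

#' @export
print.pdi_interface <- function(x, ...) {
  cat("<pdi_interface> ", nrow(x$atoms), " interface atoms in ",
      nrow(x$residues), " residues/nucleotides (",
      sum(x$residues$region == "core"), " core, ",
      sum(x$residues$region == "rim"), " rim)\n", sep = "")
  invisible(x)
}

#' Tidy an interface into one row per interface residue
#'
#' @param x a `pdi_interface`.
#' @param ... unused.
#' @return a tibble: residue identity, component, region, interface atom
#'   count, buried area and (when clustered) patch index.
#' @export
tidy.pdi_interface <- function(x, ...) {
  x$residues |>
    select("component", "chain", "residue_number", "insert", "residue_name",
           "region", "n_interface_atoms", "delta_area", any_of("patch"))
}

#' One-row summary of an interface
#'
#' @param x a `pdi_interface`.
#' @param ... unused.
#' @return a one-row tibble with areas, counts and core/rim tallies.
#' @export
glance.pdi_interface <- function(x, ...) {
  a <- x$atoms
  tibble(
    area_protein = sum(a$delta_area[a$component == "protein"]),
    area_dna = sum(a$delta_area[a$component == "dna"]),
    area_total = sum(a$delta_area),
    n_atoms_protein = sum(a$component == "protein"),
    n_atoms_dna = sum(a$component == "dna"),
    n_atoms_total = nrow(a),
    n_residues_protein = sum(x$residues$component == "protein"),
    n_nucleotides = sum(x$residues$component == "dna"),
    n_core = sum(x$residues$region == "core"),
    n_rim = sum(x$residues$region == "rim"),
    fraction_fully_buried = if (nrow(a) > 0) mean(a$fully_buried) else NA_real_
  )
}

#' Tidy a full report into its interface residue table
#'
#' @param x a `pdi_report`.
#' @param ... unused.
#' @return the interface residue tibble, joined with per-residue entropy
#'   when conservation was computed.
#' @export
tidy.pdi_report <- function(x, ...) {
  out <- tidy(x$interface)
  if (!is.null(x$entropy)) {
    out <- left_join(out,
                     select(x$entropy, all_of(RESIDUE_KEY), "s", "conserved"),
                     by = RESIDUE_KEY)
  }
  out
}

#' One-row summary of a full report
#'
#' @param x a `pdi_report`.
#' @param ... unused.
#' @return a one-row tibble combining interface, donor, hydrogen-bond,
#'   water and conservation summaries.
#' @export
glance.pdi_report <- function(x, ...) {
  g <- glance(x$interface)
  wc <- x$waters$counts
  out <- dplyr::bind_cols(
    g,
    tibble(rp = x$rp, dp = x$donors$dp,
           ss_class = x$secondary_structure$class),
    wc
  )
  if (!is.null(x$entropy)) {
    e <- glance(x$entropy)
    out$n_cons <- e$n_cons
    out$mean_entropy_interface <- e$mean_interface
    out$mean_entropy_core <- e$mean_core
    out$mean_entropy_rim <- e$mean_rim
  }
  out
}

#' Plot the interface projected down its shortest axis
#'
#' Interface residues are drawn at their mean projected position: protein
#' residues as circles (core) and squares (rim), coloured by entropy when
#' available; nucleotide atoms are coloured by moiety (base, sugar,
#' phosphate).
#'
#' @param object a `pdi_report` (with a non-degenerate projection).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pdi_report <- function(object, ...) {
  proj <- object$projection
  if (is.null(proj)) stop("report has no projection (degenerate interface)")
  pres <- proj |>
    filter(.data$component == "protein") |>
    group_by(across(all_of(RESIDUE_KEY)), .data$region) |>
    summarise(px = mean(.data$px), py = mean(.data$py), .groups = "drop")
  if (!is.null(object$entropy)) {
    pres <- left_join(pres,
                      select(object$entropy, all_of(RESIDUE_KEY), "s"),
                      by = RESIDUE_KEY)
  } else {
    pres$s <- NA_real_
  }
  datoms <- filter(proj, .data$component == "dna")
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = datoms,
      ggplot2::aes(x = .data$px, y = .data$py, colour = .data$moiety),
      size = 1, alpha = 0.6) +
    ggplot2::geom_point(
      data = pres,
      ggplot2::aes(x = .data$px, y = .data$py, fill = .data$s,
                   shape = .data$region),
      size = 3, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(core = 21, rim = 22)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "principal axis 1 (Å)",
                  y = "principal axis 2 (Å)",
                  fill = "entropy (nats)", shape = "region",
                  colour = "DNA moiety") +
    ggplot2::theme_minimal()
}

#' Plot per-residue interface entropies
#'
#' @param object a `pdi_entropy_profile`.
#' @param ... unused.
#' @return a ggplot object: entropies along the sequence, core/rim coded,
#'   with the interface mean as a dashed line.
#' @export
autoplot.pdi_entropy_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_number, y = .data$s,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_interface"),
                        linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "entropy s(i) (nats)",
                  fill = "region") +
    ggplot2::theme_minimal()
}
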