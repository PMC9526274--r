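#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a target set into its region table
#'
#' @param x a `target_set`.
#' @param ... unused.
#' @return the regions tibble with stitched-offset columns `cum` and `nu_end`.
#' @export
tidy.target_set <- function(x, ...) {
  dplyr::mutate(x$regions, cum = x$cum, nu_end = x$ends)
}

#' @rdname tidy.target_set
#' @export
glance.target_set <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$regions), l_T = x$l_T, l_ext = x$l_ext,
                 mode = x$mode, n_elements = length(unique(x$regions$element_id)))
}

#' Tidy a variant set into one long table
#'
#' @param x a `variant_set`.
#' @param ... unused.
#' @return a tibble (`chrom`, `start`, `end`, `type`, `alt`).
#' @export
tidy.variant_set <- function(x, ...) {
  dplyr::bind_rows(
    x$snvs |> dplyr::transmute(chrom = .data$chrom, start = .data$pos,
                               end = .data$pos, type = "snv", alt = .data$alt),
    x$deletions |> dplyr::transmute(chrom = .data$chrom, start = .data$d1,
                                    end = .data$d2, type = "del",
                                    alt = NA_character_),
    x$insertions |> dplyr::transmute(chrom = .data$chrom, start = .data$pos,
                                     end = .data$pos, type = "ins",
                                     alt = .data$seq)
  ) |> dplyr::arrange(.data$chrom, .data$start)
}

#' @rdname tidy.variant_set
#' @export
glance.variant_set <- function(x, ...) {
  tibble::tibble(n_snv = nrow(x$snvs), n_del = nrow(x$deletions),
                 n_ins = nrow(x$insertions), n_skipped = x$n_skipped)
}

#' @rdname tidy.target_set
#' @param x a `gene_model`.
#' @export
glance.gene_model <- function(x, ...) {
  tibble::tibble(n_genes = length(unique(x$transcripts$gene_id)),
                 n_transcripts = nrow(x$transcripts),
                 n_exons = nrow(x$exons), n_cds = nrow(x$cds))
}

#' Plot allele counts along the vector coordinates
#'
#' @param object a `frequency_vector`.
#' @param targets optional matching `target_set` (adds genomic positions to
#'   the hover-free labels; the x axis stays in vector coordinates).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.frequency_vector <- function(object, targets = NULL, ...) {
  df <- tidy.frequency_vector(object, targets = targets, keep_zero = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu, y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$nu, yend = 0),
                          colour = "steelblue") +
    ggplot2::labs(
      x = "vector coordinate (nu)", y = "allele count",
      title = sprintf("allele %s counts over %d samples", object$allele,
                      object$n_G)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the stitched target-region layout
#'
#' Regions in genomic coordinates, one row per element, coloured by strand —
#' a quick visual check that stitching and redundancy look as intended.
#'
#' @param object a `target_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.target_set <- function(object, ...) {
  r <- tidy.target_set(object)
  r$element <- factor(r$element_id, levels = unique(r$element_id))
  ggplot2::ggplot(r) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$element, yend = .data$element,
                   colour = .data$strand),
      linewidth = 2
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genomic position", y = NULL,
                  title = sprintf("%d target regions, l_T = %d",
                                  nrow(r), object$l_T)) +
    ggplot2::theme_minimal()
}

#' Summarize annotation records by consequence term
#'
#' @param records an annotation-record tibble.
#' @return a ggplot: term counts coloured by severity.
#' @export
plot_impact_summary <- function(records) {
  df <- records |>
    dplyr::mutate(term = .data$terms) |>
    tidyr::unnest("term") |>
    dplyr::count(.data$term) |>
    dplyr::left_join(impact_terms(), by = "term")
  df$term <- factor(df$term, levels = df$term[order(df$n)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$term,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "records", y = NULL, fill = "severity") +
    ggplot2::theme_minimal()
}
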