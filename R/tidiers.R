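#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_hline
#'   geom_ribbon geom_tile geom_col scale_y_log10 labs facet_wrap theme_minimal
#'   scale_color_manual scale_fill_brewer
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy/summarize a probe design
#'
#' `tidy()` returns the probe catalog; `glance()` one row of design-level
#' summaries (probe and gap counts, GC range, strand balance).
#'
#' @param x An `osseq_design`.
#' @param ... Unused.
#' @export
tidy.osseq_design <- function(x, ...) as_tibble(x$probes)

#' @rdname tidy.osseq_design
#' @export
glance.osseq_design <- function(x, ...) {
  p <- x$probes
  tibble(
    n_probes = nrow(p),
    n_gaps = nrow(x$gaps),
    n_targets = length(unique(p$parent_target)),
    n_plus = sum(p$strand == "+"),
    n_minus = sum(p$strand == "-"),
    gc_min = if (nrow(p)) min(p$gc_fraction) else NA_real_,
    gc_max = if (nrow(p)) max(p$gc_fraction) else NA_real_
  )
}

#' @rdname tidy.osseq_design
#' @param object An `osseq_design`.
#' @export
autoplot.osseq_design <- function(object, ...) {
  p <- object$probes
  ggplot(p, aes(
    x = .data$anchor_start, xend = .data$anchor_end,
    y = .data$strand, yend = .data$strand, color = .data$strand
  )) +
    geom_segment(linewidth = 3) +
    facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    scale_color_manual(values = c("+" = "#1b9e77", "-" = "#d95f02")) +
    labs(
      x = "genome position (bases)", y = "strand",
      title = "Primer probe anchors"
    ) +
    theme_minimal()
}

#' Tidy/summarize a per-probe yield table
#'
#' `tidy()` returns the per-probe on-target counts; `glance()` the capture
#' rate, one-log uniformity and totals.
#'
#' @param x An `osseq_yield` from [per_probe_yield()].
#' @param ... Unused.
#' @export
tidy.osseq_yield <- function(x, ...) {
  tibble(probe_id = x$probe_id, n_on = x$n_on)
}

#' @rdname tidy.osseq_yield
#' @export
glance.osseq_yield <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_assigned = attr(x, "n_assigned"),
    n_on = attr(x, "n_on"),
    capture_rate = attr(x, "capture_rate"),
    uniformity_1log = attr(x, "uniformity_1log")
  )
}

#' @rdname tidy.osseq_yield
#' @param object An `osseq_yield`.
#' @export
autoplot.osseq_yield <- function(object, ...) {
  d <- tibble(
    rank = rank(-object$n_on, ties.method = "first"),
    yield = object$n_on
  )
  m <- median(object$n_on)
  ggplot(d, aes(x = .data$rank, y = pmax(.data$yield, 0.5))) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = max(m, 0.5), linetype = 2) +
    geom_hline(
      yintercept = pmax(c(m / 10, 10 * m), 0.5),
      linetype = 3, color = "grey50"
    ) +
    scale_y_log10() +
    labs(
      x = "probes ranked by yield", y = "on-target reads (log scale)",
      title = "Per-probe yield and one-log uniformity window"
    ) +
    theme_minimal()
}

#' Plot a mapability track
#'
#' @param object A `kmer_track` from [classify_positions()].
#' @param ... Unused.
#' @export
autoplot.kmer_track <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$pos, y = 1, fill = .data$code)) +
    geom_tile() +
    facet_wrap(~seqname, ncol = 1) +
    scale_fill_brewer(palette = "Set2") +
    labs(
      x = "window start (0-based)", y = NULL,
      title = sprintf(
        "k-mer mapability (k = %d, margin = %d)",
        attr(object, "k"), attr(object, "margin")
      )
    ) +
    theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.ticks.y = ggplot2::element_blank()
    )
}

#' Plot observed allele fractions against expectation
#'
#' Points are observed allele fractions at truth sites (e.g. from
#' [count_alleles()] on a mixture simulation); horizontal marks show the
#' expected fraction per group.
#'
#' @param sites Tibble with `af`, `expected_af`, and optionally `zygosity`.
#' @return A ggplot.
#' @export
plot_allele_fractions <- function(sites) {
  ggplot(sites, aes(
    x = factor(.data$expected_af), y = .data$af,
    color = if ("zygosity" %in% names(sites)) .data$zygosity else NULL
  )) +
    geom_point(position = ggplot2::position_jitter(width = 0.1, height = 0)) +
    geom_point(aes(y = .data$expected_af),
      shape = 95, size = 12, color = "black"
    ) +
    labs(
      x = "expected allele fraction", y = "observed allele fraction",
      color = "zygosity",
      title = "Mixture allele fractions at spike-unique sites"
    ) +
    theme_minimal()
}
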