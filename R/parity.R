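#' Tabulate proteins by cysteine count (parity analysis)
#'
#' Counts proteins by their raw cysteine number within a protein-length
#' window. In proteomes where most cysteines are disulfide-paired, proteins
#' with an even number of cysteines are over-represented (a "sawtooth" in the
#' count histogram); the effect is clearest for mid-sized proteins, hence the
#' default 150-200 residue window. Run this after the secretion filter but
#' before the clustering mask: parity is about whole-protein cysteine totals.
#'
#' @param proteome Proteome tibble (already secretion-filtered).
#' @param length_min,length_max Inclusive protein-length window
#'   (defaults 150 and 200).
#' @param max_cys_bin Histogram cap: counts above this are pooled into a
#'   single `>= max_cys_bin` bin in printed/plotted output (default 10).
#'   The underlying even/odd tallies always use exact counts.
#' @return An object of class `parity_table`: a list with `counts` (tibble
#'   of `n_cys`, `n_proteins`), `n_total`, `even_ge2` (proteins with an even
#'   cysteine count `>= 2`), `odd_ge3` (odd count `>= 3`) and the window.
#'   An empty window gives `n_total = 0`, not an error.
#' @export
parity_table <- function(proteome, length_min = 150, length_max = 200,
                         max_cys_bin = 10) {
  stopifnot(length_min <= length_max)
  inwin <- proteome$length >= length_min & proteome$length <= length_max
  ncys <- proteome$n_cys[inwin]
  counts <- tibble::tibble(n_cys = sort(unique(ncys))) |>
    dplyr::mutate(n_proteins = vapply(.data$n_cys,
                                      function(k) sum(ncys == k), integer(1)))
  structure(
    list(counts = counts,
         n_total = length(ncys),
         even_ge2 = sum(ncys >= 2L & ncys %% 2L == 0L),
         odd_ge3 = sum(ncys >= 3L & ncys %% 2L == 1L),
         length_min = length_min, length_max = length_max,
         max_cys_bin = max_cys_bin),
    class = "parity_table"
  )
}

#' @export
print.parity_table <- function(x, ...) {
  cat(sprintf("Cysteine parity table (%d-%d aa window): %d proteins\n",
              x$length_min, x$length_max, x$n_total))
  print(tidy(x))
  cat(sprintf("even (>=2): %d   odd (>=3): %d\n", x$even_ge2, x$odd_ge3))
  invisible(x)
}

#' @describeIn parity_table Tidy histogram with the tail pooled at
#'   `>= max_cys_bin`.
#' @param x A `parity_table`.
#' @param ... Unused.
#' @export
tidy.parity_table <- function(x, ...) {
  ct <- x$counts
  if (nrow(ct) == 0L) {
    return(tibble::tibble(n_cys = integer(), n_proteins = integer(), pooled = logical()))
  }
  pooled <- ct$n_cys >= x$max_cys_bin
  out <- ct[!pooled, , drop = FALSE]
  if (any(pooled)) {
    out <- dplyr::bind_rows(out, tibble::tibble(n_cys = x$max_cys_bin,
                                                n_proteins = sum(ct$n_proteins[pooled])))
  }
  out$pooled <- out$n_cys >= x$max_cys_bin
  out
}

#' @export
glance.parity_table <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, even_ge2 = x$even_ge2, odd_ge3 = x$odd_ge3)
}

#' Even-versus-odd parity bias statistic
#'
#' Reduces a [parity_table()] to a scalar: among proteins that could plausibly
#' carry at least one disulfide (even count `>= 2`) or have a count
#' inconsistent with full pairing (odd count `>= 3`), the bias is
#' `(even - odd) / (even + odd)`, in `[-1, 1]`. Under the null that a
#' multi-cysteine protein is equally likely to fall in either class, `even`
#' is Binomial(n, 1/2); the p-value is the exact two-sided binomial test.
#' Proteins with 0 or 1 cysteines carry no pairing information and never
#' enter the statistic. This scalar summary is an extension of the visual
#' sawtooth analysis and is labelled as such in report output.
#'
#' @param table A `parity_table`.
#' @return A tibble with columns `bias`, `p_value`, `even_ge2`, `odd_ge3`.
#' @export
parity_bias <- function(table) {
  stopifnot(inherits(table, "parity_table"))
  e <- table$even_ge2; o <- table$odd_ge3
  if (e + o == 0L) abort("no multi-cysteine proteins")
  tibble::tibble(
    bias = (e - o) / (e + o),
    p_value = binom.test(e, e + o, p = 0.5)$p.value,
    even_ge2 = e,
    odd_ge3 = o
  )
}

#' Plot a parity table
#'
#' Line-and-point histogram of protein counts by cysteine number, the
#' standard way to eyeball the even/odd sawtooth.
#'
#' @param object A `parity_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parity_table <- function(object, ...) {
  dat <- tidy(object)
  labs <- ifelse(dat$pooled, paste0(">=", dat$n_cys), as.character(dat$n_cys))
  dat$label <- factor(labs, levels = labs)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$n_proteins, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n_cys %% 2 == 0), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                 labels = c(`TRUE` = "even", `FALSE` = "odd"),
                                 name = NULL) +
    ggplot2::labs(x = "cysteines per protein", y = "number of proteins") +
    ggplot2::theme_minimal()
}
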