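#' Take a census of a world
#'
#' A deterministic full scan (no RNG use): counts protocells by exact
#' gene-content signature, gene copies of each functional motif on sense
#' strands anywhere in the system, peptides of each functional kind (free,
#' membrane-embedded, and template-bound), and raw material totals.
#'
#' @param world A `drt_world`.
#' @return A one-row tibble in the same layout as [run_scenario()] output.
#' @export
take_census <- function(world) {
  .series_from_censuses(list(cpp_world_census(world$ptr)))
}

# frozen header of the on-disk series format
.series_header <- function() {
  c("step", "protocells", "mspg", "nspg", "nsr", "ctpg", "ctr",
    "msp", "nsp", "ctp", "np", "ap", "aap", "nt", "aa",
    "am_free", "am_membrane", "rna_strands", "rna_residues",
    "peptides_free", "classes")
}

#' Write / read a census time series as CSV
#'
#' One row per reporting step with a stable documented header. The exact
#' class counts are serialized into the `classes` column as
#' `"KEY:count|KEY:count"` pairs; `read_series()` restores the list column,
#' so a written series re-reads equal to the in-memory one.
#'
#' @param series A `drt_series`.
#' @param path Destination CSV file.
#' @return `write_series`: `path` invisibly; `read_series`: a tibble.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series[, setdiff(.series_header(), "classes")])
  df$classes <- vapply(series$classes, function(cl) {
    if (length(cl) == 0) return("")
    paste(paste0(names(cl), ":", as.integer(cl)), collapse = "|")
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(classes = "character"))
  df$classes <- lapply(df$classes, function(s) {
    if (is.na(s) || s == "") {
      return(stats::setNames(integer(0), character(0)))
    }
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(as.integer(vapply(parts, `[`, character(1), 2)),
                    vapply(parts, `[`, character(1), 1))
  })
  out <- tibble::as_tibble(df)
  class(out) <- c("drt_series", class(out))
  out
}

#' Declare the winner of a two-species competition
#'
#' A species wins when its competitor's gene-copy count is zero at the
#' final census while its own is positive. Any other ending (both present,
#' or joint extinction) is `"undecided"`; joint extinction is flagged in
#' the `extinction` attribute.
#'
#' @param series A `drt_series`.
#' @param competitors Character pair naming gene species, e.g.
#'   `c("NSR", "NSPG")`.
#' @return One of the competitor names or `"undecided"`, with attribute
#'   `extinction` (logical).
#' @export
declare_winner <- function(series, competitors = c("NSR", "NSPG")) {
  cols <- tolower(competitors)
  stopifnot(all(cols %in% names(series)))
  fin <- series[nrow(series), ]
  x <- fin[[cols[1]]]
  y <- fin[[cols[2]]]
  if (x > 0 && y == 0) {
    out <- competitors[1]
  } else if (y > 0 && x == 0) {
    out <- competitors[2]
  } else {
    out <- "undecided"
  }
  attr(out, "extinction") <- (x == 0 && y == 0)
  out
}

#' Plot a census time series
#'
#' Three stacked panels in the style of the reference experiments:
#' protocell counts by contained gene, gene copy counts, and peptide
#' counts. Requires ggplot2.
#'
#' @param series A `drt_series`.
#' @return A ggplot object.
#' @export
plot_series <- function(series) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_series() requires the ggplot2 package", call. = FALSE)
  }
  long <- list()
  add <- function(panel, label, value) {
    long[[length(long) + 1L]] <<- tibble::tibble(
      step = series$step, panel = panel, species = label, count = value)
  }
  for (m in c("MSPG", "NSPG", "NSR", "CTPG", "CTR")) {
    v <- cells_containing(series, m)
    if (any(v > 0)) add("protocells", paste0("C", tolower(m)), v)
  }
  for (g in c("mspg", "nspg", "nsr", "ctpg", "ctr")) {
    if (any(series[[g]] > 0)) add("genes", g, series[[g]])
  }
  for (p in c("msp", "nsp", "ctp")) {
    if (any(series[[p]] > 0)) add("peptides", p, series[[p]])
  }
  df <- do.call(rbind, long)
  df$panel <- factor(df$panel, levels = c("protocells", "genes", "peptides"))
  step <- count <- species <- NULL  # silence R CMD check notes
  ggplot2::ggplot(df, ggplot2::aes(x = step, y = count,
                                   colour = species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Monte Carlo step", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}
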