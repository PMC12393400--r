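#' @keywords internal
loci_as_list <- function(table) {
  if (is.list(table$loci)) return(table$loci)
  strsplit(as.character(table$loci), ";", fixed = TRUE) |>
    purrr::map(trimws)
}

#' Neurons labeled by an intersectional reporter cross
#'
#' Models the driver-by-reporter AND gate of intersectional labeling:
#' a recombinase (or split-GFP half) driven from one neurotransmission
#' locus switches on a conditional cassette carried at a second locus, so
#' fluorescence appears exactly in the cells expressing both. Given a
#' per-neuron expression table, returns the neurons whose expressed locus
#' set contains both the driver and the reporter locus.
#'
#' @param table An expression table: tibble with columns `neuron`,
#'   `class`, `category`, `region` and `loci` (list-column of character
#'   vectors, or semicolon-separated strings).
#' @param driver_locus,reporter_locus Locus identifiers; both must occur
#'   somewhere in the table's locus vocabulary.
#' @return A character vector of neuron names (sorted, unique).
#' @examples
#' tab <- fig6_coexpression()
#' labeled_neurons(tab, "unc-17", "eat-4")
#' @export
labeled_neurons <- function(table, driver_locus, reporter_locus) {
  stopifnot(is.data.frame(table))
  if (driver_locus == reporter_locus)
    stop("driver and reporter locus must differ", call. = FALSE)
  if (nrow(table) == 0) return(character(0))
  loci <- loci_as_list(table)
  vocab <- unique(unlist(loci))
  unknown <- setdiff(c(driver_locus, reporter_locus), vocab)
  if (length(unknown) > 0)
    stop("locus not present in the table's vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hit <- purrr::map_lgl(loci, function(l)
    driver_locus %in% l && reporter_locus %in% l)
  sort(unique(table$neuron[hit]))
}

#' Integer percentage
#'
#' @param count,total Non-negative integers with `count <= total`,
#'   `total > 0`.
#' @param digits Decimal places to report (default 0, matching printed
#'   summary-table precision).
#' @return `100 * count / total`, rounded.
#' @examples
#' percentage(10, 83)  # 12
#' percentage(8, 116)  # 7
#' @export
percentage <- function(count, total, digits = 0) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must satisfy 0 <= count <= total", call. = FALSE)
  round(100 * count / total, digits)
}

#' Tally co-transmitting neurons across reporter crosses
#'
#' A neuron counts as co-transmitting when at least one cross labels it
#' (the union over crosses; a neuron labeled by several crosses counts
#' once). Counts and integer percentages are reported per anatomical
#' category, per region, and overall.
#'
#' @param table An expression table (see [labeled_neurons()]).
#' @param crosses A data frame with columns `driver_locus` and
#'   `reporter_locus`, one row per cross.
#' @return A list of class `cotx_summary`: `neurons` (character vector of
#'   co-transmitting neurons), `by_category` and `by_region` tibbles
#'   (`n_cotx`, `n_total`, `pct`; `pct` is `NA` for empty strata), and
#'   `overall` (one row).
#' @examples
#' crosses <- tibble::tibble(driver_locus = c("unc-17", "unc-47"),
#'                           reporter_locus = "eat-4")
#' tally_cotransmission(fig6_coexpression(), crosses)
#' @export
tally_cotransmission <- function(table, crosses) {
  stopifnot(is.data.frame(crosses),
            all(c("driver_locus", "reporter_locus") %in% names(crosses)))
  labeled <- purrr::map2(crosses$driver_locus, crosses$reporter_locus,
                         function(d, r) labeled_neurons(table, d, r))
  cotx <- sort(unique(unlist(labeled)))
  is_cotx <- table$neuron %in% cotx

  strat <- function(var) {
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(g = table[[var]], cotx = is_cotx),
                      .data$g),
      n_cotx = sum(.data$cotx), n_total = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(pct = ifelse(.data$n_total > 0,
                                 percentage(.data$n_cotx, .data$n_total),
                                 NA_real_)) |>
      dplyr::rename(!!var := "g")
  }

  structure(list(
    neurons = cotx,
    by_category = strat("category"),
    by_region = strat("region"),
    overall = tibble::tibble(n_cotx = length(cotx),
                             n_total = nrow(table),
                             pct = if (nrow(table) > 0)
                               percentage(length(cotx), nrow(table))
                             else NA_real_)
  ), class = "cotx_summary")
}

#' @export
print.cotx_summary <- function(x, ...) {
  cat("<cotx_summary> ", x$overall$n_cotx, " of ", x$overall$n_total,
      " neurons co-transmitting (", x$overall$pct, "%)\n", sep = "")
  print(x$by_category)
  invisible(x)
}

#' Read / write an expression table TSV
#'
#' The on-disk dialect is a TSV with columns `neuron`, `class`,
#' `category`, `region`, `loci`, the last holding semicolon-separated
#' locus identifiers.
#'
#' @param file Path to the TSV.
#' @return `read_expression_table()` returns an expression table with a
#'   list-column `loci`.
#' @export
read_expression_table <- function(file) {
  raw <- readr::read_tsv(file, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("neuron", "class", "category", "region", "loci")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("expression table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- tibble::as_tibble(raw[need])
  out$loci <- loci_as_list(out)
  out
}

#' @rdname read_expression_table
#' @param table An expression table.
#' @export
write_expression_table <- function(table, file) {
  out <- dplyr::mutate(
    table, loci = purrr::map_chr(loci_as_list(table), paste,
                                 collapse = ";"))
  readr::write_tsv(out, file)
  invisible(file)
}

#' Co-expression table transcribed from printed reporter identifications
#'
#' The neurons identified by the intersectional reporter crosses among
#' the four major transmitter loci: the five cholinergic/glutamatergic
#' neurons (AFDL, AFDR, M5, DVA, PVN), the GABA/glutamate pharyngeal
#' neuron I2L, the dopamine/glutamate neuron PDE, the acetylcholine/GABA
#' neurons M4, SDQR and SMD, and the acetylcholine/serotonin neurons ADF,
#' HSN, VC4 and VC5. This transcribed set covers only the printed
#' identifications, not the full supplementary co-transmission roster, so
#' its totals are not nervous-system-wide totals.
#'
#' Loci: `eat-4` (VGLUT, glutamatergic), `unc-17` (VAChT, cholinergic),
#' `unc-47` (VGAT, GABAergic), `cat-1` (VMAT, monoaminergic), `dat-1`
#' (dopaminergic), `tph-1` (serotonergic).
#'
#' @return An expression table tibble with list-column `loci`.
#' @examples
#' labeled_neurons(fig6_coexpression(), "unc-47", "eat-4")  # "I2L"
#' @export
fig6_coexpression <- function() {
  tab <- tibble::tribble(
    ~neuron, ~class, ~category,     ~region,   ~loci,
    "AFDL",  "AFD",  "sensory",     "head",    c("unc-17", "eat-4"),
    "AFDR",  "AFD",  "sensory",     "head",    c("unc-17", "eat-4"),
    "M5",    "M5",   "motor",       "pharynx", c("unc-17", "eat-4"),
    "DVA",   "DVA",  "interneuron", "tail",    c("unc-17", "eat-4"),
    "PVN",   "PVN",  "interneuron", "tail",    c("unc-17", "eat-4"),
    "I2L",   "I2",   "interneuron", "pharynx", c("unc-47", "eat-4"),
    "PDE",   "PDE",  "sensory",     "midbody", c("dat-1", "eat-4"),
    "M4",    "M4",   "motor",       "pharynx", c("unc-47", "unc-17"),
    "SDQR",  "SDQ",  "interneuron", "midbody", c("unc-47", "unc-17"),
    "SMD",   "SMD",  "motor",       "head",    c("unc-47", "unc-17"),
    "ADF",   "ADF",  "sensory",     "head",    c("tph-1", "unc-17"),
    "HSN",   "HSN",  "motor",       "midbody", c("tph-1", "unc-17"),
    "VC4",   "VC",   "motor",       "midbody", c("tph-1", "unc-17"),
    "VC5",   "VC",   "motor",       "midbody", c("tph-1", "unc-17")
  )
  tab
}
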