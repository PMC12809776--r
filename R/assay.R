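#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join n row_number bind_rows distinct pull across
NULL

AA_CODES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

MCLASS_LEVELS <- c("synonymous", "missense", "deletion", "insertion", "nonsense")

#' Parse variant descriptors
#'
#' Parses compact variant strings of the form `<WT><POS><MUT>` where `WT` is a
#' one-letter amino-acid code, `POS` a 1-based protein position, and `MUT`
#' either a one-letter code, `=` (synonymous), `*` (nonsense / stop), `del`
#' (single-residue deletion) or `ins` (insertion after the position).
#' A mutant identical to the wild-type residue is treated as synonymous.
#'
#' @param x Character vector of variant descriptors, e.g. `"A123V"`, `"A123="`,
#'   `"G77del"`, `"K9*"`.
#' @return A tibble with columns `variant_id`, `wt`, `position`, `mut`,
#'   `mclass` (one row per descriptor). `mclass` is a factor with levels
#'   synonymous, missense, deletion, insertion, nonsense.
#' @examples
#' parse_variants(c("A123V", "A123=", "G77del", "K9*"))
#' @export
parse_variants <- function(x) {
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([A-Za-z]?)([0-9]+)([A-Za-z]|=|\\*|del|ins)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    abort(sprintf(
      "malformed variant descriptor(s): %s",
      paste(utils::head(x[bad], 5L), collapse = ", ")
    ))
  }
  wt <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- vapply(m, `[`, "", 4L)
  mut <- ifelse(mut %in% c("del", "ins", "=", "*"), mut, toupper(mut))
  if (any(pos < 1L)) {
    abort(sprintf("position must be >= 1 (offending: %s)",
                  paste(utils::head(x[pos < 1L], 5L), collapse = ", ")))
  }
  ok_wt <- wt %in% AA_CODES | (wt == "" & mut == "ins")
  if (any(!ok_wt)) {
    abort(sprintf("unknown wild-type residue in: %s",
                  paste(utils::head(x[!ok_wt], 5L), collapse = ", ")))
  }
  ok_mut <- mut %in% c(AA_CODES, "=", "*", "del", "ins")
  if (any(!ok_mut)) {
    abort(sprintf("unknown mutant token in: %s",
                  paste(utils::head(x[!ok_mut], 5L), collapse = ", ")))
  }
  mclass <- dplyr::case_when(
    mut == "=" | mut == wt ~ "synonymous",
    mut == "*" ~ "nonsense",
    mut == "del" ~ "deletion",
    mut == "ins" ~ "insertion",
    TRUE ~ "missense"
  )
  mut <- ifelse(mut == "=", wt, ifelse(mut == "*", "ter", mut))
  tibble(
    variant_id = x,
    wt = wt,
    position = pos,
    mut = mut,
    mclass = factor(mclass, levels = MCLASS_LEVELS)
  )
}

#' Construct a DMS assay from a count table
#'
#' Builds a `dms_assay` object from a wide data frame with one row per variant:
#' a `variant` column holding descriptors understood by [parse_variants()], and
#' one count column per (selection round, replicate) named `c_<t>_<r>` (or any
#' names matchable by `count_regex`, with round and replicate as the two
#' capture groups). Rows whose descriptor contains more than one mutation
#' (separated by `;` or `,`) are higher-order variants and are dropped with a
#' message, mirroring the usual DMS single-mutant filter.
#'
#' @param data Data frame with a variant descriptor column and count columns.
#' @param variant_col Name of the descriptor column. Default `"variant"`.
#' @param count_regex Regular expression with two integer capture groups
#'   (round, replicate) identifying count columns. Default `"^c_(\\d+)_(\\d+)$"`.
#' @param meta Optional named list of assay metadata (e.g. `protein`,
#'   `condition`).
#' @return A `dms_assay`: a list with the variant tibble, the raw count matrix
#'   (rows = variants, columns = round/replicate pairs), column layout
#'   (`rounds` tibble with `t` and `rep`), `T` (last selection round), `R`
#'   (replicates), and slots filled later by preprocessing (`m`, `pmap`,
#'   `position_groups`, `gmap`).
#' @seealso [read_counts()], [preprocess_assay()]
#' @export
dms_assay <- function(data, variant_col = "variant",
                      count_regex = "^c_(\\d+)_(\\d+)$", meta = list()) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("empty count table")
  if (!variant_col %in% names(data)) {
    abort(sprintf("no `%s` column in count table", variant_col))
  }
  cc <- grep(count_regex, names(data), value = TRUE)
  if (length(cc) == 0L) abort("no count columns matched `count_regex`")
  mm <- regmatches(cc, regexec(count_regex, cc))
  tt <- as.integer(vapply(mm, `[`, "", 2L))
  rr <- as.integer(vapply(mm, `[`, "", 3L))
  rounds <- tibble(col = cc, t = tt, rep = rr) |> arrange(.data$t, .data$rep)
  # every round must be observed in every replicate
  tab <- table(rounds$t, rounds$rep)
  if (any(tab != 1L)) {
    abort("inconsistent count columns: each (round, replicate) pair must appear exactly once")
  }

  desc <- as.character(data[[variant_col]])
  high_order <- grepl("[;,]", desc)
  if (any(high_order)) {
    inform(sprintf("dropping %d higher-order (multi-mutation) variant(s)", sum(high_order)))
    data <- data[!high_order, , drop = FALSE]
    desc <- desc[!high_order]
  }
  if (nrow(data) == 0L) abort("no single-mutation variants left after filtering")

  variants <- parse_variants(desc)
  counts <- as.matrix(data[, rounds$col, drop = FALSE])
  storage.mode(counts) <- "double"
  if (any(counts < 0, na.rm = TRUE)) abort("negative counts are not allowed")
  rownames(counts) <- variants$variant_id

  structure(
    list(
      variants = variants,
      counts = counts,
      rounds = rounds,
      T = max(rounds$t),
      R = max(rounds$rep),
      m = NULL,
      pmap = NULL,
      position_groups = NULL,
      gmap = NULL,
      n_dropped = sum(high_order),
      meta = meta
    ),
    class = "dms_assay"
  )
}

#' Read a raw DMS count table from delimited text
#'
#' Reads a CSV/TSV count table and constructs a [dms_assay()]. Wide layout is
#' canonical (`variant`, `c_<t>_<r>` columns); a long layout with columns
#' `variant`, `round`, `rep`, `count` is also accepted and pivoted.
#'
#' @param path Path to a delimited text file.
#' @param layout `"wide"` (default) or `"long"`.
#' @inheritParams dms_assay
#' @return A `dms_assay`.
#' @export
read_counts <- function(path, layout = c("wide", "long"),
                        variant_col = "variant",
                        count_regex = "^c_(\\d+)_(\\d+)$", meta = list()) {
  layout <- match.arg(layout)
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) abort("empty count table")
  if (layout == "long") {
    need <- c(variant_col, "round", "rep", "count")
    if (!all(need %in% names(df))) {
      abort("long layout requires columns: variant, round, rep, count")
    }
    df <- df |>
      mutate(.col = sprintf("c_%d_%d", as.integer(.data$round), as.integer(.data$rep))) |>
      select(dplyr::all_of(variant_col), ".col", "count") |>
      tidyr::pivot_wider(names_from = ".col", values_from = "count")
  }
  dms_assay(df, variant_col = variant_col, count_regex = count_regex, meta = meta)
}

#' @export
print.dms_assay <- function(x, ...) {
  cat(sprintf(
    "<dms_assay> %d variants, rounds 0..%d, %d replicate(s)%s\n",
    nrow(x$variants), x$T, x$R,
    if (!is.null(x$m)) " [preprocessed]" else ""
  ))
  tb <- table(x$variants$mclass)
  cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (!is.null(x$position_groups)) {
    cat(sprintf("  position groups: %d (incl. control/pseudo)\n", nrow(x$position_groups)))
  }
  invisible(x)
}

#' Number of variants in an assay
#' @param assay A `dms_assay`.
#' @return Integer count of retained variants.
#' @export
n_variants <- function(assay) nrow(assay$variants)

# Subset an assay to a logical/integer variant index, keeping mappings aligned.
# Internal; used by the subsampling design module.
assay_subset <- function(assay, idx) {
  out <- assay
  out$variants <- assay$variants[idx, , drop = FALSE]
  out$counts <- assay$counts[idx, , drop = FALSE]
  if (!is.null(assay$m)) out$m <- assay$m[idx, , drop = FALSE]
  if (!is.null(assay$pmap)) out$pmap <- assay$pmap[idx]
  if (!is.null(assay$gmap)) out$gmap <- assay$gmap[idx]
  out
}
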