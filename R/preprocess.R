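#' Preprocessing configuration
#'
#' Bundles the tuning constants of the count-preprocessing pipeline: variant
#' filtering, missing-data imputation, normalisation to aligned log counts,
#' position-group construction and mean-group assignment.
#'
#' @param max_missing_frac Variants whose fraction of missing count cells
#'   exceeds this are removed. Default 0.5.
#' @param impute_strategy `"position_mean"` (mean of observed counts at the
#'   same position/round/replicate, falling back to `pseudocount`) or
#'   `"pseudocount"`.
#' @param pseudocount Positive value added before the log transform and used
#'   as the imputation fallback. Default 0.5.
#' @param min_pos_variants Minimum variants per position group; sparser
#'   positions are merged into the next position. Default 5.
#' @param n_mean_groups Number of equal-frequency bins of the naive per-variant
#'   score used to pool heteroscedastic error scales. Default 5.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(max_missing_frac = 0.5,
                              impute_strategy = c("position_mean", "pseudocount"),
                              pseudocount = 0.5,
                              min_pos_variants = 5L,
                              n_mean_groups = 5L) {
  impute_strategy <- match.arg(impute_strategy)
  stopifnot(
    max_missing_frac >= 0, max_missing_frac <= 1,
    pseudocount > 0, min_pos_variants >= 1, n_mean_groups >= 1
  )
  structure(
    list(
      max_missing_frac = max_missing_frac,
      impute_strategy = impute_strategy,
      pseudocount = pseudocount,
      min_pos_variants = as.integer(min_pos_variants),
      n_mean_groups = as.integer(n_mean_groups)
    ),
    class = "preprocess_config"
  )
}

#' Remove variants with too many missing count cells
#'
#' @param assay A `dms_assay`.
#' @param config A [preprocess_config()].
#' @return The filtered assay; the number of removed variants is reported via
#'   a message and stored in `assay$n_filtered`.
#' @export
filter_variants <- function(assay, config = preprocess_config()) {
  frac_na <- rowMeans(is.na(assay$counts))
  drop <- frac_na > config$max_missing_frac
  if (all(drop)) abort("all variants removed by the missingness filter")
  if (any(drop)) {
    inform(sprintf("filtered %d variant(s) with > %.0f%% missing cells",
                   sum(drop), 100 * config$max_missing_frac))
  }
  out <- assay_subset(assay, !drop)
  out$n_filtered <- sum(drop)
  out
}

#' Impute missing count cells
#'
#' Fills each missing cell with the mean of observed counts at the same
#' (position, round, replicate), falling back to the pseudocount when no
#' same-position observation exists (or always, under the `"pseudocount"`
#' strategy). Observed cells are never altered.
#'
#' @inheritParams filter_variants
#' @return The assay with a complete count matrix.
#' @export
impute_counts <- function(assay, config = preprocess_config()) {
  cnt <- assay$counts
  nas <- is.na(cnt)
  if (!any(nas)) return(assay)
  if (config$impute_strategy == "position_mean") {
    pos <- assay$variants$position
    for (j in which(colSums(nas) > 0L)) {
      col <- cnt[, j]
      pm <- tapply(col, pos, mean, na.rm = TRUE) # NaN where all-missing
      fill <- pm[as.character(pos)]
      fill[!is.finite(fill)] <- config$pseudocount
      col[is.na(col)] <- fill[is.na(col)]
      cnt[, j] <- col
    }
  } else {
    cnt[nas] <- config$pseudocount
  }
  assay$counts <- cnt
  assay
}

#' Normalise counts to aligned log counts
#'
#' Computes the aligned count
#' `m[v,t,r] = log(c[v,t,r] + pseudocount) - log(libsize[t,r]) - center[t,r]`,
#' where `libsize` is the column total and `center` is the per-column median of
#' the synonymous variants' values (total-count median when the assay has no
#' synonymous variants). By construction the synonymous median of `m` is 0 in
#' every column, anchoring the wild-type-like null at score 0.
#'
#' @inheritParams filter_variants
#' @return The assay with slot `m` filled.
#' @export
normalize_counts <- function(assay, config = preprocess_config()) {
  cnt <- assay$counts
  if (anyNA(cnt)) abort("counts contain missing cells; run impute_counts() first")
  libsize <- colSums(cnt)
  if (any(libsize <= 0)) abort("zero column total; cannot normalise")
  m <- log(sweep(cnt + config$pseudocount, 2L, libsize, "/"))
  is_syn <- assay$variants$mclass == "synonymous"
  center <- if (any(is_syn)) {
    apply(m[is_syn, , drop = FALSE], 2L, stats::median)
  } else {
    apply(m, 2L, stats::median)
  }
  assay$m <- sweep(m, 2L, center, "-")
  assay
}

#' Build the position-group map
#'
#' Maps each variant to a position group: synonymous variants are pooled into
#' one virtual control group; deletions and insertions are pooled into one
#' pseudo-position group per indel type; each remaining residue position with
#' fewer than `min_pos_variants` variants is merged into the next larger
#' position, cascading until every group reaches the minimum (a sparse
#' terminal group merges backward into the previous one).
#'
#' @inheritParams filter_variants
#' @return The assay with `pmap` (integer group index per variant) and
#'   `position_groups` (tibble with `pos_group`, `label`,
#'   `type` in residue/control/indel, `n_variants`) filled.
#' @export
build_position_map <- function(assay, config = preprocess_config()) {
  v <- assay$variants
  is_syn <- v$mclass == "synonymous"
  is_del <- v$mclass == "deletion"
  is_ins <- v$mclass == "insertion"
  is_res <- !(is_syn | is_del | is_ins) # missense + nonsense keep their position

  key <- rep(NA_character_, nrow(v))
  if (any(is_res)) {
    pos <- sort(unique(v$position[is_res]))
    grp_of_pos <- stats::setNames(seq_along(pos), pos) # start: one group per position
    counts <- table(factor(v$position[is_res], levels = pos))
    # forward cascade: sparse position merges into the next larger position
    sizes <- as.integer(counts)
    assign_to <- seq_along(pos)
    i <- 1L
    while (i < length(pos)) {
      if (sizes[i] < config$min_pos_variants) {
        sizes[i + 1L] <- sizes[i + 1L] + sizes[i]
        assign_to[assign_to == i] <- i + 1L
        sizes[i] <- 0L
      }
      i <- i + 1L
    }
    # terminal group: merge backward if still sparse
    last <- max(assign_to)
    if (sizes[last] < config$min_pos_variants && length(unique(assign_to)) > 1L) {
      prev <- max(setdiff(unique(assign_to), last))
      assign_to[assign_to == last] <- prev
    }
    key[is_res] <- sprintf("pos_%06d", assign_to[match(v$position[is_res], pos)])
  }
  key[is_del] <- "indel_del"
  key[is_ins] <- "indel_ins"
  key[is_syn] <- "control"

  lv <- c(sort(unique(key[is_res])),
          intersect(c("indel_del", "indel_ins"), key),
          if (any(is_syn)) "control")
  f <- factor(key, levels = lv)
  assay$pmap <- as.integer(f)
  # group label = largest original position in the group (residue groups)
  lab <- vapply(lv, function(k) {
    if (startsWith(k, "pos_")) {
      as.character(max(v$position[is_res & key == k]))
    } else k
  }, "")
  assay$position_groups <- tibble(
    pos_group = seq_along(lv),
    label = lab,
    type = dplyr::case_when(
      startsWith(lv, "pos_") ~ "residue",
      lv == "control" ~ "control",
      TRUE ~ "indel"
    ),
    n_variants = as.integer(table(f))
  )
  assay
}

# Naive per-variant functional score: OLS slope of aligned count on t/T.
# Used for mean-group binning and as the unshrunk baseline in tests.
naive_scores <- function(assay) {
  if (is.null(assay$m)) abort("aligned counts missing; run normalize_counts() first")
  x <- assay$rounds$t / assay$T
  xc <- x - mean(x)
  drop(assay$m %*% xc) / sum(xc^2)
}

#' Assign heteroscedastic mean groups
#'
#' Computes a naive per-variant score (ordinary least-squares slope of the
#' aligned count on scaled round t/T) and splits variants into
#' `n_mean_groups` equal-frequency bins of that score. Variants in the same
#' bin share one error scale in the model, pooling information about
#' mean-dependent noise.
#'
#' @inheritParams filter_variants
#' @return The assay with `gmap` (integer bin per variant) filled.
#' @export
assign_mean_groups <- function(assay, config = preprocess_config()) {
  G <- config$n_mean_groups
  if (G > n_variants(assay)) abort("n_mean_groups exceeds the number of variants")
  s <- naive_scores(assay)
  if (G == 1L) {
    assay$gmap <- rep(1L, length(s))
  } else {
    qs <- stats::quantile(s, probs = seq(0, 1, length.out = G + 1L), type = 7)
    qs[1L] <- -Inf; qs[G + 1L] <- Inf
    assay$gmap <- as.integer(cut(s, breaks = qs, labels = FALSE))
  }
  assay
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: [filter_variants()], [impute_counts()],
#' [normalize_counts()], [build_position_map()] and [assign_mean_groups()].
#' Deterministic given the configuration.
#'
#' @inheritParams filter_variants
#' @return A preprocessed `dms_assay` ready for [fit_dms()].
#' @export
preprocess_assay <- function(assay, config = preprocess_config()) {
  assay |>
    filter_variants(config) |>
    impute_counts(config) |>
    normalize_counts(config) |>
    build_position_map(config) |>
    assign_mean_groups(config)
}
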