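#' Load a substitution matrix in NCBI text format
#'
#' Reads a whitespace-delimited scoring matrix as distributed by NCBI
#' (comment lines starting with `#`, a header row of residue codes, one row
#' per residue). The package bundles the published BLOSUM90 table; any matrix
#' in the same format can be supplied instead.
#'
#' @param path Path to a matrix file; default is the bundled BLOSUM90.
#' @return An integer matrix with residue-code dimnames.
#' @export
blosum_matrix <- function(path = NULL) {
  path <- path %||% system.file("extdata", "BLOSUM90.txt", package = "dmsvar")
  df <- utils::read.table(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- list(rownames(df), colnames(df))
  storage.mode(m) <- "integer"
  if (!isSymmetric(unname(m))) abort("substitution matrix is not symmetric")
  m
}

#' Score an amino-acid substitution
#'
#' @param wt,mut One-letter residue codes (vectorised).
#' @param matrix A scoring matrix from [blosum_matrix()].
#' @return Integer substitution score(s); symmetric in its arguments.
#' @examples
#' blosum_score("D", "E")
#' @export
blosum_score <- function(wt, mut, matrix = blosum_matrix()) {
  bad <- !(wt %in% rownames(matrix)) | !(mut %in% colnames(matrix))
  if (any(bad)) {
    abort(sprintf("unknown residue code(s): %s",
                  paste(unique(c(wt[bad], mut[bad])), collapse = ", ")))
  }
  matrix[cbind(wt, mut)]
}

#' Build the amino-acid substitution grouping
#'
#' Groups observed missense substitutions by BLOSUM score: distinct scores are
#' sorted ascending and adjacent score levels are greedily merged until the
#' positions carrying at least one variant of the group cover at least
#' `min_coverage` of all residue position groups (a trailing undersized group
#' merges into its neighbour). Nonsense variants get one dedicated group;
#' deletions and insertions get one dedicated group each (or the zero-effect
#' group when `indel_effects = FALSE`). Synonymous variants form the final
#' group `A`, whose effect is structurally zero. Group weights are the
#' mean-normalised variant counts of the non-synonymous groups, and the
#' constraint factor realises the degenerate weighted sum-to-zero prior.
#'
#' @param assay A preprocessed `dms_assay` (position map built).
#' @param min_coverage Minimum fraction of residue position groups a
#'   substitution group must touch. Default 0.2.
#' @param matrix Substitution matrix, default bundled BLOSUM90.
#' @param coverage_by Count coverage over `"positions"` (default: distinct
#'   residue position groups touched) or `"variants"` (fraction of missense
#'   variants in the group).
#' @param indel_effects If `TRUE` (default) indel groups carry substitution
#'   effects inside the weighted sum-to-zero set; if `FALSE` indels are pinned
#'   to the zero-effect synonymous group.
#' @return A `substitution_scheme`: list with `groups` (tibble: `group`,
#'   `type`, `score_min`, `score_max`, `n_variants`), `amap` (integer group
#'   per variant), `A` (total group count incl. the synonymous group),
#'   `w` (length `A - 1`), `M` and the whitened factor `B`
#'   (see [build_constraint()]).
#' @export
build_groups <- function(assay, min_coverage = 0.2, matrix = blosum_matrix(),
                         coverage_by = c("positions", "variants"),
                         indel_effects = TRUE) {
  coverage_by <- match.arg(coverage_by)
  if (is.null(assay$position_groups)) abort("run build_position_map() first")
  v <- assay$variants
  is_mis <- v$mclass == "missense"
  is_non <- v$mclass == "nonsense"
  is_del <- v$mclass == "deletion"
  is_ins <- v$mclass == "insertion"
  is_syn <- v$mclass == "synonymous"
  if (!any(is_mis | is_non | is_del | is_ins)) {
    abort("no non-synonymous variants; nothing to group")
  }

  n_res_groups <- sum(assay$position_groups$type == "residue")
  score <- rep(NA_integer_, nrow(v))
  score[is_mis] <- blosum_score(v$wt[is_mis], v$mut[is_mis], matrix)

  # greedy merge of adjacent score levels until the coverage floor is met
  mis_groups <- integer(0)
  lvl_group <- integer(0)
  lvls <- sort(unique(score[is_mis]))
  if (length(lvls)) {
    gid <- 1L
    cur <- integer(0)
    lvl_group <- stats::setNames(integer(length(lvls)), lvls)
    coverage <- function(lv_set) {
      in_set <- is_mis & score %in% lv_set
      if (coverage_by == "positions") {
        length(unique(assay$pmap[in_set])) / max(n_res_groups, 1L)
      } else {
        sum(in_set) / sum(is_mis)
      }
    }
    for (i in seq_along(lvls)) {
      cur <- c(cur, lvls[i])
      lvl_group[as.character(cur)] <- gid
      if (coverage(cur) >= min_coverage) {
        gid <- gid + 1L
        cur <- integer(0)
      }
    }
    if (length(cur)) { # trailing undersized group merges backward
      lvl_group[as.character(cur)] <- max(1L, gid - 1L)
    }
    mis_groups <- sort(unique(lvl_group))
  }

  key <- rep(NA_character_, nrow(v))
  key[is_mis] <- sprintf("mis_%02d", lvl_group[as.character(score[is_mis])])
  key[is_non] <- "nonsense"
  if (indel_effects) {
    key[is_del] <- "deletion"
    key[is_ins] <- "insertion"
  } else {
    key[is_del] <- "synonymous"
    key[is_ins] <- "synonymous"
  }
  key[is_syn] <- "synonymous"

  lv <- c(sort(unique(key[is_mis])),
          intersect(c("nonsense", "deletion", "insertion"), key),
          "synonymous")
  f <- factor(key, levels = lv)
  amap <- as.integer(f)
  A <- length(lv)

  groups <- tibble(
    group = seq_len(A),
    type = ifelse(startsWith(lv, "mis_"), "missense", lv),
    score_min = vapply(lv, function(k) {
      if (startsWith(k, "mis_")) min(score[is_mis & key == k]) else NA_integer_
    }, 1L),
    score_max = vapply(lv, function(k) {
      if (startsWith(k, "mis_")) max(score[is_mis & key == k]) else NA_integer_
    }, 1L),
    n_variants = as.integer(table(f))
  )

  scheme <- structure(
    list(groups = groups, amap = amap, A = A, levels = lv,
         coverage_by = coverage_by, min_coverage = min_coverage),
    class = "substitution_scheme"
  )
  scheme$w <- compute_weights(scheme)
  if (A >= 4L) {
    cf <- build_constraint(scheme$w, A)
    scheme$M <- cf$M
    scheme$B <- cf$B
  }
  scheme
}

#' @export
print.substitution_scheme <- function(x, ...) {
  cat(sprintf("<substitution_scheme> A = %d groups (last = synonymous, effect 0)\n", x$A))
  print(x$groups, n = x$A)
  invisible(x)
}

#' Mean-normalised group weights
#'
#' Weights of the non-synonymous substitution groups, `w_a = n_a / mean(n)`,
#' so that `mean(w) == 1` and equal group sizes give the unit vector. The
#' weighted sum-to-zero constraint `sum(w * nu) == 0` with these weights is
#' invariant to how substitutions are grouped.
#'
#' @param scheme A `substitution_scheme`.
#' @return Numeric vector of length `A - 1`.
#' @export
compute_weights <- function(scheme) {
  n <- scheme$groups$n_variants[-scheme$A]
  if (any(n == 0L)) abort("empty non-synonymous substitution group")
  n / mean(n)
}

#' Whitened factor of the degenerate sum-to-zero prior
#'
#' The prior on the non-synonymous substitution effects is
#' `nu[-A] ~ Normal(0, diag(w)^-1 M diag(w)^-1)` with
#' `M[i,j] = 1` if `i == j` and `-1/(A-2)` otherwise — an exchangeable
#' correlation matrix of rank `A - 2` whose null space is the all-ones vector.
#' Eigendecomposing `M` gives a factor `B` (`(A-1) x (A-2)`, columns scaled by
#' the square roots of the `A - 2` positive eigenvalues, each
#' `(A-1)/(A-2)`) with `M = B %*% t(B)` and `t(B) %*% 1 == 0`. Drawing
#' `nu[-A] = diag(w)^-1 %*% B %*% z` with standard-normal `z` therefore
#' satisfies `sum(w * nu[-A]) == 0` exactly on every draw.
#'
#' @param w Mean-normalised weights, length `A - 1`.
#' @param A Total group count (synonymous group included); must be at least 4
#'   so the constraint has at least two free dimensions.
#' @return List with `M` and `B`.
#' @export
build_constraint <- function(w, A) {
  if (A < 4L) {
    abort("need at least 4 substitution groups (A >= 4); regroup with a lower min_coverage")
  }
  if (length(w) != A - 1L) abort("w must have length A - 1")
  K <- A - 1L
  M <- matrix(-1 / (A - 2), K, K)
  diag(M) <- 1
  eig <- eigen(M, symmetric = TRUE)
  pos <- eig$values > 1e-10
  if (sum(pos) != A - 2L) abort("unexpected rank of the constraint correlation matrix")
  B <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), sum(pos))
  list(M = M, B = B)
}

# nu (length A-1) from whitened z (length A-2): exact weighted sum-to-zero.
nu_from_z <- function(z, scheme) {
  drop(scheme$B %*% z) / scheme$w
}
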