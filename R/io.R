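#' Write fit and decomposition outputs to delimited text
#'
#' Writes the per-variant score table (`scores.csv`), the per-position table
#' (`positions.csv`), the protein-level variance decomposition
#' (`decomposition.csv`) and, for models 2-3, the substitution-effect table
#' (`substitution_effects.csv`) into a directory. Optionally archives the
#' posterior draws of the position-level parameters as a long CSV.
#'
#' @param fit A `dms_fit`.
#' @param dir Output directory (created if absent).
#' @param decomposition Optional precomputed [variance_decomposition()]
#'   result; computed from the fit when `NULL`.
#' @param draws Also write the position-level posterior draws. Default `FALSE`.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(fit, dir, decomposition = NULL, draws = FALSE) {
  if (!inherits(fit, "dms_fit")) abort("`fit` must be a dms_fit object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scores = file.path(dir, "scores.csv"),
    positions = file.path(dir, "positions.csv"),
    decomposition = file.path(dir, "decomposition.csv")
  )
  readr::write_csv(fit$scores, paths[["scores"]])
  readr::write_csv(fit$positions, paths[["positions"]])
  dec <- decomposition %||% variance_decomposition(fit)
  readr::write_csv(dec, paths[["decomposition"]])
  if (fit$model >= 2) {
    paths[["substitution_effects"]] <- file.path(dir, "substitution_effects.csv")
    readr::write_csv(nu_summary(fit), paths[["substitution_effects"]])
  }
  if (draws) {
    paths[["draws"]] <- file.path(dir, "position_draws.csv")
    long <- purrr::map_dfr(
      c("phi", "sigma2", if (fit$model == 3) "rho"),
      function(f) {
        arr <- fit$draws[[f]]
        d <- dim(arr)
        tibble(
          family = f,
          chain = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
          iter = rep(rep(seq_len(d[1L]), times = d[2L]), times = d[3L]),
          index = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
          value = as.numeric(arr)
        )
      }
    )
    readr::write_csv(long, paths[["draws"]])
  }
  invisible(paths)
}

#' Read back a written score table
#'
#' @param path Path to a `scores.csv` written by [write_outputs()].
#' @return The score tibble.
#' @export
read_scores <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
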