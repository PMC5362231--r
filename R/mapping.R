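# Gridded occupancy and standard-error surfaces per year, exported as
# portable per-year CSV "map stacks" (the static equivalent of a dynamic
# occupancy map).

#' Predict an occupancy surface over a grid
#'
#' Adds per-cell occupancy probability (`psi`) and delta-method standard
#' error (`se`) columns to a prediction grid.
#'
#' @param fit An `occu_fit`.
#' @param grid `data.frame` with `cell`, `easting`, `northing` and one
#'   column per occupancy covariate of the fit. Covariates must already
#'   be on the fit's standardised scale unless `standardised = FALSE`, in
#'   which case the fit's stored constants are applied.
#' @param standardised Whether the grid covariates are already
#'   standardised.
#' @return The grid with `psi` and `se` columns appended.
#' @export
predict_surface <- function(fit, grid, standardised = TRUE) {
  stopifnot(is.data.frame(grid))
  if (!nrow(grid)) stop("empty prediction grid")
  need <- fit$occ_terms
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stop(sprintf("grid is missing covariate '%s' (first offending cell: %s)",
                 miss[1], grid$cell[1] %||% 1))
  W <- as.matrix(grid[, need, drop = FALSE])
  if (any(!is.finite(W))) {
    bad <- which(!is.finite(W), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite covariate '%s' at cell %s",
                 need[bad[2]], grid$cell[bad[1]] %||% bad[1]))
  }
  if (!standardised) {
    if (is.null(fit$data$std)) stop("fit carries no standardisation constants")
    W <- apply_standardisation(W, fit$data$std)
  }
  grid$psi <- as.numeric(predict_psi(fit, W))
  grid$se <- as.numeric(delta_method_se_psi(fit, W))
  grid
}

#' Export per-year occupancy surfaces as a map stack
#'
#' Writes one `map_<year>.csv` per year (columns `cell`, `easting`,
#' `northing`, `psi`, `se`, values fixed at 6 decimals so re-exports are
#' byte-identical) plus a `manifest.json` listing years, species and fit
#' identifiers.
#'
#' @param per_year_grids Named list (names = years) of grids as returned
#'   by [predict_surface()].
#' @param out_dir Output directory (created if needed).
#' @param species Species label for the manifest.
#' @param fit_ids Optional per-year fit identifiers.
#' @return Character vector of files written, invisibly.
#' @export
export_map_stack <- function(per_year_grids, out_dir,
                             species = NA_character_, fit_ids = NULL) {
  stopifnot(is.list(per_year_grids), length(per_year_grids) >= 1)
  years <- names(per_year_grids)
  if (is.null(years) || any(!nzchar(years)))
    stop("per_year_grids must be a named list (names = years)")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  files <- character()
  for (yr in years) {
    g <- per_year_grids[[yr]]
    if (!is.data.frame(g) || !nrow(g)) stop(sprintf("empty grid for %s", yr))
    stopifnot(all(c("cell", "easting", "northing", "psi", "se") %in% names(g)))
    out <- data.frame(cell = g$cell, easting = g$easting,
                      northing = g$northing,
                      psi = sprintf("%.6f", g$psi),
                      se = sprintf("%.6f", g$se))
    f <- file.path(out_dir, sprintf("map_%s.csv", yr))
    utils::write.csv(out, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  manifest <- list(years = years, species = species,
                   fit_ids = fit_ids %||% rep(NA_character_, length(years)),
                   n_cells = vapply(per_year_grids, nrow, 0L),
                   columns = c("cell", "easting", "northing", "psi", "se"),
                   rounding_decimals = 6L)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

#' Read a map stack written by [export_map_stack()]
#'
#' @param dir Map-stack directory.
#' @return Named list of per-year grids plus a `"manifest"` attribute.
#' @export
read_map_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grids <- lapply(manifest$years, function(yr)
    utils::read.csv(file.path(dir, sprintf("map_%s.csv", yr))))
  names(grids) <- manifest$years
  attr(grids, "manifest") <- manifest
  grids
}
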