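#' Stem-analysis data tables
#'
#' A `taper_data` object is a tibble of stem-analysis section measurements,
#' one row per measured section, with tree- and plot-level covariates
#' repeated down the rows. It is the common input to every fitting function
#' in the package.
#'
#' Required columns:
#' \describe{
#'   \item{plot_id, tree_id}{identifiers; a tree is keyed by the pair.}
#'   \item{D_cm}{diameter at breast height (1.3 m), cm; constant per tree.}
#'   \item{H_m}{total tree height, m; constant per tree; must exceed 1.3.}
#'   \item{h_m}{section height above ground, m; `0 < h_m < H_m`.}
#'   \item{d_cm}{over-bark stem diameter at `h_m`, cm; non-negative.}
#'   \item{Sd_trees_ha}{stand density, living trees per hectare; constant
#'     per plot.}
#'   \item{BA_m2_ha, Cd, age_yr}{optional plot covariates: basal area
#'     (m2/ha), canopy density (fraction in (0, 1]), and stand age (years).
#'     May be `NA`; they are required only by taper-model variants that use
#'     them.}
#' }
#'
#' Diameters are over-bark as measured; no bark correction is applied, and
#' no unit conversion is performed (heights in m, diameters in cm
#' throughout).
#'
#' @param x A data frame with the columns above.
#' @return `taper_data()` returns `x` as a validated tibble with class
#'   `"taper_data"`, rows ordered by plot, tree and section height.
#' @examples
#' td <- taper_data(tibble::tibble(
#'   plot_id = "p1", tree_id = "t1", D_cm = 21, H_m = 17.2,
#'   h_m = c(0.86, 8.6, 15.5), d_cm = c(24.1, 13.7, 3.9),
#'   Sd_trees_ha = 787, BA_m2_ha = 25.3, Cd = 0.7, age_yr = 36
#' ))
#' n_trees(td)
#' @export
taper_data <- function(x) {
  required <- c("plot_id", "tree_id", "D_cm", "H_m", "h_m", "d_cm",
                "Sd_trees_ha")
  optional <- c("BA_m2_ha", "Cd", "age_yr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "stemtaper_schema_error")
  }
  x <- tibble::as_tibble(x)
  for (col in setdiff(optional, names(x))) x[[col]] <- NA_real_
  x <- dplyr::select(x, dplyr::all_of(c(required, optional)),
                     dplyr::everything())
  if (nrow(x) == 0) {
    abort("taper_data needs at least one section row",
          class = "stemtaper_validation_error")
  }

  num_cols <- c("D_cm", "H_m", "h_m", "d_cm", "Sd_trees_ha", optional)
  for (col in num_cols) x[[col]] <- as.numeric(x[[col]])

  check_pos <- function(col, strict_min = 0) {
    bad <- !is.na(x[[col]]) & x[[col]] <= strict_min
    if (any(bad)) {
      abort(sprintf("Column %s must be > %s (first offending row: %d)",
                    col, format(strict_min), which(bad)[1]),
            class = "stemtaper_validation_error")
    }
  }
  check_pos("D_cm"); check_pos("h_m"); check_pos("Sd_trees_ha")
  check_pos("H_m", 1.3)
  if (any(!is.na(x$d_cm) & x$d_cm < 0)) {
    abort("Column d_cm must be >= 0", class = "stemtaper_validation_error")
  }
  if (any(!is.na(x$Cd) & (x$Cd <= 0 | x$Cd > 1))) {
    abort("Column Cd must lie in (0, 1]",
          class = "stemtaper_validation_error")
  }

  bad_h <- x$h_m >= x$H_m
  if (any(bad_h)) {
    i <- which(bad_h)[1]
    abort(sprintf(
      "Section height h_m (%.3f) >= total height H_m (%.3f) for tree %s/%s",
      x$h_m[i], x$H_m[i], x$plot_id[i], x$tree_id[i]),
      class = "stemtaper_validation_error")
  }

  # tree-level constants must not conflict within a tree,
  # plot-level covariates must not conflict within a plot
  chk <- function(data, keys, cols, what) {
    grp <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
    for (col in cols) {
      n_distinct_vals <- dplyr::summarise(
        grp, n = dplyr::n_distinct(.data[[col]], na.rm = FALSE),
        .groups = "drop")
      bad <- n_distinct_vals$n > 1
      if (any(bad)) {
        key <- paste(unlist(n_distinct_vals[which(bad)[1], keys]),
                     collapse = "/")
        abort(sprintf("Conflicting %s values of %s within %s %s",
                      what, col, paste(keys, collapse = "/"), key),
              class = "stemtaper_consistency_error")
      }
    }
  }
  chk(x, c("plot_id", "tree_id"), c("D_cm", "H_m"), "tree-level")
  chk(x, "plot_id", c("Sd_trees_ha", "BA_m2_ha", "Cd", "age_yr"),
      "plot-level")

  x <- dplyr::arrange(x, .data$plot_id, .data$tree_id, .data$h_m)
  dup <- dplyr::group_by(x, .data$plot_id, .data$tree_id)
  dup <- dplyr::summarise(dup, dup = anyDuplicated(.data$h_m) > 0,
                          .groups = "drop")
  if (any(dup$dup)) {
    i <- which(dup$dup)[1]
    abort(sprintf("Duplicate section heights within tree %s/%s",
                  dup$plot_id[i], dup$tree_id[i]),
          class = "stemtaper_validation_error")
  }
  class(x) <- unique(c("taper_data", class(x)))
  x
}

#' @rdname taper_data
#' @return `n_trees()` returns the number of distinct trees.
#' @export
n_trees <- function(x) {
  nrow(dplyr::distinct(as.data.frame(x)[c("plot_id", "tree_id")]))
}

# stable per-tree key used for grouping throughout the package
tree_key <- function(x) paste(x$plot_id, x$tree_id, sep = "\r")

#' Read and write stem-analysis CSV files
#'
#' The interchange format is a UTF-8 CSV with header
#' `plot_id,tree_id,D_cm,H_m,h_m,d_cm,Sd_trees_ha,BA_m2_ha,Cd,age_yr`,
#' one row per section measurement. Covariates are repeated on every row
#' and must be consistent within their plot (or tree, for `D_cm`/`H_m`).
#' `BA_m2_ha`, `Cd` and `age_yr` may be empty.
#'
#' @param path Path to a CSV file.
#' @return `read_stem_csv()` returns a validated [taper_data] tibble.
#' @export
read_stem_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "stemtaper_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         .default = readr::col_character()))
  # convert via strtod (correctly rounded) so written files parse back to
  # bit-identical doubles
  for (col in setdiff(names(x), c("plot_id", "tree_id"))) {
    x[[col]] <- as.numeric(x[[col]])
  }
  taper_data(x)
}

#' @rdname read_stem_csv
#' @param data A [taper_data] tibble (or coercible data frame).
#' @return `write_stem_csv()` invisibly returns `path`.
#' @export
write_stem_csv <- function(data, path) {
  data <- taper_data(data)
  cols <- c("plot_id", "tree_id", "D_cm", "H_m", "h_m", "d_cm",
            "Sd_trees_ha", "BA_m2_ha", "Cd", "age_yr")
  out <- dplyr::select(tibble::as_tibble(data), dplyr::all_of(cols))
  # serialise doubles at 17 significant digits so write/read round trips
  # reproduce every numeric field bit-for-bit
  for (col in cols[-(1:2)]) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# run code with a local RNG state seeded by `seed`; global stream untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split a taper dataset into fitting and validation parts
#'
#' The split unit is the whole tree: all sections of a tree land in the
#' same part, because section measurements within a tree are statistically
#' dependent and a row-level split would leak information between parts.
#' The validation part receives `round(fraction * n_trees)` randomly chosen
#' trees.
#'
#' @param data A [taper_data] tibble.
#' @param fraction Proportion of trees assigned to the validation part,
#'   in (0, 1). Default 0.25.
#' @param seed Integer seed making the split reproducible.
#' @return A list with elements `fitting` and `validation`, both
#'   [taper_data] tibbles forming a partition of the input trees.
#' @export
split_fit_validation <- function(data, fraction = 0.25, seed = 1) {
  data <- taper_data(data)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction < 1)
  trees <- dplyr::distinct(tibble::as_tibble(data)[c("plot_id", "tree_id")])
  n <- nrow(trees)
  if (n < 2) {
    abort("Need at least 2 trees to split", class = "stemtaper_validation_error")
  }
  n_val <- round(fraction * n)
  if (n_val == 0 || n_val == n) {
    abort(sprintf("fraction %.3f gives an empty part (%d of %d trees)",
                  fraction, n_val, n),
          class = "stemtaper_validation_error")
  }
  idx <- with_local_seed(seed, sample.int(n, n_val))
  key_all <- paste(trees$plot_id, trees$tree_id, sep = "\r")
  val_keys <- key_all[idx]
  in_val <- tree_key(data) %in% val_keys
  list(fitting = taper_data(data[!in_val, , drop = FALSE]),
       validation = taper_data(data[in_val, , drop = FALSE]))
}
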