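# End-to-end run modes: calibration-curve analysis and category comparison.

read_inputs_dir <- function(inputs_dir) {
  files <- sort(list.files(inputs_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no input CSV files in ", inputs_dir)
  inputs <- lapply(files, read_spot_input)
  names(inputs) <- vapply(seq_along(inputs), function(i)
    unname(inputs[[i]]$meta["experiment"]) %||%
      tools::file_path_sans_ext(basename(files[i])), character(1))
  inputs
}

resolve_glycan_list <- function(glist, exclude_neugc = FALSE) {
  if (is.character(glist)) glist <- read_glycan_list(glist)
  filter_glycan_list(glist, exclude_neugc = exclude_neugc)
}

exp_list_frame <- function(table, stats, extra = NULL) {
  out <- table
  for (s in colnames(stats$mean)) {
    out[[paste0("mean.", s)]] <- stats$mean[, s]
    out[[paste0("sd.", s)]] <- stats$sd[, s]
    out[[paste0("cv_percent.", s)]] <- stats$cv[, s]
  }
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

write_exp_list <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the calibration-curve analysis
#'
#' The first of the two run modes: reads per-spot inputs generated from
#' calibration spots (serum volumes spotted in replicate), annotates and
#' quantifies them against the glycan list, fits a least-squares line of
#' pmol on volume for every spectral ID, and writes the standard outputs
#' into \code{out_dir}: \code{exp_list.csv}, \code{exp_list_zero_cut.csv},
#' \code{summary.csv}, \code{each_glycan_quant_point.html} (all signals) and
#' \code{each_glycan_quant_point_rcut.html} (only signals with R-squared at
#' or above \code{rcut}).
#'
#' @param glist glycan list (data.frame or CSV path).
#' @param inputs_dir directory of per-spot input CSVs (typically
#'   \code{calibration_line/}).
#' @param out_dir output directory (created if needed).
#' @param rcut R-squared threshold for the filtered chart (default 0.8).
#' @param exclude_neugc drop NeuGc glycans from the list before matching.
#' @param tolerance,is_mz,is_pmol overrides passed to
#'   [build_expression_table()].
#' @param registry residue registry.
#' @return Invisibly, a list with the expression table, its zero-cut subset,
#'   the per-signal fits (data.frame with list-column \code{fit}) and the
#'   per-volume statistics.
#' @export
run_calibration <- function(glist, inputs_dir, out_dir, rcut = 0.8,
                            exclude_neugc = FALSE, tolerance = NULL,
                            is_mz = NULL, is_pmol = NULL,
                            registry = default_registry()) {
  glist <- resolve_glycan_list(glist, exclude_neugc)
  inputs <- read_inputs_dir(inputs_dir)
  vols <- vapply(inputs, function(x)
    as.numeric(unname(x$meta["volume_ul"])), numeric(1))
  if (anyNA(vols))
    stop("calibration inputs must carry volume_ul metadata")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  expr <- build_expression_table(inputs, glist, tolerance = tolerance,
                                 is_mz = is_mz, is_pmol = is_pmol)
  tab <- expr$table
  amt <- as.matrix(tab[, grep("^amt\\.", names(tab)), drop = FALSE])
  series <- paste0(format(vols, trim = TRUE), "uL")
  stats <- aggregate_series(amt, series)
  ztab <- zero_cut(tab)
  zstats <- aggregate_series(
    as.matrix(ztab[, grep("^amt\\.", names(ztab)), drop = FALSE]), series)

  # one fit per spectral ID (candidates of a signal share its amounts)
  sid <- unique(ztab$spectral_id)
  fit_by_sid <- lapply(sid, function(s) {
    amounts <- as.numeric(
      ztab[match(s, ztab$spectral_id), grep("^amt\\.", names(ztab))])
    fit_calibration(vols, amounts)
  })
  names(fit_by_sid) <- as.character(sid)
  fits <- ztab[, c("spectral_id", "observed_mz", "class", "composition_id",
                   "composition_text", "theoretical_mz")]
  fits$fit <- fit_by_sid[as.character(fits$spectral_id)]
  fits$a <- vapply(fits$fit, function(f) f$a, numeric(1))
  fits$b <- vapply(fits$fit, function(f) f$b, numeric(1))
  fits$r_squared <- vapply(fits$fit, function(f) f$r_squared, numeric(1))
  fits$se_slope <- vapply(fits$fit, function(f) f$se_slope, numeric(1))
  fits <- fits[order(fits$theoretical_mz, fits$composition_id), ]
  rownames(fits) <- NULL

  extra <- fits[match(paste(ztab$spectral_id, ztab$composition_id),
                      paste(fits$spectral_id, fits$composition_id)),
                c("a", "b", "r_squared")]
  names(extra) <- c("slope_pmol_per_ul", "intercept_pmol", "r_squared")
  write_exp_list(exp_list_frame(tab, stats),
                 file.path(out_dir, "exp_list.csv"))
  write_exp_list(exp_list_frame(ztab, zstats, extra),
                 file.path(out_dir, "exp_list_zero_cut.csv"))
  write_summary(ztab, zstats, file.path(out_dir, "summary.csv"), registry)
  render_calibration_html(fits,
                          file.path(out_dir, "each_glycan_quant_point.html"))
  render_calibration_html(rcut_filter(fits, rcut),
                          file.path(out_dir,
                                    "each_glycan_quant_point_rcut.html"),
                          title = sprintf(
                            "Calibration curves (R&#178; &#8805; %.2f)", rcut))
  invisible(list(table = tab, zero_cut = ztab, fits = fits, stats = stats,
                 volumes = vols, expression = expr))
}

#' Run the category-comparison analysis
#'
#' The second run mode: per-spot inputs carry series/label metadata instead
#' of volumes; amounts are aggregated per series (mean, sd, CV) and every
#' pair of series is compared with a two-sided Welch t-test. Outputs in
#' \code{out_dir}: \code{exp_list.csv}, \code{exp_list_zero_cut.csv},
#' \code{summary.csv} and \code{each_glycan_quant.html} (bar charts with
#' error bars).
#'
#' @inheritParams run_calibration
#' @param p_adjust multiple-testing adjustment for the pairwise p-values:
#'   \code{"none"} (default, raw p-values) or \code{"BH"}
#'   (Benjamini-Hochberg across glycans, per pair).
#' @return Invisibly, a list with the expression table, its zero-cut subset,
#'   the per-series statistics and the pairwise p-value matrix.
#' @export
run_category <- function(glist, inputs_dir, out_dir,
                         exclude_neugc = FALSE, tolerance = NULL,
                         is_mz = NULL, is_pmol = NULL,
                         p_adjust = c("none", "BH"),
                         registry = default_registry()) {
  p_adjust <- match.arg(p_adjust)
  glist <- resolve_glycan_list(glist, exclude_neugc)
  inputs <- read_inputs_dir(inputs_dir)
  series <- vapply(inputs, function(x) {
    lb <- unname(x$meta["label"]) %||% ""
    sid <- unname(x$meta["series"]) %||% ""
    if (nzchar(lb)) lb else paste0("series", sid)
  }, character(1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  expr <- build_expression_table(inputs, glist, tolerance = tolerance,
                                 is_mz = is_mz, is_pmol = is_pmol)
  tab <- expr$table
  amt <- as.matrix(tab[, grep("^amt\\.", names(tab)), drop = FALSE])
  stats <- aggregate_series(amt, series)
  ztab <- zero_cut(tab)
  zamt <- as.matrix(ztab[, grep("^amt\\.", names(ztab)), drop = FALSE])
  zstats <- aggregate_series(zamt, series)

  lev <- unique(series)
  pvals <- NULL
  if (length(lev) >= 2L && nrow(ztab) > 0L) {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
    pvals <- vapply(pairs, function(pr) {
      p <- vapply(seq_len(nrow(zamt)), function(i)
        test_between_series(zamt[i, series == pr[1]],
                            zamt[i, series == pr[2]]), numeric(1))
      if (p_adjust == "BH") stats::p.adjust(p, method = "BH") else p
    }, numeric(nrow(ztab)))
    if (is.null(dim(pvals))) pvals <- matrix(pvals, nrow = nrow(ztab))
    colnames(pvals) <- vapply(pairs, function(pr)
      paste0("p.", pr[1], "_vs_", pr[2]), character(1))
  }
  write_exp_list(exp_list_frame(tab, stats),
                 file.path(out_dir, "exp_list.csv"))
  write_exp_list(exp_list_frame(ztab, zstats, as.data.frame(pvals)),
                 file.path(out_dir, "exp_list_zero_cut.csv"))
  write_summary(ztab, zstats, file.path(out_dir, "summary.csv"), registry)
  render_category_html(ztab, zstats,
                       file.path(out_dir, "each_glycan_quant.html"))
  invisible(list(table = tab, zero_cut = ztab, stats = zstats,
                 p_values = pvals, series = series, expression = expr))
}
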