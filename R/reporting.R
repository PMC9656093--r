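# Linked glycans, Glyconnect URLs, summary.csv and HTML chart rendering.

GLYCONNECT_PREFIX <- "https://glyconnect.expasy.org/browser/compositions?f="

#' Linked glycans: one-residue neighbors among detected compositions
#'
#' Two compositions are "linked" when they differ by exactly one residue
#' count unit (L1 distance 1 in residue-count space, same core state) -- a
#' proxy for adjacency in the biosynthetic pathway (e.g. a precursor missing
#' one 6NeuAc). Used in the summary to judge the plausibility of an
#' attribution.
#'
#' @param target_id 15-digit composition ID of the glycan of interest.
#' @param detected data.frame of detected compositions with columns
#'   \code{composition_id} and \code{spectral_id}.
#' @return The rows of \code{detected} linked to the target (the target
#'   itself is never its own neighbor).
#' @export
linked_glycans <- function(target_id, detected) {
  t_comp <- parse_composition_id(target_id)
  if (nrow(detected) == 0L) return(detected[0L, , drop = FALSE])
  ids <- unique(detected$composition_id)
  dist1 <- vapply(ids, function(id) {
    c2 <- parse_composition_id(id)
    c2$has_core == t_comp$has_core &&
      sum(abs(c2$counts - t_comp$counts)) == 1L
  }, logical(1))
  out <- detected[detected$composition_id %in% ids[dist1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Glyconnect composition-browser URL
#'
#' Builds the query URL for the Glyconnect composition browser from a
#' composition's total residue counts: core residues are folded in (Hex + 3,
#' HexNAc + 2), Fuc is reported as dHex, the two SALSA linkage variants of
#' NeuAc (and of NeuGc) are summed since the database indexes generic
#' compositions, and GlcA maps to HexA. Segments appear in the fixed order
#' Hex, HexNAc, dHex, NeuAc, NeuGc, HexA with zero counts omitted.
#'
#' @param comp a [composition()] carrying the M3 core.
#' @param registry residue registry.
#' @return URL string.
#' @examples
#' glyconnect_url(composition(c(Hex = 2, HexNAc = 1, "3-8NeuAc" = 1)))
#' @export
glyconnect_url <- function(comp, registry = default_registry()) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (!comp$has_core)
    stop("Glyconnect URLs are defined for compositions with the M3 core")
  cnt <- function(nm) {
    s <- match(nm, registry$name)
    if (is.na(s)) 0L else comp$counts[s]
  }
  totals <- c(Hex = cnt("Hex") + CORE_HEX,
              HexNAc = cnt("HexNAc") + CORE_HEXNAC,
              dHex = cnt("Fuc"),
              NeuAc = cnt("3-8NeuAc") + cnt("6NeuAc"),
              NeuGc = cnt("3-8NeuGc") + cnt("6NeuGc"),
              HexA = cnt("GlcA"))
  totals <- totals[totals > 0L]
  paste0(GLYCONNECT_PREFIX,
         paste0(names(totals), ":", totals, collapse = ""))
}

render_linked_field <- function(linked) {
  if (nrow(linked) == 0L) return("")
  paste(sprintf("%s [%d]", linked$composition_text, linked$spectral_id),
        collapse = "; ")
}

#' Write the analysis summary
#'
#' One row per (spectral ID, candidate glycan): observed mass, composition,
#' linked glycans with their spectral IDs in brackets, series aggregates
#' (mean, sd, CV) first, then per-experiment amounts, and the Glyconnect
#' query URL.
#'
#' @param table expression table (typically after [zero_cut()]).
#' @param stats result of [aggregate_series()] on the table's amounts.
#' @param path output CSV path.
#' @param registry residue registry.
#' @return Invisibly, the summary data.frame.
#' @export
write_summary <- function(table, stats, path,
                          registry = default_registry()) {
  amt_cols <- grep("^amt\\.", names(table), value = TRUE)
  detected <- table[, c("composition_id", "spectral_id",
                        "composition_text")]
  rows <- data.frame(spectral_id = table$spectral_id,
                     observed_mz = round(table$observed_mz, 4),
                     composition = table$composition_text,
                     composition_id = table$composition_id,
                     stringsAsFactors = FALSE)
  rows$linked_glycans <- vapply(seq_len(nrow(table)), function(i) {
    ln <- linked_glycans(table$composition_id[i],
                         detected[detected$spectral_id !=
                                    table$spectral_id[i], ])
    render_linked_field(unique(ln))
  }, character(1))
  for (s in colnames(stats$mean)) {
    rows[[paste0("mean.", s)]] <- round(stats$mean[, s], 6)
    rows[[paste0("sd.", s)]] <- round(stats$sd[, s], 6)
    rows[[paste0("cv_percent.", s)]] <- round(stats$cv[, s], 3)
  }
  rows <- cbind(rows, round(table[, amt_cols, drop = FALSE], 6))
  rows$glyconnect_url <- vapply(table$composition_id, function(id)
    glyconnect_url(parse_composition_id(id), registry), character(1),
    USE.NAMES = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

# --- HTML rendering (self-contained, inline SVG, no external assets) ------

svg_scatter_panel <- function(fit, title_lines) {
  w <- 320; h <- 260; mlft <- 45; mbot <- 35; mtop <- 10; mrgt <- 10
  pts <- fit$points
  xr <- range(0, pts$volume); yr <- range(0, pts$pmol, fit$b)
  if (diff(yr) == 0) yr <- yr + c(-1, 1)
  sx <- function(x) mlft + (x - xr[1]) / diff(xr) * (w - mlft - mrgt)
  sy <- function(y) h - mbot - (y - yr[1]) / diff(yr) * (h - mbot - mtop)
  # per-volume mean +- sd error bars
  agg <- split(pts$pmol, pts$volume)
  vols <- as.numeric(names(agg))
  mu <- vapply(agg, mean, numeric(1))
  sdev <- vapply(agg, function(v)
    if (length(v) > 1L) stats::sd(v) else 0, numeric(1))
  bars <- paste0(vapply(seq_along(vols), function(i) {
    x <- sx(vols[i]); y1 <- sy(mu[i] - sdev[i]); y2 <- sy(mu[i] + sdev[i])
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#888"/>',
            x, y1, x, y2)
  }, character(1)), collapse = "")
  dots <- paste0(sprintf(
    '<circle cx="%.1f" cy="%.1f" r="3" fill="#1f77b4" fill-opacity="0.7"/>',
    sx(pts$volume), sy(pts$pmol)), collapse = "")
  line <- sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#d62728" stroke-width="1.5"/>',
                  sx(xr[1]), sy(fit$a * xr[1] + fit$b),
                  sx(xr[2]), sy(fit$a * xr[2] + fit$b))
  axes <- sprintf(paste0(
    '<line x1="%1$.1f" y1="%3$.1f" x2="%2$.1f" y2="%3$.1f" stroke="black"/>',
    '<line x1="%1$.1f" y1="%4$.1f" x2="%1$.1f" y2="%3$.1f" stroke="black"/>'),
    sx(xr[1]), sx(xr[2]), sy(yr[1]), sy(yr[2]))
  lab <- sprintf(paste0(
    '<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">volume (uL)</text>',
    '<text x="12" y="%.1f" font-size="10" text-anchor="middle" transform="rotate(-90 12 %.1f)">pmol</text>'),
    (sx(xr[1]) + sx(xr[2])) / 2, h - 8, h / 2, h / 2)
  ann <- sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="end">y = %.3f x %+.3f, R&#178; = %.3f</text>',
                 w - mrgt - 2, h - mbot - 6, fit$a, fit$b, fit$r_squared)
  head_txt <- paste0(vapply(seq_along(title_lines), function(i)
    sprintf('<div class="t%d">%s</div>', i, title_lines[i]), character(1)),
    collapse = "")
  sprintf('<div class="panel">%s<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">%s%s%s%s%s%s</svg></div>',
          head_txt, w, h, axes, bars, dots, line, ann, lab)
}

svg_bar_panel <- function(means, sds, labels, title_lines) {
  w <- 320; h <- 260; mlft <- 45; mbot <- 45; mtop <- 10; mrgt <- 10
  k <- length(means)
  yr <- range(0, means + ifelse(is.na(sds), 0, sds))
  if (diff(yr) == 0) yr <- c(0, 1)
  sy <- function(y) h - mbot - (y - yr[1]) / diff(yr) * (h - mbot - mtop)
  bw <- (w - mlft - mrgt) / max(k, 1) * 0.7
  gap <- (w - mlft - mrgt) / max(k, 1)
  items <- vapply(seq_len(k), function(i) {
    x <- mlft + (i - 0.5) * gap - bw / 2
    bar <- sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="#1f77b4"/>',
                   x, sy(means[i]), bw, sy(0) - sy(means[i]))
    err <- if (!is.na(sds[i]) && sds[i] > 0)
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
              x + bw / 2, sy(means[i] - sds[i]), x + bw / 2,
              sy(means[i] + sds[i])) else ""
    txt <- sprintf('<text x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%s</text>',
                   x + bw / 2, h - mbot + 12, xml_escape(labels[i]))
    paste0(bar, err, txt)
  }, character(1))
  axis <- sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
                  mlft, sy(yr[1]), w - mrgt, sy(yr[1]))
  head_txt <- paste0(vapply(seq_along(title_lines), function(i)
    sprintf('<div class="t%d">%s</div>', i, title_lines[i]), character(1)),
    collapse = "")
  sprintf('<div class="panel">%s<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">%s%s</svg></div>',
          head_txt, w, h, axis, paste0(items, collapse = ""))
}

html_page <- function(title, body) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", title),
    "<style>body{font-family:sans-serif} .panel{display:inline-block;margin:8px;border:1px solid #ccc;padding:6px} .t1{font-weight:bold;font-size:12px} .t2,.t3{font-size:11px;color:#333}</style>",
    "</head><body>", sprintf("<h1>%s</h1>", title), body,
    "</body></html>")
}

#' Render calibration-curve charts
#'
#' Writes a self-contained HTML page with one panel per glycan signal:
#' scatter of replicate points with per-volume error bars, the least-squares
#' line, and the fit annotation (a, b, R-squared) together with the m/z,
#' composition and 15-digit composition ID.
#'
#' @param fits data.frame as built by [run_calibration()]: one row per
#'   (spectral_id, candidate), with a \code{fit} list-column.
#' @param path output HTML path.
#' @param title page title.
#' @return Invisibly, \code{path}.
#' @export
render_calibration_html <- function(fits, path,
                                    title = "Calibration curves") {
  body <- if (nrow(fits) == 0L)
    "<p>No glycans passed the filter.</p>"
  else paste0(vapply(seq_len(nrow(fits)), function(i) {
    svg_scatter_panel(fits$fit[[i]], c(
      sprintf("m/z %.4f [%d]", fits$observed_mz[i], fits$spectral_id[i]),
      xml_escape(fits$composition_text[i]),
      fits$composition_id[i]))
  }, character(1)), collapse = "\n")
  writeLines(html_page(title, body), path)
  invisible(path)
}

#' Render per-glycan abundance bar charts
#'
#' Writes a self-contained HTML page with one bar-plus-error-bar panel per
#' glycan signal, one bar per series (mean +- sd).
#'
#' @param table expression table rows to plot.
#' @param stats [aggregate_series()] result aligned with \code{table}.
#' @param path output HTML path.
#' @param title page title.
#' @return Invisibly, \code{path}.
#' @export
render_category_html <- function(table, stats, path,
                                 title = "Glycan abundances by series") {
  body <- if (nrow(table) == 0L)
    "<p>No glycans passed the filter.</p>"
  else paste0(vapply(seq_len(nrow(table)), function(i) {
    svg_bar_panel(stats$mean[i, ], stats$sd[i, ], colnames(stats$mean), c(
      sprintf("m/z %.4f [%d]", table$observed_mz[i], table$spectral_id[i]),
      xml_escape(table$composition_text[i]),
      table$composition_id[i]))
  }, character(1)), collapse = "\n")
  writeLines(html_page(title, body), path)
  invisible(path)
}
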