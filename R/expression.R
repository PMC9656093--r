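# Peak annotation, cross-experiment clustering, internal-standard
# quantification and per-series statistics.

DEFAULT_TOLERANCE <- 0.2  # Da; overridable from the plate file or call

# Default internal-standard m/z: BOA-labeled, sodiated disialyloctasaccharide
# (A2GN1), total composition (Hex)5 (HexNAc)3 (6NeuAc)2 = 2229.8767 Da.
# Its single core GlcNAc means it is not an intact N-glycan composition, so
# it never collides with a glycan-list entry.
default_is_mz <- function(registry = default_registry(),
                          label = label_scheme_boa_na()) {
  5 * registry$mass[registry$name == "Hex"] +
    3 * registry$mass[registry$name == "HexNAc"] +
    2 * registry$mass[registry$name == "6NeuAc"] +
    label_constant(label)
}

#' Match peaks against a glycan list
#'
#' For each peak, every glycan-list entry whose theoretical m/z lies within
#' \code{tolerance} of the observed m/z becomes a candidate; peaks with no
#' candidate are dropped, and all candidates of a peak are retained (isobaric
#' compositions are never arbitrated without MS/MS evidence).
#'
#' @param peaks data.frame with columns \code{mz}, \code{area}.
#' @param glist a glycan list (see [enumerate_compositions()]).
#' @param tolerance matching tolerance in Da (> 0).
#' @return data.frame with one row per (peak, candidate) pair: \code{peak}
#'   (row index into \code{peaks}), \code{observed_mz}, \code{area},
#'   \code{entry} (row index into \code{glist}), \code{composition_id},
#'   \code{theoretical_mz}, \code{delta_mz}.
#' @export
match_peaks <- function(peaks, glist, tolerance = DEFAULT_TOLERANCE) {
  if (nrow(glist) == 0L) stop("glycan list is empty")
  stopifnot(tolerance > 0)
  if (nrow(peaks) == 0L)
    return(data.frame(peak = integer(0), observed_mz = numeric(0),
                      area = numeric(0), entry = integer(0),
                      composition_id = character(0),
                      composition_text = character(0),
                      theoretical_mz = numeric(0), delta_mz = numeric(0)))
  theo <- glist$theoretical_mz  # sorted ascending by construction
  o <- order(theo)
  theo_s <- theo[o]
  lo <- findInterval(peaks$mz - tolerance, theo_s) + 1L
  hi <- findInterval(peaks$mz + tolerance, theo_s)
  n_hit <- pmax(hi - lo + 1L, 0L)
  pk <- rep(seq_len(nrow(peaks)), n_hit)
  ent <- unlist(lapply(seq_len(nrow(peaks)), function(i)
    if (n_hit[i] > 0L) o[lo[i]:hi[i]] else integer(0)))
  out <- data.frame(peak = pk, observed_mz = peaks$mz[pk],
                    area = peaks$area[pk], entry = ent,
                    composition_id = glist$composition_id[ent],
                    composition_text = glist$composition_text[ent],
                    theoretical_mz = theo[ent])
  out$delta_mz <- out$observed_mz - out$theoretical_mz
  out
}

#' Cluster matched peaks across experiments into spectral IDs
#'
#' Replicate spots produce near-identical peaks; these are grouped into one
#' "spectral cluster" per signal. Peaks are single-linkage grouped by m/z
#' with the matching tolerance as the link threshold; within a group, each
#' experiment may contribute at most one peak (the one nearest the group
#' mean), and displaced peaks seed new clusters by re-running the linkage
#' among themselves. Clusters are numbered densely from 1 in ascending mean
#' m/z.
#'
#' @param peaks data.frame with columns \code{experiment}, \code{mz} (one
#'   row per matched peak; deduplicated over candidates).
#' @param tolerance link threshold in Da.
#' @return Integer vector of spectral IDs, parallel to the rows of
#'   \code{peaks}.
#' @export
cluster_across_experiments <- function(peaks, tolerance = DEFAULT_TOLERANCE) {
  n <- nrow(peaks)
  if (n == 0L) return(integer(0))
  stopifnot(tolerance > 0)
  assign_pass <- function(idx) {
    # single-linkage chain over ascending m/z
    idx <- idx[order(peaks$mz[idx], peaks$experiment[idx])]
    gaps <- diff(peaks$mz[idx])
    grp <- cumsum(c(1L, as.integer(gaps > tolerance)))
    split(idx, grp)
  }
  final <- list()
  queue <- assign_pass(seq_len(n))
  while (length(queue) > 0L) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    exps <- peaks$experiment[g]
    if (!anyDuplicated(exps)) {
      final[[length(final) + 1L]] <- g
      next
    }
    ctr <- mean(peaks$mz[g])
    keep <- vapply(split(g, exps), function(ii)
      ii[which.min(abs(peaks$mz[ii] - ctr))], integer(1))
    rest <- setdiff(g, keep)
    final[[length(final) + 1L]] <- sort(keep)
    queue <- c(assign_pass(rest), queue)
  }
  means <- vapply(final, function(g) mean(peaks$mz[g]), numeric(1))
  ord <- order(means)
  ids <- integer(n)
  for (k in seq_along(ord)) ids[final[[ord[k]]]] <- k
  ids
}

#' Internal-standard quantification
#'
#' Converts a peak area to pmol by the area ratio to the spiked internal
#' standard: \code{pmol = area / is_area * is_pmol}.
#'
#' @param area peak area(s).
#' @param is_area internal-standard peak area in the same experiment (> 0).
#' @param is_pmol spiked internal-standard amount in pmol (> 0).
#' @return Amount(s) in pmol.
#' @export
quantify <- function(area, is_area, is_pmol) {
  stopifnot(is_area > 0, is_pmol > 0)
  area / is_area * is_pmol
}

# Locate the internal-standard peak: nearest peak to is_mz within tolerance.
# Returns its row index, or NA if the IS was not detected.
find_is_peak <- function(peaks, is_mz, tolerance) {
  if (nrow(peaks) == 0L) return(NA_integer_)
  d <- abs(peaks$mz - is_mz)
  i <- which.min(d)
  if (d[i] <= tolerance) i else NA_integer_
}

#' Per-series mean, standard deviation and CV
#'
#' @param amounts numeric matrix (rows = glycan signals, columns =
#'   experiments), in pmol.
#' @param series factor/character vector assigning each column to a series.
#' @return List of three matrices \code{mean}, \code{sd}, \code{cv}
#'   (rows as in \code{amounts}, one column per series level). \code{sd} is
#'   the sample standard deviation (n-1) and is NA for singleton series;
#'   \code{cv} is \code{100 * sd / mean}, NA when the mean is not positive.
#' @export
aggregate_series <- function(amounts, series) {
  series <- as.character(series)
  stopifnot(length(series) == ncol(amounts))
  lev <- unique(series)
  m <- s <- matrix(NA_real_, nrow(amounts), length(lev),
                   dimnames = list(NULL, lev))
  for (j in seq_along(lev)) {
    cols <- which(series == lev[j])
    sub <- amounts[, cols, drop = FALSE]
    m[, j] <- rowMeans(sub)
    if (length(cols) > 1L) s[, j] <- apply(sub, 1L, stats::sd)
  }
  cv <- 100 * s / m
  cv[!is.finite(cv)] <- NA_real_
  cv[is.na(m) | m <= 0] <- NA_real_
  list(mean = m, sd = s, cv = cv)
}

#' Welch t-test between two series
#'
#' Two-sided Welch (unequal-variance) t-test on per-experiment amounts.
#' When both series are constant the test statistic is undefined; equal
#' means then give p = 1 and unequal means p = 0.
#'
#' @param a,b numeric vectors of amounts (>= 2 values each).
#' @return p-value in [0, 1].
#' @export
test_between_series <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Drop all-zero rows from an expression table
#'
#' Removes rows whose amounts are zero or missing in every experiment;
#' all other rows are untouched. Idempotent.
#'
#' @param table an expression table (see [build_expression_table()]).
#' @return The filtered table.
#' @export
zero_cut <- function(table) {
  amt <- as.matrix(table[, grep("^amt\\.", names(table)), drop = FALSE])
  keep <- apply(amt, 1L, function(x) any(!is.na(x) & x > 0))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an expression table from per-spot inputs
#'
#' The end-to-end annotation/quantification step: matches every experiment's
#' peaks against the glycan list, clusters matched peaks across experiments
#' into spectral IDs, locates the internal-standard peak per experiment, and
#' converts member areas to pmol. An experiment whose internal standard is
#' not found is flagged and its amounts reported as missing (NA), whereas a
#' cluster simply absent from an experiment contributes 0 pmol.
#'
#' @param inputs named list of spot inputs as returned by
#'   [read_spot_input()].
#' @param glist glycan list.
#' @param tolerance matching tolerance in Da; if NULL, taken from the first
#'   input's \code{tolerance_da} metadata, else 0.2.
#' @param is_mz internal-standard m/z; defaults to the BOA/Na
#'   disialyloctasaccharide surrogate mass (see package vignette).
#' @param is_pmol spiked IS amount; if NULL, taken from metadata
#'   \code{is_pmol}, else an error.
#' @return List with \code{table} (data.frame: one row per spectral ID x
#'   candidate composition with columns \code{spectral_id},
#'   \code{observed_mz}, \code{class}, \code{composition_id},
#'   \code{composition_text}, \code{theoretical_mz} and one \code{amt.<exp>}
#'   column per experiment), \code{experiments} (data.frame of per-experiment
#'   metadata incl. \code{is_area}), \code{tolerance}, \code{is_mz},
#'   \code{is_pmol}.
#' @export
build_expression_table <- function(inputs, glist, tolerance = NULL,
                                   is_mz = NULL, is_pmol = NULL) {
  stopifnot(length(inputs) > 0L)
  if (nrow(glist) == 0L) stop("glycan list is empty")
  meta1 <- inputs[[1L]]$meta
  if (is.null(tolerance))
    tolerance <- if ("tolerance_da" %in% names(meta1))
      as.numeric(meta1[["tolerance_da"]]) else DEFAULT_TOLERANCE
  if (is.null(is_mz)) is_mz <- default_is_mz()
  if (is.null(is_pmol)) {
    if (!"is_pmol" %in% names(meta1))
      stop("is_pmol absent from input metadata; supply it explicitly")
    is_pmol <- as.numeric(meta1[["is_pmol"]])
  }
  exps <- names(inputs)
  if (is.null(exps) || any(!nzchar(exps)))
    exps <- vapply(inputs, function(x)
      unname(x$meta["experiment"]) %||% "", character(1))
  if (anyDuplicated(exps)) stop("experiment names must be unique")

  is_idx <- vapply(inputs, function(x)
    find_is_peak(x$peaks, is_mz, tolerance), integer(1))
  is_area <- vapply(seq_along(inputs), function(i)
    if (is.na(is_idx[i])) NA_real_ else
      inputs[[i]]$peaks$area[is_idx[i]], numeric(1))
  if (any(is.na(is_area)))
    warning("internal standard not found in: ",
            paste(exps[is.na(is_area)], collapse = ", "),
            "; amounts reported as NA")

  # the internal-standard peak is not an analyte: exclude it from matching
  matches <- lapply(seq_along(inputs), function(i) {
    pk <- inputs[[i]]$peaks
    if (!is.na(is_idx[i])) pk <- pk[-is_idx[i], , drop = FALSE]
    m <- match_peaks(pk, glist, tolerance)
    if (nrow(m) > 0L) m$experiment <- exps[i]
    m
  })
  all_m <- do.call(rbind, matches[vapply(matches, nrow, 1L) > 0L])
  if (is.null(all_m) || nrow(all_m) == 0L) {
    tab <- data.frame(spectral_id = integer(0), observed_mz = numeric(0),
                      class = character(0), composition_id = character(0),
                      composition_text = character(0),
                      theoretical_mz = numeric(0))
    for (e in exps) tab[[paste0("amt.", e)]] <- numeric(0)
    return(list(table = tab,
                experiments = data.frame(experiment = exps, is_area = is_area),
                tolerance = tolerance, is_mz = is_mz, is_pmol = is_pmol))
  }
  # unique matched peaks (a peak may carry several candidates)
  upk <- unique(all_m[, c("experiment", "peak", "observed_mz", "area")])
  upk$sid <- cluster_across_experiments(
    data.frame(experiment = upk$experiment, mz = upk$observed_mz), tolerance)
  key_m <- paste(all_m$experiment, all_m$peak)
  key_u <- paste(upk$experiment, upk$peak)
  all_m$sid <- upk$sid[match(key_m, key_u)]

  sids <- sort(unique(upk$sid))
  mean_mz <- vapply(sids, function(s)
    mean(upk$observed_mz[upk$sid == s]), numeric(1))

  # amounts: cluster x experiment
  amt <- matrix(0, length(sids), length(exps),
                dimnames = list(NULL, exps))
  for (r in seq_len(nrow(upk))) {
    i <- match(upk$sid[r], sids); j <- match(upk$experiment[r], exps)
    amt[i, j] <- amt[i, j] + upk$area[r]
  }
  for (j in seq_along(exps))
    amt[, j] <- if (is.na(is_area[j])) NA_real_ else
      quantify(amt[, j], is_area[j], is_pmol)

  # rows: cluster x candidate (union over members)
  cand <- unique(all_m[, c("sid", "entry")])
  cand <- cand[order(cand$sid, glist$composition_id[cand$entry]), ]
  tab <- data.frame(
    spectral_id = match(cand$sid, sids),
    observed_mz = mean_mz[match(cand$sid, sids)],
    class = glist$class[cand$entry],
    composition_id = glist$composition_id[cand$entry],
    composition_text = glist$composition_text[cand$entry],
    theoretical_mz = glist$theoretical_mz[cand$entry],
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(amt[match(cand$sid, sids), , drop = FALSE]))
  names(tab)[-(1:6)] <- paste0("amt.", exps)
  tab <- tab[order(tab$spectral_id, tab$composition_id), ]
  rownames(tab) <- NULL
  list(table = tab,
       experiments = data.frame(experiment = exps, is_area = is_area,
                                stringsAsFactors = FALSE),
       tolerance = tolerance, is_mz = is_mz, is_pmol = is_pmol)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
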