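# Synthetic masslists, plate files and truth tables with known glycan
# content, so every pipeline stage is testable without instrument data.

#' Default synthetic serum glycan panel
#'
#' A small panel spanning the serum N-glycome: abundant complex biantennary
#' glycans, oligomannose, a mannose-rich hybrid, a GlcA-bearing hybrid and
#' two LacDiNAc structures, with per-uL concentrations spanning two orders
#' of magnitude.
#'
#' @return data.frame with columns \code{composition_text},
#'   \code{conc_pmol_per_ul}.
#' @export
default_panel <- function() {
  data.frame(
    composition_text = c(
      "(Hex)2 (HexNAc)2 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (6NeuAc)1 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (6NeuAc)2 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (3-8NeuAc)1 (6NeuAc)1 + (Man)3(GlcNAc)2",
      "(Hex)2 (HexNAc)2 (Fuc)1 (6NeuAc)1 + (Man)3(GlcNAc)2",
      "(Hex)2 + (Man)3(GlcNAc)2",
      "(Hex)5 + (Man)3(GlcNAc)2",
      "(Hex)6 + (Man)3(GlcNAc)2",
      "(Hex)5 (HexNAc)1 (6NeuAc)1 + (Man)3(GlcNAc)2",
      "(Hex)5 (HexNAc)1 (Fuc)1 (GlcA)1 + (Man)3(GlcNAc)2",
      "(HexNAc)4 (Fuc)2 (6NeuAc)1 + (Man)3(GlcNAc)2",
      "(Hex)1 (HexNAc)4 (6NeuAc)2 + (Man)3(GlcNAc)2"),
    conc_pmol_per_ul = c(8, 20, 30, 6, 10, 4, 1.5, 0.8,
                         0.6, 0.4, 0.5, 0.3),
    stringsAsFactors = FALSE)
}

#' Synthetic experiment design
#'
#' Describes a calibration-plate experiment: a glycan panel with per-uL
#' concentrations, the spotted serum volumes and replicates (defaults mirror
#' a routine calibration layout: four replicate spots at each of 2, 4, 6, 8
#' and 10 uL), the internal standard, and the noise model (Gaussian m/z
#' jitter, multiplicative Gaussian area noise, uniform contaminant peaks
#' kept away from true masses).
#'
#' @param panel data.frame (\code{composition_text},
#'   \code{conc_pmol_per_ul}); see [default_panel()].
#' @param volumes serum volumes in uL.
#' @param replicates replicate spots per volume.
#' @param groups optional data.frame (\code{series}, \code{label},
#'   \code{replicates}, \code{scale}) for category-mode designs; each group
#'   experiment carries \code{conc * scale} pmol of each panel glycan.
#'   When supplied, \code{volumes}/\code{replicates} are ignored.
#' @param is_pmol spiked internal-standard amount (pmol).
#' @param is_mz internal-standard m/z; defaults to the package's
#'   disialyloctasaccharide surrogate mass.
#' @param mz_sigma Gaussian m/z jitter sd (Da).
#' @param area_cv multiplicative area noise (fractional sd).
#' @param n_noise_peaks contaminant peaks per spot.
#' @param noise_mz_range m/z window for contaminant peaks.
#' @param noise_clearance minimum distance (Da) between a contaminant peak
#'   and any avoided mass.
#' @param area_scale arbitrary area units per pmol.
#' @param seed RNG seed; seeded designs generate bit-identical files.
#' @return A \code{synth_design} list.
#' @export
synth_design <- function(panel = default_panel(),
                         volumes = c(2, 4, 6, 8, 10), replicates = 4L,
                         groups = NULL,
                         is_pmol = 20, is_mz = NULL,
                         mz_sigma = 0.02, area_cv = 0.05,
                         n_noise_peaks = 5L,
                         noise_mz_range = c(1000, 3400),
                         noise_clearance = 0.5,
                         area_scale = 1000, seed = 1L) {
  stopifnot(all(panel$conc_pmol_per_ul > 0), mz_sigma >= 0, area_cv >= 0,
            is_pmol > 0, area_scale > 0)
  if (is.null(is_mz)) is_mz <- default_is_mz()
  structure(list(panel = panel, volumes = volumes,
                 replicates = as.integer(replicates), groups = groups,
                 is_pmol = is_pmol, is_mz = is_mz, mz_sigma = mz_sigma,
                 area_cv = area_cv, n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range,
                 noise_clearance = noise_clearance,
                 area_scale = area_scale, seed = as.integer(seed)),
            class = "synth_design")
}

design_experiments <- function(design) {
  if (!is.null(design$groups)) {
    g <- design$groups
    do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      data.frame(experiment = sprintf("%s_%d", g$label[i],
                                      seq_len(g$replicates[i])),
                 code = sprintf("%d#%s", g$series[i], g$label[i]),
                 dose = g$scale[i], stringsAsFactors = FALSE)))
  } else {
    grid <- expand.grid(rep = seq_len(design$replicates),
                        vol = design$volumes, KEEP.OUT.ATTRS = FALSE)
    data.frame(experiment = sprintf("cal_%gul_%d", grid$vol, grid$rep),
               code = sprintf("%g_%d", grid$vol, grid$rep),
               dose = grid$vol, stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic masslist workbook and truth table
#'
#' Writes a multi-tab XLSX masslist (one tab per spot, columns m/z and
#' area) plus a truth CSV listing the spiked pmol of every panel glycan in
#' every tab. Each panel glycan contributes one peak at its theoretical m/z
#' plus Gaussian jitter, with area proportional to spiked amount times
#' multiplicative noise; the internal-standard peak is added the same way;
#' contaminant peaks are drawn uniformly, rejected within
#' \code{noise_clearance} of any mass in \code{avoid_mz}.
#'
#' @param design a [synth_design()].
#' @param path output XLSX path.
#' @param truth_path output truth CSV path (default: alongside \code{path}).
#' @param registry,label mass model for theoretical masses.
#' @param avoid_mz masses contaminant peaks must stay clear of; defaults to
#'   the panel and internal-standard masses. Pass a glycan list's
#'   \code{theoretical_mz} to guarantee contaminants match nothing.
#' @return Invisibly, the truth data.frame (\code{experiment},
#'   \code{composition_id}, \code{pmol}).
#' @export
generate_masslist <- function(design, path, truth_path = NULL,
                              registry = default_registry(),
                              label = label_scheme_boa_na(),
                              avoid_mz = NULL) {
  stopifnot(inherits(design, "synth_design"))
  comps <- lapply(design$panel$composition_text, parse_composition,
                  registry = registry)
  theo <- vapply(comps, composition_mass, numeric(1), registry = registry,
                 label = label)
  ids <- vapply(comps, composition_id, character(1))
  if (is.null(avoid_mz)) avoid_mz <- c(theo, design$is_mz)
  lo <- design$noise_mz_range[1]; hi <- design$noise_mz_range[2]
  if (all(vapply(seq(lo, hi, length.out = 1000L), function(x)
    any(abs(avoid_mz - x) < design$noise_clearance), logical(1))))
    stop("noise m/z range is entirely within the clearance of avoided masses")
  exps <- design_experiments(design)
  if (nrow(exps) > 384L) stop("design exceeds 384 spots")

  set.seed(design$seed)
  sheets <- vector("list", nrow(exps))
  names(sheets) <- exps$experiment
  truth <- vector("list", nrow(exps))
  for (i in seq_len(nrow(exps))) {
    pmol <- design$panel$conc_pmol_per_ul * exps$dose[i]
    mz <- theo + if (design$mz_sigma > 0)
      stats::rnorm(length(theo), 0, design$mz_sigma) else 0
    area <- design$area_scale * pmol *
      pmax(1 + stats::rnorm(length(pmol), 0, design$area_cv), 1e-6)
    is_area <- design$area_scale * design$is_pmol *
      pmax(1 + stats::rnorm(1L, 0, design$area_cv), 1e-6)
    noise_mz <- numeric(0)
    if (design$n_noise_peaks > 0L) {
      tries <- 0L
      while (length(noise_mz) < design$n_noise_peaks && tries < 10000L) {
        x <- stats::runif(1L, lo, hi)
        tries <- tries + 1L
        if (all(abs(avoid_mz - x) >= design$noise_clearance))
          noise_mz <- c(noise_mz, x)
      }
      if (length(noise_mz) < design$n_noise_peaks)
        stop("could not place contaminant peaks clear of avoided masses")
    }
    noise_area <- if (length(noise_mz) > 0L)
      design$area_scale * stats::runif(length(noise_mz), 0.1, 5) else numeric(0)
    df <- data.frame(mz = c(mz, design$is_mz +
                              if (design$mz_sigma > 0)
                                stats::rnorm(1L, 0, design$mz_sigma) else 0,
                            noise_mz),
                     area = c(area, is_area, noise_area))
    df <- df[order(df$mz), ]
    sheets[[i]] <- data.frame(`m/z` = df$mz, area = df$area,
                              check.names = FALSE)
    truth[[i]] <- data.frame(experiment = exps$experiment[i],
                             composition_id = ids, pmol = pmol,
                             stringsAsFactors = FALSE)
  }
  write_xlsx_sheets(sheets, path, headers = TRUE)
  truth <- do.call(rbind, truth)
  if (is.null(truth_path))
    truth_path <- file.path(dirname(path), "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(truth)
}

#' Generate the matching plate layout workbook
#'
#' Writes a plate XLSX whose first row carries the common parameters
#' (\code{is_pmol}, \code{tolerance_da}) and whose grid codes the design's
#' spots row-major from A1, using the calibration (\code{volume_replicate})
#' or category (\code{series#label}) cell grammar.
#'
#' @param design a [synth_design()].
#' @param path output XLSX path.
#' @param tolerance_da tolerance to record in the common row.
#' @return Invisibly, \code{path}.
#' @export
generate_plate <- function(design, path, tolerance_da = DEFAULT_TOLERANCE) {
  stopifnot(inherits(design, "synth_design"))
  exps <- design_experiments(design)
  if (nrow(exps) > 384L) stop("design exceeds 384 spots")
  grid <- matrix(NA_character_, nrow = 17L, ncol = PLATE_COLS)
  grid[1L, 1:4] <- c("is_pmol", format(design$is_pmol, digits = 15),
                     "tolerance_da", format(tolerance_da, digits = 15))
  for (i in seq_len(nrow(exps))) {
    r <- (i - 1L) %/% PLATE_COLS + 2L
    cc <- (i - 1L) %% PLATE_COLS + 1L
    grid[r, cc] <- exps$code[i]
  }
  df <- as.data.frame(grid, stringsAsFactors = FALSE)
  write_xlsx_sheets(list(plate = df), path, headers = FALSE)
  invisible(path)
}
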