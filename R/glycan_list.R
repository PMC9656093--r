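# Candidate N-glycan enumeration, SALSA linkage expansion, list CSV IO.

#' Default glycan class rules
#'
#' The enumeration covers serum N-glycans up to tetra-antennary structures:
#'
#' \itemize{
#'   \item \strong{HM} (oligomannose): 2-6 non-core Hex on the M3 core,
#'     nothing else.
#'   \item \strong{hybrid / mr_hybrid}: M5-derived glycans with 2-6 non-core
#'     Hex ("mannose-rich" when > 3), 1-3 non-core HexNAc (the antenna
#'     GlcNAc, optionally a bisecting GlcNAc and/or a LacDiNAc GalNAc),
#'     0-3 Fuc, and acidic caps bounded by the HexNAc count.
#'   \item \strong{1_ant .. 4_ant} (complex): antennae a in 1..4, non-core
#'     HexNAc a or a+1 (the +1 admits one LacDiNAc branch, letting HexNAc
#'     exceed Hex), non-core Hex (galactoses) up to a, 0-3 Fuc, acidic caps
#'     bounded by the HexNAc count.
#' }
#'
#' Acidic residues follow the competition rule NeuAc + NeuGc + GlcA <= 4 with
#' GlcA <= 1. Generic NeuAc/NeuGc counts are expanded into all SALSA
#' linkage-resolved (alpha-2,3/2,8 vs alpha-2,6) splits at generation time.
#'
#' @return A data.frame of per-class count bounds consumed by
#'   [enumerate_compositions()].
#' @export
default_class_rules <- function() {
  rules <- rbind(
    data.frame(class = "HM", hex_min = 2L, hex_max = 6L,
               hexnac_min = 0L, hexnac_max = 0L, fuc_max = 0L,
               acid_max = 0L, stringsAsFactors = FALSE),
    data.frame(class = "hybrid", hex_min = 2L, hex_max = 6L,
               hexnac_min = 1L, hexnac_max = 3L, fuc_max = 3L,
               acid_max = 4L, stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:4, function(a) {
      data.frame(class = paste0(a, "_ant"), hex_min = 0L, hex_max = a,
                 hexnac_min = a, hexnac_max = min(a + 1L, 5L), fuc_max = 3L,
                 acid_max = 4L, stringsAsFactors = FALSE)
    }))
  )
  rules
}

# Ordered (3-8, 6) splits of generic NeuAc count a and NeuGc count g:
# exactly (a+1)(g+1) rows.
salsa_splits <- function(a, g) {
  stopifnot(a >= 0L, g >= 0L)
  grid <- expand.grid(ac38 = 0L:a, gc38 = 0L:g, KEEP.OUT.ATTRS = FALSE)
  data.frame(ac38 = grid$ac38, ac6 = a - grid$ac38,
             gc38 = grid$gc38, gc6 = g - grid$gc38)
}

#' Expand generic sialic acid counts into SALSA linkage variants
#'
#' SALSA derivatization converts sialic acid linkage isomerism into a mass
#' difference (alpha-2,6 isopropylamide vs alpha-2,3/2,8 methylamide,
#' 28.0313 Da apart), so a composition with a generic NeuAc count \code{a}
#' and NeuGc count \code{g} corresponds to (a+1)(g+1) distinguishable
#' linkage-resolved compositions.
#'
#' @param comp a [composition()] whose linkage-resolved sialic acid slots are
#'   all zero (the base composition).
#' @param n_neuac,n_neugc generic (linkage-unresolved) sialic acid counts.
#' @param registry residue registry.
#' @return A list of \code{(a+1)(g+1)} compositions; the 3-8 and 6 counts of
#'   each variant sum to \code{n_neuac} (resp. \code{n_neugc}).
#' @export
salsa_expand <- function(comp, n_neuac, n_neugc,
                         registry = default_registry()) {
  stopifnot(inherits(comp, "glycan_composition"))
  slot <- function(nm) match(nm, registry$name)
  s <- vapply(c("3-8NeuAc", "6NeuAc", "3-8NeuGc", "6NeuGc"), slot, 1L)
  if (anyNA(s)) stop("registry lacks SALSA sialic acid residues")
  if (any(comp$counts[s] > 0L))
    stop("base composition already carries linkage-resolved sialic acids")
  sp <- salsa_splits(as.integer(n_neuac), as.integer(n_neugc))
  lapply(seq_len(nrow(sp)), function(i) {
    cnt <- comp$counts
    cnt[s] <- c(sp$ac38[i], sp$ac6[i], sp$gc38[i], sp$gc6[i])
    comp_from_slots(cnt, comp$has_core)
  })
}

#' Enumerate candidate glycan compositions
#'
#' Enumerates all compositions admitted by the class rules (see
#' [default_class_rules()]) under the registry count ranges, expands generic
#' sialic acid counts into SALSA linkage-resolved variants, deduplicates by
#' composition ID (a composition reachable from several classes is listed
#' once, under the first class in rule order), and sorts by theoretical mass.
#'
#' @param rules class rule table; see [default_class_rules()].
#' @param registry residue registry.
#' @param label label scheme used for theoretical masses.
#' @return A \code{glycan_list}: data.frame with columns \code{class},
#'   \code{composition_id}, \code{composition_text}, \code{theoretical_mz}.
#' @examples
#' gl <- enumerate_compositions()
#' head(gl)
#' @export
enumerate_compositions <- function(rules = default_class_rules(),
                                   registry = default_registry(),
                                   label = label_scheme_boa_na()) {
  slot <- function(nm) match(nm, registry$name)
  s_hex <- slot("Hex"); s_hexnac <- slot("HexNAc"); s_fuc <- slot("Fuc")
  s_glca <- slot("GlcA")
  s_sial <- vapply(c("3-8NeuAc", "6NeuAc", "3-8NeuGc", "6NeuGc"), slot, 1L)
  lim <- function(s) if (is.na(s)) 0L else registry$max[s]
  if (any(rules$hex_min > rules$hex_max | rules$hexnac_min > rules$hexnac_max))
    stop("contradictory count ranges in class rules")

  out <- list(); k <- 0L
  for (r in seq_len(nrow(rules))) {
    rl <- rules[r, ]
    for (hex in rl$hex_min:min(rl$hex_max, lim(s_hex)))
      for (hexnac in rl$hexnac_min:min(rl$hexnac_max, lim(s_hexnac)))
        for (fuc in 0L:min(rl$fuc_max, lim(s_fuc))) {
          acid_cap <- min(rl$acid_max, hexnac, 4L)
          for (glca in 0L:min(acid_cap, lim(s_glca)))
            for (nac in 0L:(acid_cap - glca)) {
              ngc_max <- acid_cap - glca - nac
              for (ngc in 0L:ngc_max) {
                base <- integer(15L)
                base[s_hex] <- hex; base[s_hexnac] <- hexnac
                base[s_fuc] <- fuc
                if (!is.na(s_glca)) base[s_glca] <- glca
                sp <- salsa_splits(nac, ngc)
                for (i in seq_len(nrow(sp))) {
                  cnt <- base
                  cnt[s_sial] <- c(sp$ac38[i], sp$ac6[i], sp$gc38[i], sp$gc6[i])
                  k <- k + 1L
                  out[[k]] <- list(class = rl$class, counts = cnt)
                }
              }
            }
        }
  }
  comps <- lapply(out, function(e) comp_from_slots(e$counts, TRUE))
  ids <- vapply(comps, composition_id, character(1))
  keep <- !duplicated(ids)
  comps <- comps[keep]; ids <- ids[keep]
  cls <- vapply(out, function(e) e$class, character(1))[keep]
  mz <- vapply(comps, composition_mass, numeric(1),
               registry = registry, label = label)
  txt <- vapply(comps, format_composition, character(1), registry = registry)
  ord <- order(mz, ids)
  gl <- data.frame(class = cls[ord], composition_id = ids[ord],
                   composition_text = txt[ord], theoretical_mz = mz[ord],
                   stringsAsFactors = FALSE)
  rownames(gl) <- NULL
  class(gl) <- c("glycan_list", "data.frame")
  attr(gl, "label_scheme") <- label$name
  gl
}

#' Filter a glycan list
#'
#' Subsets a glycan list preserving order. \code{exclude_neugc} drops every
#' entry carrying NeuGc (of either linkage), the standard restriction for
#' human serum where NeuGc is absent.
#'
#' @param glist a glycan list (from [enumerate_compositions()] or
#'   [read_glycan_list()]).
#' @param exclude_neugc drop NeuGc-bearing entries.
#' @param mass_range optional \code{c(lo, hi)} window on theoretical m/z.
#' @param classes optional character vector of classes to keep.
#' @return The filtered glycan list.
#' @export
filter_glycan_list <- function(glist, exclude_neugc = FALSE,
                               mass_range = NULL, classes = NULL) {
  keep <- rep(TRUE, nrow(glist))
  if (isTRUE(exclude_neugc)) {
    # NeuGc slots are registry slots 8 and 9 -> digits 8 and 9 of the ID
    ngc <- as.integer(substr(glist$composition_id, 8L, 8L)) +
      as.integer(substr(glist$composition_id, 9L, 9L))
    keep <- keep & ngc == 0L
  }
  if (!is.null(mass_range))
    keep <- keep & glist$theoretical_mz >= mass_range[1] &
      glist$theoretical_mz <= mass_range[2]
  if (!is.null(classes)) keep <- keep & glist$class %in% classes
  out <- glist[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Glycan list CSV input and output
#'
#' The glycan list is a plain UTF-8 CSV with header
#' \code{class,composition_id,composition_text,theoretical_mz} so users can
#' inspect and hand-edit it (added rows annotate exactly like generated
#' ones). Masses are written at full precision; reading validates each row
#' and enforces unique composition IDs.
#'
#' @param glist a glycan list.
#' @param path file path.
#' @return \code{read_glycan_list}: the glycan list data.frame.
#' @export
write_glycan_list <- function(glist, path) {
  df <- as.data.frame(glist)
  df$theoretical_mz <- sprintf("%.6f", df$theoretical_mz)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_glycan_list
#' @export
read_glycan_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "character", "character"))
  need <- c("class", "composition_id", "composition_text", "theoretical_mz")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("glycan list is missing columns: ", paste(miss, collapse = ", "))
  mz <- suppressWarnings(as.numeric(df$theoretical_mz))
  bad <- which(is.na(mz) | !grepl("^[0-9]{15}C?$", df$composition_id))
  if (length(bad) > 0L)
    stop("malformed glycan list row at line ", bad[1] + 1L)
  dup <- which(duplicated(df$composition_id))
  if (length(dup) > 0L)
    stop("duplicate composition_id '", df$composition_id[dup[1]],
         "' at line ", dup[1] + 1L)
  df$theoretical_mz <- mz
  class(df) <- c("glycan_list", "data.frame")
  df
}
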