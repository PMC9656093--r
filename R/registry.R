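# Residue registry and label schemes: all mass arithmetic starts here.

#' Default residue registry
#'
#' Returns the 15-slot residue registry used throughout the package. Slots
#' hold the monosaccharide and modification residues of derivatized N-glycans:
#' Hex, HexNAc, Fuc, the four SALSA linkage-resolved sialic acids
#' (3-8NeuAc/6NeuAc and 3-8NeuGc/6NeuGc, whose masses differ by 28.0313 Da
#' because alpha-2,6-linked sialic acids become isopropylamides while
#' alpha-2,3/2,8-linked ones become methylamides), and glucuronic acid (GlcA).
#' The remaining slots are placeholders (max count 0) reserved for further
#' modifications such as acetylation, sulfation or phosphorylation; they keep
#' the 15-digit composition ID width stable.
#'
#' @return A data.frame with one row per slot and columns \code{id},
#'   \code{name}, \code{mass} (monoisotopic residue mass, Da), \code{min},
#'   \code{max} (allowed count range, excluding the M3 core), \code{category}
#'   and \code{description}.
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- data.frame(
    id = 1:15,
    name = c("Hex", "HexNAc", "Fuc", "slot4", "slot5",
             "3-8NeuAc", "6NeuAc", "3-8NeuGc", "6NeuGc",
             "slot10", "slot11", "slot12", "slot13", "GlcA", "slot15"),
    mass = c(162.0528, 203.0793, 146.0579, NA, NA,
             304.1270, 332.1583, 320.1219, 348.1532,
             NA, NA, NA, NA, 217.0950, NA),
    min = 0L,
    max = c(6L, 5L, 3L, 0L, 0L, 4L, 4L, 4L, 4L, 0L, 0L, 0L, 0L, 1L, 0L),
    category = c("neutral", "neutral", "deoxyhexose", "modification",
                 "modification", "acidic", "acidic", "acidic", "acidic",
                 "modification", "modification", "modification",
                 "modification", "acidic", "modification"),
    description = c(
      "Hexose", "N-acetylhexosamine", "Fucose (dHex)",
      "unused placeholder", "unused placeholder",
      "NeuAc, alpha-2,3/2,8 linkage (SALSA methylamide)",
      "NeuAc, alpha-2,6 linkage (SALSA isopropylamide)",
      "NeuGc, alpha-2,3/2,8 linkage (SALSA methylamide)",
      "NeuGc, alpha-2,6 linkage (SALSA isopropylamide)",
      "unused placeholder", "unused placeholder", "unused placeholder",
      "unused placeholder", "Glucuronic acid (SALSA isopropylamide)",
      "unused placeholder"),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

#' Read or write a residue registry CSV
#'
#' The registry is configurable from a plain CSV with columns
#' \code{id,name,mass,min,max,category,description} so that other glycan
#' classes (O-glycans, glycosphingolipid glycans) or extra modifications can
#' be analyzed without code change.
#'
#' @param path file path.
#' @param registry a registry data.frame (for writing).
#' @return \code{read_registry}: a validated registry data.frame.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "mass", "min", "max", "category", "description")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0L)
    stop("registry file is missing columns: ", paste(miss, collapse = ", "))
  reg$id <- as.integer(reg$id)
  reg$min <- as.integer(reg$min)
  reg$max <- as.integer(reg$max)
  validate_registry(reg[need])
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_registry <- function(reg) {
  if (nrow(reg) != 15L) stop("registry must have exactly 15 slots, got ", nrow(reg))
  if (!identical(reg$id, 1:15)) stop("registry slot ids must be 1..15 in order")
  if (anyDuplicated(reg$name)) stop("registry residue names must be unique")
  active <- reg$max > 0L
  if (any(active & (is.na(reg$mass) | reg$mass <= 0)))
    stop("active residues (max > 0) must have positive mass")
  if (any(reg$min > reg$max)) stop("registry has min > max for some slot")
  if (any(reg$min < 0L)) stop("registry counts must be non-negative")
  reg
}

# Monoisotopic mass constants (Da).
MASS_WATER <- 18.010565
MASS_NA <- 22.989770
# O-benzylhydroxylamine oxime label: net increment C7H9NO - H2O.
MASS_BOA_DELTA <- 105.057849

#' Label schemes
#'
#' A label scheme fixes the constant mass term added to the residue-mass sum
#' of every composition: the reducing-end water of the free glycan, the net
#' mass increment of the reducing-end derivatization, and the adduct ion.
#' The default models O-benzylhydroxylamine (BOA) oxime labeling with sodium
#' adducts, the conditions of routine serum N-glycomics; the total constant
#' is K = 18.010565 + 105.057849 + 22.989770 = 146.058184 Da.
#'
#' @param name scheme name.
#' @param label_delta Da added by the reducing-end label, net of the
#'   condensation water.
#' @param adduct_mass adduct mass in Da (sodium by default).
#' @param include_water whether to add the free-glycan water term.
#' @return A \code{label_scheme} object (a list with the fields above).
#' @examples
#' label_constant(label_scheme_boa_na())  # 146.058184
#' @export
label_scheme <- function(name, label_delta, adduct_mass,
                         include_water = TRUE) {
  s <- list(name = as.character(name), label_delta = as.numeric(label_delta),
            adduct_mass = as.numeric(adduct_mass),
            include_water = isTRUE(include_water))
  if (!is.finite(s$label_delta) || !is.finite(s$adduct_mass))
    stop("label scheme masses must be finite")
  structure(s, class = "label_scheme")
}

#' @rdname label_scheme
#' @export
label_scheme_boa_na <- function() {
  label_scheme("BOA-Na", MASS_BOA_DELTA, MASS_NA, include_water = TRUE)
}

#' @rdname label_scheme
#' @param scheme a \code{label_scheme}.
#' @export
label_constant <- function(scheme) {
  (if (scheme$include_water) MASS_WATER else 0) +
    scheme$label_delta + scheme$adduct_mass
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("Label scheme '%s': label %+0.6f Da, adduct %+0.6f Da, water %s (K = %0.6f Da)\n",
              x$name, x$label_delta, x$adduct_mass,
              if (x$include_water) "included" else "excluded",
              label_constant(x)))
  invisible(x)
}
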