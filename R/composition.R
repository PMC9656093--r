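# Glycan compositions: construction, mass, canonical text and 15-digit IDs.

# The M3 core (Man)3(GlcNAc)2 contributes 3 Hex + 2 HexNAc residue masses.
CORE_HEX <- 3L
CORE_HEXNAC <- 2L

#' Glycan compositions
#'
#' A composition is a multiset of residue counts over the 15 registry slots
#' plus a flag for the common N-glycan M3 core (Man)3(GlcNAc)2. Counts refer
#' to residues outside the core; the core contributes 3 Hex and 2 HexNAc
#' residue masses when present.
#'
#' @param counts named integer vector; names are residue names known to the
#'   registry (e.g. \code{c(Hex = 2, "6NeuAc" = 1)}). May be empty.
#' @param has_core logical; whether the M3 core is present.
#' @param registry a residue registry (see [default_registry()]).
#' @return A \code{glycan_composition}: list with \code{counts} (length-15
#'   integer vector in slot order) and \code{has_core}.
#' @examples
#' comp <- composition(c(Hex = 2), has_core = TRUE)
#' format_composition(comp)       # "(Hex)2 + (Man)3(GlcNAc)2"
#' composition_id(comp)           # "200000000000000C"
#' @export
composition <- function(counts = integer(0), has_core = TRUE,
                        registry = default_registry()) {
  full <- integer(15L)
  if (length(counts) > 0L) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("composition counts must be named by residue")
    idx <- match(names(counts), registry$name)
    if (anyNA(idx))
      stop("unknown residue(s): ",
           paste(names(counts)[is.na(idx)], collapse = ", "))
    if (any(counts < 0)) stop("composition counts must be non-negative")
    full[idx] <- as.integer(counts)
  }
  structure(list(counts = full, has_core = isTRUE(has_core)),
            class = "glycan_composition")
}

comp_from_slots <- function(slots, has_core) {
  structure(list(counts = as.integer(slots), has_core = isTRUE(has_core)),
            class = "glycan_composition")
}

#' Theoretical mass of a composition
#'
#' Sum of the residue masses, plus the core contribution when present, plus
#' the label-scheme constant (water + reducing-end label + adduct). This is
#' the theoretical singly charged adduct m/z of the derivatized glycan.
#'
#' @param comp a [composition()].
#' @param registry residue registry supplying residue masses.
#' @param label a [label_scheme()]; BOA oxime label with sodium adduct by
#'   default.
#' @return Mass in Da.
#' @examples
#' composition_mass(composition(c(Hex = 2)))  # 1362.4808, prints as 1362.5
#' @export
composition_mass <- function(comp, registry = default_registry(),
                             label = label_scheme_boa_na()) {
  stopifnot(inherits(comp, "glycan_composition"))
  cnt <- comp$counts
  used <- which(cnt > 0L)
  if (any(is.na(registry$mass[used])))
    stop("residue(s) without mass in registry: ",
         paste(registry$name[used][is.na(registry$mass[used])], collapse = ", "))
  m <- sum(cnt[used] * registry$mass[used])
  if (comp$has_core)
    m <- m + CORE_HEX * registry$mass[registry$name == "Hex"] +
      CORE_HEXNAC * registry$mass[registry$name == "HexNAc"]
  m + label_constant(label)
}

#' Canonical composition text
#'
#' Formats a composition as \code{"(Name)n ... + (Man)3(GlcNAc)2"} with
#' residues in registry slot order and zero counts omitted; the core suffix
#' is present iff the composition carries the M3 core.
#'
#' @inheritParams composition_mass
#' @return A single string.
#' @export
format_composition <- function(comp, registry = default_registry()) {
  stopifnot(inherits(comp, "glycan_composition"))
  used <- which(comp$counts > 0L)
  parts <- sprintf("(%s)%d", registry$name[used], comp$counts[used])
  body <- paste(parts, collapse = " ")
  if (comp$has_core) {
    if (nzchar(body)) paste(body, "+ (Man)3(GlcNAc)2") else "(Man)3(GlcNAc)2"
  } else {
    body
  }
}

#' Parse canonical composition text
#'
#' Inverse of [format_composition()]: accepts the canonical grammar
#' \code{"(Name)n ... + (Man)3(GlcNAc)2"} (or the bare core, or a core-free
#' residue list) and returns the composition. Round-trips with
#' [format_composition()].
#'
#' @param text composition string.
#' @inheritParams composition_mass
#' @return A [composition()].
#' @export
parse_composition <- function(text, registry = default_registry()) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  core_re <- "\\(Man\\)3\\s*\\(GlcNAc\\)2$"
  has_core <- grepl(core_re, s)
  if (has_core) {
    s <- sub(core_re, "", s)
    s <- sub("\\+\\s*$", "", trimws(s))
    s <- trimws(s)
  }
  counts <- integer(15L)
  pos <- 1L
  while (nzchar(s)) {
    m <- regexpr("^\\(([^)]+)\\)(\\d+)\\s*", s, perl = TRUE)
    if (m == -1L)
      stop(sprintf("cannot parse composition near position %d: '%s'", pos, s))
    tok <- regmatches(s, m)
    name <- sub("^\\(([^)]+)\\)(\\d+)\\s*$", "\\1", tok)
    n <- as.integer(sub("^\\(([^)]+)\\)(\\d+)\\s*$", "\\2", tok))
    slot <- match(name, registry$name)
    if (is.na(slot))
      stop(sprintf("unknown residue '%s' at position %d", name, pos))
    counts[slot] <- counts[slot] + n
    pos <- pos + attr(m, "match.length")
    s <- substring(s, attr(m, "match.length") + 1L)
  }
  comp_from_slots(counts, has_core)
}

#' 15-digit composition ID
#'
#' Encodes a composition as 15 digits in registry slot order (digit i is the
#' count of the residue in slot i), followed by \code{"C"} iff the M3 core is
#' present. Counts above 9 cannot be encoded and raise an error.
#'
#' @inheritParams composition_mass
#' @return A string of 15 digits, optionally suffixed \code{"C"}.
#' @export
composition_id <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (any(comp$counts > 9L))
    stop("composition count exceeds 9; cannot encode as single digit")
  paste0(paste(comp$counts, collapse = ""), if (comp$has_core) "C" else "")
}

#' Decode a 15-digit composition ID
#'
#' @param id a 15-digit string, optionally suffixed \code{"C"}.
#' @return A [composition()].
#' @export
parse_composition_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!grepl("^[0-9]{15}C?$", id)) stop("malformed composition id: ", id)
  digits <- as.integer(strsplit(substr(id, 1L, 15L), "")[[1L]])
  comp_from_slots(digits, grepl("C$", id))
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format_composition(x), sprintf("  [%s]\n", composition_id(x)))
  invisible(x)
}
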