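# Shared fixtures. The full enumerated list is built once per test run.

full_list_cache <- new.env(parent = emptyenv())

full_glycan_list <- function() {
  if (is.null(full_list_cache$gl))
    full_list_cache$gl <- enumerate_compositions()
  full_list_cache$gl
}

human_glycan_list <- function() {
  if (is.null(full_list_cache$gl_h))
    full_list_cache$gl_h <- filter_glycan_list(full_glycan_list(),
                                               exclude_neugc = TRUE)
  full_list_cache$gl_h
}

# Published serum N-glycan reference table: composition (without the core
# suffix) and the composition-browser query segment, transcribed from the
# instrument-vendor-independent report of glycans with linear calibration
# response. Used for list-membership and URL-grammar checks.
serum_reference_rows <- function() {
  raw <- c(
    "(Hex)2 | Hex:5HexNAc:2",
    "(Hex)1 (HexNAc)1 | Hex:4HexNAc:3",
    "(HexNAc)2 | Hex:3HexNAc:4",
    "(Hex)3 | Hex:6HexNAc:2",
    "(Hex)2 (HexNAc)1 | Hex:5HexNAc:3",
    "(HexNAc)2 (Fuc)1 | Hex:3HexNAc:4dHex:1",
    "(Hex)1 (HexNAc)2 | Hex:4HexNAc:4",
    "(HexNAc)3 | Hex:3HexNAc:5",
    "(Hex)4 | Hex:7HexNAc:2",
    "(Hex)1 (HexNAc)1 (3-8NeuAc)1 | Hex:4HexNAc:3NeuAc:1",
    "(Hex)3 (HexNAc)1 | Hex:6HexNAc:3",
    "(Hex)1 (HexNAc)1 (6NeuAc)1 | Hex:4HexNAc:3NeuAc:1",
    "(Hex)1 (HexNAc)2 (Fuc)1 | Hex:4HexNAc:4dHex:1",
    "(Hex)2 (HexNAc)2 | Hex:5HexNAc:4",
    "(HexNAc)3 (Fuc)1 | Hex:3HexNAc:5dHex:1",
    "(Hex)1 (HexNAc)3 | Hex:4HexNAc:5",
    "(Hex)5 | Hex:8HexNAc:2",
    "(Hex)2 (HexNAc)1 (3-8NeuAc)1 | Hex:5HexNAc:3NeuAc:1",
    "(Hex)2 (HexNAc)1 (6NeuAc)1 | Hex:5HexNAc:3NeuAc:1",
    "(Hex)2 (HexNAc)2 (Fuc)1 | Hex:5HexNAc:4dHex:1",
    "(Hex)1 (HexNAc)2 (6NeuAc)1 | Hex:4HexNAc:4NeuAc:1",
    "(Hex)1 (HexNAc)3 (Fuc)1 | Hex:4HexNAc:5dHex:1",
    "(Hex)2 (HexNAc)3 | Hex:5HexNAc:5",
    "(Hex)6 | Hex:9HexNAc:2",
    "(HexNAc)3 (Fuc)1 (GlcA)1 | Hex:3HexNAc:5dHex:1HexA:1",
    "(Hex)3 (HexNAc)1 (3-8NeuAc)1 | Hex:6HexNAc:3NeuAc:1",
    "(Hex)3 (HexNAc)1 (6NeuAc)1 | Hex:6HexNAc:3NeuAc:1",
    "(Hex)2 (HexNAc)2 (3-8NeuAc)1 | Hex:5HexNAc:4NeuAc:1",
    "(Hex)1 (HexNAc)2 (Fuc)1 (6NeuAc)1 | Hex:4HexNAc:4dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)2 (6NeuAc)1 | Hex:5HexNAc:4NeuAc:1",
    "(Hex)1 (HexNAc)3 (6NeuAc)1 | Hex:4HexNAc:5NeuAc:1",
    "(Hex)2 (HexNAc)2 (Fuc)1 (3-8NeuAc)1 | Hex:5HexNAc:4dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)2 (Fuc)1 (6NeuAc)1 | Hex:5HexNAc:4dHex:1NeuAc:1",
    "(Hex)1 (HexNAc)3 (Fuc)3 | Hex:4HexNAc:5dHex:3",
    "(Hex)1 (HexNAc)3 (Fuc)1 (6NeuAc)1 | Hex:4HexNAc:5dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)3 (6NeuAc)1 | Hex:5HexNAc:5NeuAc:1",
    "(Hex)2 (HexNAc)2 (6NeuAc)1 (GlcA)1 | Hex:5HexNAc:4NeuAc:1HexA:1",
    "(Hex)4 (HexNAc)1 (Fuc)3 | Hex:7HexNAc:3dHex:3",
    "(Hex)4 (HexNAc)1 (Fuc)1 (3-8NeuAc)1 | Hex:7HexNAc:3dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)2 (3-8NeuAc)2 | Hex:5HexNAc:4NeuAc:2",
    "(Hex)5 (HexNAc)1 (6NeuAc)1 | Hex:8HexNAc:3NeuAc:1",
    "(Hex)2 (HexNAc)2 (3-8NeuAc)1 (6NeuAc)1 | Hex:5HexNAc:4NeuAc:2",
    "(Hex)5 (HexNAc)1 (Fuc)1 (GlcA)1 | Hex:8HexNAc:3dHex:1HexA:1",
    "(Hex)1 (HexNAc)5 (GlcA)1 | Hex:4HexNAc:7HexA:1",
    "(Hex)2 (HexNAc)2 (6NeuAc)2 | Hex:5HexNAc:4NeuAc:2",
    "(Hex)3 (HexNAc)2 (Fuc)2 (GlcA)1 | Hex:6HexNAc:4dHex:2HexA:1",
    "(Hex)3 (HexNAc)3 (6NeuAc)1 | Hex:6HexNAc:5NeuAc:1",
    "(HexNAc)4 (Fuc)2 (6NeuAc)1 | Hex:3HexNAc:6dHex:2NeuAc:1",
    "(Hex)1 (HexNAc)4 (Fuc)1 (6NeuAc)1 | Hex:4HexNAc:6dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)2 (Fuc)1 (3-8NeuAc)2 | Hex:5HexNAc:4dHex:1NeuAc:2",
    "(Hex)2 (HexNAc)2 (Fuc)1 (3-8NeuAc)1 (6NeuAc)1 | Hex:5HexNAc:4dHex:1NeuAc:2",
    "(Hex)3 (HexNAc)2 (3-8NeuAc)1 (6NeuAc)1 | Hex:6HexNAc:4NeuAc:2",
    "(Hex)1 (HexNAc)5 (Fuc)1 (GlcA)1 | Hex:4HexNAc:7dHex:1HexA:1",
    "(Hex)2 (HexNAc)2 (Fuc)1 (6NeuAc)2 | Hex:5HexNAc:4dHex:1NeuAc:2",
    "(Hex)3 (HexNAc)3 (Fuc)1 (6NeuAc)1 | Hex:6HexNAc:5dHex:1NeuAc:1",
    "(Hex)2 (HexNAc)3 (6NeuAc)2 | Hex:5HexNAc:5NeuAc:2",
    "(Hex)1 (HexNAc)4 (6NeuAc)2 | Hex:4HexNAc:6NeuAc:2",
    "(Hex)5 (HexNAc)2 (Fuc)3 | Hex:8HexNAc:4dHex:3",
    "(Hex)3 (HexNAc)3 (3-8NeuAc)2 | Hex:6HexNAc:5NeuAc:2",
    "(Hex)2 (HexNAc)3 (Fuc)3 (6NeuAc)1 | Hex:5HexNAc:5dHex:3NeuAc:1",
    "(Hex)2 (HexNAc)3 (Fuc)1 (3-8NeuAc)1 (6NeuAc)1 | Hex:5HexNAc:5dHex:1NeuAc:2",
    "(Hex)3 (HexNAc)3 (3-8NeuAc)1 (6NeuAc)1 | Hex:6HexNAc:5NeuAc:2",
    "(Hex)2 (HexNAc)3 (Fuc)1 (6NeuAc)2 | Hex:5HexNAc:5dHex:1NeuAc:2",
    "(Hex)3 (HexNAc)3 (6NeuAc)2 | Hex:6HexNAc:5NeuAc:2",
    "(Hex)4 (HexNAc)4 (6NeuAc)1 | Hex:7HexNAc:6NeuAc:1",
    "(Hex)3 (HexNAc)2 (Fuc)2 (3-8NeuAc)2 | Hex:6HexNAc:4dHex:2NeuAc:2",
    "(Hex)5 (HexNAc)3 (Fuc)3 | Hex:8HexNAc:5dHex:3",
    "(Hex)2 (HexNAc)5 (3-8NeuAc)1 (GlcA)1 | Hex:5HexNAc:7NeuAc:1HexA:1",
    "(Hex)3 (HexNAc)3 (Fuc)1 (3-8NeuAc)1 (6NeuAc)1 | Hex:6HexNAc:5dHex:1NeuAc:2",
    "(Hex)5 (HexNAc)2 (Fuc)3 (3-8NeuAc)1 | Hex:8HexNAc:4dHex:3NeuAc:1",
    "(Hex)2 (HexNAc)5 (Fuc)1 (3-8NeuAc)1 (GlcA)1 | Hex:5HexNAc:7dHex:1NeuAc:1HexA:1",
    "(Hex)3 (HexNAc)3 (3-8NeuAc)2 (6NeuAc)1 | Hex:6HexNAc:5NeuAc:3",
    "(Hex)2 (HexNAc)3 (Fuc)3 (6NeuAc)2 | Hex:5HexNAc:5dHex:3NeuAc:2",
    "(Hex)3 (HexNAc)3 (3-8NeuAc)1 (6NeuAc)2 | Hex:6HexNAc:5NeuAc:3",
    "(Hex)3 (HexNAc)3 (6NeuAc)3 | Hex:6HexNAc:5NeuAc:3",
    "(Hex)4 (HexNAc)4 (3-8NeuAc)1 (6NeuAc)1 | Hex:7HexNAc:6NeuAc:2",
    "(Hex)3 (HexNAc)3 (Fuc)1 (3-8NeuAc)3 | Hex:6HexNAc:5dHex:1NeuAc:3",
    "(Hex)3 (HexNAc)3 (Fuc)1 (3-8NeuAc)1 (6NeuAc)2 | Hex:6HexNAc:5dHex:1NeuAc:3")
  parts <- strsplit(raw, " | ", fixed = TRUE)
  data.frame(
    composition_text = paste(vapply(parts, `[`, "", 1L),
                             "+ (Man)3(GlcNAc)2"),
    url = paste0("https://glyconnect.expasy.org/browser/compositions?f=",
                 vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
}

# tiny three-entry list for fast IO/matching tests
tiny_glycan_list <- function() {
  texts <- c("(Hex)2 + (Man)3(GlcNAc)2",
             "(Hex)1 (HexNAc)1 (6NeuAc)1 + (Man)3(GlcNAc)2",
             "(Hex)5 (HexNAc)1 (6NeuAc)1 + (Man)3(GlcNAc)2")
  comps <- lapply(texts, parse_composition)
  gl <- data.frame(
    class = c("HM", "1_ant", "mr_hybrid"),
    composition_id = vapply(comps, composition_id, ""),
    composition_text = texts,
    theoretical_mz = vapply(comps, composition_mass, 0),
    stringsAsFactors = FALSE)
  class(gl) <- c("glycan_list", "data.frame")
  gl
}

# brute-force all-pairs matching oracle
oracle_match <- function(peaks, glist, tolerance) {
  hits <- list()
  for (i in seq_len(nrow(peaks)))
    for (j in seq_len(nrow(glist)))
      if (abs(peaks$mz[i] - glist$theoretical_mz[j]) <= tolerance)
        hits[[length(hits) + 1L]] <- c(peak = i, entry = j)
  if (length(hits) == 0L)
    return(data.frame(peak = integer(0), entry = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

# brute-force connected components of the |dm/z| <= tolerance graph
oracle_components <- function(mz, tolerance) {
  n <- length(mz)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (abs(mz[i] - mz[j]) <= tolerance && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    if (!changed) break
  }
  match(comp, unique(comp))
}
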