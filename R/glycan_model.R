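# Glycan composition model: parsing, monoisotopic masses, classification and
# derived structural features for N-glycans described at composition level.

.GLYCAN_LETTERS <- c("H", "N", "F", "S")

# Monoisotopic residue masses in Da, water already condensed out:
# Hex C6H10O5, HexNAc C8H13NO5, dHex (fucose) C6H10O4, NeuAc C11H17NO8.
.GLYCAN_RESIDUE_MASS <- c(
  H = 162.05282342,
  N = 203.07937252,
  F = 146.05790880,
  S = 291.09541651
)

.GLYCAN_CLASSES <- c("oligomannose", "hybrid", "complex", "paucimannose_other")

#' Parse N-glycan composition strings
#'
#' Compositions are written in the compact letter+count notation used to
#' annotate glycopeptides, e.g. `"N4H5S1F1"`: `H` hexose, `N`
#' N-acetylhexosamine, `F` deoxyhexose (fucose), `S` N-acetylneuraminic
#' (sialic) acid. Letters are case-insensitive and may appear in any order,
#' but each at most once; residues not mentioned default to zero. The empty
#' string denotes the empty composition.
#'
#' @param x character vector of composition strings.
#' @return A data frame of class `glycan_composition` with integer columns
#'   `H`, `N`, `F`, `S`, one row per input string.
#' @seealso [render_glycan()] for the canonical inverse.
#' @examples
#' parse_glycan(c("N4H5S1F1", "H5N2"))
#' @export
parse_glycan <- function(x) {
  if (!is.character(x)) {
    stop("`x` must be a character vector of glycan composition strings")
  }
  counts <- matrix(0L, nrow = length(x), ncol = 4L,
                   dimnames = list(NULL, .GLYCAN_LETTERS))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s)) {
      stop("glycan composition string is NA (element ", i, ")")
    }
    s0 <- gsub("[[:space:]]", "", s)
    if (!nzchar(s0)) next
    tokens <- regmatches(s0, gregexpr("[A-Za-z][0-9]*", s0))[[1]]
    if (paste(tokens, collapse = "") != s0) {
      bad <- sub("^([A-Za-z][0-9]*)*", "", s0)
      stop(sprintf("cannot parse glycan '%s': unexpected text '%s'", s, bad))
    }
    res <- toupper(substr(tokens, 1L, 1L))
    num <- substring(tokens, 2L)
    if (any(!nzchar(num))) {
      stop(sprintf("cannot parse glycan '%s': token '%s' is missing a count",
                   s, tokens[!nzchar(num)][1L]))
    }
    unknown <- !(res %in% .GLYCAN_LETTERS)
    if (any(unknown)) {
      stop(sprintf("cannot parse glycan '%s': unknown residue code in token '%s'",
                   s, tokens[unknown][1L]))
    }
    if (anyDuplicated(res)) {
      stop(sprintf("cannot parse glycan '%s': residue '%s' given more than once",
                   s, res[duplicated(res)][1L]))
    }
    counts[i, res] <- as.integer(num)
  }
  out <- as.data.frame(counts)
  class(out) <- c("glycan_composition", "data.frame")
  out
}

#' Coerce to a glycan composition table
#'
#' @param x character vector of composition strings, or a data frame with
#'   non-negative integer columns `H`, `N`, `F`, `S`.
#' @return a `glycan_composition` data frame.
#' @export
as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_glycan(x))
  if (is.data.frame(x) || is.list(x)) {
    comp <- as.data.frame(x)
    for (l in .GLYCAN_LETTERS) {
      if (is.null(comp[[l]])) comp[[l]] <- 0L
    }
    comp <- comp[, .GLYCAN_LETTERS, drop = FALSE]
    vals <- unlist(comp, use.names = FALSE)
    if (length(vals) && (any(is.na(vals)) || any(vals < 0) ||
                         any(vals != floor(vals)))) {
      stop("glycan residue counts must be non-negative integers")
    }
    for (l in .GLYCAN_LETTERS) comp[[l]] <- as.integer(comp[[l]])
    class(comp) <- c("glycan_composition", "data.frame")
    return(comp)
  }
  stop("cannot interpret `x` as glycan compositions")
}

#' Render glycan compositions in canonical notation
#'
#' The canonical order is N, H, F, S with zero-count residues omitted, so
#' `render_glycan(parse_glycan(x))` is a normal form: it round-trips through
#' the parser to an identical composition. The empty composition renders as
#' the empty string.
#'
#' @param comp compositions as accepted by [as_glycan_composition()].
#' @return character vector of canonical composition strings.
#' @export
render_glycan <- function(comp) {
  comp <- as_glycan_composition(comp)
  vapply(seq_len(nrow(comp)), function(i) {
    cnt <- c(N = comp$N[i], H = comp$H[i], F = comp$F[i], S = comp$S[i])
    cnt <- cnt[cnt > 0L]
    paste0(names(cnt), cnt, collapse = "")
  }, character(1))
}

#' Monoisotopic mass of a glycan
#'
#' Sum of residue monoisotopic masses (Hex, HexNAc, dHex, NeuAc residues,
#' i.e. with the condensation water already removed). Additive by
#' construction: `glycan_mass(a + b) == glycan_mass(a) + glycan_mass(b)`.
#'
#' @inheritParams render_glycan
#' @return numeric vector of masses in Da.
#' @export
glycan_mass <- function(comp) {
  comp <- as_glycan_composition(comp)
  as.numeric(as.matrix(comp[, .GLYCAN_LETTERS]) %*%
               .GLYCAN_RESIDUE_MASS[.GLYCAN_LETTERS])
}

#' Monoisotopic mass of a glycopeptide
#'
#' @param peptide_mass monoisotopic mass of the peptide backbone in Da
#'   (non-negative; the backbone mass already includes its terminal water).
#' @inheritParams render_glycan
#' @return numeric vector: backbone plus glycan residue masses.
#' @export
glycopeptide_mass <- function(peptide_mass, comp) {
  if (!is.numeric(peptide_mass) || any(is.na(peptide_mass))) {
    stop("`peptide_mass` must be numeric with no missing values")
  }
  if (any(peptide_mass < 0)) {
    stop("`peptide_mass` must be non-negative")
  }
  peptide_mass + glycan_mass(comp)
}

#' Classify N-glycan compositions
#'
#' Composition-only maturation classes:
#' * `oligomannose`: N = 2, H >= 5, no fucose or sialic acid;
#' * `hybrid`: N = 3 and H >= 5;
#' * `complex`: N >= 3 and not hybrid;
#' * `paucimannose_other`: everything else (truncated cores, "unmatured"
#'   structures, N = 2 compositions carrying F or S).
#'
#' Linkage isomers are not resolved; the rules are deterministic and total,
#' assigning exactly one class to every composition.
#'
#' @inheritParams render_glycan
#' @return character vector with values among
#'   `c("oligomannose", "hybrid", "complex", "paucimannose_other")`.
#' @export
classify_glycan <- function(comp) {
  comp <- as_glycan_composition(comp)
  H <- comp$H; N <- comp$N; F_ <- comp$F; S <- comp$S
  cls <- rep("paucimannose_other", nrow(comp))
  hybrid <- N == 3L & H >= 5L
  cls[N >= 3L & !hybrid] <- "complex"
  cls[hybrid] <- "hybrid"
  cls[N == 2L & H >= 5L & F_ == 0L & S == 0L] <- "oligomannose"
  cls
}

#' Derive structural features from glycan compositions
#'
#' Antenna count is N - 2 for complex glycans (biantennary = N4, triantennary
#' = N5, tetraantennary = N6), 1 for hybrid, 0 otherwise. Sialylated antennae
#' are capped at the antenna count. Terminal galactoses for complex glycans
#' are estimated as hexoses beyond the 3 core mannoses, clamped to
#' `[0, antennae]`; non-complex glycans get 0.
#'
#' @inheritParams render_glycan
#' @return data frame with one row per composition and columns
#'   `glycan_class`, `antennae`, `sialic_antennae`, `galactoses`,
#'   `is_fucosylated`, `is_sialylated`, `has_antennae`.
#' @export
glycan_features <- function(comp) {
  comp <- as_glycan_composition(comp)
  cls <- classify_glycan(comp)
  ant <- ifelse(cls == "complex", comp$N - 2L, ifelse(cls == "hybrid", 1L, 0L))
  gal <- ifelse(cls == "complex", pmin(pmax(comp$H - 3L, 0L), ant), 0L)
  data.frame(
    glycan_class = cls,
    antennae = as.integer(ant),
    sialic_antennae = as.integer(pmin(comp$S, ant)),
    galactoses = as.integer(gal),
    is_fucosylated = comp$F >= 1L,
    is_sialylated = comp$S >= 1L,
    has_antennae = ant >= 1L
  )
}
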