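# Exact monoisotopic mass arithmetic: formulas, adducts, ppm errors.
#
# All masses are monoisotopic (most abundant isotope of each element), in Da.
# Ion m/z accounts for the electron mass per unit charge: printed FTICR
# reference values are proton-accurate, not hydrogen-atom-accurate, and the
# ~0.55 mDa difference is far larger than the instrument's sub-ppm accuracy.

#' Monoisotopic element mass table
#'
#' Returns the packaged table of monoisotopic atomic masses (CODATA/AME
#' values, >= 7 decimal places) as a named numeric vector. The electron mass
#' is included as the distinct entry `"e"`. The table is read once and
#' cached; the returned vector is a copy, so the cached table is immutable.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' element_masses()[c("C", "H", "e")]
element_masses <- function() {
  if (is.null(.msimetab$elements)) {
    tab <- read.delim(.extdata("element_masses.tsv"), stringsAsFactors = FALSE)
    m <- setNames(as.numeric(tab$mass), tab$symbol)
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("element mass table corrupt: non-positive or non-numeric mass")
    }
    .msimetab$elements <- m
  }
  .msimetab$elements
}

electron_mass <- function() unname(element_masses()[["e"]])
proton_mass <- function() {
  m <- element_masses()
  unname(m[["H"]] - m[["e"]])
}

#' Parse a molecular formula
#'
#' Parses a flat Hill-style formula string (element symbols each optionally
#' followed by a positive integer count; no parentheses, charges or isotope
#' labels) into a `mol_formula` object.
#'
#' @param text Formula string, e.g. `"C10H16N5O13P3"`.
#' @return A `mol_formula`: a named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C3H9N")      # trimethylamine
#' parse_formula("C5H14NO4P")  # phosphocholine
parse_formula <- function(text) {
  if (inherits(text, "mol_formula")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula error: empty or non-character formula string")
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("formula error: cannot parse '", text,
         "' as a flat Hill-notation formula")
  }
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  el <- sub("[0-9]*$", "", tokens)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  n[is.na(n)] <- 1L
  if (any(n < 1L)) stop("formula error: zero count in '", text, "'")
  known <- names(element_masses())
  bad <- setdiff(unique(el), known)
  if (length(bad)) {
    stop("formula error: unknown element symbol '", bad[[1]], "' in '", text, "'")
  }
  counts <- vapply(split(n, el), sum, integer(1))
  # Hill order: C, H first, then alphabetical
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  structure(counts[ord], class = "mol_formula")
}

empty_formula <- function() structure(integer(0), class = "mol_formula")

#' @export
format.mol_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`==.mol_formula` <- function(e1, e2) {
  a <- parse_formula(e1); b <- parse_formula(e2)
  identical(unclass(a)[order(names(a))], unclass(b)[order(names(b))])
}

#' Formula addition and subtraction
#'
#' Element-wise count arithmetic. Subtraction fails if any count would go
#' negative.
#'
#' @param e1,e2 `mol_formula` objects (or formula strings).
#' @return A `mol_formula`.
#' @name formula-arith
#' @export
`+.mol_formula` <- function(e1, e2) {
  a <- parse_formula(e1); b <- parse_formula(e2)
  el <- union(names(a), names(b))
  counts <- setNames(integer(length(el)), el)
  counts[names(a)] <- counts[names(a)] + unclass(a)
  counts[names(b)] <- counts[names(b)] + unclass(b)
  parse_formula(paste0(names(counts[counts > 0]), counts[counts > 0], collapse = ""))
}

#' @rdname formula-arith
#' @export
`-.mol_formula` <- function(e1, e2) {
  a <- parse_formula(e1); b <- parse_formula(e2)
  el <- union(names(a), names(b))
  counts <- setNames(integer(length(el)), el)
  counts[names(a)] <- counts[names(a)] + unclass(a)
  counts[names(b)] <- counts[names(b)] - unclass(b)
  if (any(counts < 0L)) {
    stop("formula error: subtraction would give negative count for ",
         paste(names(counts)[counts < 0L], collapse = ", "))
  }
  keep <- counts > 0L
  if (!any(keep)) return(empty_formula())
  parse_formula(paste0(names(counts[keep]), counts[keep], collapse = ""))
}

#' Monoisotopic mass of a formula
#'
#' @param formula A `mol_formula` or formula string. The empty formula has
#'   mass 0.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C3H9N")     # 59.073499
#' monoisotopic_mass("C5H14NO4P") # 183.066045
monoisotopic_mass <- function(formula) {
  f <- if (inherits(formula, "mol_formula")) formula else parse_formula(formula)
  if (!length(f)) return(0)
  m <- element_masses()
  missing <- setdiff(names(f), names(m))
  if (length(missing)) {
    stop("configuration error: element(s) missing from mass table: ",
         paste(missing, collapse = ", "))
  }
  sum(m[names(f)] * unclass(f))
}

#' Parse an adduct name
#'
#' Parses ion-type names such as `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"` and
#' `"[M-H]-"` into an `adduct_spec` holding the added formula, removed
#' formula and signed charge. Names round-trip through [format()].
#'
#' @param name Adduct name string.
#' @return An `adduct_spec` list with fields `name`, `added`, `removed`,
#'   `charge`.
#' @export
parse_adduct <- function(name) {
  if (inherits(name, "adduct_spec")) return(name)
  m <- regexec("^\\[M((?:[+-][A-Za-z][A-Za-z0-9]*)*)\\]([0-9]*)([+-])$", name)
  g <- regmatches(name, m)[[1]]
  if (!length(g)) stop("adduct error: cannot parse adduct name '", name, "'")
  nz <- if (nzchar(g[[3]])) as.integer(g[[3]]) else 1L
  charge <- nz * if (g[[4]] == "+") 1L else -1L
  added <- empty_formula(); removed <- empty_formula()
  if (nzchar(g[[2]])) {
    terms <- regmatches(g[[2]], gregexpr("[+-][A-Za-z][A-Za-z0-9]*", g[[2]]))[[1]]
    for (t in terms) {
      f <- parse_formula(substring(t, 2))
      if (substring(t, 1, 1) == "+") added <- added + f else removed <- removed + f
    }
  }
  structure(list(name = name, added = added, removed = removed, charge = charge),
            class = "adduct_spec")
}

#' @export
format.adduct_spec <- function(x, ...) x$name

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct> ", x$name, "  charge ", x$charge, "\n", sep = "")
  invisible(x)
}

#' Packaged adduct definitions
#'
#' @return Data frame of the adducts searched per ionization mode.
#' @export
adduct_table <- function() {
  if (is.null(.msimetab$adducts)) {
    .msimetab$adducts <- read.delim(.extdata("adducts.tsv"),
                                    stringsAsFactors = FALSE, na.strings = NULL)
  }
  .msimetab$adducts
}

#' Ion m/z of a neutral formula under an adduct
#'
#' Computes `(mass(M) + mass(added) - mass(removed) - charge * m_e) / |charge|`.
#' The electron-mass term is required to reproduce proton-accurate reference
#' m/z values at the 1e-6 Da level.
#'
#' @param formula Neutral molecular formula (`mol_formula` or string).
#' @param adduct Adduct name or `adduct_spec`.
#' @return m/z in Da.
#' @export
#' @examples
#' ion_mz("C10H16N5O13P3", "[M-H]-") # ATP, 505.988470
#' ion_mz("C40H80NO8P", "[M+H]+")    # 734.569432
ion_mz <- function(formula, adduct) {
  f <- if (inherits(formula, "mol_formula")) formula else parse_formula(formula)
  a <- parse_adduct(adduct)
  # verify the removal is possible on the intact ion composition
  invisible((f + a$added) - a$removed) # errors with a clear message if not
  mz <- (monoisotopic_mass(f) + monoisotopic_mass(a$added) -
           monoisotopic_mass(a$removed) - a$charge * electron_mass()) /
    abs(a$charge)
  mz
}

#' Signed relative mass error
#'
#' Error convention is `(observed - theoretical) / theoretical`, exposed in
#' ppm and ppb (`ppb = 1000 * ppm` exactly).
#'
#' @param observed,theoretical m/z values in Da (vectorized; recycled).
#' @return A `mass_error` data frame with columns `observed`, `theoretical`,
#'   `delta_da`, `ppm`, `ppb`.
#' @export
#' @examples
#' mass_error(505.98833, ion_mz("C10H16N5O13P3", "[M-H]-"))
mass_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("domain error: theoretical m/z must be positive and finite")
  }
  rel <- (observed - theoretical) / theoretical
  structure(data.frame(observed = observed, theoretical = theoretical,
                       delta_da = observed - theoretical,
                       ppm = rel * 1e6, ppb = rel * 1e9),
            class = c("mass_error", "data.frame"))
}

#' @export
print.mass_error <- function(x, ...) {
  df <- as.data.frame(x)
  df$observed <- sprintf("%.6f", df$observed)
  df$theoretical <- sprintf("%.6f", df$theoretical)
  df$delta_da <- sprintf("%+.6f", df$delta_da)
  df$ppm <- sprintf("%+.3f", df$ppm)
  df$ppb <- sprintf("%+.0f", df$ppb)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Neutral loss between precursor and fragment
#'
#' `precursor - fragment` under the singly-charged assumption, in Da.
#'
#' @param precursor_mz,fragment_mz m/z in Da; the fragment must be strictly
#'   below the precursor.
#' @return Loss mass in Da.
#' @export
#' @examples
#' neutral_loss(566.32166, 507.24815) # 59.07351, trimethylamine
neutral_loss <- function(precursor_mz, fragment_mz) {
  if (any(fragment_mz <= 0) || any(precursor_mz <= 0)) {
    stop("domain error: m/z values must be positive")
  }
  if (any(fragment_mz >= precursor_mz)) {
    stop("domain error: fragment m/z must be strictly below the precursor")
  }
  precursor_mz - fragment_mz
}

# round-half-even display at 6 decimals; comparisons always use full precision
format_mz <- function(x, digits = 6L) sprintf(paste0("%.", digits, "f"), round(x, digits))
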