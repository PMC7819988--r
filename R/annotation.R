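# Accurate-mass (MS1) annotation against a compound database and MS/MS
# confirmation via neutral-loss / diagnostic-fragment rules. All rule and
# candidate masses are recomputed from molecular formulas at load time;
# nothing is hard-coded.

COMPOUND_CLASSES <- c("PC", "LPC", "SM", "PA", "PS", "TG", "GPC",
                      "nucleotide", "other")

#' Load a compound database
#'
#' Reads a tab-separated compound database with header columns
#' `id, name, formula, class, adducts_pos, adducts_neg` (adduct lists are
#' `;`-separated; an empty field means the compound is not searched in that
#' mode). Every formula is parsed and validated; duplicate ids and malformed
#' rows are rejected with the offending line number.
#'
#' @param path Path to the TSV file. Defaults to the packaged database.
#' @return A `compound_db` data frame.
#' @export
#' @examples
#' db <- load_compound_db()
#' head(db)
load_compound_db <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("compound_db.tsv")
  if (!file.exists(path)) stop("config error: compound database not found: ", path)
  db <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  req <- c("id", "name", "formula", "class", "adducts_pos", "adducts_neg")
  if (!all(req %in% names(db))) {
    stop("load error: compound DB must have columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(db) == 0L) {
    return(structure(db[req], class = c("compound_db", "data.frame")))
  }
  dup <- db$id[duplicated(db$id)]
  if (length(dup)) stop("load error: duplicate compound id(s): ",
                        paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(db))) {
    line <- i + 1L # header is line 1
    f <- tryCatch(parse_formula(db$formula[i]), error = function(e) {
      stop("load error at line ", line, " (id '", db$id[i], "'): ",
           conditionMessage(e), call. = FALSE)
    })
    if (!db$class[i] %in% COMPOUND_CLASSES) {
      stop("load error at line ", line, ": class '", db$class[i],
           "' not in controlled vocabulary (",
           paste(COMPOUND_CLASSES, collapse = ", "), ")")
    }
    adds <- c(split_adducts(db$adducts_pos[i]), split_adducts(db$adducts_neg[i]))
    if (!length(adds)) {
      stop("load error at line ", line, ": compound '", db$id[i],
           "' has no allowed adducts")
    }
    for (a in adds) parse_adduct(a)
  }
  structure(db[req], class = c("compound_db", "data.frame"))
}

split_adducts <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Theoretical ion table for a database and mode
#'
#' Expands a compound database into one row per (compound, allowed adduct)
#' with the theoretical m/z, for the given ionization mode.
#'
#' @param db A `compound_db`.
#' @param mode `"positive"` or `"negative"`.
#' @return Data frame with columns `compound_id`, `name`, `class`, `adduct`,
#'   `mz`.
#' @export
compound_ions <- function(db, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  col <- if (mode == "positive") "adducts_pos" else "adducts_neg"
  out <- lapply(seq_len(nrow(db)), function(i) {
    adds <- split_adducts(db[[col]][i])
    if (!length(adds)) return(NULL)
    f <- parse_formula(db$formula[i])
    data.frame(compound_id = db$id[i], name = db$name[i], class = db$class[i],
               adduct = adds,
               mz = vapply(adds, function(a) ion_mz(f, a), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(compound_id = character(0), name = character(0),
                      class = character(0), adduct = character(0),
                      mz = numeric(0))
  }
  out[order(out$mz, out$compound_id), , drop = FALSE]
}

#' Annotate an observed m/z by accurate mass
#'
#' Returns every (compound, adduct) in the database whose theoretical m/z
#' lies within the ppm tolerance of the observed value, ranked by absolute
#' error (ties broken by compound id). An empty result is a valid no-match.
#'
#' @param observed_mz Observed m/z in Da (scalar).
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @param db A `compound_db` (default: packaged database).
#' @param tolerance_ppm Matching half-window in ppm (default 2).
#' @param ions Optional precomputed [compound_ions()] table (for repeated
#'   queries).
#' @return An `annotation` data frame: `observed_mz`, `compound_id`, `name`,
#'   `class`, `adduct`, `theoretical_mz`, `error_ppm`, `evidence`,
#'   `n_competing`.
#' @export
#' @examples
#' annotate_ms1(505.98833, "negative")    # ATP [M-H]-
#' annotate_ms1(566.32166, "positive")    # LysoPC(20:4) [M+Na]+
annotate_ms1 <- function(observed_mz, mode = c("positive", "negative"),
                         db = load_compound_db(), tolerance_ppm = 2,
                         ions = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(observed_mz) == 1L, is.finite(observed_mz))
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("domain error: tolerance_ppm must be > 0")
  }
  if (is.null(ions)) ions <- compound_ions(db, mode)
  if (nrow(ions) == 0L) stop("domain error: compound database is empty for mode ", mode)
  ppm <- (observed_mz - ions$mz) / ions$mz * 1e6
  hit <- abs(ppm) <= tolerance_ppm
  res <- data.frame(observed_mz = rep(observed_mz, sum(hit)),
                    compound_id = ions$compound_id[hit],
                    name = ions$name[hit], class = ions$class[hit],
                    adduct = ions$adduct[hit],
                    theoretical_mz = ions$mz[hit], error_ppm = ppm[hit],
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(abs(res$error_ppm), res$compound_id), , drop = FALSE]
  res$evidence <- rep("MS1-only", nrow(res))
  res$n_competing <- rep(max(nrow(res) - 1L, 0L), nrow(res))
  rownames(res) <- NULL
  structure(res, class = c("annotation", "data.frame"))
}

#' Load MS/MS fragmentation rules
#'
#' Reads a TSV of neutral-loss and diagnostic-fragment rules
#' (`rule_id, type, formula, adduct, classes, tolerance_ppb, description`).
#' Loss masses and fragment ion m/z are recomputed from the formulas via the
#' mass engine at load time.
#'
#' @param path Path to the rules TSV (default: packaged rules).
#' @return Data frame of rules with computed `loss_mass` / `fragment_mz`.
#' @export
load_fragmentation_rules <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("fragmentation_rules.tsv")
  r <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  stopifnot(all(c("rule_id", "type", "formula", "adduct", "classes",
                  "tolerance_ppb") %in% names(r)))
  if (any(!r$type %in% c("loss", "fragment"))) {
    stop("load error: rule type must be 'loss' or 'fragment'")
  }
  if (any(!is.finite(r$tolerance_ppb) | r$tolerance_ppb <= 0)) {
    stop("load error: rule tolerance_ppb must be > 0")
  }
  r$loss_mass <- NA_real_
  r$fragment_mz <- NA_real_
  for (i in seq_len(nrow(r))) {
    if (r$type[i] == "loss") {
      r$loss_mass[i] <- monoisotopic_mass(r$formula[i])
    } else {
      r$fragment_mz[i] <- ion_mz(r$formula[i], r$adduct[i])
    }
  }
  r
}

#' Match MS/MS fragments against fragmentation rules
#'
#' A loss rule matches when the neutral loss from the precursor to some
#' fragment agrees with the rule's loss mass within the ppb tolerance; a
#' diagnostic-fragment rule matches when some fragment m/z agrees with the
#' rule's ion m/z. Fragment-rule polarity must match the acquisition mode.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragment_mzs Numeric vector of fragment m/z (may be empty; an
#'   empty match set is returned, not an error).
#' @param mode `"positive"` or `"negative"`.
#' @param rules Rule table from [load_fragmentation_rules()].
#' @param tolerance_ppb Override tolerance applied to all rules; `NULL`
#'   (default) uses each rule's own tolerance.
#' @return Data frame of matched rules with the observed loss/fragment and
#'   its signed ppb error.
#' @export
#' @examples
#' rules <- load_fragmentation_rules()
#' annotate_msms(566.32166, c(507.24815, 383.25558), "positive", rules)
annotate_msms <- function(precursor_mz, fragment_mzs,
                          mode = c("positive", "negative"),
                          rules = load_fragmentation_rules(),
                          tolerance_ppb = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(rule_id = character(0), type = character(0),
                      classes = character(0), fragment_mz = numeric(0),
                      observed = numeric(0), theoretical = numeric(0),
                      error_ppb = numeric(0), stringsAsFactors = FALSE)
  if (length(fragment_mzs) == 0L) return(empty)
  stopifnot(all(is.finite(fragment_mzs)), is.finite(precursor_mz))
  out <- list()
  for (i in seq_len(nrow(rules))) {
    tol <- if (is.null(tolerance_ppb)) rules$tolerance_ppb[i] else tolerance_ppb
    if (rules$type[i] == "loss") {
      frag <- fragment_mzs[fragment_mzs < precursor_mz & fragment_mzs > 0]
      if (!length(frag)) next
      loss <- neutral_loss(precursor_mz, frag)
      err <- (loss - rules$loss_mass[i]) / rules$loss_mass[i] * 1e9
      hit <- abs(err) <= tol
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          rule_id = rules$rule_id[i], type = "loss",
          classes = rules$classes[i], fragment_mz = frag[hit],
          observed = loss[hit], theoretical = rules$loss_mass[i],
          error_ppb = err[hit], stringsAsFactors = FALSE)
      }
    } else {
      pol <- if (grepl("\\-$", rules$adduct[i])) "negative" else "positive"
      if (pol != mode) next
      err <- (fragment_mzs - rules$fragment_mz[i]) / rules$fragment_mz[i] * 1e9
      hit <- abs(err) <= tol
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          rule_id = rules$rule_id[i], type = "fragment",
          classes = rules$classes[i], fragment_mz = fragment_mzs[hit],
          observed = fragment_mzs[hit], theoretical = rules$fragment_mz[i],
          error_ppb = err[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consolidate MS1 candidates with MS/MS evidence
#'
#' Applies the unambiguous-identification policy: a single MS1 candidate is
#' reported as is (promoted to `MS2-confirmed` when a class-consistent rule
#' matched); with several candidates, MS/MS rules discriminate by compound
#' class and a uniquely class-consistent candidate is promoted; anything
#' still ambiguous is flagged, retaining all competitors, rather than
#' auto-picked.
#'
#' @param ms1 Result of [annotate_ms1()] (must be non-empty).
#' @param ms2 Result of [annotate_msms()] (may be empty).
#' @return A one-row `annotation` data frame with `evidence`, `ambiguous`
#'   and `n_competing`; the full competitor set is kept in
#'   `attr(, "competitors")`.
#' @export
consolidate_annotation <- function(ms1, ms2 = NULL) {
  if (is.null(ms1) || nrow(ms1) == 0L) {
    stop("precondition error: consolidate_annotation needs >= 1 MS1 candidate")
  }
  rule_classes <- character(0)
  if (!is.null(ms2) && nrow(ms2) > 0L) {
    rule_classes <- unique(unlist(strsplit(ms2$classes, ";", fixed = TRUE)))
  }
  pick_result <- function(row, evidence, ambiguous, n_competing) {
    row$evidence <- evidence
    row$ambiguous <- ambiguous
    row$n_competing <- n_competing
    attr(row, "competitors") <- as.data.frame(ms1)
    structure(row, class = c("annotation", "data.frame"))
  }
  if (nrow(ms1) == 1L) {
    confirmed <- length(rule_classes) > 0L && ms1$class[1] %in% rule_classes
    return(pick_result(ms1[1, , drop = FALSE],
                       if (confirmed) "MS2-confirmed" else "MS1-only",
                       FALSE, 0L))
  }
  consistent <- which(ms1$class %in% rule_classes)
  if (length(rule_classes) && length(consistent) == 1L) {
    return(pick_result(ms1[consistent, , drop = FALSE], "MS2-confirmed",
                       FALSE, nrow(ms1) - 1L))
  }
  # still ambiguous: keep best-|error| candidate only as the report anchor,
  # flagged, with the whole competitor set attached
  pick_result(ms1[1, , drop = FALSE],
              if (length(consistent) > 1L) "MS2-confirmed" else "MS1-only",
              TRUE, nrow(ms1))
}

#' Write an annotation report
#'
#' One CSV row per annotation result.
#'
#' @param annotations A data frame (or list of `annotation` rows).
#' @param path Output CSV path.
#' @export
write_annotation_report <- function(annotations, path) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- do.call(rbind, lapply(annotations, as.data.frame))
  }
  write.table(annotations, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}
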