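# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
ATOMIC_MASSES <- c(C = 12, H = 1.00782503, O = 15.99491462, N = 14.00307401,
                   P = 30.97376200, S = 31.97207117, Na = 22.98976928,
                   K = 38.96370649, Li = 7.01600344, Cl = 34.96885268)
ELECTRON_MASS <- 0.00054857990907

#' Parse a Hill-style elemental formula
#'
#' @param text formula string such as `"C13H28"` or `"C39H69O8P"`.
#' @return named integer vector (element -> count) of class
#'   `elemental_formula`. Unknown element symbols are rejected.
#' @export
parse_formula <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("unparseable formula: \"", text, "\"")
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(ATOMIC_MASSES))
  if (length(unknown))
    stop("unknown element(s) in \"", text, "\": ",
         paste(unknown, collapse = ", "))
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  # Hill order: C, H, then alphabetical
  ord <- order(match(names(out), c("C", "H"), nomatch = 3L), names(out))
  structure(out[ord], class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic atomic mass (C 12 exactly,
#' H 1.00782503, O 15.99491462, ...).
#'
#' @param f an `elemental_formula` or a formula string.
#' @return mass in daltons.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(ATOMIC_MASSES[names(f)] * unclass(f))
}

#' ESI+ adduct rules
#'
#' The 14 positive-ionization adduct scan modes used for annotation:
#' M+H; M+Na; M+H-2H2O; M+H-H2O; M+K; M+2Na-H; M+2H; M+3H; M+H+Na;
#' M+2H+Na; M+2Na; M+2Na+H; M+Li; M+CH3OH+H. Each rule carries its charge
#' and the summed neutral-species mass delta; the ion m/z is computed with
#' electron correction in [adduct_mz()]. Charges follow the adduct name:
#' +1 except M+2H, M+H+Na, M+2Na (2+) and M+3H, M+2H+Na, M+2Na+H (3+).
#'
#' @return data.frame: `name`, `charge`, `delta` (Da added to the neutral
#'   molecule before electron correction).
#' @export
adduct_rules <- function() {
  H <- ATOMIC_MASSES[["H"]]; Na <- ATOMIC_MASSES[["Na"]]
  K <- ATOMIC_MASSES[["K"]]; Li <- ATOMIC_MASSES[["Li"]]
  H2O <- 2 * H + ATOMIC_MASSES[["O"]]
  MeOH <- ATOMIC_MASSES[["C"]] + 4 * H + ATOMIC_MASSES[["O"]]
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+H-2H2O]+", "[M+H-H2O]+", "[M+K]+",
             "[M+2Na-H]+", "[M+2H]2+", "[M+3H]3+", "[M+H+Na]2+",
             "[M+2H+Na]3+", "[M+2Na]2+", "[M+2Na+H]3+", "[M+Li]+",
             "[M+CH3OH+H]+"),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 2L, 3L, 2L, 3L, 1L, 1L),
    delta = c(H, Na, H - 2 * H2O, H - H2O, K, 2 * Na - H, 2 * H, 3 * H,
              H + Na, 2 * H + Na, 2 * Na, 2 * Na + H, Li, MeOH + H),
    stringsAsFactors = FALSE)
}

#' Theoretical m/z of an adduct of a neutral molecule
#'
#' `m/z = (M + delta - z * m_e) / z`: the carrier atoms are added as
#' neutral species and z electron masses are subtracted, giving the exact
#' cation mass (e.g. the proton at 1.00727646 Da).
#'
#' @param M neutral monoisotopic mass (Da), `> 0`.
#' @param rule one row of [adduct_rules()] (or a list with `name`,
#'   `charge`, `delta`).
#' @return m/z in daltons.
#' @export
adduct_mz <- function(M, rule) {
  if (any(M <= 0)) stop("neutral mass must be > 0")
  mz <- (M + rule$delta - rule$charge * ELECTRON_MASS) / rule$charge
  if (any(mz <= 0))
    stop("adduct ", rule$name, " yields nonpositive m/z for M = ", M)
  mz
}

#' @rdname adduct_mz
#' @param mz observed or theoretical m/z.
#' @return `neutral_mass`: the neutral monoisotopic mass implied by an
#'   ion m/z under the rule (inverse of `adduct_mz`).
#' @export
neutral_mass <- function(mz, rule) {
  mz * rule$charge - rule$delta + rule$charge * ELECTRON_MASS
}

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`. Reports print the
#' rounded absolute value (the accurate mass error, AME).
#'
#' @param observed,theoretical m/z values; `theoretical > 0`.
#' @return signed ppm error.
#' @export
dppm <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' Read a compound database CSV
#'
#' Expected columns: `name`, `formula`, `category` (Lipid Maps category:
#' FA, GL, GP, SP, ST, PR, SL, PK, ON, OS, or NC).
#'
#' @param path CSV file path.
#' @return data.frame with validated columns and a `neutral_mass` column.
#' @export
read_compound_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "category")
  miss <- setdiff(needed, names(db))
  if (length(miss)) stop("compound db lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !db$category %in% LIPID_CATEGORIES
  if (any(bad)) stop("unknown lipid categor(ies): ",
                     paste(unique(db$category[bad]), collapse = ", "))
  db$neutral_mass <- vapply(db$formula, function(f) monoisotopic_mass(f), 0)
  db
}

LIPID_CATEGORIES <- c("FA", "GL", "GP", "SP", "ST", "PR", "SL", "PK",
                      "ON", "OS", "NC")

#' Annotate an observed m/z against a compound database
#'
#' Computes the theoretical m/z of every (compound, adduct rule) pair,
#' keeps matches with `|dppm| <= tol`, and ranks them by absolute mass
#' error ascending. Hits tied on the integer-rounded AME are all reported.
#' When nothing matches, a single NC (not classified) row is returned.
#'
#' @param mz observed ion m/z (single value).
#' @param db compound database from [read_compound_db()] (or a data.frame
#'   with `name`, `formula`, `category`; neutral masses are computed if
#'   absent).
#' @param rules adduct rules (default [adduct_rules()]).
#' @param tol maximum |mass error| in ppm (default 10).
#' @return data.frame: `query_mz`, `name`, `formula`, `category`,
#'   `adduct`, `neutral_mass`, `theoretical_mz`, `dppm`, `ame`
#'   (integer |dppm|), `broad_class`; ordered by `ame` then `|dppm|`.
#' @export
annotate <- function(mz, db, rules = adduct_rules(), tol = 10) {
  stopifnot(length(mz) == 1, nrow(db) > 0)
  if (is.null(db$neutral_mass))
    db$neutral_mass <- vapply(db$formula, function(f) monoisotopic_mass(f), 0)
  grid <- expand.grid(ci = seq_len(nrow(db)), ri = seq_len(nrow(rules)))
  theo <- (db$neutral_mass[grid$ci] + rules$delta[grid$ri] -
             rules$charge[grid$ri] * ELECTRON_MASS) / rules$charge[grid$ri]
  err <- dppm(mz, theo)
  keep <- abs(err) <= tol
  if (!any(keep)) {
    return(data.frame(query_mz = mz, name = NA_character_,
                      formula = NA_character_, category = "NC",
                      adduct = NA_character_, neutral_mass = NA_real_,
                      theoretical_mz = NA_real_, dppm = NA_real_,
                      ame = NA_integer_, broad_class = "NC",
                      stringsAsFactors = FALSE))
  }
  hits <- data.frame(
    query_mz = mz,
    name = db$name[grid$ci[keep]],
    formula = db$formula[grid$ci[keep]],
    category = db$category[grid$ci[keep]],
    adduct = rules$name[grid$ri[keep]],
    neutral_mass = db$neutral_mass[grid$ci[keep]],
    theoretical_mz = theo[keep],
    dppm = err[keep],
    ame = as.integer(round(abs(err[keep]))),
    stringsAsFactors = FALSE)
  hits$broad_class <- assign_broad_class(hits$category)
  hits[order(hits$ame, abs(hits$dppm)), , drop = FALSE]
}

#' Broad polarity class of a Lipid Maps category
#'
#' Maps each category to a broad class: fatty acyls and sterol lipids are
#' nonpolar (NP); glycerolipids, glycerophospholipids, prenol lipids,
#' polyketides, sphingolipids and saccharolipids are polar (PL);
#' organonitrogen, organosulfur and unclassified ions stay NC.
#'
#' @param category character vector of categories.
#' @param mapping named character vector overriding the default mapping.
#' @return character vector of `"NP"`, `"PL"`, `"NC"`.
#' @export
assign_broad_class <- function(category, mapping = NULL) {
  map <- c(FA = "NP", ST = "NP",
           GL = "PL", GP = "PL", PR = "PL", PK = "PL", SP = "PL", SL = "PL",
           ON = "NC", OS = "NC", NC = "NC")
  if (!is.null(mapping)) map[names(mapping)] <- mapping
  unknown <- setdiff(unique(category), names(map))
  if (length(unknown))
    stop("unknown categor(ies): ", paste(unknown, collapse = ", "))
  unname(map[category])
}

#' Bundled discriminatory-ion table and compound database
#'
#' `wheat_discriminatory_ions()` loads the packaged transcription of the
#' published table of ions separating durum from bread wheat in the
#' two-class OPLS-DA model: 35 unique ions (one listed on two rows for an
#' accurate-mass-error tie), with retention time, m/z, best-choice adduct,
#' neutral adduct mass, integer mass error, tentative identity, empirical
#' formula, Lipid Maps category, the class each ion is elevated in, and
#' broad polarity class. `wheat_compound_db()` loads the companion
#' compound database (name, formula, category) derived from the annotated
#' rows, usable as an offline [annotate()] target.
#'
#' @return data.frame (tab-separated fixture parsed with
#'   `check.names = FALSE`).
#' @export
wheat_discriminatory_ions <- function() {
  path <- system.file("extdata", "wheat_discriminatory_ions.tsv",
                      package = "wheatms", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' @rdname wheat_discriminatory_ions
#' @export
wheat_compound_db <- function() {
  read_compound_db(system.file("extdata", "wheat_compounds.csv",
                               package = "wheatms", mustWork = TRUE))
}

#' Annotation report for a set of ions
#'
#' Runs [annotate()] for each ion and keeps the top-ranked hit(s) — all
#' hits tied at the smallest integer AME — mirroring the best-choice
#' reporting convention.
#'
#' @param ions data.frame with `feature_id`, `rt`, `mz` (e.g. the selected
#'   ions joined with feature metadata).
#' @param db compound database.
#' @param rules adduct rules.
#' @param tol ppm tolerance.
#' @return data.frame, one or more rows per ion.
#' @export
annotate_ions <- function(ions, db, rules = adduct_rules(), tol = 10) {
  res <- lapply(seq_len(nrow(ions)), function(i) {
    hits <- annotate(ions$mz[i], db, rules, tol)
    best <- hits[is.na(hits$ame) | hits$ame == hits$ame[1], , drop = FALSE]
    cbind(feature_id = ions$feature_id[i], rt = ions$rt[i], best,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
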