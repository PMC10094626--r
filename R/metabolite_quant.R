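# Targeted NAD metabolomics arithmetic: monoisotopic masses, inclusion-list
# m/z, ppm matching, protein normalization and redox-couple ratios.

# Most-abundant-isotope masses (Da). C-12 is exactly 12 by definition.
ISOTOPE_MASS <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  P = 30.97376151,
  S = 31.97207069)

ELECTRON_MASS_DA <- 0.00054858

#' Parse a molecular formula
#'
#' `"C21H28N7O14P2"` -> named integer vector `c(C = 21, H = 28, ...)`.
#' One- or two-letter element symbols; a missing count means 1.
#'
#' @param formula character scalar.
#' @return named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("H2O")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) <= 1L)
  if (length(formula) == 0L || !nzchar(gsub("\\s", "", formula)))
    return(stats::setNames(integer(0), character(0)))
  s <- gsub("[\\s_]", "", formula, perl = TRUE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (sum(nchar(parts)) != nchar(s))
    nt_chemistry_error(sprintf("cannot parse formula '%s'", formula))
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses (C = 12 exactly, H = 1.00782503,
#' N = 14.00307401, O = 15.99491462, P = 30.97376151, S = 31.97207069), with no
#' electron correction.
#'
#' @param formula a formula string or a named element-count vector.
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C21H28N7O14P2") # 664.11695 (5 dp)
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  if (any(counts < 0) || any(counts != round(counts)))
    nt_chemistry_error("element counts must be non-negative integers")
  unknown <- setdiff(names(counts), names(ISOTOPE_MASS))
  if (length(unknown))
    nt_chemistry_error(sprintf("unknown element(s): %s",
                               paste(unknown, collapse = ", ")))
  sum(counts * ISOTOPE_MASS[names(counts)])
}

#' Theoretical m/z of an ion
#'
#' `(monoisotopic_mass - n_e * m_e) / charge`, where the electron convention
#' sets `n_e`: `"none"` (0 electrons removed; a plain atomic-mass sum) or
#' `"minus-1e"` (1 electron removed, the physically complete value for a
#' singly protonated cation whose formula already includes the proton).
#'
#' @param formula formula string or named element-count vector of the intact
#'   ion (adduct included).
#' @param charge positive integer charge.
#' @param electron_convention `"none"` or `"minus-1e"`.
#' @return m/z in Da per unit charge.
#' @export
#' @examples
#' theoretical_mz("C21H30N7O14P2", 1, "minus-1e") # 666.13205 (5 dp)
theoretical_mz <- function(formula, charge = 1L,
                           electron_convention = c("none", "minus-1e")) {
  electron_convention <- match.arg(electron_convention)
  if (length(charge) != 1L || is.na(charge) || charge < 1 || charge != round(charge))
    nt_chemistry_error("charge must be a positive integer")
  n_e <- switch(electron_convention, "none" = 0, "minus-1e" = 1)
  (monoisotopic_mass(formula) - n_e * ELECTRON_MASS_DA) / charge
}

#' Match an observed m/z within a ppm tolerance
#'
#' `|observed - theoretical| / theoretical * 1e6 <= tol_ppm`, with the
#' theoretical value as the reference. The targeted acquisition used a 5-ppm
#' tolerance, the default here.
#'
#' @param observed_mz,theoretical_mz_da m/z values (> 0).
#' @param tol_ppm tolerance in parts per million.
#' @return logical.
#' @export
ppm_match <- function(observed_mz, theoretical_mz_da, tol_ppm = 5) {
  if (any(observed_mz <= 0) || any(theoretical_mz_da <= 0))
    nt_chemistry_error("m/z values must be positive")
  abs(observed_mz - theoretical_mz_da) / theoretical_mz_da * 1e6 <= tol_ppm
}

#' Load the packaged NAD inclusion list
#'
#' The four-row inclusion list of the targeted assay (NAD+, NADH, NADP+,
#' NADPH): protonated-ion formula, per-row electron convention, printed
#' accurate mass, inclusion-window centre/half-width, and retention time. The
#' NADPH row's printed mass matches no single-electron convention (it is
#' consistent only with removing two electrons) and is stored verbatim with
#' convention `"as-printed"`.
#'
#' @return data.frame `name, ion_formula, convention, printed_mass_da,
#'   inclusion_center_mz, inclusion_halfwidth_mz, rt_min`.
#' @export
load_inclusion_list <- function() {
  path <- system.file("extdata", "nad_inclusion_list.csv", package = "noveltank")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    conv <- df$convention[i]
    if (conv %in% c("none", "minus-1e")) {
      mz <- theoretical_mz(df$ion_formula[i], 1L, conv)
      if (abs(mz - df$printed_mass_da[i]) > 0.002)
        nt_chemistry_error(sprintf(
          "inclusion list row %s: computed %0.5f differs from printed %0.5f",
          df$name[i], mz, df$printed_mass_da[i]))
    }
  }
  df
}

#' Normalize metabolite areas to protein and compute redox ratios
#'
#' Per sample: `normalized_area = area / protein_conc` for every metabolite,
#' plus the within-sample ratios NAD+/NADH and NADP+/NADPH computed from raw
#' areas (the protein normalization cancels algebraically inside a ratio) and
#' their log10 transforms for downstream ANOVA. A zero or missing denominator
#' flags the ratio as missing rather than raising an error.
#'
#' @param records long-format data.frame with columns `sample_id`, `genotype`,
#'   `age_months`, `metabolite` (`"NAD+"`, `"NADH"`, `"NADP+"`, `"NADPH"`),
#'   `area` (>= 0) and `protein_conc` (mg/mL, > 0).
#' @return one row per sample: normalized areas (`<metabolite>_norm`), ratio
#'   columns `nad_ratio`, `nadp_ratio`, their log10s, and logical
#'   `nad_ratio_missing` / `nadp_ratio_missing` flags.
#' @export
normalize_and_ratio <- function(records) {
  need <- c("sample_id", "genotype", "age_months", "metabolite", "area", "protein_conc")
  if (!all(need %in% names(records)))
    nt_input_error(sprintf("records need columns: %s", paste(need, collapse = ", ")))
  if (any(records$area < 0, na.rm = TRUE)) nt_input_error("areas must be >= 0")
  if (any(records$protein_conc <= 0)) nt_input_error("protein_conc must be > 0")

  samples <- unique(records$sample_id)
  rows <- lapply(samples, function(sid) {
    r <- records[records$sample_id == sid, ]
    getm <- function(m) {
      i <- which(r$metabolite == m)
      if (length(i)) r$area[i[1]] else NA_real_
    }
    ratio <- function(num, den) {
      if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
    }
    nad <- ratio(getm("NAD+"), getm("NADH"))
    nadp <- ratio(getm("NADP+"), getm("NADPH"))
    out <- data.frame(sample_id = sid, genotype = r$genotype[1],
                      age_months = r$age_months[1],
                      nad_ratio = nad, nad_ratio_log10 = log10(nad),
                      nad_ratio_missing = is.na(nad),
                      nadp_ratio = nadp, nadp_ratio_log10 = log10(nadp),
                      nadp_ratio_missing = is.na(nadp),
                      stringsAsFactors = FALSE)
    for (m in unique(records$metabolite)) {
      i <- which(r$metabolite == m)
      col <- paste0(gsub("[^A-Za-z]", "", tolower(m)),
                    if (grepl("\\+$", m)) "p" else "", "_norm")
      out[[col]] <- if (length(i)) r$area[i[1]] / r$protein_conc[i[1]] else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
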