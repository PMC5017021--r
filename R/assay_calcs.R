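# Conventional atomic weights (u), 4-5 significant figures.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, Cl = 35.453, Cu = 63.546)

#' Parse a chemical formula
#'
#' Supports simple element-count formulas and hydrate-style composites
#' joined with `.` or the middle dot, with an optional leading multiplier
#' per part (e.g. `"CuO"`, `"CuCl2.2H2O"`).
#'
#' @param formula formula string.
#' @return named integer vector of element counts, class `ChemFormula`.
#' @export
parse_formula <- function(formula) {
  parts <- strsplit(formula, "[.·]")[[1]]
  counts <- integer(0)
  for (part in parts) {
    mult <- 1L
    m <- regmatches(part, regexec("^(\\d+)(.*)$", part))[[1]]
    if (length(m) == 3L && nzchar(m[2])) {
      mult <- as.integer(m[2])
      part <- m[3]
    }
    toks <- regmatches(part, gregexpr("[A-Z][a-z]?\\d*", part))[[1]]
    if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(part)) {
      stop("cannot parse formula part: ", part)
    }
    for (tok in toks) {
      el <- sub("\\d+$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + mult * n
    }
  }
  if (!all(names(counts) %in% names(ATOMIC_MASSES))) {
    stop("unknown element(s): ",
         paste(setdiff(names(counts), names(ATOMIC_MASSES)), collapse = ", "))
  }
  structure(counts, class = "ChemFormula")
}

as_formula <- function(x) {
  if (inherits(x, "ChemFormula")) x else parse_formula(x)
}

#' Molar mass of a formula
#'
#' @param formula a formula string or `ChemFormula`.
#' @return molar mass in g/mol.
#' @export
formula_mass <- function(formula) {
  f <- as_formula(formula)
  sum(ATOMIC_MASSES[names(f)] * unclass(f))
}

#' Mass fraction of an element in a compound
#'
#' @param formula a formula string or `ChemFormula`.
#' @param element element symbol; must occur in the formula.
#' @return proportion of the compound's mass contributed by the element.
#' @export
metal_mass_fraction <- function(formula, element) {
  f <- as_formula(formula)
  if (!element %in% names(f)) stop("element ", element, " absent from formula")
  unname(ATOMIC_MASSES[element] * f[[element]]) / formula_mass(f)
}

#' Maximal ion release from complete dissolution, and its inverse
#'
#' `max_ion_release` gives the element concentration released if a compound
#' at `conc_compound` dissolves completely; `required_compound_conc` gives
#' the compound concentration needed to deliver a target ion concentration;
#' `dissolution_percent` expresses a measured ion concentration as a
#' percentage of the maximum.
#'
#' @param conc_compound compound concentration (e.g. ug/ml).
#' @param formula a formula string or `ChemFormula`.
#' @param element element symbol.
#' @param target_ion_conc desired ion concentration.
#' @param measured,maximum measured and maximal ion concentrations.
#' @return a concentration (same units as the input) or a percentage.
#' @export
max_ion_release <- function(conc_compound, formula, element) {
  stopifnot(conc_compound > 0)
  conc_compound * metal_mass_fraction(formula, element)
}

#' @rdname max_ion_release
#' @export
required_compound_conc <- function(target_ion_conc, formula, element) {
  stopifnot(target_ion_conc > 0)
  frac <- metal_mass_fraction(formula, element)
  if (frac == 0) stop("element has zero mass fraction")
  target_ion_conc / frac
}

#' @rdname max_ion_release
#' @export
dissolution_percent <- function(measured, maximum) {
  stopifnot(maximum > 0, measured >= 0)
  measured / maximum * 100
}

#' Glutathione redox ratio from luminescence-assay readouts
#'
#' The assay reports total glutathione and (in NEM-treated duplicate wells)
#' oxidized glutathione, both in GSH-equivalent concentration units; one
#' mole of oxidized GSSG is reduced to two moles of GSH for detection, so
#' GSSG = gssg_equiv / 2, reduced GSH = total - gssg_equiv, and the redox
#' ratio is reduced GSH / GSSG.
#'
#' @param total_gsh_equiv_uM total glutathione, uM GSH equivalents.
#' @param gssg_well_gsh_equiv_uM GSSG well readout, uM GSH equivalents;
#'   must not exceed the total.
#' @return list with `gssg_uM`, `gsh_uM` (reduced) and `ratio` (`Inf` when
#'   no GSSG is detected).
#' @export
gsh_gssg_ratio <- function(total_gsh_equiv_uM, gssg_well_gsh_equiv_uM) {
  if (gssg_well_gsh_equiv_uM < 0 || total_gsh_equiv_uM < 0) {
    stop("concentrations must be non-negative")
  }
  if (gssg_well_gsh_equiv_uM > total_gsh_equiv_uM) {
    stop("GSSG-well readout exceeds total glutathione")
  }
  gssg <- gssg_well_gsh_equiv_uM / 2
  gsh <- total_gsh_equiv_uM - gssg_well_gsh_equiv_uM
  list(gssg_uM = gssg, gsh_uM = gsh,
       ratio = if (gssg == 0) Inf else gsh / gssg)
}

#' Efficiency-corrected relative gene expression
#'
#' Relative expression ratio of a target gene versus a reference
#' (housekeeping) gene, treated versus control:
#' `E_target^(Ct_control_target - Ct_treated_target) /
#'  E_ref^(Ct_control_ref - Ct_treated_ref)`,
#' where E is the amplification efficiency in fold per cycle (2 = perfect
#' doubling).
#'
#' @param ct_target_control,ct_target_treated Ct values for the target gene.
#' @param ct_ref_control,ct_ref_treated Ct values for the reference gene.
#' @param e_target,e_ref amplification efficiencies in (1, 2].
#' @return the expression fold change.
#' @export
pfaffl_ratio <- function(ct_target_control, ct_target_treated,
                         ct_ref_control, ct_ref_treated,
                         e_target = 2, e_ref = 2) {
  if (e_target <= 1 || e_target > 2 || e_ref <= 1 || e_ref > 2) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  if (any(c(ct_target_control, ct_target_treated, ct_ref_control,
            ct_ref_treated) < 0)) {
    stop("Ct values must be >= 0")
  }
  e_target^(ct_target_control - ct_target_treated) /
    e_ref^(ct_ref_control - ct_ref_treated)
}
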