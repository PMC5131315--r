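# Electronic-continuum correction (ECC) for ionic charges, and the
# composition arithmetic around it. The ECC includes electronic polarization
# in a mean-field way by multiplying ionic charges by 1/sqrt(eps_el), with
# eps_el the electronic (optical-frequency, n^2) part of the water dielectric
# constant. For water eps_el ~ 1.78, giving a factor of 0.75 and scaled
# charges of +1.5e for Ca2+ and -0.75e for Cl-.

#' ECC charge-scaling factor
#'
#' `f = 1 / sqrt(eps_electronic)`. Full precision is returned; the
#' conventional display value is the 2-decimal rounding (0.75 for water).
#'
#' @param eps_electronic electronic part of the solvent dielectric constant
#'   (> 1; 1 is the vacuum identity)
#' @return scaling factor (dimensionless)
#' @export
scaling_factor <- function(eps_electronic = 1.78) {
  if (!is.numeric(eps_electronic) || eps_electronic <= 0)
    stop("eps_electronic must be positive")
  1 / sqrt(eps_electronic)
}

#' Scale formal ionic charges
#'
#' Elementwise multiplication by the scaling factor; stored values are not
#' rounded. Lipid partial charges are deliberately left untouched by this
#' package: only free ions are scaled (scaling is a property of the
#' ion-in-dielectric model, and 16 cations of +1.5e exactly neutralize 24
#' unscaled -1e lipids).
#'
#' @param formal named or unnamed numeric charges (e)
#' @param f scaling factor, 0 < f <= 1 (default the exact conventional 0.75)
#' @return object of class `scaled_charges` with fields `factor`, `formal`,
#'   `scaled`
#' @export
scale_charges <- function(formal, f = 0.75) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop("scaling factor must be in (0, 1]")
  structure(list(factor = f, formal = formal, scaled = formal * f),
            class = "scaled_charges")
}

#' @export
print.scaled_charges <- function(x, ...) {
  cat(sprintf("ECC scaled charges (f = %.4f, displayed %.2f):\n",
              x$factor, round(x$factor, 2)))
  nm <- names(x$formal) %||% sprintf("ion%d", seq_along(x$formal))
  for (i in seq_along(x$formal))
    cat(sprintf("  %-6s %+g e -> %+g e\n", nm[i], x$formal[i], x$scaled[i]))
  invisible(x)
}

#' Number of cations needed to neutralize a net lipid charge
#'
#' Returns `|Q| / q` when that is an integer; otherwise the integer count
#' minimizing the residual `|Q + n q|`, with a warning and the residual
#' attached as attribute `"residual"` (always, also when zero).
#'
#' @param net_lipid_charge total lipid charge Q in e (<= 0)
#' @param cation_charge scaled cation charge q in e (> 0)
#' @return integer cation count
#' @export
neutralizing_cation_count <- function(net_lipid_charge, cation_charge) {
  if (cation_charge == 0) stop("cation charge must be nonzero")
  if (cation_charge < 0) stop("cation charge must be positive")
  if (net_lipid_charge > 0) stop("net lipid charge must be <= 0")
  n <- round(abs(net_lipid_charge) / cation_charge)
  residual <- net_lipid_charge + n * cation_charge
  if (abs(residual) > 1e-9)
    warning(sprintf("no integer count neutralizes exactly; residual %+g e",
                    residual))
  structure(as.integer(n), residual = residual)
}

#' Nominal salt concentration from ion-pair and water counts
#'
#' Convention: concentrations are quoted with respect to the number of water
#' molecules in the box, `c = (n_pairs / n_water) * molarity_water`, with the
#' pure-water molarity 55.51 mol/L by default (configurable).
#'
#' @param n_ion_pairs number of salt ion pairs
#' @param n_water number of water molecules (> 0)
#' @param molarity_water reference molarity of pure water, mol/L
#' @return concentration in mol/L
#' @export
nominal_concentration <- function(n_ion_pairs, n_water, molarity_water = 55.51) {
  if (n_water <= 0) stop("n_water must be > 0")
  (n_ion_pairs / n_water) * molarity_water
}

#' Ion pairs needed for a target nominal concentration
#'
#' Inverse of [nominal_concentration()], rounded to the nearest integer.
#'
#' @param target_conc mol/L
#' @inheritParams nominal_concentration
#' @return integer number of ion pairs
#' @export
ion_pairs_for_concentration <- function(target_conc, n_water,
                                        molarity_water = 55.51) {
  if (n_water <= 0) stop("n_water must be > 0")
  as.integer(round(target_conc * n_water / molarity_water))
}

#' Build and audit a bilayer system composition
#'
#' Assembles lipid counts, water count, and ion counts (neutralizing cations
#' plus added salt) into a composition report, with the net system charge
#' flagged if nonzero.
#'
#' @param n_pc,n_ps zwitterionic / anionic lipid counts
#' @param ps_charge formal charge per PS lipid (e, unscaled)
#' @param n_water water molecule count
#' @param salt_conc nominal added CaCl2 concentration (mol/L), beyond
#'   neutralization
#' @param f ECC scaling factor applied to the ions
#' @return object of class `composition` (a list)
#' @export
composition <- function(n_pc, n_ps = 0, ps_charge = -1, n_water,
                        salt_conc = 0, f = 0.75) {
  stopifnot(n_pc >= 0, n_ps >= 0, n_water > 0)
  q_ca <- 2 * f
  q_cl <- -1 * f
  net_lipid <- n_ps * ps_charge
  n_neutral <- neutralizing_cation_count(net_lipid, q_ca)
  n_pairs <- ion_pairs_for_concentration(salt_conc, n_water)
  n_ca <- as.integer(n_neutral) + n_pairs
  n_cl <- 2L * n_pairs
  net <- net_lipid + n_ca * q_ca + n_cl * q_cl
  out <- list(
    n_pc = as.integer(n_pc), n_ps = as.integer(n_ps),
    n_lipids = as.integer(n_pc + n_ps),
    net_lipid_charge = net_lipid, n_water = as.integer(n_water),
    f = f, ca_charge = q_ca, cl_charge = q_cl,
    n_ca_neutralizing = as.integer(n_neutral), n_salt_pairs = n_pairs,
    n_ca = n_ca, n_cl = n_cl,
    nominal_conc = nominal_concentration(n_pairs, n_water),
    net_system_charge = net
  )
  if (abs(net) > 1e-9)
    warning(sprintf("system is not neutral: net charge %+g e", net))
  structure(out, class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("bilayer composition:\n")
  cat(sprintf("  lipids: %d PC + %d PS (net lipid charge %+g e)\n",
              x$n_pc, x$n_ps, x$net_lipid_charge))
  cat(sprintf("  water: %d molecules\n", x$n_water))
  cat(sprintf("  ions (f = %.2f): %d Ca2+ (%+g e; %d neutralizing) + %d Cl- (%+g e)\n",
              x$f, x$n_ca, x$ca_charge, x$n_ca_neutralizing, x$n_cl, x$cl_charge))
  cat(sprintf("  nominal added CaCl2: %.4g mol/L; net system charge %+.3g e\n",
              x$nominal_conc, x$net_system_charge))
  invisible(x)
}
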