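#' Molar mass of 3-hydroxybutyrate (free acid, C4H8O3)
#'
#' Used to convert an oral dose in grams into the millimole amount placed in
#' the gastrointestinal depot compartment at time zero.
#'
#' @format Numeric scalar, g/mol.
#' @export
HB_MOLAR_MASS <- 104.10

#' Parameter set for the one-compartment oral 3-HB model
#'
#' Bundles the six kinetic parameters of the model: systemic clearance,
#' baseline (endogenous steady-state) serum concentration, first-order
#' absorption rate constant, Michaelis constant times gut-compartment volume,
#' volume of distribution, and maximum saturable absorption rate. The
#' endogenous production rate is always `CL * C0` and is never stored
#' separately.
#'
#' @param CL Systemic clearance, L/min. Must be > 0.
#' @param C0 Baseline serum 3-HB concentration, mM. Must be >= 0.
#' @param ka First-order (non-saturable) absorption rate constant, 1/min.
#'   `ka = 0` removes the non-saturable pathway.
#' @param Km_prime Michaelis constant multiplied by the gut compartment
#'   volume, mmol (half-saturation amount). Must be > 0.
#' @param Vd Volume of distribution, L. Must be > 0.
#' @param Vmax Maximum saturable absorption rate, mmol/min. `Vmax = 0`
#'   removes the saturable pathway.
#' @param molar_mass Dose conversion constant, g/mol. Defaults to
#'   [HB_MOLAR_MASS].
#'
#' @return An object of class `pk_params` (a named list).
#' @examples
#' p <- pk_params(CL = 1.82, C0 = 0.063, ka = 0.02, Km_prime = 30,
#'                Vd = 85.7, Vmax = 0.5)
#' p
#' @export
pk_params <- function(CL, C0, ka, Km_prime, Vd, Vmax,
                      molar_mass = HB_MOLAR_MASS) {
  p <- list(CL = CL, C0 = C0, ka = ka, Km_prime = Km_prime,
            Vd = Vd, Vmax = Vmax, molar_mass = molar_mass)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax", "molar_mass")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  if (p$CL <= 0) stop("CL must be > 0")
  if (p$C0 < 0) stop("C0 must be >= 0")
  if (p$ka < 0) stop("ka must be >= 0")
  if (p$Km_prime <= 0) stop("Km_prime must be > 0")
  if (p$Vd <= 0) stop("Vd must be > 0")
  if (p$Vmax < 0) stop("Vmax must be >= 0")
  if (p$molar_mass <= 0) stop("molar_mass must be > 0")
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment oral 3-HB model parameters\n")
  cat(sprintf("  CL       %.4g L/min   (endogenous production CL*C0 = %.4g mmol/min)\n",
              x$CL, x$CL * x$C0))
  cat(sprintf("  C0       %.4g mM\n", x$C0))
  cat(sprintf("  ka       %.4g /min\n", x$ka))
  cat(sprintf("  Km'      %.4g mmol\n", x$Km_prime))
  cat(sprintf("  Vd       %.4g L\n", x$Vd))
  cat(sprintf("  Vmax     %.4g mmol/min\n", x$Vmax))
  invisible(x)
}

#' Convert an oral dose in grams to millimoles
#'
#' @param dose_g Oral dose, g. Must be >= 0.
#' @param molar_mass Molar mass, g/mol.
#' @return Dose amount in mmol (`1000 * dose_g / molar_mass`).
#' @examples
#' dose_mmol(2)  # 2 g of 3-HB
#' @export
dose_mmol <- function(dose_g, molar_mass = HB_MOLAR_MASS) {
  stopifnot(is.numeric(dose_g), all(dose_g >= 0), molar_mass > 0)
  1000 * dose_g / molar_mass
}

#' Model variants of the absorption pathway
#'
#' The full model has both a saturable (Michaelis-Menten) and a non-saturable
#' (first-order) gastrointestinal absorption pathway. The reduced variants
#' keep only one of the two: `"nonsaturable_only"` forces `Vmax = 0`,
#' `"saturable_only"` forces `ka = 0`.
#'
#' @param variant One of `"full"`, `"nonsaturable_only"`, `"saturable_only"`.
#' @return The matched variant string.
#' @export
pk_variant <- function(variant = c("full", "nonsaturable_only", "saturable_only")) {
  match.arg(variant)
}

# Apply a variant's parameter mask (zero the removed pathway).
apply_variant <- function(params, variant) {
  variant <- pk_variant(variant)
  if (variant == "nonsaturable_only") params$Vmax <- 0
  if (variant == "saturable_only") params$ka <- 0
  params
}

# Names of the kinetic parameters free under each variant.
variant_free_params <- function(variant) {
  switch(pk_variant(variant),
         full = c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax"),
         nonsaturable_only = c("CL", "C0", "ka", "Vd"),
         saturable_only = c("CL", "C0", "Km_prime", "Vd", "Vmax"))
}
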